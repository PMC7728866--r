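# shared fixtures, built in code

toy_item <- function(a, b, id = "toy", scale = "toy") {
  item_bank(id, scale, "target", a, list(b))
}

# a small random bank with given per-item category counts
random_bank <- function(ks, seed, scale = "rnd") {
  set.seed(seed)
  th <- lapply(ks, function(k) sort(runif(k - 1L, -2, 2.5)))
  item_bank(sprintf("%s_it%02d", scale, seq_along(ks)), scale, "target",
            runif(length(ks), 1.2, 4), th)
}

anxiety_bank <- function() {
  b <- nrs_proctcae_bank()
  b[b$scale_id == "anxiety", ]
}

# exhaustive response-pattern oracle for P(summed score | theta)
enumerate_score_likelihoods <- function(bank, grid) {
  th <- item_thresholds(bank)
  probs <- lapply(seq_len(nrow(bank)), function(j)
    grm_prob(list(slope = bank$slope[j], thresholds = th[[j]]), grid$points))
  ks <- bank$n_categories
  patterns <- expand.grid(lapply(ks, function(k) 0:(k - 1L)))
  S <- sum(ks - 1L)
  L <- matrix(0, S + 1L, length(grid$points))
  for (r in seq_len(nrow(patterns))) {
    p <- rep(1, length(grid$points))
    for (j in seq_along(ks)) p <- p * probs[[j]][patterns[[j]][r] + 1L, ]
    s <- sum(patterns[r, ])
    L[s + 1L, ] <- L[s + 1L, ] + p
  }
  L
}
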