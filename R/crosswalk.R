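#' Summed-score likelihoods by the Lord-Wingersky recursion
#'
#' Computes `L[s, q] = P(summed score = s | theta_q)` for a set of
#' polytomous GRM items by dynamic-programming convolution: initialize
#' with the first item's category probabilities at each grid point, then
#' fold in each subsequent item by convolving over its categories. Every
#' column is a proper probability distribution over the possible summed
#' scores `0 .. sum(K_i - 1)`.
#'
#' @param bank an [item_bank()] on a common metric.
#' @param grid a [normal_quadrature()] grid.
#' @return An `(S+1) x Q` matrix with rownames `0:S`; each column sums
#'   to 1.
#' @export
summed_score_likelihoods <- function(bank, grid = normal_quadrature()) {
  validate_item_bank(bank)
  if (nrow(bank) == 0L) stop("empty item bank")
  th <- item_thresholds(bank)
  Q <- length(grid$points)
  L <- grm_prob(list(slope = bank$slope[1L], thresholds = th[[1L]]),
                grid$points)
  if (nrow(bank) > 1L) for (j in 2:nrow(bank)) {
    P <- grm_prob(list(slope = bank$slope[j], thresholds = th[[j]]),
                  grid$points)
    Snew <- nrow(L) + nrow(P) - 1L
    Lnew <- matrix(0, Snew, Q)
    for (k in seq_len(nrow(P)))
      Lnew[(k - 1L) + seq_len(nrow(L)), ] <-
        Lnew[(k - 1L) + seq_len(nrow(L)), ] + L * rep(P[k, ], each = nrow(L))
    L <- Lnew
  }
  rownames(L) <- 0:(nrow(L) - 1L)
  L
}

#' Summed-score EAP latent-trait estimates
#'
#' For each possible summed score `s`, forms the posterior over the grid,
#' `posterior_q proportional to L[s, q] w_q` (the grid weights act as the
#' latent prior), and returns its mean and standard deviation. Under the
#' GRM the summed score has a monotone likelihood ratio in theta, so the
#' EAP is strictly increasing in `s`.
#'
#' @inheritParams summed_score_likelihoods
#' @return Data frame: `raw_score`, `eap`, `posterior_sd`.
#' @export
summed_score_eap <- function(bank, grid = normal_quadrature()) {
  L <- summed_score_likelihoods(bank, grid)
  post <- L * rep(grid$weights, each = nrow(L))
  norm <- rowSums(post)
  if (any(norm <= 0))
    stop("a summed score has zero prior-weighted likelihood everywhere")
  post <- post / norm
  eap <- as.numeric(post %*% grid$points)
  v <- rowSums(post * outer(eap, grid$points, function(m, t) (t - m)^2))
  data.frame(raw_score = 0:(nrow(L) - 1L), eap = eap,
             posterior_sd = sqrt(v))
}

#' Build a raw-score to T-score crosswalk table
#'
#' Maps each possible summed raw score on a measure to the PROMIS-style
#' T-score metric, `T = 50 + 10 theta`, via [summed_score_eap()]; the
#' reported SE is 10 times the posterior SD (the usual summed-score-EAP
#' convention). Item parameters must already be on the reference (anchor)
#' metric. Raw scores are reported with an optional display offset so
#' instruments whose native codes start at 1 (PRO-CTCAE) print naturally.
#'
#' @param bank an [item_bank()] of the measure's items (a single row for
#'   single-item measures), on the reference metric.
#' @param grid a [normal_quadrature()] grid; weights define the EAP prior.
#' @param observed_counts optional integer vector of per-raw-score
#'   respondent counts (length S+1, in score order).
#' @param measure_id label for the table (defaults to the first item id).
#' @param raw_offset added to the internal 0-based raw score for display.
#' @param t_mean,t_sd the reporting metric (defaults 50, 10).
#' @return A data frame of class `crosswalk_table` with columns
#'   `raw_score`, `t_score`, `se`, and `n` (NA when no counts are given);
#'   T-scores and SEs are kept at full precision, rounding to one decimal
#'   is applied only when printing.
#' @examples
#' xw <- build_crosswalk(item_bank("nrs_anxiety", "anxiety", "target", 2.99,
#'   c(-0.63, -0.08, 0.33, 0.63, 0.85, 1.13, 1.41, 1.73, 2.16, 2.79)))
#' print(xw)  # raw 0 -> T 39.9 (SE 6.8)
#' @export
build_crosswalk <- function(bank, grid = normal_quadrature(),
                            observed_counts = NULL,
                            measure_id = bank$item_id[1L],
                            raw_offset = 0L, t_mean = 50, t_sd = 10) {
  eap <- summed_score_eap(bank, grid)
  out <- data.frame(raw_score = eap$raw_score + raw_offset,
                    t_score = t_mean + t_sd * eap$eap,
                    se = t_sd * eap$posterior_sd,
                    n = NA_integer_)
  if (!is.null(observed_counts)) {
    if (length(observed_counts) != nrow(out))
      stop("observed_counts must have one entry per possible raw score")
    out$n <- as.integer(observed_counts)
  }
  class(out) <- c("crosswalk_table", "data.frame")
  attr(out, "measure_id") <- measure_id
  attr(out, "prior") <- sprintf("normal grid prior, %d points on [%g, %g]",
                                length(grid$points), min(grid$points),
                                max(grid$points))
  out
}

#' @export
print.crosswalk_table <- function(x, ...) {
  cat("Crosswalk table:", attr(x, "measure_id"), "\n")
  disp <- data.frame(raw_score = x$raw_score,
                     t_score = sprintf("%.1f", x$t_score),
                     se = sprintf("%.1f", x$se),
                     n = ifelse(is.na(x$n), "", x$n))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
plot.crosswalk_table <- function(x, ...) {
  graphics::plot(x$raw_score, x$t_score, type = "b", pch = 16,
                 xlab = "Raw score", ylab = "T-score",
                 main = attr(x, "measure_id"), ...)
  graphics::arrows(x$raw_score, x$t_score - x$se,
                   x$raw_score, x$t_score + x$se,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Write a crosswalk table as delimited text
#'
#' @param x a `crosswalk_table`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "crosswalk_table"))
  df <- as.data.frame(x)
  df$t_score <- round(df$t_score, 4)
  df$se <- round(df$se, 4)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Reverse-code ordinal responses
#'
#' Maps code `x` to `(k - 1) - x`, an involution. Used for items keyed in
#' the opposite direction from their domain (e.g. a sleep-quality rating
#' recoded to sleep disturbance).
#'
#' @param responses integer codes in `[0, k-1]` (NA allowed).
#' @param k number of categories.
#' @return The reverse-coded vector.
#' @export
reverse_code <- function(responses, k) {
  ok <- !is.na(responses)
  if (any(responses[ok] < 0L | responses[ok] > k - 1L))
    stop("codes outside [0, k-1]")
  (k - 1L) - responses
}
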