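test_that("the summed-score recursion reduces to the item probabilities for one item", {
  grid <- normal_quadrature(21L, -4, 4)
  bank <- random_bank(c(5L), seed = 3)
  L <- summed_score_likelihoods(bank, grid)
  expect_equal(unname(L), unname(grm_prob(bank, grid$points)),
               tolerance = 1e-14)
})

test_that("the recursion equals exhaustive pattern enumeration", {
  grid <- normal_quadrature(15L, -4, 4)
  configs <- list(c(4L, 4L, 4L), c(5L, 3L, 2L), c(5L, 5L, 5L, 5L),
                  c(2L, 2L), c(3L, 5L, 4L, 2L))
  for (i in seq_along(configs)) {
    bank <- random_bank(configs[[i]], seed = 40 + i)
    L <- summed_score_likelihoods(bank, grid)
    expect_lt(max(abs(L - enumerate_score_likelihoods(bank, grid))), 1e-12)
    expect_equal(colSums(L), rep(1, 15), tolerance = 1e-12)
  }
})

test_that("summed-score EAP is monotone and symmetric where the model is", {
  bank <- random_bank(c(4L, 5L, 4L), seed = 6)
  eap <- summed_score_eap(bank)
  expect_true(all(diff(eap$eap) > 0))
  expect_true(all(eap$posterior_sd > 0))
  # symmetric item under a symmetric prior: the middle score maps to 0
  sym <- toy_item(2.2, c(-1.5, -0.5, 0.5, 1.5))
  es <- summed_score_eap(sym, normal_quadrature(101L, -6, 6))
  expect_equal(es$eap[3], 0, tolerance = 1e-10)
  expect_equal(es$eap, -rev(es$eap), tolerance = 1e-10)
})

test_that("EAP matches a direct integration oracle on a two-item bank", {
  bank <- random_bank(c(3L, 4L), seed = 18)
  grid <- normal_quadrature(61L, -5, 5)
  eap <- summed_score_eap(bank, grid)
  L <- enumerate_score_likelihoods(bank, grid)   # independent of recursion
  for (s in 0:5) {
    post <- L[s + 1, ] * grid$weights
    post <- post / sum(post)
    m <- sum(grid$points * post)
    expect_equal(eap$eap[s + 1], m, tolerance = 1e-10)
    expect_equal(eap$posterior_sd[s + 1],
                 sqrt(sum((grid$points - m)^2 * post)), tolerance = 1e-10)
  }
})

test_that("crosswalk tables live on the T metric, strictly increasing", {
  bank <- anxiety_bank()
  xw <- build_crosswalk(bank[bank$item_id == "nrs_anxiety", ])
  expect_s3_class(xw, "crosswalk_table")
  expect_identical(nrow(xw), 11L)
  expect_true(all(diff(xw$t_score) > 0))
  expect_true(all(xw$se > 0))
  # degenerate binary item
  xw2 <- build_crosswalk(toy_item(1.8, 0.4))
  expect_identical(nrow(xw2), 2L)
  expect_lt(xw2$t_score[1], xw2$t_score[2])
  # display offset for 1-based instruments
  xw3 <- build_crosswalk(bank[bank$item_id == "ctcae_anxiety_severity", ],
                         raw_offset = 1L)
  expect_identical(xw3$raw_score, 1:5)
})

test_that("doubling the quadrature barely moves any T-score", {
  bank <- nrs_proctcae_bank()
  for (id in c("nrs_pain_intensity", "ctcae_fatigue_severity")) {
    one <- bank[bank$item_id == id, ]
    t1 <- build_crosswalk(one, normal_quadrature(101L, -6, 6))$t_score
    t2 <- build_crosswalk(one, normal_quadrature(201L, -6, 6))$t_score
    expect_lt(max(abs(t1 - t2)), 0.05)
  }
})

test_that("observed counts attach by score and mismatches are rejected", {
  bank <- toy_item(2, c(-1, 0, 1))
  xw <- build_crosswalk(bank, observed_counts = c(5L, 10L, 3L, 2L))
  expect_identical(xw$n, c(5L, 10L, 3L, 2L))
  expect_error(build_crosswalk(bank, observed_counts = 1:3), "one entry")
})

test_that("reverse coding is an involution on the valid range", {
  expect_identical(reverse_code(0L, 11L), 10L)
  x <- c(0L, 4L, 10L, NA, 7L)
  expect_identical(reverse_code(reverse_code(x, 11L), 11L), x)
  expect_error(reverse_code(11L, 11L), "codes outside")
  # a reverse-coded item's crosswalk mirrors the original's category order
  bank <- random_bank(c(5L), seed = 2)
  dat <- simulate_cohort(500, bank, seed = 2)
  rev_counts <- tabulate(reverse_code(dat$responses[, 1], 5L) + 1L, 5L)
  expect_identical(rev_counts, rev(tabulate(dat$responses[, 1] + 1L, 5L)))
})
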