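test_that("the marginal log-likelihood never decreases across EM cycles", {
  bank <- random_bank(c(4L, 4L, 5L, 3L), seed = 31)
  dat <- simulate_cohort(400, bank, seed = 31)
  fit <- grm_calibrate(dat, control = grm_control(max_iter = 60))
  expect_gt(length(fit$ll_trace), 3)
  expect_true(all(diff(fit$ll_trace) > -1e-6 * abs(fit$ll_trace[-1])))
})

test_that("estimates are invariant to person order", {
  bank <- random_bank(c(4L, 5L), seed = 5)
  dat <- simulate_cohort(300, bank, seed = 5)
  perm <- rev(seq_len(nrow(dat$responses)))
  dat2 <- response_matrix(dat$responses[perm, ], dat$n_categories,
                          dat$covariates[perm, ])
  ctl <- grm_control(max_iter = 40)
  f1 <- grm_calibrate(dat, control = ctl)
  f2 <- grm_calibrate(dat2, control = ctl)
  # agreement up to floating-point summation order in the E-step
  expect_equal(coef(f1)$slope, coef(f2)$slope, tolerance = 1e-5)
  expect_equal(item_thresholds(coef(f1)), item_thresholds(coef(f2)),
               tolerance = 1e-5)
})

test_that("fixed anchors are returned bit-for-bit and fixing all items skips estimation", {
  bank <- random_bank(c(4L, 4L, 5L), seed = 12)
  bank$role <- "anchor"
  dat <- simulate_cohort(200, bank, seed = 12)
  fit <- grm_calibrate(dat, anchor = bank)
  expect_identical(coef(fit)$slope, bank$slope)
  expect_identical(item_thresholds(coef(fit)), item_thresholds(bank))
  expect_identical(fit$n_iterations, 1L)
  expect_true(fit$converged)
  # mixed fit: anchors untouched, targets free
  half <- bank[1:2, ]
  fit2 <- grm_calibrate(dat, anchor = half,
                        control = grm_control(max_iter = 30))
  est <- coef(fit2)
  m <- match(half$item_id, est$item_id)
  expect_identical(est$slope[m], half$slope)
  expect_identical(item_thresholds(est)[m], item_thresholds(half))
  expect_identical(sort(fit2$fixed_item_ids), sort(half$item_id))
  expect_true(all(est$role[m] == "anchor"))
})

test_that("degenerate items and unresolvable anchors raise clear errors", {
  resp <- cbind(itA = rep(1L, 50), itB = rbinom(50, 3, 0.5))
  dat <- response_matrix(resp, n_categories = c(3L, 4L))
  expect_error(grm_calibrate(dat), "itA")
  bank <- random_bank(c(4L), seed = 1)
  dat2 <- simulate_cohort(100, bank, seed = 1)
  ghost <- bank; ghost$item_id <- "missing_item"
  expect_error(grm_calibrate(dat2, anchor = ghost), "absent")
})

test_that("a free calibration with a standard-normal prior recovers the generating metric", {
  bank <- random_bank(c(5L, 5L, 5L, 5L, 5L, 5L), seed = 77)
  dat <- simulate_cohort(1500, bank, seed = 77)
  fit <- grm_calibrate(dat)
  expect_true(fit$converged)
  est <- coef(fit)
  m <- match(bank$item_id, est$item_id)
  expect_lt(mean(abs(est$slope[m] - bank$slope)), 0.25)
  expect_lt(mean(abs(unlist(item_thresholds(est)[m]) -
                       unlist(item_thresholds(bank)))), 0.12)
})

test_that("model methods expose the fit coherently", {
  bank <- random_bank(c(4L, 5L), seed = 8)
  dat <- simulate_cohort(400, bank, seed = 8)
  fit <- grm_calibrate(dat, control = grm_control(max_iter = 40))
  expect_output(print(fit), "Graded response model")
  s <- summary(fit)
  expect_output(print(s), "log-likelihood")
  expect_lt(max(s$max_abs_residual), 0.05)
  expect_s3_class(coef(fit), "item_bank")
  expect_equal(as.numeric(logLik(fit)), fit$log_likelihood)
  expect_equal(predict(fit, 0, type = "tcc"), tcc(coef(fit), 0))
  sim <- simulate(fit, nsim = 2, seed = 3, n_persons = 50)
  expect_length(sim, 2)
  expect_identical(dim(sim[[1]]$responses), c(50L, 2L))
  res <- residuals(fit)
  expect_equal(sum(res$observed) - sum(res$implied), 0, tolerance = 1e-8)
})

test_that("screen_items flags sparse and empty categories without collapsing", {
  full <- response_matrix(cbind(it = rep(0:3, each = 25)), 4L)
  sc <- screen_items(full, min_count = 10L)
  expect_false(any(sc$flagged))
  gap <- response_matrix(cbind(it = rep(c(0L, 1L, 3L), 30)), 4L)
  sc2 <- screen_items(gap, min_count = 5L)
  expect_true(sc2$flagged[sc2$category == 2])
  expect_identical(attr(sc2, "at_risk"), "it")
  # a small cohort on an 11-category item leaves the top categories sparse
  nrs <- nrs_proctcae_bank()
  nrs <- nrs[nrs$item_id == "nrs_depression", ]
  small <- simulate_cohort(50, nrs, seed = 6)
  sc3 <- screen_items(small, min_count = 5L)
  top <- sc3[sc3$category >= 9, ]
  expect_true(all(top$flagged))
  expect_identical(sc3$count,
                   as.integer(tabulate(small$responses[, 1] + 1L, 11L)))
})
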