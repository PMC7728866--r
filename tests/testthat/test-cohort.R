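test_that("cohort generation is reproducible and respects the missingness spec", {
  bank <- random_bank(c(5L, 11L, 4L), seed = 50)
  d1 <- simulate_cohort(300, bank, seed = 99, missing_rate = 0.1)
  d2 <- simulate_cohort(300, bank, seed = 99, missing_rate = 0.1)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$covariates, d2$covariates)
  d3 <- simulate_cohort(300, bank, seed = 98, missing_rate = 0.1)
  expect_false(identical(d1$responses, d3$responses))
  d0 <- simulate_cohort(300, bank, seed = 99)
  expect_false(anyNA(d0$responses))
  frac <- mean(is.na(d1$responses))
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
  expect_true(all(rowSums(!is.na(d1$responses)) >= 1))
  expect_error(simulate_cohort(100, bank, missing_rate = 1), "missing_rate")
})

test_that("observed category margins converge to the quadrature-implied margins", {
  bank <- anxiety_bank()
  grid <- normal_quadrature(201L, -8, 8)
  dat <- simulate_cohort(2000, bank, seed = 4)
  err2000 <- c()
  for (j in seq_len(nrow(bank))) {
    implied <- as.numeric(grm_prob(bank[j, ], grid$points) %*% grid$weights)
    obs <- tabulate(dat$responses[, j] + 1L, bank$n_categories[j]) / 2000
    err2000 <- c(err2000, abs(obs - implied))
  }
  # binomial sampling noise at n = 2000 has sd up to ~0.011 per category
  expect_lt(max(err2000), 0.035)
  expect_lt(mean(err2000), 0.01)
  big <- simulate_cohort(20000, bank, seed = 4)
  errbig <- c()
  for (j in seq_len(nrow(bank))) {
    implied <- as.numeric(grm_prob(bank[j, ], grid$points) %*% grid$weights)
    obs <- tabulate(big$responses[, j] + 1L, bank$n_categories[j]) / 20000
    errbig <- c(errbig, abs(obs - implied))
  }
  expect_lt(mean(errbig), mean(err2000))   # shrinking error with n
})

test_that("latent subgroup shifts propagate to observed-score smd with matching sign", {
  bank <- make_anchor_bank("dom", 6, seed = 13)
  dat <- simulate_cohort(3000, bank, seed = 13,
                         subgroup_effects = list(older = 0.4))
  score <- rowSums(dat$responses)
  older <- dat$covariates$age >= 60
  smd <- standardized_mean_difference(score, older)
  expect_gt(smd, 0.15)   # same sign, attenuated by categorization
  flipped <- simulate_cohort(3000, bank, seed = 13,
                             subgroup_effects = list(older = -0.4))
  smd2 <- standardized_mean_difference(rowSums(flipped$responses),
                                       flipped$covariates$age >= 60)
  expect_lt(smd2, -0.15)
})

test_that("injected uniform DIF shifts responses only in the designated subgroup", {
  bank <- random_bank(c(5L, 5L), seed = 22)
  clean <- simulate_cohort(800, bank, seed = 22)
  dif <- simulate_cohort(800, bank, seed = 22,
                         dif_items = list(rnd_it01 = 0.8), dif_group = "older")
  younger <- clean$covariates$age < 60
  expect_identical(clean$responses[younger, ], dif$responses[younger, ])
  expect_identical(clean$responses[, "rnd_it02"], dif$responses[, "rnd_it02"])
  older_scores_clean <- mean(clean$responses[!younger, "rnd_it01"])
  older_scores_dif <- mean(dif$responses[!younger, "rnd_it01"])
  expect_lt(older_scores_dif, older_scores_clean)  # harder thresholds, lower scores
  expect_error(simulate_cohort(100, bank, dif_items = list(ghost = 1)),
               "absent")
})

test_that("synthetic anchor banks are valid, seed-stable, and seed-distinct", {
  b1 <- make_anchor_bank("fatigue", 8, seed = 1)
  expect_silent(validate_item_bank(b1))
  expect_identical(nrow(b1), 8L)
  expect_true(all(b1$role == "anchor"))
  expect_true(all(b1$slope >= 1.5 & b1$slope <= 4.5))
  expect_identical(b1$slope, make_anchor_bank("fatigue", 8, seed = 1)$slope)
  expect_false(identical(b1$slope, make_anchor_bank("fatigue", 8, seed = 2)$slope))
  # demographics follow the default mix
  dat <- simulate_cohort(4000, b1, seed = 1)
  expect_equal(mean(dat$covariates$gender == "F"), 0.61, tolerance = 0.03)
  expect_equal(mean(dat$covariates$age), 56.4, tolerance = 1)
  expect_true(all(dat$covariates$age >= 18 & dat$covariates$age <= 89))
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  bank <- random_bank(c(4L), seed = 1)
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_cohort(50, bank, seed = 7))
  expect_identical(rnorm(1), before)
})
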