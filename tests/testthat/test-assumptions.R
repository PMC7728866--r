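test_that("pearson correlation obeys its algebra and its preconditions", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- 0.5 * x + rnorm(100)
  expect_equal(pearson_correlation(3 * x - 2, 10 * y + 5),
               pearson_correlation(x, y), tolerance = 1e-12)
  x[1:3] <- NA
  expect_equal(pearson_correlation(x, x), 1)   # pairwise deletion
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_correlation(c(1, NA), c(1, 2)), "3 complete")
})

test_that("standardized mean difference is exact under construction and antisymmetric", {
  set.seed(2)
  base <- rnorm(200)
  scores <- c(base, base)
  grp <- rep(c(TRUE, FALSE), each = 200)
  expect_equal(standardized_mean_difference(scores, grp), 0)
  pooled <- sqrt(stats::var(base))   # equal groups
  shifted <- c(base + pooled, base)
  expect_equal(standardized_mean_difference(shifted, grp), 1, tolerance = 1e-12)
  d1 <- standardized_mean_difference(shifted, grp)
  d2 <- standardized_mean_difference(shifted, !grp)
  expect_equal(d1, -d2)
  expect_error(standardized_mean_difference(base, rep(TRUE, 200)), "2 observations")
})

test_that("the invariance screen applies a strict 0.10 rule per split", {
  anchor <- c(gender = 0.05, age = -0.26)
  tgt <- list(
    clean = c(gender = 0.05, age = -0.26),
    boundary = c(gender = 0.05, age = -0.16),     # delta exactly 0.10
    interference = c(gender = 0.05, age = -0.13)  # delta 0.13
  )
  scr <- invariance_screen(tgt, anchor)
  dec <- tapply(scr$exclude, scr$measure_id, any)
  expect_false(dec[["clean"]])
  expect_false(dec[["boundary"]])   # strict inequality: 0.10 still links
  expect_true(dec[["interference"]])
  expect_identical(unique(scr$reason[scr$measure_id == "interference"]),
                   "smd_invariance")
  expect_error(invariance_screen(tgt, c(0.1, 0.2)), "named")
})

test_that("bivariate-normal cell probabilities match an independent implementation", {
  tau_x <- c(-1, 0, 0.7, 1.5)
  tau_y <- c(-0.8, 0.1, 0.9, 1.8)
  for (rho in c(-0.7, 0, 0.55, 0.9)) {
    cells <- prolink:::.bvn_cells(tau_x, tau_y, rho)
    expect_equal(sum(cells), 1, tolerance = 1e-10)
    bx <- c(-Inf, tau_x, Inf); by <- c(-Inf, tau_y, Inf)
    S <- matrix(c(1, rho, rho, 1), 2)
    oracle <- outer(1:5, 1:5, Vectorize(function(i, j)
      mvtnorm::pmvnorm(c(bx[i], by[j]), c(bx[i + 1], by[j + 1]), sigma = S)))
    expect_lt(max(abs(cells - oracle)), 1e-9)
  }
})

test_that("polychoric correlation recovers the generating latent correlation", {
  set.seed(11)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  cuts1 <- c(-0.8, 0, 0.9); cuts2 <- c(-0.5, 0.6)
  x <- findInterval(z1, cuts1); y <- findInterval(z2, cuts2)
  expect_equal(polychoric_correlation(x, y), 0.6, tolerance = 0.05)
  y0 <- findInterval(rnorm(n), cuts2)
  expect_equal(polychoric_correlation(x, y0), 0, tolerance = 0.05)
  expect_gt(polychoric_correlation(x, x), 0.99)
  expect_error(polychoric_correlation(rep(0L, 50), rep(c(0L, 1L), 25)),
               "2 observed categories")
})

test_that("the polychoric matrix is symmetric, unit-diagonal, and PSD", {
  bank <- random_bank(c(4L, 4L, 5L, 3L), seed = 21)
  dat <- simulate_cohort(600, bank, seed = 21)
  R <- polychoric_matrix(dat)
  expect_equal(R, t(R))
  expect_equal(diag(R), setNames(rep(1, 4), colnames(dat$responses)))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(R[upper.tri(R)] > 0.25))  # common latent trait
})

test_that("omega_h separates general-factor structures from clustered ones", {
  # constructed loading structures, no sampling noise
  make_R <- function(load, p = 9) {
    R <- tcrossprod(rep(load, p)); diag(R) <- 1; R
  }
  expect_gte(omega_hierarchical(make_R(0.7), 3L), 0.85)
  # two independent clusters: no general variance
  blk <- tcrossprod(rep(0.7, 4)); diag(blk) <- 1
  R2 <- as.matrix(Matrix::bdiag(blk, blk))
  expect_lt(suppressWarnings(omega_hierarchical(R2, 2L)), 0.1)
  # monotone in the strength of the general factor
  oms <- vapply(c(0.4, 0.6, 0.8),
                function(l) omega_hierarchical(make_R(l), 3L), 0)
  expect_true(all(diff(oms) > 0))
  expect_true(all(oms >= 0 & oms <= 1))
  expect_error(omega_hierarchical(make_R(0.7), 5L), "2 or 3")
})

test_that("the domain assumption report screens, decides, and explains", {
  anchors <- make_anchor_bank("anxiety", 8, seed = 11)
  gen <- combine_banks(anchors, anxiety_bank())
  tm <- list(nrs_anxiety = "nrs_anxiety",
             ctcae_anxiety_severity = "ctcae_anxiety_severity")
  dat <- simulate_cohort(1200, gen, seed = 33)
  rep <- assumption_report(dat, anchors$item_id, tm, "anxiety")
  expect_s3_class(rep, "assumption_report")
  expect_true(all(abs(rep$correlations) <= 1))
  expect_gte(rep$omega_h, 0.70)
  expect_identical(rep$decisions$measure_id, names(tm))
  expect_true(all(rep$decisions$link))
  expect_output(print(rep), "omega_h")
  # advisory correlation rule: flag but do not block by default
  expect_false(any(rep$decisions$reason == "low_correlation"))
})
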