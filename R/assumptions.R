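#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; pairs with any missing
#'   value are dropped.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x[ok], y[ok])
}

#' Standardized mean difference between two groups
#'
#' `(mean(group1) - mean(group2)) / pooled SD`, with the pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. By convention
#' group 1 is the focal group (female, or the older age group), so the
#' reported sign is focal minus reference.
#'
#' @param scores numeric vector (missing values dropped with their
#'   labels).
#' @param group logical or two-level vector; `TRUE` (or the first level
#'   encountered sorted decreasingly, e.g. `"F"` before `"M"` is *not*
#'   assumed — pass logical for clarity) marks the focal group.
#' @return The standardized mean difference.
#' @export
standardized_mean_difference <- function(scores, group) {
  ok <- !is.na(scores) & !is.na(group)
  scores <- scores[ok]; group <- group[ok]
  if (!is.logical(group)) stop("group must be logical (TRUE = focal group)")
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 observations")
  s1 <- stats::var(scores[group]); s2 <- stats::var(scores[!group])
  pooled <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero")
  (mean(scores[group]) - mean(scores[!group])) / pooled
}

#' Subgroup-invariance screen for linking
#'
#' Compares each target measure's standardized mean difference (smd) with
#' the anchor's smd on the same persons, for each subgroup split. A
#' measure is flagged for exclusion when `|smd_target - smd_anchor|`
#' exceeds the threshold (strict inequality) in any split: similar smds
#' support the assumption that the linking relationship is invariant
#' across the subgroups.
#'
#' @param target_smd named list (one element per measure) of named numeric
#'   vectors of smds, e.g. `list(nrs = c(gender = .1, age = .2))`.
#' @param anchor_smd named numeric vector of the anchor's smds on the same
#'   splits.
#' @param threshold exclusion threshold on the absolute smd delta
#'   (default 0.10).
#' @return Data frame: `measure_id`, `split`, `smd`, `anchor_smd`,
#'   `delta`, `exclude`, `reason` (`"smd_invariance"` or `""`).
#' @export
invariance_screen <- function(target_smd, anchor_smd, threshold = 0.10) {
  if (is.null(names(anchor_smd)) || !length(anchor_smd))
    stop("anchor_smd must be a named vector of subgroup smds")
  rows <- lapply(names(target_smd), function(m) {
    s <- target_smd[[m]]
    if (!all(names(anchor_smd) %in% names(s)))
      stop("measure ", m, " is missing smds for some splits")
    d <- abs(s[names(anchor_smd)] - anchor_smd)
    data.frame(measure_id = m, split = names(anchor_smd),
               smd = as.numeric(s[names(anchor_smd)]),
               anchor_smd = as.numeric(anchor_smd),
               delta = as.numeric(d),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  excl <- tapply(out$delta > threshold, out$measure_id, any)
  out$exclude <- as.logical(excl[out$measure_id])
  out$reason <- ifelse(out$exclude, "smd_invariance", "")
  out
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1]
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b; J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1L, idx]^2)
}

# P(a1 < X < a2, Y in each band) for standard bivariate normal with
# correlation rho: Gauss-Legendre in x, exact normal CDF bands in y.
.bvn_cells <- function(tau_x, tau_y, rho, gl = .gauss_legendre(24L)) {
  bx <- c(-8.5, tau_x, 8.5); by <- c(-Inf, tau_y, Inf)
  s <- sqrt(1 - rho^2)
  nx <- length(bx) - 1L; ny <- length(by) - 1L
  out <- matrix(0, nx, ny)
  for (j in seq_len(nx)) {
    mid <- (bx[j + 1L] + bx[j]) / 2; half <- (bx[j + 1L] - bx[j]) / 2
    x <- mid + half * gl$nodes
    wx <- half * gl$weights * stats::dnorm(x)
    cum <- vapply(by[-1L], function(b)
      if (is.infinite(b)) rep(1, length(x))
      else stats::pnorm((b - rho * x) / s), numeric(length(x)))
    band <- cum - cbind(0, cum[, -ny, drop = FALSE])
    out[j, ] <- colSums(wx * band)
  }
  out
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimate: thresholds from the marginal category proportions
#' by the inverse normal CDF, then maximum likelihood for the latent
#' correlation given the observed contingency table, the bivariate-normal
#' cell probabilities being evaluated by Gauss-Legendre quadrature.
#'
#' @param x,y integer category codes (0-based, NA dropped pairwise).
#' @return The estimated latent correlation.
#' @export
polychoric_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("both variables need at least 2 observed categories")
  tau_x <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  tau_y <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  gl <- .gauss_legendre(24L)
  nll <- function(rho) {
    p <- pmax(.bvn_cells(tau_x, tau_y, rho, gl), 1e-12)
    -sum(tab * log(p))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation matrix
#'
#' Pairwise two-step polychoric correlations over all items of a response
#' matrix, forced positive-semidefinite by eigenvalue clipping when
#' needed.
#'
#' @param data a [response_matrix()] (>= 2 items).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  r <- data$responses
  p <- ncol(r)
  if (p < 2L) stop("need at least 2 items")
  R <- diag(p)
  dimnames(R) <- list(colnames(r), colnames(r))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
    R[i, j] <- R[j, i] <- polychoric_correlation(r[, i], r[, j])
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 1e-6)
    R <- e$vectors %*% diag(v) %*% t(e$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(colnames(r), colnames(r))
  }
  R
}

# iterated principal-axes factoring; returns unrotated loadings
.principal_axes <- function(R, nf, max_iter = 200L, tol = 1e-6) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  h2 <- pmin(pmax(smc, 0.05), 0.995)
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R; diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(nf), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(nf)], 0)), nf)
    h2new <- rowSums(L^2)
    if (any(h2new > 0.995)) { heywood <- TRUE; h2new <- pmin(h2new, 0.995) }
    if (max(abs(h2new - h2)) < tol) { h2 <- h2new; break }
    h2 <- h2new
  }
  if (heywood)
    warning("Heywood case: communalities clipped to 0.995")
  # stable column signs: make each column sum positive
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L %*% diag(sgn, nf)
}

#' Omega hierarchical from a correlation matrix
#'
#' Estimates the proportion of total score variance attributable to a
#' general factor: principal-axes factoring with `n_group_factors` group
#' factors, an oblique rotation, a single higher-order factor extracted
#' from the factor correlations, and a Schmid-Leiman orthogonalization.
#' The statistic is `(sum of general-factor loadings)^2 / (sum of all
#' entries of the correlation matrix)`; values of 0.70 or more are the
#' conventional benchmark for "unidimensional enough to calibrate".
#'
#' The oblique rotation is promax (the oblique method shipped with base
#' R); with a strong general factor the statistic is insensitive to the
#' choice within the oblique family.
#'
#' @param corr correlation matrix (e.g. from [polychoric_matrix()]).
#' @param n_group_factors number of group factors (2 or 3; >= 3 items per
#'   group factor recommended).
#' @return `omega_h` in `[0, 1]`.
#' @export
omega_hierarchical <- function(corr, n_group_factors = 3L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  nf <- as.integer(n_group_factors)
  if (!nf %in% c(2L, 3L)) stop("n_group_factors must be 2 or 3")
  if (nrow(corr) < 3L * nf)
    warning("fewer than 3 items per group factor; solution may be unstable")
  L <- .principal_axes(corr, nf)
  # drop group factors that carry no loading (essentially unidimensional
  # input): rotation is undefined for an empty factor
  keep <- sqrt(colSums(L^2)) > 0.05
  if (sum(keep) < 2L) {
    g <- L[, which.max(colSums(L^2))]
    if (sum(g) < 0) g <- -g
    return(min(max(sum(g)^2 / sum(corr), 0), 1))
  }
  L <- L[, keep, drop = FALSE]
  nf <- ncol(L)
  rot <- stats::promax(L)
  P <- unclass(rot$loadings)
  U <- rot$rotmat
  ui <- solve(U)
  Phi <- stats::cov2cor(ui %*% t(ui))
  # align factor signs so general loadings are positive on balance
  sgn <- ifelse(colSums(P) < 0, -1, 1)
  P <- P %*% diag(sgn, nf)
  Phi <- diag(sgn, nf) %*% Phi %*% diag(sgn, nf)
  # higher-order general factor from the factor correlations
  gamma <- if (nf == 2L) {
    rep(sqrt(max(min(Phi[1L, 2L], 1), 0)), 2L)
  } else {
    drop(.principal_axes(Phi, 1L, max_iter = 100L))
  }
  g <- drop(P %*% gamma)       # Schmid-Leiman general-factor loadings
  omega <- sum(g)^2 / sum(corr)
  min(max(omega, 0), 1)
}

#' Full linking-assumption report for one domain
#'
#' Runs the three screens for a domain: (1) Pearson correlation between
#' each target measure's raw score and the anchor summed score, flagged
#' (advisory) below `r_threshold`; (2) subgroup smd invariance by gender
#' (female minus male) and age (older minus younger at `age_split`), with
#' measures excluded when the smd delta against the anchor exceeds
#' `smd_threshold`; (3) omega hierarchical of the polychoric correlations
#' of all items combined, flagged below `omega_threshold`.
#'
#' The correlation rule is advisory rather than blocking: a correlation
#' slightly below the conventional .75 bound is reported but does not by
#' itself exclude a measure. Exclusion decisions carry machine-readable
#' reasons (`low_correlation` only when `block_low_correlation = TRUE`).
#'
#' @param data a [response_matrix()] containing anchor and target items,
#'   with `gender` and `age` covariates.
#' @param anchor_items character vector of anchor item ids.
#' @param target_measures named list: measure id -> character vector of
#'   the item ids forming that measure (usually length 1).
#' @param scale_id domain label.
#' @param r_threshold advisory lower bound on the correlation.
#' @param smd_threshold exclusion threshold on the absolute smd delta.
#' @param omega_threshold benchmark for omega hierarchical.
#' @param n_group_factors group factors for [omega_hierarchical()].
#' @param age_split age cut for the older/younger subgroups.
#' @param block_low_correlation if `TRUE`, a low correlation excludes the
#'   measure rather than only flagging it.
#' @return An object of class `assumption_report`: list with `scale_id`,
#'   `correlations`, `smd` (long table from [invariance_screen()]),
#'   `omega_h`, and `decisions` (measure, link yes/no, reason).
#' @export
assumption_report <- function(data, anchor_items, target_measures,
                              scale_id = "scale",
                              r_threshold = 0.75, smd_threshold = 0.10,
                              omega_threshold = 0.70,
                              n_group_factors = 3L, age_split = 60,
                              block_low_correlation = FALSE) {
  stopifnot(inherits(data, "response_matrix"))
  cov <- data$covariates
  if (is.null(cov) || !all(c("gender", "age") %in% names(cov)))
    stop("data must carry gender and age covariates")
  resp <- data$responses
  if (!all(anchor_items %in% colnames(resp)))
    stop("anchor items absent from data")
  anchor_score <- rowSums(resp[, anchor_items, drop = FALSE])
  female <- cov$gender == "F"
  older <- cov$age >= age_split

  meas_score <- lapply(target_measures, function(it)
    rowSums(resp[, it, drop = FALSE]))
  r <- vapply(meas_score, pearson_correlation, 0, y = anchor_score)
  anchor_smd <- c(gender = standardized_mean_difference(anchor_score, female),
                  age = standardized_mean_difference(anchor_score, older))
  smd_by <- lapply(meas_score, function(s)
    c(gender = standardized_mean_difference(s, female),
      age = standardized_mean_difference(s, older)))
  smd_tab <- invariance_screen(smd_by, anchor_smd, smd_threshold)

  omega <- omega_hierarchical(polychoric_matrix(data), n_group_factors)

  excl_smd <- tapply(smd_tab$exclude, smd_tab$measure_id, any)
  decisions <- data.frame(measure_id = names(target_measures),
                          r = as.numeric(r),
                          low_correlation = as.numeric(r) < r_threshold,
                          stringsAsFactors = FALSE)
  decisions$link <- !as.logical(excl_smd[decisions$measure_id])
  decisions$reason <- ifelse(!decisions$link, "smd_invariance", "")
  if (block_low_correlation) {
    newly <- decisions$link & decisions$low_correlation
    decisions$link[newly] <- FALSE
    decisions$reason[newly] <- "low_correlation"
  }
  structure(list(scale_id = scale_id, correlations = r,
                 anchor_smd = anchor_smd, smd = smd_tab,
                 omega_h = omega, omega_threshold = omega_threshold,
                 decisions = decisions),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Linking-assumption report:", x$scale_id, "\n")
  cat(sprintf("  omega_h = %.3f (benchmark >= %.2f)\n",
              x$omega_h, x$omega_threshold))
  cat("  measure decisions:\n")
  d <- x$decisions
  for (i in seq_len(nrow(d)))
    cat(sprintf("    %-28s r = %.2f  %s%s\n", d$measure_id[i], d$r[i],
                if (d$link[i]) "link" else "exclude",
                if (nzchar(d$reason[i])) paste0(" (", d$reason[i], ")") else ""))
  invisible(x)
}

#' Write an assumption report as delimited text
#'
#' @param report an `assumption_report`.
#' @param path output file for the per-measure decision table.
#' @return `path`, invisibly.
#' @export
write_assumption_report <- function(report, path) {
  stopifnot(inherits(report, "assumption_report"))
  d <- report$decisions
  d$omega_h <- report$omega_h
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
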