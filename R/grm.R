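#' Graded-response-model category probabilities
#'
#' Computes `P(X = k | theta)` for an ordered-category item under
#' Samejima's graded response model on the logistic metric: the boundary
#' ("operating characteristic") curves are
#' `P*_k(theta) = 1 / (1 + exp(-a (theta - b_k)))` for k = 1..K-1, with
#' `P*_0 = 1` and `P*_K = 0`, and category probabilities are their
#' successive differences.
#'
#' @param item a one-row [item_bank()], or a list with elements `slope` and
#'   `thresholds`.
#' @param theta numeric vector of latent-trait values.
#' @return A `K x length(theta)` matrix of category probabilities; each
#'   column sums to 1.
#' @examples
#' it <- list(slope = 2, thresholds = 0)
#' grm_prob(it, 0)   # c(0.5, 0.5)
#' @export
grm_prob <- function(item, theta) {
  ab <- .item_ab(item)
  if (any(!is.finite(theta))) stop("theta must be finite")
  K <- length(ab$b) + 1L
  # boundary curves: (K-1) x Q
  ps <- 1 / (1 + exp(-ab$a * outer(ab$b, theta, function(b, t) t - b)))
  pstar <- rbind(rep(1, length(theta)), ps, rep(0, length(theta)))
  pstar[1:K, , drop = FALSE] - pstar[2:(K + 1L), , drop = FALSE]
}

.item_ab <- function(item) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    list(a = item$slope, b = item_thresholds(item)[[1L]])
  } else {
    stopifnot(is.numeric(item$slope), item$slope > 0)
    b <- item$thresholds
    if (is.unsorted(b, strictly = TRUE)) stop("thresholds must be strictly increasing")
    list(a = item$slope, b = b)
  }
}

#' Expected item score
#'
#' `E(X | theta) = sum_k k P_k(theta)`, a continuous nondecreasing function
#' of the latent trait bounded by 0 and K-1 (0-based category codes).
#'
#' @inheritParams grm_prob
#' @return Numeric vector of expected scores, one per `theta`.
#' @export
expected_score <- function(item, theta) {
  p <- grm_prob(item, theta)
  drop(crossprod(p, seq_len(nrow(p)) - 1))[seq_along(theta)]
}

#' Test characteristic curve
#'
#' Expected summed score of a set of items as a function of the latent
#' trait: the sum of the per-item expected scores. The TCC is the object
#' the Stocking-Lord criterion matches between two calibrations.
#'
#' @param bank an [item_bank()] (one or more rows).
#' @param theta numeric vector of latent-trait values.
#' @return Numeric vector of expected summed scores, one per `theta`.
#' @export
tcc <- function(bank, theta) {
  if (nrow(bank) == 0L) stop("empty item bank")
  th <- item_thresholds(bank)
  out <- numeric(length(theta))
  for (i in seq_len(nrow(bank)))
    out <- out + expected_score(list(slope = bank$slope[i], thresholds = th[[i]]),
                                theta)
  out
}

#' Equally spaced normal quadrature grid
#'
#' A grid of equally spaced points with weights proportional to a normal
#' density, renormalized to sum to one. The default (101 points on
#' `[-6, 6]`, standard normal) is the latent prior used for calibration and
#' summed-score EAP scoring throughout the package; it is wider than the
#' `[-4, 4]` range over which linking results are usually displayed so that
#' posteriors of extreme scores are not clipped.
#'
#' @param n_points number of points (>= 2).
#' @param lo,hi grid bounds, `lo < hi`.
#' @param mean,sd mean and standard deviation of the weighting density.
#' @return A list of class `quadrature` with elements `points` and
#'   `weights`.
#' @export
normal_quadrature <- function(n_points = 101L, lo = -6, hi = 6,
                              mean = 0, sd = 1) {
  if (n_points < 2L) stop("n_points must be >= 2")
  if (!(lo < hi)) stop("need lo < hi")
  if (sd <= 0) stop("sd must be > 0")
  pts <- seq(lo, hi, length.out = n_points)
  w <- stats::dnorm(pts, mean, sd)
  structure(list(points = pts, weights = w / sum(w)), class = "quadrature")
}

#' @export
print.quadrature <- function(x, ...) {
  cat(sprintf("Quadrature grid: %d points on [%.3g, %.3g]\n",
              length(x$points), min(x$points), max(x$points)))
  invisible(x)
}
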