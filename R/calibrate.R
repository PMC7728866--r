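#' Control parameters for GRM calibration
#'
#' @param max_iter maximum number of EM cycles.
#' @param tol convergence: largest absolute change in any item parameter
#'   (slope or threshold, natural scale) between cycles.
#' @param mstep_maxit BFGS iteration cap per item per M-step.
#' @return A list of class `grm_control`.
#' @export
grm_control <- function(max_iter = 500L, tol = 1e-4, mstep_maxit = 50L) {
  stopifnot(max_iter >= 1L, tol > 0, mstep_maxit >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 mstep_maxit = as.integer(mstep_maxit)),
            class = "grm_control")
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM estimation of Samejima's graded response model for ordinal response
#' data, with the latent trait integrated over a fixed quadrature grid
#' whose weights define the population prior (standard normal by default,
#' which identifies the metric). Three calibration variants are covered:
#'
#' * **free / concurrent** (`anchor = NULL`): every item's slope and
#'   thresholds are estimated; with anchor and target items in `data`
#'   this is a concurrent calibration on an arbitrary (prior-identified)
#'   metric.
#' * **fixed-anchor** (`anchor` = an [item_bank()]): the anchor items'
#'   parameters are held at their established values in every M-step, so
#'   the freely estimated target items land directly on the anchor-defined
#'   metric.
#'
#' The E-step computes each person's posterior over the grid; the M-step
#' maximizes the expected complete-data log-likelihood item by item with
#' BFGS on an unconstrained reparameterization (log-slope; first threshold
#' plus log-gaps), which guarantees positive slopes and strictly ordered
#' thresholds. Missing responses contribute nothing to the person
#' likelihood (ignorable missingness). The observed marginal
#' log-likelihood is nondecreasing across cycles.
#'
#' @param data a [response_matrix()]; every item needs at least two
#'   observed categories.
#' @param anchor optional `item_bank` of fixed items; its `item_id`s must
#'   occur among `data`'s items.
#' @param grid a [normal_quadrature()] grid; its weights are the latent
#'   prior.
#' @param scale_id domain label stored on the estimated bank.
#' @param control a [grm_control()] list.
#' @return An object of class `grm_fit`; see [coef.grm_fit()],
#'   [summary.grm_fit()], [plot.grm_fit()], [simulate.grm_fit()].
#' @examples
#' bank <- make_anchor_bank("demo", 4, seed = 7)
#' dat <- simulate_cohort(300, bank, seed = 7)
#' fit <- grm_calibrate(dat, control = grm_control(max_iter = 50))
#' coef(fit)
#' @export
grm_calibrate <- function(data, anchor = NULL,
                          grid = normal_quadrature(),
                          scale_id = "scale",
                          control = grm_control()) {
  stopifnot(inherits(data, "response_matrix"))
  resp <- data$responses
  ids <- colnames(resp)
  K <- data$n_categories
  for (j in seq_along(ids)) {
    obs <- sum(tabulate(resp[, j] + 1L, nbins = K[j]) > 0L)
    if (obs < 2L)
      stop("item ", ids[j], " has fewer than 2 observed categories; cannot calibrate")
  }
  fixed <- logical(length(ids))
  params <- .grm_start(resp, K)
  if (!is.null(anchor)) {
    validate_item_bank(anchor)
    if (!all(anchor$item_id %in% ids))
      stop("anchor items absent from data: ",
           paste(setdiff(anchor$item_id, ids), collapse = ", "))
    ath <- item_thresholds(anchor)
    for (i in seq_len(nrow(anchor))) {
      j <- match(anchor$item_id[i], ids)
      if (length(ath[[i]]) != K[j] - 1L)
        stop("anchor item ", anchor$item_id[i],
             ": category count disagrees with data")
      params[[j]] <- list(a = anchor$slope[i], b = ath[[i]])
      fixed[j] <- TRUE
    }
  }

  theta <- grid$points
  logw <- log(grid$weights)
  n <- nrow(resp); Q <- length(theta)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: person log-likelihood over the grid
    ll <- matrix(0, n, Q)
    logP <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      P <- grm_prob(list(slope = params[[j]]$a, thresholds = params[[j]]$b), theta)
      logP[[j]] <- log(pmax(P, 1e-300))
      x <- resp[, j]
      ok <- !is.na(x)
      ll[ok, ] <- ll[ok, ] + logP[[j]][x[ok] + 1L, , drop = FALSE]
    }
    lw <- sweep(ll, 2L, logw, "+")
    m <- apply(lw, 1L, max)
    post <- exp(lw - m)
    rs <- rowSums(post)
    ll_trace <- c(ll_trace, sum(m + log(rs)))
    post <- post / rs

    # M-step per free item
    delta <- 0
    for (j in seq_along(ids)) {
      if (fixed[j]) next
      x <- resp[, j]
      ok <- !is.na(x)
      r <- rowsum(post[ok, , drop = FALSE], group = x[ok], reorder = TRUE)
      rfull <- matrix(0, K[j], Q)
      rfull[as.integer(rownames(r)) + 1L, ] <- r
      new <- .grm_mstep(params[[j]], rfull, theta, control$mstep_maxit)
      delta <- max(delta, abs(new$a - params[[j]]$a),
                   if (length(new$b)) max(abs(new$b - params[[j]]$b)) else 0)
      params[[j]] <- new
    }
    if (all(fixed)) { converged <- TRUE; break }
    if (delta < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }

  bank <- item_bank(ids, scale_id, ifelse(fixed, "anchor", "target"),
                    vapply(params, `[[`, 0, "a"),
                    lapply(params, `[[`, "b"))
  structure(list(bank = bank, log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, n_iterations = iter,
                 converged = converged, fixed_item_ids = ids[fixed],
                 grid = grid, data = data,
                 call = match.call()),
            class = "grm_fit")
}

# start values: slope 1.5, thresholds from observed cumulative proportions
.grm_start <- function(resp, K) {
  lapply(seq_len(ncol(resp)), function(j) {
    x <- resp[, j]; x <- x[!is.na(x)]
    cnt <- tabulate(x + 1L, nbins = K[j])
    p_ge <- rev(cumsum(rev(cnt)))[-1L] / length(x)  # P(X >= k), k=1..K-1
    b <- -stats::qlogis(pmin(pmax(p_ge, 1e-3), 1 - 1e-3)) / 1.5
    # enforce strict ordering for degenerate marginals
    for (k in seq_along(b)[-1L]) if (b[k] <= b[k - 1L]) b[k] <- b[k - 1L] + 1e-3
    list(a = 1.5, b = b)
  })
}

# maximize the expected complete-data log-likelihood for one item;
# par = (log a, b1, log(b2-b1), ...) keeps a > 0 and b strictly ordered
.grm_mstep <- function(par0, r, theta, maxit) {
  b0 <- par0$b
  p0 <- c(log(par0$a), b0[1L],
          if (length(b0) > 1L) log(pmax(diff(b0), 1e-6)))
  fit <- stats::optim(p0, .grm_ecll, .grm_ecll_grad, r = r, theta = theta,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  .par_decode(fit$par)
}

.par_decode <- function(p) {
  a <- exp(p[1L])
  gaps <- pmax(exp(p[-(1:2)]), 1e-6)   # keep thresholds strictly ordered
  b <- if (length(p) == 2L) p[2L] else p[2L] + c(0, cumsum(gaps))
  list(a = a, b = b)
}

# category probabilities without input validation (internal hot path)
.grm_P <- function(a, b, theta) {
  K <- length(b) + 1L
  pstar <- rbind(rep(1, length(theta)),
                 1 / (1 + exp(-a * outer(b, theta, function(b, t) t - b))),
                 rep(0, length(theta)))
  pstar[1:K, , drop = FALSE] - pstar[2:(K + 1L), , drop = FALSE]
}

# negative expected complete-data log-likelihood
.grm_ecll <- function(p, r, theta) {
  if (any(!is.finite(p)) || any(abs(p) > 30)) return(1e10)
  ab <- .par_decode(p)
  -sum(r * log(pmax(.grm_P(ab$a, ab$b, theta), 1e-12)))
}

.grm_ecll_grad <- function(p, r, theta) {
  if (any(!is.finite(p)) || any(abs(p) > 30)) return(numeric(length(p)))
  ab <- .par_decode(p)
  a <- ab$a; b <- ab$b
  Km1 <- length(b); K <- Km1 + 1L
  tmb <- outer(b, theta, function(b, t) t - b)     # (K-1) x Q, theta - b_k
  pstar <- 1 / (1 + exp(-a * tmb))
  w <- pstar * (1 - pstar)
  P <- rbind(rep(1, length(theta)), pstar, rep(0, length(theta)))
  P <- pmax(P[1:K, , drop = FALSE] - P[2:(K + 1L), , drop = FALSE], 1e-12)
  g <- r / P                                       # K x Q
  D <- g[2:K, , drop = FALSE] - g[1:Km1, , drop = FALSE]  # df/dpstar_k
  dfda <- sum(D * w * tmb)
  dfdb <- -a * rowSums(D * w)
  # chain rule through (log a, b1, log-gaps)
  gr <- c(a * dfda, sum(dfdb),
          if (Km1 > 1L) exp(p[-(1:2)]) * rev(cumsum(rev(dfdb[-1L]))))
  -gr
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("Graded response model fit (MML-EM)\n")
  cat(sprintf("  %d persons, %d items (%d fixed anchors)\n",
              nrow(x$data$responses), nrow(x$bank),
              length(x$fixed_item_ids)))
  cat(sprintf("  log-likelihood %.2f after %d EM cycles (%sconverged)\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Extract estimated item parameters
#'
#' @param object a `grm_fit`.
#' @param ... unused.
#' @return The estimated [item_bank()].
#' @export
coef.grm_fit <- function(object, ...) object$bank

#' @export
logLik.grm_fit <- function(object, ...) {
  p <- sum(object$bank$n_categories[!object$bank$item_id %in%
                                      object$fixed_item_ids])
  structure(object$log_likelihood, df = p, class = "logLik",
            nobs = nrow(object$data$responses))
}

#' Summarize a GRM calibration
#'
#' @param object a `grm_fit`.
#' @param ... unused.
#' @return A list of class `summary.grm_fit` with the parameter table,
#'   convergence information, and the largest absolute marginal-proportion
#'   residual per item (observed vs model-implied category proportions).
#' @export
summary.grm_fit <- function(object, ...) {
  res <- residuals(object)
  worst <- tapply(abs(res$residual), res$item_id, max)
  structure(list(bank = object$bank,
                 log_likelihood = object$log_likelihood,
                 n_iterations = object$n_iterations,
                 converged = object$converged,
                 fixed_item_ids = object$fixed_item_ids,
                 max_abs_residual = worst),
            class = "summary.grm_fit")
}

#' @export
print.summary.grm_fit <- function(x, ...) {
  cat("Graded response model calibration\n\n")
  print(x$bank)
  cat(sprintf("\nlog-likelihood %.2f; %d EM cycles; converged: %s\n",
              x$log_likelihood, x$n_iterations, x$converged))
  if (length(x$fixed_item_ids))
    cat("fixed anchors:", paste(x$fixed_item_ids, collapse = ", "), "\n")
  cat("largest |observed - implied| category proportion per item:\n")
  print(round(x$max_abs_residual, 4))
  invisible(x)
}

#' Marginal category-proportion residuals
#'
#' Observed minus model-implied marginal category proportions per item,
#' the implied proportions being the quadrature average of the category
#' probabilities under the fitted prior. A coarse absolute-fit diagnostic.
#'
#' @param object a `grm_fit`.
#' @param ... unused.
#' @return Data frame: `item_id`, `category`, `observed`, `implied`,
#'   `residual`.
#' @export
residuals.grm_fit <- function(object, ...) {
  th <- item_thresholds(object$bank)
  out <- lapply(seq_len(nrow(object$bank)), function(j) {
    x <- object$data$responses[, object$bank$item_id[j]]
    x <- x[!is.na(x)]
    K <- object$bank$n_categories[j]
    obs <- tabulate(x + 1L, nbins = K) / length(x)
    P <- grm_prob(list(slope = object$bank$slope[j], thresholds = th[[j]]),
                  object$grid$points)
    imp <- as.numeric(P %*% object$grid$weights)
    data.frame(item_id = object$bank$item_id[j], category = 0:(K - 1L),
               observed = obs, implied = imp, residual = obs - imp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Predicted expected scores from a fitted calibration
#'
#' @param object a `grm_fit`.
#' @param theta latent-trait values at which to evaluate.
#' @param type `"tcc"` for the expected summed score over all items, or
#'   `"item"` for a matrix of per-item expected scores.
#' @param ... unused.
#' @export
predict.grm_fit <- function(object, theta = seq(-4, 4, by = 0.1),
                            type = c("tcc", "item"), ...) {
  type <- match.arg(type)
  if (type == "tcc") return(tcc(object$bank, theta))
  th <- item_thresholds(object$bank)
  out <- sapply(seq_len(nrow(object$bank)), function(j)
    expected_score(list(slope = object$bank$slope[j], thresholds = th[[j]]),
                   theta))
  colnames(out) <- object$bank$item_id
  out
}

#' Simulate response data from a fitted calibration
#'
#' Draws new cohorts from the fitted item parameters with a standard
#' normal latent distribution (parametric-bootstrap style).
#'
#' @param object a `grm_fit`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_persons cohort size (defaults to the fitted sample size).
#' @param ... passed to [simulate_cohort()].
#' @return A list of [response_matrix()] objects (length `nsim`).
#' @export
simulate.grm_fit <- function(object, nsim = 1, seed = 1L,
                             n_persons = nrow(object$data$responses), ...) {
  lapply(seq_len(nsim), function(s)
    simulate_cohort(n_persons, object$bank, seed = seed + s - 1L, ...))
}

#' Plot test or item characteristic curves of a fitted calibration
#'
#' @param x a `grm_fit`.
#' @param type `"tcc"` or `"icc"` (expected score per item).
#' @param theta evaluation grid.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grm_fit <- function(x, type = c("tcc", "icc"),
                         theta = seq(-4, 4, by = 0.1), ...) {
  type <- match.arg(type)
  if (type == "tcc") {
    graphics::plot(theta, tcc(x$bank, theta), type = "l",
                   xlab = expression(theta), ylab = "Expected summed score",
                   main = "Test characteristic curve", ...)
  } else {
    es <- predict(x, theta, type = "item")
    graphics::matplot(theta, es, type = "l", lty = 1,
                      xlab = expression(theta), ylab = "Expected item score",
                      main = "Item characteristic curves", ...)
    graphics::legend("topleft", colnames(es), col = seq_len(ncol(es)),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
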