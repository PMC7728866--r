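#' Simulate a single-group-design cohort
#'
#' Draws latent traits from a normal distribution, applies optional
#' subgroup mean shifts and uniform DIF (threshold shifts in one
#' subgroup), and samples graded-response-model category codes for every
#' item in `bank`. The defaults emulate the observed-study conditions the
#' package's validation harness assumes: a single group answering anchor
#' and target measures together, 61% female, age roughly normal with mean
#' 56.4 and SD 12.5 truncated to 18-89 years.
#'
#' @param n_persons number of respondents.
#' @param bank an [item_bank()] with the generating parameters.
#' @param theta_mean,theta_sd latent-trait population mean and SD.
#' @param prop_female probability of gender `"F"`.
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param subgroup_effects named list of latent mean shifts added for
#'   members of a subgroup, e.g. `list(female = 0.2, older = -0.1)`
#'   (`older` means age >= `age_split`).
#' @param age_split age cut defining the older subgroup.
#' @param dif_items named list: for each item id, a threshold shift added
#'   to all of that item's thresholds for the `dif_group` subgroup only
#'   (uniform DIF).
#' @param dif_group `"older"` or `"female"`.
#' @param missing_rate probability, applied independently per cell, that a
#'   response is missing completely at random.
#' @param seed integer seed; the draw is fully reproducible.
#' @return A [response_matrix()] with `gender` and `age` covariates and a
#'   `theta` attribute holding the generating latent traits.
#' @export
simulate_cohort <- function(n_persons, bank,
                            theta_mean = 0, theta_sd = 1,
                            prop_female = 0.61,
                            age_mean = 56.4, age_sd = 12.5,
                            age_range = c(18, 89),
                            subgroup_effects = list(),
                            age_split = 60,
                            dif_items = list(),
                            dif_group = "older",
                            missing_rate = 0,
                            seed = 1L) {
  validate_item_bank(bank)
  stopifnot(n_persons >= 1L, theta_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (length(dif_items) && is.null(names(dif_items)))
    stop("dif_items must be a named list of threshold shifts")
  if (!all(names(dif_items) %in% bank$item_id))
    stop("dif_items refer to items absent from the bank")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  gender <- ifelse(stats::runif(n_persons) < prop_female, "F", "M")
  age <- stats::qnorm(stats::runif(n_persons,
                                   stats::pnorm(age_range[1], age_mean, age_sd),
                                   stats::pnorm(age_range[2], age_mean, age_sd)),
                      age_mean, age_sd)
  shift <- numeric(n_persons)
  if (!is.null(subgroup_effects$female))
    shift <- shift + subgroup_effects$female * (gender == "F")
  if (!is.null(subgroup_effects$older))
    shift <- shift + subgroup_effects$older * (age >= age_split)
  theta <- stats::rnorm(n_persons, theta_mean + shift, theta_sd)

  in_dif_group <- switch(dif_group,
                         older = age >= age_split,
                         female = gender == "F",
                         stop("dif_group must be 'older' or 'female'"))
  th <- item_thresholds(bank)
  resp <- matrix(NA_integer_, n_persons, nrow(bank),
                 dimnames = list(NULL, bank$item_id))
  for (j in seq_len(nrow(bank))) {
    id <- bank$item_id[j]
    dshift <- if (id %in% names(dif_items)) dif_items[[id]] else 0
    resp[, j] <- .draw_grm(bank$slope[j], th[[j]], theta,
                           ifelse(in_dif_group, dshift, 0))
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(resp)) < missing_rate, nrow(resp))
    # never blank out a person's entire row: keep one response
    full <- rowSums(!drop) == 0L
    if (any(full)) drop[full, 1L] <- FALSE
    resp[drop] <- NA_integer_
  }
  out <- response_matrix(resp, bank$n_categories,
                         data.frame(gender = gender, age = age,
                                    stringsAsFactors = FALSE))
  attr(out, "theta") <- theta
  out
}

# inverse-CDF draw from the GRM: one uniform per person, compared against
# the person's cumulative boundary curves (optionally DIF-shifted)
.draw_grm <- function(a, b, theta, bshift) {
  u <- stats::runif(length(theta))
  x <- integer(length(theta))
  for (k in seq_along(b)) {
    pstar <- 1 / (1 + exp(-a * (theta - (b[k] + bshift))))
    x <- x + (u < pstar)
  }
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a plausible synthetic anchor bank
#'
#' The previously established calibrations of the PROMIS anchor short
#' forms are not redistributable, so validation runs use synthetic anchor
#' items: 5-category items with slopes in `[1.5, 4.5]` and threshold
#' midpoints spread over `[-1.5, 2.5]`, deterministic for a given seed.
#' Anchor-dependent quantities are therefore validated in distribution
#' only, never against published values.
#'
#' @param scale_id domain name for all generated items.
#' @param n_items number of anchor items (>= 2).
#' @param seed integer seed.
#' @param n_categories categories per item.
#' @return An `item_bank` with `role = "anchor"`.
#' @export
make_anchor_bank <- function(scale_id, n_items, seed = 1L,
                             n_categories = 5L) {
  stopifnot(n_items >= 2L, n_categories >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  slopes <- stats::runif(n_items, 1.5, 4.5)
  mids <- seq(-1.5, 2.5, length.out = n_items) +
    stats::runif(n_items, -0.3, 0.3)
  K <- n_categories
  th <- lapply(seq_len(n_items), function(i) {
    gaps <- stats::runif(K - 2L, 0.5, 1.2)
    b <- mids[i] + c(0, cumsum(gaps))
    b - mean(b) + mids[i]
  })
  item_bank(sprintf("%s_anchor%02d", scale_id, seq_len(n_items)),
            scale_id, "anchor", slopes, th, instrument = "synthetic-anchor")
}
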