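#' Construct an item-parameter bank
#'
#' An item bank is a data frame holding graded-response-model (GRM) item
#' parameters on the logistic metric (no 1.7 scaling constant): one row per
#' item with a positive discrimination (`slope`) and `n_categories - 1`
#' strictly increasing category boundary locations stored in columns
#' `b1`, `b2`, ... (trailing columns `NA` for items with fewer categories).
#'
#' @param item_id character vector of unique item identifiers.
#' @param scale_id character vector naming the domain each item measures
#'   (e.g. `"anxiety"`).
#' @param role `"anchor"` (parameters define the metric) or `"target"`
#'   (parameters to be placed on the anchor metric).
#' @param slope positive discriminations.
#' @param thresholds a list with one numeric vector of ordered boundary
#'   locations per item, or a single numeric vector when one item is given.
#' @param instrument optional character vector naming the instrument family
#'   (e.g. `"NRS"`, `"PRO-CTCAE"`).
#' @return A data frame of class `item_bank`.
#' @examples
#' item_bank("nrs_anxiety", "anxiety", "target", 2.99,
#'           list(c(-0.63, -0.08, 0.33, 0.63, 0.85,
#'                  1.13, 1.41, 1.73, 2.16, 2.79)))
#' @export
item_bank <- function(item_id, scale_id, role, slope, thresholds,
                      instrument = NA_character_) {
  if (is.numeric(thresholds)) thresholds <- list(thresholds)
  n <- length(item_id)
  stopifnot(length(slope) == n, length(thresholds) == n)
  scale_id <- rep_len(scale_id, n)
  role <- rep_len(role, n)
  instrument <- rep_len(instrument, n)
  kmax <- max(vapply(thresholds, length, 1L))
  bmat <- matrix(NA_real_, n, kmax,
                 dimnames = list(NULL, paste0("b", seq_len(kmax))))
  for (i in seq_len(n)) bmat[i, seq_along(thresholds[[i]])] <- thresholds[[i]]
  bank <- data.frame(item_id = unname(as.character(item_id)),
                     scale_id = unname(as.character(scale_id)),
                     instrument = unname(as.character(instrument)),
                     role = unname(as.character(role)),
                     n_categories = unname(vapply(thresholds, length, 1L) + 1L),
                     slope = unname(as.numeric(slope)),
                     bmat,
                     row.names = NULL,
                     stringsAsFactors = FALSE)
  class(bank) <- c("item_bank", "data.frame")
  validate_item_bank(bank)
  bank
}

#' Validate an item bank
#'
#' Checks the `item_bank` invariants: unique ids, positive slopes, strictly
#' increasing thresholds, and `n_categories` consistent with the number of
#' non-missing boundary columns.
#'
#' @param bank an `item_bank`.
#' @return `bank`, invisibly; stops with an informative error otherwise.
#' @export
validate_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank))
  need <- c("item_id", "scale_id", "role", "n_categories", "slope")
  if (!all(need %in% names(bank)))
    stop("item bank is missing columns: ",
         paste(setdiff(need, names(bank)), collapse = ", "))
  if (anyDuplicated(bank$item_id))
    stop("duplicated item_id in bank")
  if (any(!is.finite(bank$slope)) || any(bank$slope <= 0))
    stop("all slopes must be finite and > 0")
  if (any(!bank$role %in% c("anchor", "target")))
    stop("role must be 'anchor' or 'target'")
  th <- item_thresholds(bank)
  for (i in seq_len(nrow(bank))) {
    b <- th[[i]]
    if (length(b) != bank$n_categories[i] - 1L)
      stop("item ", bank$item_id[i], ": n_categories inconsistent with thresholds")
    if (length(b) && (any(!is.finite(b)) || is.unsorted(b, strictly = TRUE)))
      stop("item ", bank$item_id[i], ": thresholds must be finite and strictly increasing")
  }
  invisible(bank)
}

#' Extract per-item threshold vectors
#'
#' @param bank an `item_bank`.
#' @return A named list with one numeric vector of boundary locations per item.
#' @export
item_thresholds <- function(bank) {
  bcols <- grep("^b[0-9]+$", names(bank), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  out <- lapply(seq_len(nrow(bank)), function(i) {
    b <- as.numeric(bank[i, bcols])
    b[seq_len(bank$n_categories[i] - 1L)]
  })
  names(out) <- bank$item_id
  out
}

#' Combine item banks
#'
#' Stacks two or more banks whose items may have different category
#' counts, padding the threshold columns as needed.
#'
#' @param ... `item_bank` objects.
#' @return A single `item_bank`.
#' @export
combine_banks <- function(...) {
  banks <- list(...)
  for (b in banks) validate_item_bank(b)
  th <- unlist(lapply(banks, item_thresholds), recursive = FALSE)
  item_bank(unlist(lapply(banks, `[[`, "item_id")),
            unlist(lapply(banks, `[[`, "scale_id")),
            unlist(lapply(banks, `[[`, "role")),
            unlist(lapply(banks, `[[`, "slope")),
            th,
            unlist(lapply(banks, `[[`, "instrument")))
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x), "items,",
      length(unique(x$scale_id)), "scale(s)\n")
  print.data.frame(x, digits = 3, row.names = FALSE, ...)
  invisible(x)
}

#' Read an item-parameter bank from a delimited file
#'
#' Expects columns `item_id`, `scale_id`, `role`, `slope`, and `b1`, `b2`,
#' ... with trailing thresholds empty for items with fewer categories.
#' Additional columns (e.g. `instrument`, linking constants) are carried
#' through.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return An `item_bank`.
#' @export
read_item_bank <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  df$n_categories <- rowSums(!is.na(df[, bcols, drop = FALSE])) + 1L
  if (is.null(df$instrument)) df$instrument <- NA_character_
  class(df) <- c("item_bank", "data.frame")
  validate_item_bank(df)
  df
}

#' Write an item-parameter bank to a delimited file
#'
#' @param bank an `item_bank`.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, sep = ",") {
  validate_item_bank(bank)
  utils::write.table(as.data.frame(bank), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Calibrated bank for the NRS and PRO-CTCAE symptom items
#'
#' Returns the published graded-response-model parameters of the five 0-10
#' numeric-rating-scale items (11 categories) and fifteen PRO-CTCAE items
#' (5 categories) on the PROMIS T-score metric, after concurrent calibration
#' and Stocking-Lord transformation. Columns `sl_a` and `sl_b` carry the
#' linking constants that were applied per domain.
#'
#' Category codes are 0-based throughout the package; the PRO-CTCAE native
#' 1-5 response scale maps to internal codes 0-4 (the `code_offset` column
#' records the display offset).
#'
#' @return An `item_bank` with 20 target items.
#' @export
nrs_proctcae_bank <- function() {
  path <- system.file("extdata", "symptom_item_bank.csv",
                      package = "prolink", mustWork = TRUE)
  read_item_bank(path)
}

#' Published raw-score to T-score concordance tables
#'
#' The printed crosswalk cells (T-score, its standard error, and the number
#' of respondents observed at each raw score) for the thirteen single-item
#' measures that passed the linking-assumption screens. Raw scores are on
#' the instrument-native scale (NRS 0-10; PRO-CTCAE 1-5).
#'
#' @return A data frame with columns `item_id`, `raw_score`, `t_score`,
#'   `se`, `n`.
#' @export
published_concordance <- function() {
  path <- system.file("extdata", "published_concordance.csv",
                      package = "prolink", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
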