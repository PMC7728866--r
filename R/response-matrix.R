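#' Construct a persons-by-items response matrix
#'
#' Wraps an integer matrix of 0-based ordinal category codes (persons in
#' rows, items in columns, `NA` for missing) together with the per-item
#' category count and optional person-level covariates used by the
#' invariance screens.
#'
#' @param responses integer matrix; column names are item ids.
#' @param n_categories integer vector, one K per item. Defaults to
#'   `max code + 1` observed per column.
#' @param covariates optional data frame with one row per person; the
#'   invariance screens look for columns `gender` (levels `"F"`/`"M"`) and
#'   `age` (years).
#' @param person_ids optional character vector of row identifiers.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, n_categories = NULL,
                            covariates = NULL, person_ids = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  if (is.null(n_categories))
    n_categories <- apply(responses, 2, function(x) max(x, 0L, na.rm = TRUE)) + 1L
  n_categories <- as.integer(rep_len(n_categories, ncol(responses)))
  if (min(responses, na.rm = TRUE) < 0L)
    stop("category codes must be >= 0 (0-based)")
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    if (any(x[!is.na(x)] >= n_categories[j]))
      stop("item ", colnames(responses)[j], ": code outside [0, K-1]")
  }
  if (!is.null(person_ids)) rownames(responses) <- person_ids
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(responses))
  }
  structure(list(responses = responses,
                 n_categories = stats::setNames(n_categories, colnames(responses)),
                 covariates = covariates),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  r <- x$responses
  cat(sprintf("Response matrix: %d persons x %d items (%.1f%% missing)\n",
              nrow(r), ncol(r), 100 * mean(is.na(r))))
  cat("Items:", paste(colnames(r), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Subset items of a response matrix
#'
#' @param x a `response_matrix`.
#' @param items character vector of item ids (or column indices).
#' @return A `response_matrix` restricted to those items.
#' @export
select_items <- function(x, items) {
  stopifnot(inherits(x, "response_matrix"))
  response_matrix(x$responses[, items, drop = FALSE],
                  x$n_categories[items], x$covariates)
}

#' Read a wide-format response file
#'
#' One row per person; item columns hold integer category codes with
#' missing responses left empty (or set to `na_string`). Columns named
#' `gender`, `age`, or `person_id` are treated as covariates, not items.
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @param n_categories optional per-item category counts (named or in file
#'   column order).
#' @param na_string missing-value sentinel.
#' @return A `response_matrix`.
#' @export
read_responses <- function(path, sep = ",", n_categories = NULL,
                           na_string = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na_string, stringsAsFactors = FALSE)
  covnames <- intersect(c("person_id", "gender", "age"), names(df))
  items <- setdiff(names(df), covnames)
  cov <- if (length(setdiff(covnames, "person_id")))
    df[setdiff(covnames, "person_id")] else NULL
  response_matrix(as.matrix(df[items]), n_categories, cov,
                  person_ids = df$person_id)
}

#' Write a response matrix to a delimited file
#'
#' @param x a `response_matrix`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "response_matrix"))
  df <- as.data.frame(x$responses)
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Screen items for sparse or empty categories
#'
#' Tabulates observed category counts per item and flags categories whose
#' count falls below `min_count`. No collapsing is performed; sparse top
#' categories are common for severe-symptom items and are retained, but
#' flagged items are at risk of unstable threshold estimates.
#'
#' @param data a `response_matrix`.
#' @param min_count flag categories observed fewer than this many times.
#' @return A data frame with one row per item-category: `item_id`,
#'   `category`, `count`, `flagged`; attribute `at_risk` lists items with
#'   any empty category.
#' @export
screen_items <- function(data, min_count = 10L) {
  stopifnot(inherits(data, "response_matrix"))
  out <- do.call(rbind, lapply(seq_along(data$n_categories), function(j) {
    K <- data$n_categories[j]
    cnt <- tabulate(data$responses[, j] + 1L, nbins = K)
    data.frame(item_id = names(data$n_categories)[j],
               category = 0:(K - 1L), count = cnt,
               flagged = cnt < min_count)
  }))
  rownames(out) <- NULL
  at_risk <- unique(out$item_id[out$count == 0L])
  structure(out, at_risk = at_risk)
}
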