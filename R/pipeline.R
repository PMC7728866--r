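#' Rebuild the published crosswalk tables from the packaged bank
#'
#' Constructs, with no response data, the raw-score to T-score concordance
#' table of every item in the packaged NRS/PRO-CTCAE bank
#' ([nrs_proctcae_bank()]) via the Lord-Wingersky recursion and
#' summed-score EAP under the standard-normal prior on the default
#' 101-point grid over `[-6, 6]`. Five 11-row NRS tables and fifteen 5-row
#' PRO-CTCAE tables are produced; the thirteen measures that passed the
#' published assumption screens can be compared cell by cell with
#' [published_concordance()]. PRO-CTCAE raw scores are displayed on the
#' native 1-5 scale.
#'
#' @param grid a [normal_quadrature()] grid.
#' @param attach_published_n attach the published per-score respondent
#'   counts where available.
#' @return Named list of [build_crosswalk()] tables, one per item.
#' @export
published_crosswalks <- function(grid = normal_quadrature(),
                                 attach_published_n = TRUE) {
  bank <- nrs_proctcae_bank()
  pub <- if (attach_published_n) published_concordance() else NULL
  out <- lapply(seq_len(nrow(bank)), function(i) {
    row <- bank[i, ]
    off <- if (!is.null(row$code_offset)) row$code_offset else 0L
    cnt <- NULL
    if (!is.null(pub) && row$item_id %in% pub$item_id) {
      p <- pub[pub$item_id == row$item_id, ]
      cnt <- p$n[order(p$raw_score)]
    }
    build_crosswalk(row, grid, observed_counts = cnt,
                    measure_id = row$item_id, raw_offset = off)
  })
  names(out) <- bank$item_id
  out
}

#' Run the full linking study for one or more domains
#'
#' Orchestrates, per domain: the linking-assumption report; a fixed-anchor
#' calibration and/or a concurrent calibration followed by Stocking-Lord
#' linking; the TCC comparison of the two routes; and a crosswalk table
#' for every target measure the screens admitted. All artifacts are
#' written under `out_dir` and listed, with content hashes, in the
#' returned manifest; excluded measures appear in the manifest with their
#' reasons rather than being silently dropped.
#'
#' @param data a [response_matrix()] holding all items, with `gender` and
#'   `age` covariates.
#' @param anchor_bank `item_bank` of established anchor parameters (the
#'   reference metric).
#' @param domains named list, one element per domain:
#'   `list(anchor_items = <ids>, target_measures = list(<measure id> =
#'   <item ids>))`.
#' @param method `"fixed"`, `"concurrent_sl"`, or `"both"`.
#' @param out_dir output directory (created if absent).
#' @param grid calibration/scoring grid.
#' @param sl_grid Stocking-Lord criterion grid.
#' @param r_threshold,smd_threshold,omega_threshold screen settings, see
#'   [assumption_report()].
#' @param control [grm_control()] settings.
#' @param override_exclusions build crosswalks even for excluded measures
#'   (recorded in the manifest).
#' @return A list of class `linking_study` with per-domain results and a
#'   `manifest` data frame (`domain`, `artifact`, `file`, `md5`, `note`).
#' @export
run_linking_study <- function(data, anchor_bank, domains,
                              method = c("both", "fixed", "concurrent_sl"),
                              out_dir = tempfile("linking_study_"),
                              grid = normal_quadrature(),
                              sl_grid = normal_quadrature(49L, -4, 4),
                              r_threshold = 0.75, smd_threshold = 0.10,
                              omega_threshold = 0.70,
                              control = grm_control(),
                              override_exclusions = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(data, "response_matrix"))
  validate_item_bank(anchor_bank)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  note <- function(domain, artifact, file = NA_character_, msg = "") {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(domain = domain, artifact = artifact, file = file,
                 md5 = if (!is.na(file) && file.exists(file))
                   unname(tools::md5sum(file)) else NA_character_,
                 note = msg, stringsAsFactors = FALSE)
  }

  for (dom in names(domains)) {
    spec <- domains[[dom]]
    res <- tryCatch({
      ids <- c(spec$anchor_items, unlist(spec$target_measures))
      if (!all(ids %in% colnames(data$responses)))
        stop("domain ", dom, ": unresolved item ids: ",
             paste(setdiff(ids, colnames(data$responses)), collapse = ", "))
      sub <- select_items(data, ids)
      rep <- assumption_report(sub, spec$anchor_items, spec$target_measures,
                               scale_id = dom, r_threshold = r_threshold,
                               smd_threshold = smd_threshold,
                               omega_threshold = omega_threshold)
      f <- file.path(out_dir, paste0(dom, "_assumptions.csv"))
      write_assumption_report(rep, f)
      note(dom, "assumption_report", f)

      abank <- anchor_bank[anchor_bank$item_id %in% spec$anchor_items, ]
      fit_fixed <- fit_conc <- link <- target_sl <- NULL
      if (method %in% c("both", "fixed")) {
        fit_fixed <- grm_calibrate(sub, anchor = abank, grid = grid,
                                   scale_id = dom, control = control)
        f <- file.path(out_dir, paste0(dom, "_calibration_fixed.csv"))
        write_item_bank(coef(fit_fixed), f)
        note(dom, "calibration_fixed", f)
      }
      if (method %in% c("both", "concurrent_sl")) {
        fit_conc <- grm_calibrate(sub, grid = grid, scale_id = dom,
                                  control = control)
        cbank <- coef(fit_conc)
        free_anchor <- cbank[match(abank$item_id, cbank$item_id), ]
        free_anchor$role <- "anchor"
        link <- stocking_lord(abank, free_anchor, sl_grid)
        f <- file.path(out_dir, paste0(dom, "_sl_constants.txt"))
        write_linking_constants(link, f)
        note(dom, "linking_constants", f)
        tids <- unlist(spec$target_measures)
        target_sl <- transform_params(
          cbank[match(tids, cbank$item_id), ], link)
        f <- file.path(out_dir, paste0(dom, "_calibration_concurrent_sl.csv"))
        write_item_bank(target_sl, f)
        note(dom, "calibration_concurrent_sl", f)
      }
      comparison <- NULL
      if (method == "both") {
        tids <- unlist(spec$target_measures)
        bank_fixed <- coef(fit_fixed)
        comparison <- compare_linking_methods(
          bank_fixed[match(tids, bank_fixed$item_id), ], target_sl)
        f <- file.path(out_dir, paste0(dom, "_tcc_comparison.csv"))
        utils::write.table(as.data.frame(comparison), f, sep = ",",
                           row.names = FALSE, quote = FALSE)
        note(dom, "tcc_comparison", f,
             sprintf("max_difference=%.4f", attr(comparison, "max_difference")))
      }
      # crosswalks for admitted measures, from the preferred route
      final_bank <- if (!is.null(target_sl)) target_sl else {
        bf <- coef(fit_fixed)
        bf[bf$role == "target", ]
      }
      xwalks <- list()
      for (m in names(spec$target_measures)) {
        d <- rep$decisions[rep$decisions$measure_id == m, ]
        if (!d$link && !override_exclusions) {
          note(dom, paste0("crosswalk_", m), NA_character_,
               paste0("excluded: ", d$reason))
          next
        }
        mb <- final_bank[final_bank$item_id %in% spec$target_measures[[m]], ]
        counts <- tabulate(rowSums(sub$responses[, spec$target_measures[[m]],
                                                 drop = FALSE]) + 1L,
                           nbins = sum(mb$n_categories - 1L) + 1L)
        xw <- build_crosswalk(mb, grid, observed_counts = counts,
                              measure_id = m)
        f <- file.path(out_dir, paste0(dom, "_crosswalk_", m, ".csv"))
        write_crosswalk(xw, f)
        note(dom, paste0("crosswalk_", m), f,
             if (!d$link) "excluded measure built on override" else "")
        xwalks[[m]] <- xw
      }
      list(assumptions = rep, fit_fixed = fit_fixed, fit_concurrent = fit_conc,
           linking = link, comparison = comparison, crosswalks = xwalks)
    }, error = function(e) {
      note(dom, "error", NA_character_, conditionMessage(e))
      NULL
    })
    results[[dom]] <- res
  }
  manifest <- do.call(rbind, manifest)
  f <- file.path(out_dir, "manifest.csv")
  utils::write.table(manifest, f, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  structure(list(results = results, manifest = manifest, out_dir = out_dir),
            class = "linking_study")
}

#' @export
print.linking_study <- function(x, ...) {
  cat("Linking study:", length(x$results), "domain(s), artifacts in",
      x$out_dir, "\n")
  print(x$manifest[, c("domain", "artifact", "note")], row.names = FALSE)
  invisible(x)
}
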