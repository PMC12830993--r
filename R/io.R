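#' Read a scan table
#'
#' Reads the long-format scan interchange CSV (one row per peak:
#' optional `event_id`, `scan`, `mz`, `intensity`), or an mzML file
#' whose centroided spectra are mapped to scans in acquisition order.
#' Rows are validated: non-positive m/z or negative intensity are
#' rejected with their line numbers.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"mzml"` (requires the `mzR`
#'   package).
#' @return A scan tibble.
#' @export
read_scans <- function(path, format = c("csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "mzml") return(read_scans_mzml(path))
  scans <- readr::read_csv(path, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(scans) == 0) {
    warn(paste0("Empty scan file: ", path))
    return(tibble(scan = integer(), mz = numeric(), intensity = numeric()))
  }
  needed <- c("scan", "mz", "intensity")
  missing <- setdiff(needed, names(scans))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(scans$mz <= 0 | scans$intensity < 0 | scans$scan < 0)
  if (length(bad)) {
    abort(paste0("Invalid rows (non-positive m/z, negative intensity or ",
                 "negative scan index) at data line(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..."))
  }
  as_tibble(scans)
}

read_scans_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Reading mzML requires the mzR package.")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  n <- nrow(mzR::header(ms))
  purrr::map_dfr(seq_len(n), function(i) {
    p <- mzR::peaks(ms, i)
    tibble(scan = i, mz = p[, 1], intensity = p[, 2])
  })
}

#' Write a scan table to CSV
#'
#' @param scans Scan tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  readr::write_csv(scans, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-event metadata
#'
#' The metadata table carries, per event id: specimen id, cancer type,
#' class (when known) and cohort role.
#'
#' @param path File path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"event_id" %in% names(md)) abort("Metadata needs an event_id column.")
  as_tibble(md)
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path, progress = FALSE)
  invisible(path)
}

cv_report_table <- function(x) {
  hdr <- c("Group", "PIRL-MS spectra data points",
           "Correctly classified data points", "Misclassified data points",
           "Unclassifiable data points", "Classifiable data points",
           "Per classifiable data points (%)",
           "Per all (classifiable and unclassifiable) data points (%)")
  rows <- x$per_fold %>%
    mutate(Group = as.character(.data$fold)) %>%
    select("Group", "total", "correct", "misclassified", "unclassifiable",
           "classifiable", "acc_classifiable", "acc_all")
  tot <- dplyr::bind_cols(tibble(Group = "Total"),
                          x$totals %>% select("total", "correct",
                                              "misclassified",
                                              "unclassifiable",
                                              "classifiable",
                                              "acc_classifiable", "acc_all"))
  out <- dplyr::bind_rows(rows, tot) %>%
    mutate(across(c("acc_classifiable", "acc_all"), ~ round(.x, 2)))
  stats::setNames(out, hdr)
}

blind_report_table <- function(x) {
  x$rates %>%
    mutate(across(c("sensitivity", "specificity"), ~ round(.x, 2)))
}

report_to_list <- function(x) {
  if (inherits(x, "cv_report")) {
    list(kind = "cross_validation",
         per_fold = x$per_fold, totals = x$totals,
         accuracy_per_classifiable = x$accuracy_per_classifiable,
         accuracy_per_all = x$accuracy_per_all,
         accuracy_per_classifiable_foldmean =
           x$accuracy_per_classifiable_foldmean,
         duty_cycle = x$duty_cycle,
         confusion = x$confusion, smote = isTRUE(x$smote))
  } else if (inherits(x, "blind_report")) {
    list(kind = "blind_evaluation",
         attempts = x$attempts, bad = x$bad,
         unclassifiable = x$unclassifiable,
         classifiable = x$classifiable, duty_cycle = x$duty_cycle,
         contingency = x$contingency, rates = x$rates,
         mean_probability = x$mean_probability,
         probability_halfband = x$probability_halfband,
         mean_concordance = x$mean_concordance,
         concordance_halfband = x$concordance_halfband,
         sd_multiplier = x$sd_multiplier)
  } else {
    abort("Unknown report type.")
  }
}

#' Write a report as a JSON / CSV pair
#'
#' Writes the machine-readable JSON and the human-readable CSV table of
#' a cross-validation or blind report, embedding the seed and a hash of
#' the configuration for provenance. The CSV columns mirror the
#' conventional accounting-table layout; the JSON and CSV contain
#' identical numbers.
#'
#' @param report A `cv_report` or `blind_report`.
#' @param dir Output directory (created if missing).
#' @param name Base file name (without extension).
#' @param seed,config Optional provenance embedded in the JSON.
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(report, dir, name = "report", seed = NULL,
                          config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- report_to_list(report)
  payload$provenance <- list(
    seed = seed,
    config_hash = if (is.null(config)) NULL else rlang::hash(config)
  )
  json_path <- file.path(dir, paste0(name, ".json"))
  csv_path <- file.path(dir, paste0(name, ".csv"))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  tab <- if (inherits(report, "cv_report")) cv_report_table(report)
         else blind_report_table(report)
  readr::write_csv(tab, csv_path, progress = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Save / load a fitted model
#'
#' The model (PCA basis, LDA projection, class statistics and all
#' thresholds) is serialized to a single portable archive.
#'
#' @param model A `rejection_lda`.
#' @param path File path (conventionally `.rds`).
#' @return `path` (`write_model`) or the model (`read_model`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rejection_lda"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rejection_lda")) abort("Not a rejection_lda archive.")
  model
}
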