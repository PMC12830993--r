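#' Group a scan stream into sampling events by event id
#'
#' Builds one row per operator-delimited sampling attempt from a long scan
#' table that already carries an `event_id` column, computing the combined
#' spectrum (the concatenation of member-scan peak lists), the signal
#' duration (number of member scans at 1 scan/s) and the event total ion
#' count. Use [detect_events()] instead when the stream has no event
#' delimitation and events must be recognised from the per-scan TIC
#' trigger.
#'
#' @param scans Tibble with columns `event_id`, `scan`, `mz`, `intensity`.
#' @return Tibble with one row per event: `event_id`, `n_scans`,
#'   `duration` (seconds), `tic`, and `peaks` (list-column of combined
#'   spectra, each a tibble of `mz`, `intensity`).
#' @export
assemble_events <- function(scans) {
  stopifnot(all(c("event_id", "scan", "mz", "intensity") %in% names(scans)))
  if (nrow(scans) == 0) {
    return(tibble(event_id = character(), n_scans = integer(),
                  duration = integer(), tic = numeric(), peaks = list()))
  }
  nested <- scans %>%
    group_by(.data$event_id) %>%
    summarise(n_scans = dplyr::n_distinct(.data$scan),
              tic = sum(.data$intensity),
              peaks = list(tibble(mz = mz, intensity = intensity)),
              .groups = "drop")
  nested %>%
    mutate(duration = .data$n_scans) %>%
    select("event_id", "n_scans", "duration", "tic", "peaks")
}

#' Recognise sampling events in an undelimited scan stream
#'
#' State machine mirroring the instrument's spectrum-recognition settings:
#' an event opens at the first scan whose per-scan TIC exceeds
#' `tic_trigger`; up to `scans_per_spectrum` qualifying scans (TIC above
#' the trigger) are then accumulated, and the event closes when that count
#' is reached or when `timeout` seconds have elapsed since opening. Scans
#' are never shared between events.
#'
#' @param scans Tibble with columns `scan`, `mz`, `intensity` (no
#'   `event_id`), ordered by scan index; one scan per second.
#' @param tic_trigger Per-scan TIC needed to open/extend an event
#'   (default 10^4).
#' @param scans_per_spectrum Maximum member scans per event (default 13).
#' @param timeout Seconds after opening at which an event closes
#'   regardless (default 13).
#' @return As [assemble_events()]: one row per recognised event, with
#'   generated event ids `D00001`, `D00002`, ...
#' @export
detect_events <- function(scans, tic_trigger = 1e4,
                          scans_per_spectrum = 13, timeout = 13) {
  stopifnot(tic_trigger > 0, scans_per_spectrum >= 1, timeout > 0)
  if (nrow(scans) == 0) return(assemble_events(scans[0, ] %>% mutate(event_id = character())))
  per_scan <- scans %>%
    group_by(.data$scan) %>%
    summarise(tic = sum(.data$intensity), .groups = "drop") %>%
    arrange(.data$scan)

  assignment <- rep(NA_integer_, nrow(per_scan))
  ev <- 0L
  open_at <- NA_real_
  members <- 0L
  for (i in seq_len(nrow(per_scan))) {
    t <- per_scan$scan[i]
    if (!is.na(open_at) && (t - open_at) >= timeout) {
      open_at <- NA_real_   # close by timeout before considering this scan
    }
    qualifying <- per_scan$tic[i] > tic_trigger
    if (is.na(open_at)) {
      if (qualifying) {     # open a new event on this scan
        ev <- ev + 1L
        open_at <- t
        members <- 1L
        assignment[i] <- ev
      }
    } else if (qualifying) {
      members <- members + 1L
      assignment[i] <- ev
      if (members >= scans_per_spectrum) open_at <- NA_real_  # close on count
    }
  }

  keep <- !is.na(assignment)
  if (!any(keep)) {
    empty <- scans[0, ] %>% mutate(event_id = character())
    return(assemble_events(empty))
  }
  id_map <- setNames(sprintf("D%05d", seq_len(ev)), seq_len(ev))
  tagged <- scans %>%
    left_join(tibble(scan = per_scan$scan, .ev = assignment), by = "scan") %>%
    filter(!is.na(.data$.ev)) %>%
    mutate(event_id = id_map[as.character(.data$.ev)]) %>%
    select(-".ev")
  assemble_events(tagged)
}

# Observed lock-mass m/z of each event: the most intense peak within
# +/- window Da of the reference, NA when no peak falls in the window.
observed_lockmass <- function(events, reference = 717.5070, window = 0.25) {
  purrr::map_dbl(events$peaks, function(p) {
    hit <- p[abs(p$mz - reference) <= window, ]
    if (nrow(hit) == 0) return(NA_real_)
    hit$mz[which.max(hit$intensity)]
  })
}

#' Quality-control check of sampling events
#'
#' Applies the three bad-data criteria in order: (a) a lock-mass peak must
#' exist within `window` Da of `reference`, (b) signal duration must
#' exceed 3 s (i.e. at least 4 member scans at 1 scan/s), and (c) the
#' combined-spectrum total ion count must exceed `min_tic`. The first
#' failing criterion names the status; events passing all three are
#' `good`.
#'
#' @param events Event tibble from [assemble_events()] or
#'   [detect_events()].
#' @param reference Lock-mass m/z (Da).
#' @param window Lock-mass search half-window (Da).
#' @param min_duration Seconds of signal that must be exceeded (default 3:
#'   a 3-scan event is bad).
#' @param min_tic Combined-spectrum TIC that must be exceeded
#'   (default 10^3).
#' @return `events` with added columns `lockmass_mz` (observed, `NA` if
#'   absent) and `qc_status` (factor: `good`, `bad_no_lockmass`,
#'   `bad_short_duration`, `bad_low_tic`).
#' @export
qc_check <- function(events, reference = 717.5070, window = 0.25,
                     min_duration = 3, min_tic = 1e3) {
  lock <- observed_lockmass(events, reference, window)
  status <- dplyr::case_when(
    is.na(lock) ~ "bad_no_lockmass",
    events$duration <= min_duration ~ "bad_short_duration",
    events$tic <= min_tic ~ "bad_low_tic",
    TRUE ~ "good"
  )
  events %>%
    mutate(lockmass_mz = lock,
           qc_status = factor(status, levels = c("good", "bad_no_lockmass",
                                                 "bad_short_duration",
                                                 "bad_low_tic")))
}

#' Correct mass drift against the internal lock-mass
#'
#' Shifts every m/z of each event's combined spectrum by
#' `reference - observed`, where `observed` is the most intense peak
#' within `window` Da of the reference, so that the lock-mass peak sits at
#' exactly the reference m/z afterwards. The correction is a uniform
#' additive shift, the simplest model consistent with a single internal
#' standard.
#'
#' @inheritParams qc_check
#' @return `events` with shifted `peaks`, updated `lockmass_mz` (now equal
#'   to `reference`) and a `mass_shift` column recording the applied shift
#'   in Da.
#' @export
lockmass_correct <- function(events, reference = 717.5070, window = 0.25) {
  lock <- if ("lockmass_mz" %in% names(events)) events$lockmass_mz
          else observed_lockmass(events, reference, window)
  if (anyNA(lock)) {
    abort(paste0("Lock-mass correction requested for ", sum(is.na(lock)),
                 " event(s) with no lock-mass peak within the window; ",
                 "filter bad_no_lockmass events first."))
  }
  shift <- reference - lock
  events$peaks <- purrr::map2(events$peaks, shift, function(p, s) {
    p$mz <- p$mz + s
    p
  })
  events$lockmass_mz <- reference
  events$mass_shift <- shift
  events
}

#' Bin combined spectra and normalise to total ion count
#'
#' Accumulates each peak with `lo <= m/z < hi` into bin
#' `floor((mz - lo) / width)` and divides every row by its in-range sum.
#' The default grid (0.1 Da over 100--1000 Da) yields 9,000 features.
#' Rows with zero in-range signal are flagged, not divided.
#'
#' @param events Event tibble (ideally lock-mass corrected).
#' @param lo,hi Half-open acquisition range in Da.
#' @param width Bin width in Da.
#' @param annotations Optional tibble keyed by `event_id` (specimen id,
#'   class, ...) carried into the result.
#' @param normalize Divide each row by its sum (default `TRUE`).
#' @return A `binned_matrix`: events x bins feature matrix with per-event
#'   annotations.
#' @export
bin_events <- function(events, lo = 100, hi = 1000, width = 0.1,
                       annotations = NULL, normalize = TRUE) {
  if (hi <= lo || width <= 0) abort("Need hi > lo and width > 0.")
  nbins <- as.integer(round((hi - lo) / width))
  n <- nrow(events)
  long <- events %>%
    select("event_id", "peaks") %>%
    mutate(.row = dplyr::row_number()) %>%
    tidyr::unnest("peaks") %>%
    filter(.data$mz >= lo, .data$mz < hi) %>%
    mutate(bin = pmin(as.integer(floor((.data$mz - lo) / width)), nbins - 1L))
  values <- as.matrix(Matrix::sparseMatrix(
    i = long$.row, j = long$bin + 1L, x = long$intensity,
    dims = c(n, nbins)))
  rownames(values) <- events$event_id
  colnames(values) <- sprintf("mz_%.4f", lo + width * (seq_len(nbins) - 1L))

  row_tic <- rowSums(values)
  zero_signal <- row_tic == 0
  if (normalize && any(!zero_signal)) {
    values[!zero_signal, ] <- values[!zero_signal, , drop = FALSE] /
      row_tic[!zero_signal]
  }
  ann <- events %>% select(dplyr::any_of(c(
    "event_id", "n_scans", "duration", "tic", "lockmass_mz",
    "mass_shift", "qc_status")))
  ann$row_tic <- row_tic
  ann$zero_signal <- zero_signal
  if (!is.null(annotations)) ann <- left_join(ann, annotations, by = "event_id")

  structure(list(values = values, lo = lo, hi = hi, width = width,
                 normalized = normalize, events = as_tibble(ann)),
            class = "binned_matrix")
}

#' Re-bin a 0.1-Da matrix to 1 Da
#'
#' Sums each block of 10 consecutive 0.1-Da bins, yielding 900 features
#' over 100--1000 Da; row sums are preserved exactly.
#'
#' @param bm A 9,000-column `binned_matrix` from [bin_events()].
#' @return A 900-column `binned_matrix`.
#' @export
rebin_1da <- function(bm) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (ncol(bm$values) != 9000) {
    abort("rebin_1da() expects the 9,000-column 0.1-Da matrix.")
  }
  grp <- rep(seq_len(900), each = 10)
  agg <- t(rowsum(t(bm$values), group = grp))
  colnames(agg) <- sprintf("mz_%d", as.integer(bm$lo + (seq_len(900) - 1)))
  out <- bm
  out$values <- agg
  out$width <- 1
  out
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("<binned_matrix> ", nrow(x$values), " events x ", ncol(x$values),
      " bins (", x$width, " Da over [", x$lo, ", ", x$hi, "))",
      if (x$normalized) ", TIC-normalized" else "", "\n", sep = "")
  print(head(x$events, 4))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

#' Subset a binned matrix by event
#'
#' @param bm A `binned_matrix`.
#' @param idx Logical/integer index, or character event ids, over events.
#' @return The subsetted `binned_matrix`.
#' @export
bm_subset <- function(bm, idx) {
  if (is.character(idx)) idx <- match(idx, bm$events$event_id)
  bm$values <- bm$values[idx, , drop = FALSE]
  bm$events <- bm$events[idx, , drop = FALSE]
  bm
}

#' @export
as_tibble.binned_matrix <- function(x, ...) {
  dplyr::bind_cols(x$events, as_tibble(x$values, .name_repair = "minimal"))
}

#' Run the full preprocessing chain on a scan stream
#'
#' Groups scans into sampling events, applies quality control, lock-mass
#' corrects the events that have a lock-mass, and bins the QC-good events
#' into the TIC-normalized feature matrix. Bad events are retained in the
#' returned event table (they count against the duty cycle) but excluded
#' from the matrix.
#'
#' @param scans Long scan tibble; if it has no `event_id` column, events
#'   are recognised with [detect_events()].
#' @param metadata Optional per-event annotation tibble (specimen id,
#'   class, ...).
#' @param reference,window Lock-mass parameters (see [qc_check()]).
#' @param lo,hi,width Binning grid (see [bin_events()]).
#' @param tic_trigger,scans_per_spectrum,timeout Event-recognition
#'   parameters, used only when `scans` lacks `event_id`.
#' @return List with `events` (all attempts, QC-annotated) and `matrix`
#'   (a `binned_matrix` of the QC-good events).
#' @export
preprocess_scans <- function(scans, metadata = NULL,
                             reference = 717.5070, window = 0.25,
                             lo = 100, hi = 1000, width = 0.1,
                             tic_trigger = 1e4, scans_per_spectrum = 13,
                             timeout = 13) {
  events <- if ("event_id" %in% names(scans)) assemble_events(scans)
            else detect_events(scans, tic_trigger, scans_per_spectrum, timeout)
  events <- qc_check(events, reference, window)
  good <- events %>% filter(.data$qc_status == "good")
  good <- lockmass_correct(good, reference, window)
  bm <- bin_events(good, lo, hi, width, annotations = metadata)
  events_out <- events %>%
    select(-"peaks") %>%
    { if (is.null(metadata)) . else left_join(., metadata, by = "event_id") }
  list(events = as_tibble(events_out), matrix = bm)
}
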