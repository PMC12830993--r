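#' Simulate a cohort of laser-sampling scan streams
#'
#' Generates a per-second scan stream for every sampling event of a
#' two-class cohort, together with the ground truth needed to score any
#' downstream analysis. Peak intensities are log-normal:
#' `intensity = exp(log_intensity + specimen effect + scan noise)`, so they
#' are strictly positive and heavy-tailed like real MS peaks. Each event
#' carries one additive m/z drift applied uniformly to all of its peaks
#' (matching a single lock-mass correction per event), a lock-mass peak at
#' `cfg$lockmass_mz`, and uniform chemical baseline noise. Injected bad
#' events violate exactly their designated quality-control criterion:
#' `no_lockmass` events lack the lock-mass peak, `short_duration` events
#' have only 3 scans, and `low_tic` events are globally rescaled so the
#' combined-spectrum total ion count falls below 10^3.
#'
#' @param cfg A [cohort_config()].
#' @param cohort_role Label recorded in the metadata (`"train"` or
#'   `"blind"`).
#' @return A list with
#'   \describe{
#'     \item{scans}{tibble of scan-level peaks: `event_id`, `scan`
#'       (global 1 Hz index), `mz` (Da), `intensity` (a.u.).}
#'     \item{truth}{per-event ground truth: `event_id`, `specimen_id`,
#'       `class`, `cancer_type`, `cohort_role`, `bad_mode` (`"none"` or the
#'       injected mode), `drift` (Da).}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(n_specimens_per_class = c(lymphoma = 2, pdx = 2),
#'                      events_per_specimen = 2, seed = 7)
#' sim <- simulate_cohort(cfg)
#' dplyr::count(sim$truth, class)
simulate_cohort <- function(cfg, cohort_role = "train") {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, simulate_cohort_impl(cfg, cohort_role))
}

simulate_cohort_impl <- function(cfg, cohort_role) {
  classes <- names(cfg$n_specimens_per_class)
  pdx_types <- c("colon", "head & neck", "lung", "ovarian", "pancreas")

  specimens <- purrr::map_dfr(classes, function(cl) {
    n <- cfg$n_specimens_per_class[[cl]]
    tibble(
      specimen_id = sprintf("%s%03d", toupper(substr(cl, 1, 1)), seq_len(n)),
      class = cl,
      cancer_type = if (cl == "lymphoma") "lymphoma"
                    else pdx_types[(seq_len(n) - 1L) %% length(pdx_types) + 1L]
    )
  })

  # signal peak tables per class: panel + shared + lock-mass
  peak_tables <- lapply(classes, function(cl) {
    dplyr::bind_rows(
      cfg$class_peak_panels[[cl]],
      cfg$shared_peaks,
      tibble(mz = cfg$lockmass_mz, log_intensity = cfg$lockmass_log_intensity)
    ) %>%
      mutate(peak_id = dplyr::row_number(),
             is_lockmass = .data$mz == cfg$lockmass_mz)
  })
  names(peak_tables) <- classes

  # per-specimen, per-peak log-intensity random effects
  effects <- purrr::map_dfr(seq_len(nrow(specimens)), function(i) {
    cl <- specimens$class[i]
    pk <- peak_tables[[cl]]
    tibble(specimen_id = specimens$specimen_id[i],
           peak_id = pk$peak_id,
           u = rnorm(nrow(pk), 0, cfg$specimen_effect_sd))
  })

  # events: how many per specimen, drift, injected badness
  eps <- cfg$events_per_specimen
  n_events_per_spec <- if (length(eps) == 1L) rep(eps, nrow(specimens))
                       else sample(seq(eps[1], eps[2]), nrow(specimens),
                                   replace = TRUE)
  events <- specimens[rep(seq_len(nrow(specimens)), n_events_per_spec), ] %>%
    mutate(event_id = sprintf("E%05d", dplyr::row_number()),
           drift = rnorm(n(), 0, cfg$mass_drift_sd))
  modes <- c("none", "no_lockmass", "short_duration", "low_tic")
  p_bad <- cfg$bad_event_rates[c("no_lockmass", "short_duration", "low_tic")]
  u01 <- runif(nrow(events))
  cuts <- cumsum(c(1 - sum(p_bad), p_bad))
  events$bad_mode <- modes[findInterval(u01, cuts) + 1L]
  events$n_scans <- ifelse(events$bad_mode == "short_duration", 3L,
                           cfg$scans_per_event)

  # signal rows: event x peak x scan
  sig <- events %>%
    select("event_id", "specimen_id", "class", "drift", "bad_mode", "n_scans") %>%
    left_join(dplyr::bind_rows(peak_tables, .id = "class"),
              by = "class", relationship = "many-to-many") %>%
    filter(!(.data$is_lockmass & .data$bad_mode == "no_lockmass")) %>%
    left_join(effects, by = c("specimen_id", "peak_id")) %>%
    tidyr::uncount(.data$n_scans, .id = "scan_local") %>%
    mutate(intensity = exp(.data$log_intensity + .data$u +
                             rnorm(n(), 0, cfg$scan_noise_sd)),
           mz_obs = .data$mz + .data$drift) %>%
    select("event_id", scan_local = "scan_local", mz = "mz_obs", "intensity")

  # chemical baseline noise rows
  noise <- NULL
  if (cfg$baseline_noise_peaks > 0) {
    noise <- events %>%
      select("event_id", "drift", "n_scans") %>%
      tidyr::uncount(.data$n_scans, .id = "scan_local") %>%
      tidyr::uncount(cfg$baseline_noise_peaks) %>%
      mutate(mz = runif(n(), cfg$mz_range[1], cfg$mz_range[2]) + .data$drift,
             # keep the lock-mass search window free of chemical noise so
             # that absence of the internal standard is detectable
             mz = ifelse(abs(.data$mz - cfg$lockmass_mz) <= 0.3,
                         .data$mz + 0.7, .data$mz),
             intensity = exp(rnorm(n(), cfg$baseline_noise_log_intensity, 1))) %>%
      select("event_id", "scan_local", "mz", "intensity")
  }

  scans <- dplyr::bind_rows(sig, noise) %>%
    filter(.data$mz >= cfg$mz_range[1], .data$mz < cfg$mz_range[2]) %>%
    arrange(match(.data$event_id, events$event_id), .data$scan_local, .data$mz)

  # rescale low-TIC events so the combined spectrum falls under the QC floor
  low <- events$event_id[events$bad_mode == "low_tic"]
  if (length(low)) {
    tics <- scans %>%
      filter(.data$event_id %in% low) %>%
      group_by(.data$event_id) %>%
      summarise(tic = sum(.data$intensity))
    fac <- setNames(500 / tics$tic, tics$event_id)
    idx <- scans$event_id %in% low
    scans$intensity[idx] <- scans$intensity[idx] * fac[scans$event_id[idx]]
  }

  # global 1 Hz scan index across the stream
  offsets <- c(0L, cumsum(events$n_scans))[seq_len(nrow(events))]
  names(offsets) <- events$event_id
  scans <- scans %>%
    mutate(scan = offsets[.data$event_id] + .data$scan_local) %>%
    select("event_id", "scan", "mz", "intensity")

  truth <- events %>%
    mutate(cohort_role = cohort_role) %>%
    select("event_id", "specimen_id", "class", "cancer_type",
           "cohort_role", "bad_mode", "drift") %>%
    as_tibble()

  list(scans = as_tibble(scans), truth = truth)
}

#' Simulate a blinded evaluation set
#'
#' Like [simulate_cohort()] but with the class labels withheld from the
#' classification path: the returned `metadata` carries specimen and event
#' identifiers only, while the truth is sealed inside an opaque object that
#' must be explicitly unsealed for scoring.
#'
#' @param cfg A [cohort_config()]; the default blind-set shape is 30
#'   lymphoma + 118 PDX specimens at ~14 events each.
#' @param hide_labels If `FALSE`, the truth is returned in the open
#'   (useful for debugging).
#' @return A list with `scans`, `metadata` (no class column when hidden)
#'   and `truth` (a `sealed_truth` when `hide_labels = TRUE`).
#' @seealso [unseal_truth()]
#' @export
simulate_blind_set <- function(cfg, hide_labels = TRUE) {
  sim <- simulate_cohort(cfg, cohort_role = "blind")
  metadata <- sim$truth %>% select("event_id", "specimen_id", "cohort_role")
  truth <- if (hide_labels) seal_truth(sim$truth) else sim$truth
  list(scans = sim$scans, metadata = metadata, truth = truth)
}

seal_truth <- function(truth) {
  structure(list(truth = truth), class = "sealed_truth")
}

#' Unseal the ground truth of a blinded set
#'
#' @param x A `sealed_truth` object from [simulate_blind_set()].
#' @return The per-event truth tibble.
#' @export
unseal_truth <- function(x) {
  if (!inherits(x, "sealed_truth")) abort("`x` is not a sealed_truth.")
  .subset2(x, "truth")
}

#' @export
print.sealed_truth <- function(x, ...) {
  cat("<sealed_truth>", nrow(.subset2(x, "truth")),
      "events; labels hidden. Use unseal_truth() to score.\n")
  invisible(x)
}

#' @export
`$.sealed_truth` <- function(x, name) {
  abort("Truth is sealed; call unseal_truth() to score.")
}

#' @export
`[[.sealed_truth` <- function(x, i, ...) {
  abort("Truth is sealed; call unseal_truth() to score.")
}
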