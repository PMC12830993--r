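#' Default class-specific peak panels
#'
#' Lipid-range (600--900 Da) marker panels used by [cohort_config()]. Each
#' panel is a tibble of peak centre (`mz`, Da) and mean log-intensity
#' (`log_intensity`, natural log of arbitrary units). The lymphoma and PDX
#' panels are disjoint; `shared` peaks appear in both classes so that the
#' two fingerprints differ in a subset of features only, as real tissue
#' spectra do.
#'
#' @return A named list with elements `lymphoma`, `pdx` and `shared`.
#' @export
default_peak_panels <- function() {
  list(
    lymphoma = tibble::tibble(
      mz = c(642.32, 671.44, 699.51, 723.53, 748.55, 782.58, 810.61, 836.63),
      log_intensity = c(8.6, 8.2, 8.9, 8.4, 8.7, 8.1, 8.5, 8.3)
    ),
    pdx = tibble::tibble(
      mz = c(618.35, 655.41, 687.48, 731.52, 760.56, 794.59, 822.62, 863.65),
      log_intensity = c(8.5, 8.3, 8.8, 8.2, 8.6, 8.4, 8.1, 8.7)
    ),
    shared = tibble::tibble(
      mz = c(153.12, 227.21, 255.23, 281.25, 303.23, 465.34,
             536.51, 600.44, 744.62, 790.54, 885.55, 909.62),
      log_intensity = c(7.8, 8.0, 8.4, 8.6, 8.2, 7.9, 7.7, 8.1, 8.3, 7.8, 7.6, 7.9)
    )
  )
}

#' Configure a synthetic sampling cohort
#'
#' Describes the statistical structure of a simulated two-class cohort of
#' laser-sampling events: class-specific lipid peak panels, per-specimen
#' random effects, per-scan intensity noise, a lock-mass peak subject to a
#' per-event mass drift, chemical baseline noise, and injected bad-data
#' modes that each violate exactly one quality-control criterion.
#'
#' Defaults mirror the study design the package models: 20 lymphoma and 90
#' solid-tumour PDX training specimens sampled ~12 times each at 13
#' one-second scans per sampling event, negative-mode spectra over
#' 100--1000 Da with a lock-mass at m/z 717.5070.
#'
#' @param n_specimens_per_class Named integer vector
#'   `c(lymphoma = , pdx = )`, specimens per class.
#' @param events_per_specimen Integer number of sampling events per
#'   specimen, or a length-2 range sampled uniformly per specimen.
#' @param scans_per_event Scans (seconds) per good sampling event.
#' @param class_peak_panels Named list of per-class peak tibbles
#'   (`mz`, `log_intensity`); one element per class, non-empty.
#' @param shared_peaks Tibble of peaks common to all classes.
#' @param lockmass_mz Internal-standard m/z (Da).
#' @param lockmass_log_intensity Mean log-intensity of the lock-mass peak.
#' @param specimen_effect_sd SD of the per-specimen, per-peak log-intensity
#'   random effect (log units); this is what makes events within a specimen
#'   correlated and grouped cross-validation necessary.
#' @param scan_noise_sd SD of per-scan log-intensity noise (log units).
#' @param mass_drift_sd SD of the per-event additive m/z shift (Da),
#'   applied uniformly to every peak of the event.
#' @param baseline_noise_peaks Number of chemical-noise peaks per scan,
#'   uniform over the acquisition range.
#' @param baseline_noise_log_intensity Mean log-intensity of noise peaks.
#' @param bad_event_rates Named probabilities
#'   `c(no_lockmass = , short_duration = , low_tic = )` with which an event
#'   is injected with the corresponding bad-data mode. Defaults are the
#'   per-attempt rates observed in a 2,079-attempt blind series
#'   (11 missing lock-mass, 23 short-duration).
#' @param mz_range Length-2 acquisition range in Da, half-open.
#' @param seed Integer seed making generation reproducible.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_specimens_per_class = c(lymphoma = 3, pdx = 4),
#'                      events_per_specimen = 2, seed = 1)
#' cfg$lockmass_mz
cohort_config <- function(n_specimens_per_class = c(lymphoma = 20, pdx = 90),
                          events_per_specimen = 12,
                          scans_per_event = 13,
                          class_peak_panels = default_peak_panels()[c("lymphoma", "pdx")],
                          shared_peaks = default_peak_panels()$shared,
                          lockmass_mz = 717.5070,
                          lockmass_log_intensity = 9.2,
                          specimen_effect_sd = 0.3,
                          scan_noise_sd = 0.4,
                          mass_drift_sd = 0.05,
                          baseline_noise_peaks = 40,
                          baseline_noise_log_intensity = 5,
                          bad_event_rates = c(no_lockmass = 11 / 2079,
                                              short_duration = 23 / 2079,
                                              low_tic = 0),
                          mz_range = c(100, 1000),
                          seed = 1L) {
  cfg <- list(
    n_specimens_per_class = n_specimens_per_class,
    events_per_specimen = events_per_specimen,
    scans_per_event = scans_per_event,
    class_peak_panels = class_peak_panels,
    shared_peaks = shared_peaks,
    lockmass_mz = lockmass_mz,
    lockmass_log_intensity = lockmass_log_intensity,
    specimen_effect_sd = specimen_effect_sd,
    scan_noise_sd = scan_noise_sd,
    mass_drift_sd = mass_drift_sd,
    baseline_noise_peaks = baseline_noise_peaks,
    baseline_noise_log_intensity = baseline_noise_log_intensity,
    bad_event_rates = bad_event_rates,
    mz_range = mz_range,
    seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.numeric(cfg$mz_range), length(cfg$mz_range) == 2,
            cfg$mz_range[1] < cfg$mz_range[2])
  if (length(cfg$n_specimens_per_class) < 2 ||
      is.null(names(cfg$n_specimens_per_class))) {
    abort("`n_specimens_per_class` must be a named vector with >= 2 classes.")
  }
  if (any(cfg$n_specimens_per_class < 1)) {
    abort("Specimen counts must be positive.")
  }
  if (!all(names(cfg$n_specimens_per_class) %in% names(cfg$class_peak_panels))) {
    abort("Every class needs a peak panel in `class_peak_panels`.")
  }
  for (cl in names(cfg$n_specimens_per_class)) {
    panel <- cfg$class_peak_panels[[cl]]
    if (is.null(panel) || nrow(panel) == 0) {
      abort(paste0("Empty peak panel for class '", cl,
                   "': classes would be indistinguishable by construction."))
    }
  }
  all_mz <- c(unlist(lapply(cfg$class_peak_panels, function(p) p$mz)),
              cfg$shared_peaks$mz, cfg$lockmass_mz)
  if (any(all_mz < cfg$mz_range[1] | all_mz >= cfg$mz_range[2])) {
    abort("All panel m/z (and the lock-mass) must lie within `mz_range` (half-open).")
  }
  if (any(cfg$bad_event_rates < 0 | cfg$bad_event_rates > 1) ||
      sum(cfg$bad_event_rates) > 1) {
    abort("`bad_event_rates` must be probabilities with sum <= 1.")
  }
  needed <- c("no_lockmass", "short_duration", "low_tic")
  if (!all(needed %in% names(cfg$bad_event_rates))) {
    abort("`bad_event_rates` must name no_lockmass, short_duration and low_tic.")
  }
  stopifnot(cfg$scans_per_event >= 1,
            all(cfg$events_per_specimen >= 1),
            length(cfg$events_per_specimen) %in% c(1L, 2L),
            cfg$specimen_effect_sd >= 0, cfg$scan_noise_sd >= 0,
            cfg$mass_drift_sd >= 0, cfg$baseline_noise_peaks >= 0)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  n <- x$n_specimens_per_class
  cat("<cohort_config>\n")
  cat("  classes:", paste0(names(n), " (n=", n, ")", collapse = ", "), "\n")
  cat("  events/specimen:", paste(x$events_per_specimen, collapse = "-"),
      " scans/event:", x$scans_per_event, "\n")
  cat("  lock-mass m/z:", x$lockmass_mz,
      " drift sd:", x$mass_drift_sd, "Da\n")
  cat("  bad-event rates:",
      paste0(names(x$bad_event_rates), "=",
             signif(x$bad_event_rates, 3), collapse = ", "), "\n")
  invisible(x)
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}
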