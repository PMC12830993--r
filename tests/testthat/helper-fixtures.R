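# Fixtures are generated in code and cached for the duration of the run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small separable cohort used by most unit tests.
tiny_cohort <- function() {
  cached("tiny", function() {
    cfg <- cohort_config(
      n_specimens_per_class = c(lymphoma = 6, pdx = 9),
      events_per_specimen = 4, seed = 101,
      bad_event_rates = c(no_lockmass = 0, short_duration = 0, low_tic = 0))
    sim <- simulate_cohort(cfg)
    prep <- preprocess_scans(sim$scans, metadata = sim$truth)
    list(cfg = cfg, sim = sim, prep = prep, bm = prep$matrix,
         specimens = dplyr::distinct(prep$matrix$events,
                                     specimen_id, class),
         model = fit_rejection_lda(prep$matrix))
  })
}

# Study-scale cohort for the acceptance properties (built once, lazily).
study_cohort <- function() {
  cached("study", function() {
    cfg <- cohort_config(seed = 20090)    # defaults: 20 + 90 specimens x 12 events
    sim <- simulate_cohort(cfg)
    prep <- preprocess_scans(sim$scans, metadata = sim$truth)
    list(cfg = cfg, sim = sim, prep = prep, bm = prep$matrix,
         specimens = dplyr::distinct(prep$matrix$events,
                                     specimen_id, class))
  })
}

# One synthetic sampling event as the preprocess functions see it.
toy_event <- function(peaks, id = "T00001", n_scans = 13) {
  tibble::tibble(event_id = id, n_scans = n_scans, duration = n_scans,
                 tic = sum(peaks$intensity), peaks = list(peaks))
}

# Undelimited scan stream with one single-peak scan per second.
stream_from_tics <- function(tics) {
  tibble::tibble(scan = seq_along(tics), mz = 500, intensity = tics)
}
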