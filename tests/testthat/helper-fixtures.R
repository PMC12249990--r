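# Shared fixtures, all generated in code.

with_seed <- breathvoc:::with_seed

# A hand-built miniature recording, independent of the generator.
tiny_sample <- function(subject = "T01", group = "control",
                        maneuver = "quiet", replicate = 1L, seed = 1) {
  with_seed(seed, {
    mz <- seq(50, 59.5, by = 0.5)
    scans <- matrix(round(stats::runif(5 * length(mz), 0, 100), 3),
                    nrow = 5)
    spectrum_series(mz, scans, scan_times = (1:5) - 0.5,
                    capnostat = round(stats::runif(5, 0, 1), 3)) |>
      (\(s) breath_sample(subject, group, maneuver, replicate, s))()
  })
}

# A reduced spectral cohort reused across feature-matrix tests (built once
# per test run).
small_cohort_cache <- new.env()
small_cohort <- function() {
  if (is.null(small_cohort_cache$coh)) {
    cfg <- synthetic_config(n_cases = 2L, n_controls = 2L, seed = 202,
                            qc_fail_rate = 0)
    small_cohort_cache$coh <- generate_cohort(cfg)
    small_cohort_cache$res <- process_cohort(small_cohort_cache$coh$samples)
  }
  list(coh = small_cohort_cache$coh, res = small_cohort_cache$res)
}

# All ion m/z the synthetic generator plants besides the VOC panel.
reserved_ions <- function() {
  c(calibrant_set(), tracer_set()$water_adduct, tracer_set()$biogenic,
    breathvoc:::REFERENCE_ION_MZ)
}
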