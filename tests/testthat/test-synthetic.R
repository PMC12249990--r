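# Synthetic cohort generator: counts, determinism, planted structure.

test_that("sample count equals subjects times recordings per subject", {
  cfg <- synthetic_config(n_cases = 2L, n_controls = 1L,
                          n_quiet_per_subject = 1L, n_forced_per_subject = 2L,
                          seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh$samples, 3L * 3L)
  expect_equal(nrow(coh$endpoints), 3L)
  expect_equal(nrow(coh$truth$samples), 9L)
  tab <- table(vapply(coh$samples, function(s) s$maneuver, character(1)))
  expect_equal(unname(tab[["quiet"]]), 3L)
  expect_equal(unname(tab[["forced"]]), 6L)
})

test_that("a minimal one-subject cohort is generated", {
  cfg <- synthetic_config(n_cases = 1L, n_controls = 0L,
                          n_quiet_per_subject = 1L, n_forced_per_subject = 0L,
                          seed = 3)
  coh <- generate_cohort(cfg)
  expect_length(coh$samples, 1L)
  expect_equal(nrow(coh$endpoints), 1L)
  expect_equal(coh$samples[[1]]$maneuver, "quiet")
  expect_equal(coh$samples[[1]]$group, "case")
})

test_that("regenerating with the same seed is bit-identical", {
  cfg <- synthetic_config(n_cases = 1L, n_controls = 1L,
                          n_forced_per_subject = 1L, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$endpoints, b$endpoints)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(synthetic_config(n_cases = 1L, n_controls = 1L,
                                        n_forced_per_subject = 1L,
                                        seed = 78))
  expect_false(identical(a$samples[[1]]$series$scans,
                         c$samples[[1]]$series$scans))
})

test_that("water-adduct trace respects the threshold per planted phase", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 21)
  water <- breathvoc:::extract_ion_trace(rec$series,
                                         tracer_set()$water_adduct)
  thr <- tracer_set()$water_threshold
  expect_true(all(water[rec$truth$phase == "exhale"] > thr))
  expect_true(all(water[rec$truth$phase == "inhale"] < thr))
})

test_that("planted cycle count follows the respiratory rate", {
  for (rate in c(12, 14, 16)) {
    rec <- generate_spectrum_series("quiet", rate = rate, seed = rate)
    expect_equal(rec$truth$n_cycles, rate)
  }
  recf <- generate_spectrum_series("forced", seed = 4)
  expect_equal(recf$truth$n_cycles, 1L)
})

test_that("capnostat lags the water-adduct trace by the configured delay", {
  cfg <- synthetic_config(capnostat_lag = 3L)
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 9,
                                  config = cfg)
  water <- breathvoc:::extract_ion_trace(rec$series,
                                         tracer_set()$water_adduct)
  cap <- rec$series$capnostat
  n <- length(cap)
  lags <- 0:6
  cors <- vapply(lags, function(L) {
    stats::cor(water[seq_len(n - L)], cap[seq_len(n - L) + L])
  }, numeric(1))
  expect_equal(lags[which.max(cors)], 3L)
})

test_that("planted group difference is recovered from latents (oracle)", {
  cfg <- synthetic_config(n_cases = 8L, n_controls = 8L,
                          n_forced_per_subject = 0L, seed = 31)
  coh <- generate_cohort(cfg)
  vocs <- coh$truth$vocs
  lat <- coh$truth$latents
  grp <- coh$endpoints$group
  for (j in which(vocs$effect_size > 0.2)) {
    diff_hat <- mean(lat[grp == "case", j]) - mean(lat[grp == "control", j])
    diff_true <- vocs$case_mean[j] - vocs$control_mean[j]
    se <- vocs$sd[j] * sqrt(1 / sum(grp == "case") +
                              1 / sum(grp == "control"))
    expect_lt(abs(diff_hat - diff_true), 3 * se)
  }
})

test_that("planting a VOC on a tracer or calibrant ion is rejected", {
  bad <- data.frame(mz = 63.02, case_mean = 10, control_mean = 10, sd = 1,
                    missing_rate = 0)
  expect_error(synthetic_config(planted_vocs = bad), "collides")
  bad2 <- data.frame(mz = 21.023, case_mean = 10, control_mean = 10, sd = 1,
                     missing_rate = 0)
  expect_error(synthetic_config(planted_vocs = bad2), "collides")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_cases = 0L, n_controls = 0L),
               "at least one subject")
  expect_error(synthetic_config(mz_min = 100, mz_max = 50), "mz_min")
  expect_error(synthetic_config(respiratory_rate = c(0, 14)),
               "respiratory_rate")
  bad_mr <- breathvoc:::default_planted_vocs()
  bad_mr$missing_rate[1] <- 1
  expect_error(synthetic_config(planted_vocs = bad_mr), "missing_rate")
})

test_that("planted mass drift displaces calibrant centroids as stated", {
  for (drift in c(0, 150)) {
    rec <- generate_spectrum_series("quiet", rate = 14, seed = 55,
                                    drift_ppm = drift)
    s <- rec$series
    obs <- vapply(calibrant_set(), function(r) {
      breathvoc:::find_ion_centroid(s$mz_axis, s$scans[5, ], r)
    }, numeric(1))
    ppm <- (obs - calibrant_set()) / calibrant_set() * 1e6
    expect_equal(ppm, rep(drift, 3), tolerance = 2 / max(drift, 1),
                 ignore_attr = TRUE)
  }
})

test_that("feature-level cohort has the advertised structure", {
  fc <- generate_feature_cohort(n_cases = 10L, n_controls = 10L,
                                n_noise = 20L, n_informative = 3L,
                                seed = 8)
  expect_equal(dim(fc$quiet$values), c(20L, 23L))
  expect_equal(fc$quiet$mz, fc$forced$mz)
  expect_equal(sum(fc$truth$informative), 3L)
  expect_identical(generate_feature_cohort(seed = 8, n_cases = 10L,
                                           n_controls = 10L, n_noise = 20L,
                                           n_informative = 3L)$quiet$values,
                   fc$quiet$values)
})
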