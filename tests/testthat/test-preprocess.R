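# Recalibration, QC, exhalation detection, smoothing, peak picking.

test_that("recalibration is near-identity on an undistorted recording", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 101,
                                  drift_ppm = 0)
  recal <- recalibrate_series(rec$series)
  expect_true(recal$ok)
  expect_lt(max(abs(recal$ppm_before), na.rm = TRUE), 2)
  expect_lt(max(abs(recal$ppm_errors), na.rm = TRUE), 2)
})

test_that("planted uniform drift is observed and corrected", {
  for (drift in c(-200, 75, 150)) {
    rec <- generate_spectrum_series("quiet", rate = 14, seed = 100 + drift,
                                    drift_ppm = drift)
    recal <- recalibrate_series(rec$series)
    expect_true(recal$ok)
    med_before <- apply(recal$ppm_before, 2, stats::median)
    expect_equal(med_before, rep(drift, 3), tolerance = 0.05,
                 ignore_attr = TRUE)
    expect_lt(max(abs(recal$ppm_errors)), 30)
  }
})

test_that("recalibration preserves axis monotonicity and flags lost calibrants", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 7)
  recal <- recalibrate_series(rec$series)
  expect_false(is.unsorted(recal$series$mz_axis, strictly = TRUE))
  # remove the high-mass calibrant: centroid search must fail and flag
  s <- rec$series
  hw <- 0.6
  idx <- which(abs(s$mz_axis - 330.85) < hw)
  s$scans[, idx] <- 0
  recal2 <- recalibrate_series(s)
  expect_false(recal2$ok)
})

test_that("QC applies the capnostat, calibrant and cycle criteria", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 12)
  good <- breath_sample("S1", "case", "quiet", 1, rec$series)
  qc <- qc_sample(good)
  expect_true(qc$passed)
  expect_equal(qc$n_cycles, 14L)
  expect_lt(max(qc$calibrant_ppm_errors), 100)

  # capnostat exceedance: 3.6 units above baseline
  bad_cap <- rec$series
  bad_cap$capnostat <- c(rep(0.1, nrow(bad_cap$scans) - 1), 3.7)
  qc2 <- qc_sample(breath_sample("S1", "case", "quiet", 1, bad_cap))
  expect_false(qc2$passed)
  expect_match(qc2$failure_reasons, "capnostat > 3.5", all = FALSE)

  # two cycles only
  short <- generate_spectrum_series("quiet", rate = 14, seed = 13,
                                    duration_s = 9)
  expect_equal(short$truth$n_cycles, 2L)
  qc3 <- qc_sample(breath_sample("S1", "case", "quiet", 1, short$series))
  expect_false(qc3$passed)
  expect_match(qc3$failure_reasons, "fewer than 3 cycles", all = FALSE)

  # planted capnostat failure flag from the generator
  bad <- generate_spectrum_series("forced", seed = 14, qc_fail = TRUE)
  qc4 <- qc_sample(breath_sample("S1", "case", "forced", 1, bad$series))
  expect_false(qc4$passed)
  expect_match(qc4$failure_reasons, "capnostat", all = FALSE)
})

test_that("QC verdict is a pure function of the reported criteria", {
  reports <- list(
    qc_sample(breath_sample("a", "case", "quiet", 1,
                            generate_spectrum_series("quiet", 14, 15)$series)),
    qc_sample(breath_sample("b", "case", "forced", 1,
                            generate_spectrum_series("forced", seed = 16,
                                                     qc_fail = TRUE)$series))
  )
  for (r in reports) {
    rederived <- r$capnostat_max <= 3.5 &&
      all(r$calibrant_ppm_errors < 100) && r$n_cycles >= r$min_cycles
    expect_identical(r$passed, rederived)
  }
})

test_that("exhalation selection needs the water threshold and biogenic maxima", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 18)
  det <- detect_exhalation_spectra(rec$series)
  expect_equal(det$n_cycles, 14L)
  expect_gt(length(det$selected), 0)
  # selected scans sit in planted exhalations (allowing transition edges)
  expect_true(all(rec$truth$phase[det$selected] != "inhale"))

  # attenuated water trace: nothing passes the 2e5 cps threshold
  weak <- rec$series
  weak$scans <- weak$scans / 10
  det2 <- detect_exhalation_spectra(weak)
  expect_length(det2$selected, 0)
  expect_equal(det2$n_cycles, 0L)
})

test_that("doubling intensities can only add selected scans", {
  rec <- generate_spectrum_series("quiet", rate = 14, seed = 19)
  base <- rec$series
  base$scans <- base$scans / 3  # push some exhalations near the threshold
  det1 <- detect_exhalation_spectra(base)
  doubled <- base
  doubled$scans <- doubled$scans * 2
  det2 <- detect_exhalation_spectra(doubled)
  expect_true(all(det1$selected %in% det2$selected))
})

test_that("best-forced selection prefers passing replicates and breaks ties low", {
  mk <- function(seed, qc_fail, replicate) {
    rec <- generate_spectrum_series("forced", seed = seed, qc_fail = qc_fail)
    preprocess_sample(breath_sample("S1", "case", "forced", replicate,
                                    rec$series))
  }
  reps <- list(mk(21, TRUE, 1L), mk(22, FALSE, 2L), mk(23, FALSE, 3L))
  best <- select_best_forced(reps)
  expect_true(best$replicate %in% c(2L, 3L))
  expect_true(best$qc$passed)

  single <- list(mk(24, FALSE, 1L))
  expect_equal(select_best_forced(single)$replicate, 1L)

  # identical replicates (same seed) tie on score: lowest index wins
  tie <- list(mk(30, FALSE, 2L), mk(30, FALSE, 1L))
  expect_equal(select_best_forced(tie)$replicate, 1L)

  none <- list(mk(25, TRUE, 1L), mk(26, TRUE, 2L))
  expect_null(select_best_forced(none))
})

test_that("averaging preserves constants and smoothing reduces noise", {
  mz <- seq(40, 60, by = 0.02)
  const <- spectrum_series(mz, matrix(c(rep(2, length(mz)),
                                        rep(4, length(mz))),
                                      nrow = 2, byrow = TRUE),
                           scan_times = c(0.5, 1.5), capnostat = c(0, 0))
  out <- average_and_smooth(const, 1:2)
  expect_equal(out, rep(3, length(mz)), tolerance = 1e-10)
  expect_error(average_and_smooth(const, integer(0)),
               "no exhalation spectra")

  truth <- 100 * exp(-(mz - 50)^2 / (2 * 0.05^2))
  noisy <- with_seed(40, {
    matrix(rep(truth, 10), nrow = 10, byrow = TRUE) +
      matrix(stats::rnorm(10 * length(mz), sd = 5), nrow = 10)
  })
  noisy[noisy < 0] <- 0
  ser <- spectrum_series(mz, noisy, scan_times = (1:10) - 0.5,
                         capnostat = rep(0, 10))
  smoothed <- average_and_smooth(ser, 1:10)
  plain_mean <- colMeans(noisy)
  expect_lt(sqrt(mean((smoothed - truth)^2)),
            sqrt(mean((plain_mean - truth)^2)))
})

test_that("peak picking recovers planted Gaussians and ignores flat noise", {
  cfg <- synthetic_config()
  mz <- breathvoc:::build_mz_axis(cfg)
  sig <- function(m) peak_sigma(m)
  spec <- 5e3 * exp(-(mz - 69.070)^2 / (2 * sig(69.07)^2)) +
    with_seed(41, pmax(0, stats::rnorm(length(mz), sd = 2)))
  pk <- pick_peaks(mz, signal::sgolayfilt(spec, p = 2, n = 9))
  hit <- pk[abs(pk$mz - 69.070) < 0.05, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$mz - 69.070), 0.005)

  expect_equal(nrow(pick_peaks(mz, rep(0, length(mz)))), 0L)
  flat <- with_seed(42, pmax(0, stats::rnorm(length(mz), sd = 2)))
  pk0 <- pick_peaks(mz, signal::sgolayfilt(flat, p = 2, n = 9))
  expect_equal(nrow(pk0[pk0$apex > 10, ]), 0L)

  doublet <- 4e3 * exp(-(mz - 100.00)^2 / (2 * sig(100)^2)) +
    3e3 * exp(-(mz - 100.50)^2 / (2 * sig(100.5)^2))
  pk2 <- pick_peaks(mz, signal::sgolayfilt(doublet, p = 2, n = 9))
  near <- pk2[abs(pk2$mz - 100.25) < 0.5, ]
  expect_equal(nrow(near), 2L)
  expect_lt(abs(sort(near$mz)[1] - 100.00), 0.01)
  expect_lt(abs(sort(near$mz)[2] - 100.50), 0.01)
})
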