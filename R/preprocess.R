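# Per-sample processing: mass-axis recalibration against the permeation
# source calibrants, quality control, exhalation-spectrum selection from the
# water-adduct and biogenic tracer ions, averaging and Savitzky-Golay
# smoothing, and peak picking.

# Locate the centroid of a calibrant ion near `ref_mz` in one spectrum.
# Search window +-0.5 m/z; centroid by a three-point parabola fit on
# log-intensity around the apex (exact for a Gaussian peak shape); falls
# back to the apex position at window edges. Returns NA when no apex stands
# above the local noise.
find_ion_centroid <- function(mz_axis, intensity, ref_mz, window = 0.5) {
  lo <- findInterval(ref_mz - window, mz_axis) + 1L
  hi <- findInterval(ref_mz + window, mz_axis)
  if (lo >= hi) return(NA_real_)
  y <- intensity[lo:hi]
  k <- which.max(y)
  # The window may be only a few bins wide at high m/z, so gauge the local
  # floor by the window minimum rather than a median/MAD estimate.
  floor_y <- min(y)
  if (y[k] < 20 || y[k] < 30 * (floor_y + 1)) return(NA_real_)
  i <- lo + k - 1L
  if (i <= 1L || i >= length(mz_axis)) return(mz_axis[i])
  y3 <- intensity[(i - 1L):(i + 1L)]
  if (any(y3 <= 0)) return(mz_axis[i])
  ly <- log(y3)
  x3 <- mz_axis[(i - 1L):(i + 1L)]
  # Vertex of the parabola through (x, log y); guards against flat tops.
  d1 <- (ly[3] - ly[1]) / 2
  d2 <- ly[1] - 2 * ly[2] + ly[3]
  if (d2 >= 0) return(mz_axis[i])
  # Uniform-in-log grid: interpolate in index space, then map back.
  off <- -d1 / d2
  off <- max(min(off, 1), -1)
  exp(log(x3[2]) + off * (log(x3[3]) - log(x3[1])) / 2)
}

#' Recalibrate a spectrum series against calibrant ions
#'
#' Every scan is recalibrated independently: the observed centroid of each
#' calibrant is located within a +-0.5 m/z search window, a degree-1
#' least-squares fit of reference vs observed position in sqrt(m/z) space
#' (TOF-linear) gives the axis correction, the corrected spectrum is
#' resampled onto the common nominal axis, and residual calibrant errors are
#' reported in ppm.
#'
#' @param series A [spectrum_series()].
#' @param calibrants A [calibrant_set()].
#' @return A list with `series` (recalibrated, on the original axis),
#'   `ppm_errors` (matrix scans x calibrants of post-fit residuals),
#'   `ppm_before` (pre-fit observed errors), and `ok` (`FALSE` when any
#'   calibrant was undetectable in any scan; such samples are flagged for
#'   QC exclusion).
#' @export
recalibrate_series <- function(series, calibrants = calibrant_set()) {
  stopifnot(inherits(series, "spectrum_series"))
  mz <- series$mz_axis
  n_scan <- nrow(series$scans)
  n_cal <- length(calibrants)
  ppm_after <- ppm_before <- matrix(NA_real_, n_scan, n_cal)
  out <- series$scans
  ok <- TRUE
  sqrt_mz <- sqrt(mz)
  for (t in seq_len(n_scan)) {
    y <- series$scans[t, ]
    obs <- vapply(calibrants, function(r) find_ion_centroid(mz, y, r),
                  numeric(1))
    if (anyNA(obs)) { ok <- FALSE; next }
    ppm_before[t, ] <- (obs - calibrants) / calibrants * 1e6
    fit <- stats::lm.fit(cbind(1, sqrt(obs)), sqrt(calibrants))
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (!is.finite(b) || b <= 0) { ok <- FALSE; next }
    corrected_axis <- (a + b * sqrt_mz)^2
    out[t, ] <- stats::approx(corrected_axis, y, xout = mz,
                              yleft = 0, yright = 0)$y
    corr_obs <- (a + b * sqrt(obs))^2
    ppm_after[t, ] <- (corr_obs - calibrants) / calibrants * 1e6
  }
  list(
    series = spectrum_series(mz, pmax(out, 0), series$scan_times,
                             series$capnostat),
    ppm_errors = ppm_after, ppm_before = ppm_before, ok = ok
  )
}

# Extracted-ion trace: per-scan maximum intensity within the extraction
# window around an ion m/z.
extract_ion_trace <- function(series, ion_mz) {
  hw <- extraction_half_width(ion_mz)
  lo <- findInterval(ion_mz - hw, series$mz_axis) + 1L
  hi <- findInterval(ion_mz + hw, series$mz_axis)
  if (lo > hi) return(rep(0, nrow(series$scans)))
  apply(series$scans[, lo:hi, drop = FALSE], 1L, max)
}

#' Select exhalation spectra from tracer ions
#'
#' A scan is selected iff the water-adduct extracted-ion intensity exceeds
#' the threshold (2e5 cps) AND the scan lies within the local-maximum
#' neighborhood (+-`max_half` scans) of at least two of the three biogenic
#' tracer traces. Local maxima are strict maxima of the running-mean
#' smoothed trace over a centered window of `max_half` scans per side
#' (truncated at the recording edges). Cycles are counted as contiguous
#' selected segments.
#'
#' @param series A recalibrated [spectrum_series()].
#' @param tracers A [tracer_set()].
#' @param max_half Half-width (scans) of the local-maximum window.
#' @return A list with `selected` (integer scan indices), `n_cycles`, and
#'   the water-adduct trace `water`.
#' @export
detect_exhalation_spectra <- function(series, tracers = tracer_set(),
                                      max_half = 2L) {
  stopifnot(inherits(series, "spectrum_series"))
  n <- nrow(series$scans)
  water <- extract_ion_trace(series, tracers$water_adduct)
  near_max <- matrix(FALSE, n, length(tracers$biogenic))
  for (j in seq_along(tracers$biogenic)) {
    tr <- running_mean(extract_ion_trace(series, tracers$biogenic[j]), 1L)
    # Strict local maxima with edge-truncated windows.
    peaks <- integer(0)
    for (i in seq_len(n)) {
      lo <- max(1L, i - max_half); hi <- min(n, i + max_half)
      win <- tr[lo:hi]
      if (hi - lo < 1L) next
      if (tr[i] > max(win[-(i - lo + 1L)])) peaks <- c(peaks, i)
    }
    for (p in peaks) {
      near_max[max(1L, p - max_half):min(n, p + max_half), j] <- TRUE
    }
  }
  selected <- which(water > tracers$water_threshold &
                      rowSums(near_max) >= 2L)
  n_cycles <- if (length(selected)) {
    sum(diff(selected) > 1L) + 1L
  } else 0L
  list(selected = selected, n_cycles = as.integer(n_cycles), water = water)
}

#' Quality control for one breath sample
#'
#' A sample passes when (i) the baseline-subtracted capnostat maximum does
#' not exceed 3.5 units, (ii) all calibrant residual errors are below
#' 100 ppm in magnitude (and all calibrants were found), and (iii) the
#' recording contains at least `min_cycles` complete inhalation-exhalation
#' cycles. The cycle criterion defaults to three for quiet breathing and
#' one for a forced expiration (which by design is a single long
#' exhalation).
#'
#' @param sample A [breath_sample()].
#' @param recal Result of [recalibrate_series()] on the sample's series; if
#'   `NULL` it is computed here.
#' @param detection Result of [detect_exhalation_spectra()]; if `NULL` it
#'   is computed here (on the recalibrated series).
#' @param capnostat_limit Capnostat exceedance threshold (units).
#' @param ppm_limit Calibrant residual acceptance margin (ppm).
#' @param min_cycles Minimum cycle count; `NULL` picks the maneuver default.
#' @return A `qc_report` list with fields `capnostat_max`,
#'   `calibrant_ppm_errors` (median |residual| per calibrant), `n_cycles`,
#'   `passed`, and `failure_reasons`.
#' @export
qc_sample <- function(sample, recal = NULL, detection = NULL,
                      capnostat_limit = CAPNOSTAT_LIMIT,
                      ppm_limit = CALIBRANT_PPM_LIMIT,
                      min_cycles = NULL) {
  stopifnot(inherits(sample, "breath_sample"))
  if (is.null(recal)) recal <- recalibrate_series(sample$series)
  if (is.null(detection)) detection <- detect_exhalation_spectra(recal$series)
  min_cycles <- min_cycles %||%
    if (sample$maneuver == "quiet") MIN_CYCLES_QUIET else 1L

  cap <- sample$series$capnostat
  capnostat_max <- max(cap) - stats::quantile(cap, 0.05, names = FALSE)
  ppm <- apply(abs(recal$ppm_errors), 2L, stats::median, na.rm = TRUE)
  reasons <- character(0)
  if (capnostat_max > capnostat_limit) {
    reasons <- c(reasons, sprintf("capnostat > %.1f", capnostat_limit))
  }
  if (!recal$ok || anyNA(ppm) || any(ppm >= ppm_limit)) {
    reasons <- c(reasons, sprintf("calibrant error >= %d ppm", ppm_limit))
  }
  if (detection$n_cycles < min_cycles) {
    reasons <- c(reasons, sprintf("fewer than %d cycles", min_cycles))
  }
  structure(
    list(capnostat_max = capnostat_max, calibrant_ppm_errors = ppm,
         n_cycles = detection$n_cycles, min_cycles = min_cycles,
         passed = length(reasons) == 0L, failure_reasons = reasons),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: capnostat %.2f, calibrants %s ppm, %d cycles%s\n",
              if (x$passed) "PASS" else "FAIL", x$capnostat_max,
              paste(sprintf("%.1f", x$calibrant_ppm_errors), collapse = "/"),
              x$n_cycles,
              if (x$passed) "" else
                paste0(" [", paste(x$failure_reasons, collapse = "; "), "]")))
  invisible(x)
}

#' Pick the best forced-expiration replicate
#'
#' Among QC-passing replicates, ranks by detected cycle count, then total
#' water-adduct signal over the selected scans; ties go to the lowest
#' replicate index. Replicates must carry QC reports (see
#' [preprocess_sample()]).
#'
#' @param replicates List of [breath_sample()] with `qc` attached and a
#'   `detection` attribute (as produced by [preprocess_sample()]).
#' @return The winning [breath_sample()], or `NULL` when every replicate
#'   fails QC (the subject's forced arm is then missing).
#' @export
select_best_forced <- function(replicates) {
  passing <- Filter(function(s) isTRUE(s$qc$passed), replicates)
  if (!length(passing)) return(NULL)
  score <- vapply(passing, function(s) {
    det <- attr(s, "detection")
    area <- if (is.null(det)) 0 else sum(det$water[det$selected])
    s$qc$n_cycles * 1e12 + area
  }, numeric(1))
  idx <- vapply(passing, function(s) s$replicate, integer(1))
  passing[[order(-score, idx)[1]]]
}

#' Average selected scans and smooth along the m/z axis
#'
#' Arithmetic mean over the selected scans followed by Savitzky-Golay
#' smoothing (window 9 points, polynomial order 2 by default).
#'
#' @param series A [spectrum_series()].
#' @param selected Integer scan indices (from
#'   [detect_exhalation_spectra()]).
#' @param sg_window,sg_order Savitzky-Golay filter length (odd) and
#'   polynomial order.
#' @return Numeric vector of length `length(series$mz_axis)`.
#' @export
average_and_smooth <- function(series, selected, sg_window = 9L,
                               sg_order = 2L) {
  if (!length(selected)) stop("no exhalation spectra", call. = FALSE)
  m <- colMeans(series$scans[selected, , drop = FALSE])
  # The smoothed spectrum may dip slightly below zero at peak flanks (the
  # filter's negative sidelobes); downstream integration is signed, so the
  # dips cancel rather than bias areas.
  signal::sgolayfilt(m, p = sg_order, n = sg_window)
}

#' Pick peaks from a smoothed mean spectrum
#'
#' Local maxima above a noise-derived prominence floor (3x the median
#' absolute deviation of the spectrum above the median baseline). The
#' support of each peak extends downhill on both sides until the intensity
#' falls below baseline + 1 MAD or rises again. Centroid is the
#' baseline-subtracted intensity-weighted mean over the support; area is
#' the trapezoidal integral of the baseline-subtracted intensity.
#'
#' @param mz_axis m/z axis.
#' @param spectrum Smoothed mean spectrum (same length).
#' @param prominence Multiplier of the MAD noise scale for the peak floor.
#' @return A `peak_table` data frame with columns `mz`, `area`, `apex`,
#'   sorted by centroid.
#' @export
pick_peaks <- function(mz_axis, spectrum, prominence = 3) {
  n <- length(spectrum)
  baseline <- stats::median(spectrum)
  noise <- stats::mad(spectrum)
  floor_y <- baseline + prominence * max(noise, .Machine$double.eps)
  is_max <- c(FALSE, spectrum[2:(n - 1)] > spectrum[1:(n - 2)] &
                spectrum[2:(n - 1)] >= spectrum[3:n], FALSE)
  cand <- which(is_max & spectrum > floor_y)
  if (!length(cand)) {
    return(structure(data.frame(mz = numeric(0), area = numeric(0),
                                apex = numeric(0)),
                     class = c("peak_table", "data.frame")))
  }
  stop_y <- baseline + max(noise, .Machine$double.eps)
  out <- lapply(cand, function(i) {
    lo <- i
    while (lo > 1L && spectrum[lo - 1L] < spectrum[lo] &&
           spectrum[lo - 1L] > stop_y) lo <- lo - 1L
    hi <- i
    while (hi < n && spectrum[hi + 1L] < spectrum[hi] &&
           spectrum[hi + 1L] > stop_y) hi <- hi + 1L
    if (lo > 1L) lo <- lo - 1L
    if (hi < n) hi <- hi + 1L
    idx <- lo:hi
    w <- pmax(spectrum[idx] - baseline, 0)
    if (sum(w) <= 0) return(NULL)
    data.frame(mz = sum(w * mz_axis[idx]) / sum(w),
               area = trapz(mz_axis[idx], w),
               apex = spectrum[i] - baseline)
  })
  tab <- do.call(rbind, out)
  tab <- tab[tab$area > 0, , drop = FALSE]
  tab <- tab[order(tab$mz), , drop = FALSE]
  # Merge apexes sharing (almost) the same centroid, keeping the taller.
  keep <- !duplicated(round(tab$mz / 1e-4))
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("peak_table", "data.frame"))
}

#' Full per-sample preprocessing
#'
#' Recalibration, exhalation selection, QC, averaging/smoothing and peak
#' picking in one call.
#'
#' @param sample A [breath_sample()].
#' @param calibrants A [calibrant_set()].
#' @param tracers A [tracer_set()].
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return The sample with `qc` attached, plus attributes `detection`,
#'   `mean_spectrum` and `peaks` (NULL when QC fails or nothing was
#'   selected).
#' @export
preprocess_sample <- function(sample, calibrants = calibrant_set(),
                              tracers = tracer_set(), sg_window = 9L,
                              sg_order = 2L) {
  recal <- recalibrate_series(sample$series, calibrants)
  detection <- detect_exhalation_spectra(recal$series, tracers)
  qc <- qc_sample(sample, recal, detection)
  out <- sample
  out$series <- recal$series
  out$qc <- qc
  attr(out, "detection") <- detection
  if (qc$passed && length(detection$selected)) {
    ms <- average_and_smooth(recal$series, detection$selected,
                             sg_window, sg_order)
    attr(out, "mean_spectrum") <- ms
    attr(out, "peaks") <- pick_peaks(recal$series$mz_axis, ms)
  }
  out
}
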