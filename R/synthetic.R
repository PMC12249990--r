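# Synthetic PTR-TOF-MS breath cohort generator.
#
# Emulates a case-control breathomics study: per subject one quiet-breathing
# recording (60 s, 12-16 exhalation cycles) and three forced-expiration
# recordings (30 s, one long exhalation), full-scan spectra on a 10-685 m/z
# axis at 1000 ms per scan, with permeation-source calibrant ions, a
# breath-modulated water-adduct tracer, biogenic tracer ions, a heavy-water
# normalization reference ion, planted case/control VOC differences, uniform
# mass-axis drift, and a delayed capnostat channel. Ground truth (phase per
# scan, planted areas, latent VOC levels, intended QC outcome) is returned
# for recovery tests.

# Default planted VOC panel: m/z and group means/dispersions of the
# quiet-breathing area comparisons for the panel of discriminative ions this
# pipeline targets (normalized peak areas, cps). The dimethyl sulfide ion at
# 63.02 is a breath-phase tracer here and therefore not plantable.
default_planted_vocs <- function() {
  data.frame(
    mz = c(42.03, 44.99, 48.04, 50.00, 57.06, 73.06, 74.05, 82.07, 90.06,
           91.06, 99.07, 103.08, 113.13, 127.00, 129.07, 133.10, 141.13,
           150.10, 173.15, 181.00, 329.82),
    case_mean = c(73.8, 7056.6, 142.5, 64.0, 601.0, 196.5, 148.6, 52.8,
                  57.1, 108.8, 68.7, 113.2, 51.6, 57.5, 42.5, 34.0, 2902.3,
                  26.3, 109.6, 37.3, 1626.3),
    control_mean = c(91.0, 8035.1, 139.7, 73.6, 547.0, 197.0, 145.5, 53.1,
                     60.0, 117.3, 72.0, 103.2, 56.7, 60.1, 50.9, 35.6,
                     3145.4, 33.5, 90.6, 39.7, 1411.8),
    sd = c(29, 1530, 117, 16, 335, 58, 41, 27, 16.6, 38, 18.5, 67, 8.7, 20,
           8.1, 7.5, 1760, 23, 28, 39.5, 532),
    missing_rate = c(0, 0, 0.05, 0, 0, 0, 0, 0, 0, 0, 0, 0.05, 0, 0, 0,
                     0.05, 0, 0.05, 0, 0.10, 0)
  )
}

#' Configuration of the synthetic breath cohort
#'
#' Defaults reproduce the emulated study design: 51 cases and 51 controls,
#' one 60 s quiet-breathing recording and three 30 s forced-expiration
#' recordings per subject (408 recordings in total), 1000 ms scans on a
#' 10-685 m/z axis, quiet respiratory rates drawn from 12-16 breaths/min.
#'
#' @param n_cases,n_controls Number of case/control subjects (>= 0, at
#'   least one subject in total).
#' @param n_quiet_per_subject,n_forced_per_subject Recordings per subject
#'   and maneuver.
#' @param quiet_seconds,forced_seconds Recording durations (s).
#' @param scan_ms Scan time in milliseconds.
#' @param respiratory_rate Two-element range (breaths/min) from which each
#'   subject's quiet-breathing rate is drawn; must lie in (0, 60].
#' @param mz_min,mz_max Mass-axis limits.
#' @param resolution TOF resolving power m/dm used for synthetic peak widths.
#' @param points_per_fwhm Mass-axis sampling density (grid points per peak
#'   FWHM; the axis is log-spaced so this is constant across the axis).
#' @param drift_ppm Uniform mass-axis distortion planted in every recording
#'   (ppm; observed m/z = true m/z * (1 + drift_ppm * 1e-6)).
#' @param planted_vocs Data frame with columns `mz`, `case_mean`,
#'   `control_mean`, `sd`, `missing_rate` describing the planted VOC panel.
#' @param noise_sd Additive baseline noise (cps) per axis point and scan.
#' @param capnostat_lag Delay of the capnostat channel behind the
#'   water-adduct trace, in scans.
#' @param qc_fail_rate Fraction of forced replicates planted to fail QC via
#'   a capnostat exceedance (exercises best-replicate selection).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases = 51L, n_controls = 51L,
                             n_quiet_per_subject = 1L,
                             n_forced_per_subject = 3L,
                             quiet_seconds = 60, forced_seconds = 30,
                             scan_ms = 1000,
                             respiratory_rate = c(12, 16),
                             mz_min = 10, mz_max = 685,
                             resolution = TOF_RESOLUTION,
                             points_per_fwhm = 3,
                             drift_ppm = 30,
                             planted_vocs = default_planted_vocs(),
                             noise_sd = 2,
                             capnostat_lag = 2L,
                             qc_fail_rate = 0.05,
                             seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0,
            n_quiet_per_subject >= 0, n_forced_per_subject >= 0)
  if (n_cases + n_controls < 1L) stop("need at least one subject", call. = FALSE)
  if (n_quiet_per_subject + n_forced_per_subject < 1L) {
    stop("need at least one recording per subject", call. = FALSE)
  }
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max", call. = FALSE)
  if (length(respiratory_rate) == 1L) {
    respiratory_rate <- rep(respiratory_rate, 2L)
  }
  if (any(respiratory_rate <= 0) || any(respiratory_rate > 60)) {
    stop("respiratory_rate must lie in (0, 60] breaths/min", call. = FALSE)
  }
  if (any(planted_vocs$missing_rate < 0) || any(planted_vocs$missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(planted_vocs$mz < mz_min) || any(planted_vocs$mz > mz_max)) {
    stop("planted VOC m/z outside [mz_min, mz_max]", call. = FALSE)
  }
  # Planted VOCs must not collide with calibrant, tracer, or reference ions:
  # their signals would be inseparable within the extraction window.
  reserved <- c(calibrant_set(), tracer_set()$water_adduct,
                tracer_set()$biogenic, REFERENCE_ION_MZ)
  for (m in planted_vocs$mz) {
    hit <- reserved[abs(reserved - m) < 2 * extraction_half_width(reserved)]
    if (length(hit)) {
      stop(sprintf(
        "planted VOC at m/z %.4f collides with reserved ion at m/z %.4f",
        m, hit[1]), call. = FALSE)
    }
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_quiet_per_subject = as.integer(n_quiet_per_subject),
         n_forced_per_subject = as.integer(n_forced_per_subject),
         quiet_seconds = quiet_seconds, forced_seconds = forced_seconds,
         scan_ms = scan_ms, respiratory_rate = sort(respiratory_rate),
         mz_min = mz_min, mz_max = mz_max, resolution = resolution,
         points_per_fwhm = points_per_fwhm, drift_ppm = drift_ppm,
         planted_vocs = planted_vocs, noise_sd = noise_sd,
         capnostat_lag = as.integer(capnostat_lag),
         qc_fail_rate = qc_fail_rate, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Log-spaced m/z axis: constant resolving power means constant peak width in
# log-m/z, so log spacing gives a fixed number of grid points per FWHM.
build_mz_axis <- function(config) {
  delta <- 1 / (config$resolution * config$points_per_fwhm)
  n <- ceiling(log(config$mz_max / config$mz_min) / delta)
  config$mz_min * exp(seq(0, n) * delta)
}

# Breath envelope in [0, 1] over scan midpoint times. Quiet breathing:
# raised-cosine exhalation bumps of fixed width repeating at the respiratory
# period. Forced expiration: a single wide raised-cosine dome. The bump
# width (3.2 s) keeps, at 1 s scans and 12-16 breaths/min, at least one scan
# above and one below the water threshold in every cycle.
breath_envelope <- function(times, maneuver, rate = 14, duration = NULL,
                            exhale_width = 3.2, forced_width = 20) {
  if (maneuver == "quiet") {
    period <- 60 / rate
    phase <- times %% period
    ifelse(phase < exhale_width,
           0.5 * (1 - cos(2 * pi * phase / exhale_width)), 0)
  } else {
    start <- 4
    u <- times - start
    ifelse(u >= 0 & u <= forced_width,
           0.5 * (1 - cos(2 * pi * u / forced_width)), 0)
  }
}

# Count complete exhalation bumps in a quiet recording.
n_planted_cycles <- function(maneuver, rate, duration, exhale_width = 3.2) {
  if (maneuver == "forced") return(1L)
  period <- 60 / rate
  as.integer(floor((duration - exhale_width) / period) + 1L)
}

# Add a Gaussian peak (given apex intensity per scan) to a scan matrix.
add_peak <- function(scans, mz_axis, center, sigma, apex_per_scan) {
  lo <- findInterval(center - 4 * sigma, mz_axis) + 1L
  hi <- findInterval(center + 4 * sigma, mz_axis)
  if (lo > hi) return(scans)
  idx <- lo:hi
  shape <- exp(-((mz_axis[idx] - center)^2) / (2 * sigma^2))
  scans[, idx] <- scans[, idx] + outer(apex_per_scan, shape)
  scans
}

#' Generate one synthetic breath recording
#'
#' Produces a [spectrum_series()] with the structure the pipeline assumes:
#' the water-adduct trace (m/z 37.038) oscillates with the breath cycle and
#' exceeds 2e5 cps during exhalation plateaus; the biogenic tracers
#' (isoprene 69.07, dimethyl sulfide 63.02, 1,2-butadiene 55.03) and planted
#' VOCs are breath-modulated; calibrant ions are constant in time; the mass
#' axis is distorted by `drift_ppm`; the capnostat lags the water-adduct
#' trace by `capnostat_lag` scans.
#'
#' @param maneuver `"quiet"` or `"forced"`.
#' @param rate Respiratory rate in breaths/min (quiet breathing).
#' @param seed Integer seed.
#' @param config A [synthetic_config()]; axis, noise and drift defaults are
#'   taken from it.
#' @param voc_areas Named numeric vector (names = m/z as written by
#'   `sprintf("%.4f", mz)`) of planted peak areas for this recording; `NULL`
#'   plants nothing beyond tracers and calibrants.
#' @param drift_ppm Mass-axis distortion for this recording.
#' @param duration_s Recording length in seconds.
#' @param qc_fail If `TRUE`, the capnostat amplitude is planted to exceed
#'   the 3.5-unit QC limit.
#' @param forced_width Width (s) of the forced-expiration dome.
#' @return A list with `series` (a [spectrum_series()]) and `truth`
#'   (per-scan phase labels `"exhale"`/`"inhale"`/`"transition"`, the
#'   planted cycle count, rate, drift and planted areas).
#' @export
generate_spectrum_series <- function(maneuver = c("quiet", "forced"),
                                     rate = 14, seed = 1L,
                                     config = synthetic_config(),
                                     voc_areas = NULL,
                                     drift_ppm = config$drift_ppm,
                                     duration_s = NULL,
                                     qc_fail = FALSE,
                                     forced_width = 20) {
  maneuver <- match.arg(maneuver)
  duration_s <- duration_s %||%
    if (maneuver == "quiet") config$quiet_seconds else config$forced_seconds
  with_seed(seed, {
    dt <- config$scan_ms / 1000
    n_scans <- as.integer(round(duration_s / dt))
    times <- (seq_len(n_scans) - 0.5) * dt
    mz_axis <- build_mz_axis(config)
    env <- breath_envelope(times, maneuver, rate, duration_s,
                           forced_width = forced_width)

    scans <- matrix(pmax(0, stats::rnorm(n_scans * length(mz_axis),
                                         sd = config$noise_sd)),
                    nrow = n_scans)
    d <- 1 + drift_ppm * 1e-6
    sig <- function(m) peak_sigma(m * d, config$resolution)

    # Calibrant ions: constant in time.
    cal <- calibrant_set()
    cal_apex <- c(5e4, 2e4, 1e4)[seq_along(cal)]
    for (j in seq_along(cal)) {
      scans <- add_peak(scans, mz_axis, cal[j] * d, sig(cal[j]),
                        rep(cal_apex[j], n_scans))
    }

    jitter <- function() 1 + stats::rnorm(n_scans, sd = 0.02)
    tr <- tracer_set()
    # Water adduct: far above the 2e5 cps threshold at exhalation plateaus,
    # far below it between cycles.
    water_apex <- (2e4 + 6e5 * env) * jitter()
    scans <- add_peak(scans, mz_axis, tr$water_adduct * d,
                      sig(tr$water_adduct), water_apex)
    # Biogenic tracers, breath-modulated.
    bio_apex <- c(4e3, 6e3, 1.2e4)
    for (j in seq_along(tr$biogenic)) {
      scans <- add_peak(scans, mz_axis, tr$biogenic[j] * d,
                        sig(tr$biogenic[j]),
                        (150 + bio_apex[j] * env) * jitter())
    }
    # Heavy-water normalization reference, breath-modulated.
    scans <- add_peak(scans, mz_axis, REFERENCE_ION_MZ * d,
                      sig(REFERENCE_ION_MZ), (500 + 2e4 * env) * jitter())

    # Planted VOCs: area -> apex via the Gaussian normalization constant.
    if (!is.null(voc_areas) && length(voc_areas)) {
      mzs <- as.numeric(names(voc_areas))
      for (j in seq_along(voc_areas)) {
        if (voc_areas[j] <= 0) next
        s <- sig(mzs[j])
        apex <- voc_areas[j] / (s * sqrt(2 * pi))
        scans <- add_peak(scans, mz_axis, mzs[j] * d, s,
                          apex * env * jitter())
      }
    }

    # Capnostat: lagged, rescaled copy of the breath envelope in arbitrary
    # units; planted failures exceed the 3.5-unit limit.
    amp <- if (qc_fail) 4.8 else 1.4
    lag <- config$capnostat_lag
    env_lag <- c(rep(0, lag), env)[seq_len(n_scans)]
    capnostat <- 0.2 + amp * env_lag + stats::rnorm(n_scans, sd = 0.02)

    phase <- ifelse(env >= 0.4, "exhale",
                    ifelse(env <= 0.2, "inhale", "transition"))
    list(
      series = spectrum_series(mz_axis, scans, times, capnostat),
      truth = list(phase = phase,
                   n_cycles = n_planted_cycles(maneuver, rate, duration_s),
                   rate = rate, drift_ppm = drift_ppm,
                   qc_fail = qc_fail,
                   voc_areas = voc_areas)
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Emits `n_quiet_per_subject + n_forced_per_subject` recordings per subject
#' with planted case-vs-control VOC differences, a subject-level endpoint
#' table whose binary endpoints (group, pneumothorax history) and
#' quantitative endpoints (cyst-volume and distal-lumen-area analogs, lung
#' function z-scores) are coupled to designated planted VOCs, and a truth
#' table for recovery tests. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `samples` (list of [breath_sample()]), `endpoints`
#'   (data frame, one row per subject), and `truth` (list with `vocs`,
#'   `latents`, `samples`, `phases`, `planted`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_sub <- config$n_cases + config$n_controls
  subjects <- sprintf("S%03d", seq_len(n_sub))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  vocs <- config$planted_vocs

  with_seed(config$seed, {
    # Subject-level latent VOC areas (shared across maneuvers/replicates).
    mu <- ifelse(group == "case", 1, 0) %o% vocs$case_mean +
      ifelse(group == "control", 1, 0) %o% vocs$control_mean
    latents <- mu + matrix(stats::rnorm(n_sub * nrow(vocs)), n_sub) *
      rep(vocs$sd, each = n_sub)
    latents <- pmax(latents, 0.05 * rep(pmin(vocs$case_mean, vocs$control_mean),
                                        each = n_sub))
    dimnames(latents) <- list(subjects, sprintf("%.4f", vocs$mz))

    # Standardized latents for endpoint coupling.
    zl <- function(mz) {
      j <- which(abs(vocs$mz - mz) < 1e-6)
      (latents[, j] - ifelse(group == "case", vocs$case_mean[j],
                             vocs$control_mean[j])) / vocs$sd[j]
    }
    is_case <- group == "case"
    endpoints <- data.frame(
      subject_id = subjects, group = group,
      pneumothorax = is_case &
        stats::runif(n_sub) < stats::plogis(-0.15 + 0.8 * zl(103.08) -
                                              0.8 * zl(133.10)),
      fev1_z = ifelse(is_case, -1.5 + 0.5 * zl(48.04) + 0.5 * zl(173.15),
                      0) + stats::rnorm(n_sub, sd = 1),
      fvc_z = ifelse(is_case, -0.8, 0) + stats::rnorm(n_sub, sd = 1),
      fev1_fvc_z = ifelse(is_case, -1.8 - 0.5 * zl(129.07) - 0.4 * zl(141.13),
                          0) + stats::rnorm(n_sub, sd = 1),
      rv_z = ifelse(is_case, 1.8 - 0.5 * zl(42.03), 0) +
        stats::rnorm(n_sub, sd = 1),
      rv_tlc_z = ifelse(is_case, 1.7 + 0.5 * zl(74.05), 0) +
        stats::rnorm(n_sub, sd = 1),
      dlco_z = ifelse(is_case, -1.9 + 0.5 * zl(48.04), 0) +
        stats::rnorm(n_sub, sd = 1),
      cyst_volume_pct = ifelse(
        is_case,
        pmin(95, pmax(0, 22.3 - 9.9 * zl(129.07) +
                        stats::rnorm(n_sub, sd = 13.2))), 0),
      lumen_area_mm2 = ifelse(
        is_case,
        pmax(0.1, 1.35 + 0.25 * zl(57.06) + stats::rnorm(n_sub, sd = 0.5)),
        NA_real_),
      mtor_inhibitor = is_case & stats::runif(n_sub) < 0.392
    )

    rates <- stats::runif(n_sub, config$respiratory_rate[1],
                          config$respiratory_rate[2])

    samples <- list()
    phases <- list()
    truth_samples <- NULL
    planted <- NULL
    for (i in seq_len(n_sub)) {
      recs <- c(rep("quiet", config$n_quiet_per_subject),
                rep("forced", config$n_forced_per_subject))
      reps <- c(seq_len(config$n_quiet_per_subject),
                seq_len(config$n_forced_per_subject))
      for (k in seq_along(recs)) {
        man <- recs[k]
        # Per-recording realized areas: 5% multiplicative jitter around the
        # subject latent; missing-at-random dropouts plant no peak.
        areas <- latents[i, ] * (1 + stats::rnorm(nrow(vocs), sd = 0.05))
        drop <- stats::runif(nrow(vocs)) < vocs$missing_rate
        areas[drop] <- 0
        qc_fail <- man == "forced" && stats::runif(1) < config$qc_fail_rate
        fw <- if (man == "forced") stats::runif(1, 16, 24) else 20
        seed_k <- config$seed + 1000L * i + 10L * k
        rec <- generate_spectrum_series(
          maneuver = man, rate = rates[i], seed = seed_k, config = config,
          voc_areas = areas, drift_ppm = config$drift_ppm,
          qc_fail = qc_fail, forced_width = fw
        )
        sid <- sprintf("%s_%s_%d", subjects[i], man, reps[k])
        samples[[sid]] <- breath_sample(subjects[i], group[i], man,
                                        reps[k], rec$series)
        phases[[sid]] <- rec$truth$phase
        truth_samples <- rbind(truth_samples, data.frame(
          sample_id = sid, subject_id = subjects[i], group = group[i],
          maneuver = man, replicate = reps[k],
          n_cycles = rec$truth$n_cycles, rate = rates[i],
          drift_ppm = config$drift_ppm, qc_fail_planted = qc_fail
        ))
        planted <- rbind(planted, data.frame(
          sample_id = sid, mz = vocs$mz, planted_area = unname(areas)
        ))
      }
    }

    truth <- list(
      vocs = transform(vocs,
                       direction = ifelse(case_mean > control_mean,
                                          "up_in_case", "down_in_case"),
                       effect_size = abs(case_mean - control_mean) / sd),
      latents = latents, samples = truth_samples, phases = phases,
      planted = planted
    )
    list(samples = samples, endpoints = endpoints, truth = truth)
  })
}

#' Generate a feature-level synthetic cohort
#'
#' Bypasses the spectral stages and directly emits the pair of
#' subjects-by-features matrices (quiet and forced maneuver) that the
#' selection stage consumes, with a small set of informative features
#' shifted between cases and controls and the rest pure noise. Used to
#' validate the resampled-importance selection and leave-one-out evaluation
#' at scale.
#'
#' @param n_cases,n_controls Subjects per group.
#' @param n_noise Number of uninformative features.
#' @param n_informative Number of features carrying a group shift.
#' @param effect_sd Group mean shift of informative features, in units of
#'   the feature's within-group standard deviation.
#' @param missing_rate Fraction of cells missing completely at random.
#' @param maneuver_cor Correlation of a subject's feature values between the
#'   two maneuvers.
#' @param seed Integer seed.
#' @return A list with `quiet` and `forced` ([feature_matrix()]),
#'   `endpoints` (data frame with `subject_id`, `group`, and a quantitative
#'   endpoint `severity` coupled to the first informative feature), and
#'   `truth` (data frame of feature m/z, informativeness and effect size).
#' @export
generate_feature_cohort <- function(n_cases = 51L, n_controls = 51L,
                                    n_noise = 50L, n_informative = 5L,
                                    effect_sd = 2, missing_rate = 0.1,
                                    maneuver_cor = 0.7, seed = 1L) {
  n_sub <- n_cases + n_controls
  n_feat <- n_noise + n_informative
  with_seed(seed, {
    mz <- sort(42.5 + (seq_len(n_feat) - 1L) * 317 / n_feat +
                 stats::runif(n_feat, 0, 0.12))
    # keep clear of calibrant/tracer/reference windows, which the
    # exclusion rules would (correctly) drop from the predictor set
    reserved <- c(calibrant_set(), tracer_set()$water_adduct,
                  tracer_set()$biogenic, REFERENCE_ION_MZ)
    for (ion in reserved) {
      hit <- abs(mz - ion) <= extraction_half_width(ion) + 0.05
      mz[hit] <- mz[hit] + extraction_half_width(ion) + 0.1
    }
    mz <- sort(mz)
    informative <- sort(sample(n_feat, n_informative))
    subjects <- sprintf("S%03d", seq_len(n_sub))
    group <- rep(c("case", "control"), c(n_cases, n_controls))
    shift <- matrix(0, n_sub, n_feat)
    shift[group == "case", informative] <- effect_sd

    z_shared <- matrix(stats::rnorm(n_sub * n_feat), n_sub)
    make_mat <- function(maneuver) {
      eps <- matrix(stats::rnorm(n_sub * n_feat), n_sub)
      z <- sqrt(maneuver_cor) * z_shared + sqrt(1 - maneuver_cor) * eps
      x <- 100 + 15 * (z + shift)
      x[x < 0] <- 0
      x[matrix(stats::runif(n_sub * n_feat) < missing_rate, n_sub)] <- NA
      feature_matrix(x, mz, maneuver, subjects = subjects, group = group)
    }
    quiet <- make_mat("quiet")
    forced <- make_mat("forced")
    severity <- 50 + 10 * z_shared[, informative[1]] + 5 * (group == "case") +
      stats::rnorm(n_sub, sd = 3)
    list(
      quiet = quiet, forced = forced,
      endpoints = data.frame(subject_id = subjects, group = group,
                             severity = severity),
      truth = data.frame(mz = mz,
                         informative = seq_len(n_feat) %in% informative,
                         effect_sd = ifelse(seq_len(n_feat) %in% informative,
                                            effect_sd, 0))
    )
  })
}
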