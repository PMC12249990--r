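# Cross-sample peak alignment, windowed signal extraction, reference-ion
# normalization and per-subject averaging into the analysis-ready feature
# matrix.

#' Align peak tables across samples into a consensus axis
#'
#' Greedy agglomerative grouping of centroids along the sorted m/z axis:
#' adjacent centroids belong to one group while their gap stays within the
#' m/z-dependent matching tolerance ([extraction_half_width()]). Groups
#' present in strictly more than `min_presence` of the samples become
#' consensus features at the member-centroid median m/z.
#'
#' @param peak_tables List of `peak_table` data frames (one per sample).
#' @param min_presence Presence fraction a group must strictly exceed.
#' @return A `consensus_axis` data frame with columns `mz`, `presence`,
#'   `half_width`.
#' @export
align_peaks <- function(peak_tables, min_presence = 0.5) {
  stopifnot(length(peak_tables) >= 1L)
  n_samples <- length(peak_tables)
  all_mz <- unlist(lapply(peak_tables, function(p) p$mz))
  all_sample <- rep(seq_len(n_samples),
                    vapply(peak_tables, nrow, integer(1)))
  if (!length(all_mz)) {
    return(structure(data.frame(mz = numeric(0), presence = numeric(0),
                                half_width = numeric(0)),
                     class = c("consensus_axis", "data.frame")))
  }
  ord <- order(all_mz)
  mz <- all_mz[ord]
  samp <- all_sample[ord]
  gaps <- diff(mz)
  tol <- extraction_half_width((mz[-1] + mz[-length(mz)]) / 2)
  grp <- cumsum(c(1L, as.integer(gaps > tol)))
  agg <- lapply(split(seq_along(mz), grp), function(idx) {
    data.frame(mz = stats::median(mz[idx]),
               presence = length(unique(samp[idx])) / n_samples)
  })
  out <- do.call(rbind, agg)
  out <- out[out$presence > min_presence, , drop = FALSE]
  out$half_width <- extraction_half_width(out$mz)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("consensus_axis", "data.frame"))
}

#' Extract windowed signals for one mean spectrum
#'
#' Per consensus feature, the baseline-subtracted trapezoidal integral of
#' the spectrum within +- half-width of the consensus m/z (signed, so the
#' smoothing filter's negative sidelobes cancel instead of biasing areas;
#' the window is extended by one grid point per side so truncation never
#' shaves the nominal four-sigma coverage). Windows with no intensity above
#' the noise floor yield `NA` (missing), never zero.
#'
#' @param mz_axis m/z axis of the mean spectrum.
#' @param spectrum Smoothed mean spectrum.
#' @param consensus A `consensus_axis` from [align_peaks()].
#' @param noise_mult Multiplier of the MAD noise scale for the
#'   detected/missing decision.
#' @return Numeric vector, one entry per consensus feature (`NA` =
#'   missing).
#' @export
extract_signals <- function(mz_axis, spectrum, consensus, noise_mult = 3) {
  baseline <- stats::median(spectrum)
  noise <- max(stats::mad(spectrum), .Machine$double.eps)
  floor_y <- baseline + noise_mult * noise
  vapply(seq_len(nrow(consensus)), function(k) {
    hw <- consensus$half_width[k]
    ctr <- consensus$mz[k]
    lo <- max(1L, findInterval(ctr - hw, mz_axis))
    hi <- min(length(mz_axis), findInterval(ctr + hw, mz_axis) + 1L)
    if (lo > hi) return(NA_real_)
    y <- spectrum[lo:hi]
    if (max(y) < floor_y) return(NA_real_)
    trapz(mz_axis[lo:hi], y - baseline)
  }, numeric(1))
}

#' Normalize per-sample vectors and average per subject
#'
#' Each sample's extracted vector is divided by its reference-ion signal
#' (the [D2O+H3O]+ heavy-water cluster by default); samples with a zero or
#' missing reference signal are excluded with a logged reason. Per subject
#' and maneuver the (single) quiet recording or the selected best forced
#' replicate contributes one row.
#'
#' @param vectors Numeric matrix, one row per sample (extracted signals).
#' @param reference Numeric vector of per-sample reference-ion signals.
#' @param subjects,groups Character vectors labelling each row.
#' @param consensus The `consensus_axis` the columns correspond to.
#' @param maneuver Maneuver label for the resulting matrix.
#' @return A [feature_matrix()]; excluded samples are reported in the
#'   `excluded` attribute.
#' @export
normalize_and_average <- function(vectors, reference, subjects, groups,
                                  consensus, maneuver) {
  stopifnot(nrow(vectors) == length(reference),
            nrow(vectors) == length(subjects))
  bad <- !is.finite(reference) | reference <= 0
  excluded <- subjects[bad]
  if (all(bad)) stop("all samples lack a usable reference-ion signal",
                     call. = FALSE)
  vec <- vectors[!bad, , drop = FALSE] / reference[!bad]
  sub <- subjects[!bad]
  grp <- groups[!bad]
  # One recording per subject reaches this point per maneuver; average
  # defensively if several do.
  agg <- rowsum(vec, sub, na.rm = FALSE) /
    as.vector(table(factor(sub, levels = sort(unique(sub)))))
  ord <- sort(unique(sub))
  fm <- feature_matrix(agg[ord, , drop = FALSE], consensus$mz, maneuver,
                       subjects = ord,
                       group = grp[match(ord, sub)])
  attr(fm, "excluded") <- excluded
  fm
}

#' Run the spectral pipeline over a cohort
#'
#' Preprocesses every recording ([preprocess_sample()]), drops QC failures,
#' selects the best forced replicate per subject, aligns peaks across the
#' retained samples, extracts windowed signals, normalizes to the
#' reference ion and assembles one [feature_matrix()] per maneuver.
#'
#' @param samples List of [breath_sample()] (e.g. from
#'   [generate_cohort()]).
#' @param calibrants,tracers Ion sets for preprocessing.
#' @param reference_mz Normalization reference ion m/z.
#' @param min_presence Alignment presence threshold.
#' @return A list with `quiet` and `forced` ([feature_matrix()] or `NULL`),
#'   `consensus` (the shared consensus axis), and `qc` (per-sample QC
#'   summary data frame).
#' @export
process_cohort <- function(samples, calibrants = calibrant_set(),
                           tracers = tracer_set(),
                           reference_mz = REFERENCE_ION_MZ,
                           min_presence = 0.5) {
  pre <- lapply(samples, preprocess_sample, calibrants = calibrants,
                tracers = tracers)
  qc_tab <- do.call(rbind, lapply(pre, function(s) data.frame(
    subject_id = s$subject_id, group = s$group, maneuver = s$maneuver,
    replicate = s$replicate, passed = s$qc$passed,
    n_cycles = s$qc$n_cycles, capnostat_max = s$qc$capnostat_max,
    reasons = paste(s$qc$failure_reasons, collapse = "; ")
  )))
  rownames(qc_tab) <- NULL

  quiet <- Filter(function(s) s$maneuver == "quiet" && isTRUE(s$qc$passed),
                  pre)
  forced_all <- Filter(function(s) s$maneuver == "forced", pre)
  forced <- list()
  for (sid in unique(vapply(forced_all, function(s) s$subject_id,
                            character(1)))) {
    reps <- Filter(function(s) s$subject_id == sid, forced_all)
    best <- select_best_forced(reps)
    if (!is.null(best)) forced[[sid]] <- best
  }

  retained <- c(quiet, forced)
  retained <- Filter(function(s) !is.null(attr(s, "peaks")), retained)
  if (!length(retained)) stop("no QC-passing samples", call. = FALSE)
  consensus <- align_peaks(lapply(retained, function(s) attr(s, "peaks")),
                           min_presence)

  ref_axis <- data.frame(mz = reference_mz,
                         half_width = extraction_half_width(reference_mz))
  build <- function(set, maneuver) {
    if (!length(set)) return(NULL)
    vectors <- t(vapply(set, function(s) {
      extract_signals(s$series$mz_axis, attr(s, "mean_spectrum"), consensus)
    }, numeric(nrow(consensus))))
    reference <- vapply(set, function(s) {
      v <- extract_signals(s$series$mz_axis, attr(s, "mean_spectrum"),
                           ref_axis)
      if (is.na(v)) 0 else v
    }, numeric(1))
    normalize_and_average(
      vectors, reference,
      subjects = vapply(set, function(s) s$subject_id, character(1)),
      groups = vapply(set, function(s) s$group, character(1)),
      consensus = consensus, maneuver = maneuver
    )
  }
  list(quiet = build(quiet, "quiet"), forced = build(forced, "forced"),
       consensus = consensus, qc = qc_tab)
}
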