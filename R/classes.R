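# Core data containers: one breath recording, a labelled sample, and the
# subjects-by-features matrix. Plain S3 lists, in the style of limma's
# list-based classes.

#' Time-indexed spectrum series of one breath recording
#'
#' @param mz_axis Strictly increasing numeric vector of m/z values.
#' @param scans Numeric matrix of intensities in counts per second, one row
#'   per scan, `length(mz_axis)` columns.
#' @param scan_times Numeric vector of scan start times in seconds, one per
#'   scan.
#' @param capnostat Numeric vector of capnostat (CO2 sensor) readings in
#'   instrument units, one per scan.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(mz_axis, scans, scan_times, capnostat) {
  mz_axis <- as.numeric(mz_axis)
  scans <- as.matrix(scans)
  if (is.unsorted(mz_axis, strictly = TRUE)) {
    stop_format("mz_axis must be strictly increasing")
  }
  if (ncol(scans) != length(mz_axis)) {
    stop_format("scans has ", ncol(scans), " columns but mz_axis has ",
                length(mz_axis), " points")
  }
  n <- nrow(scans)
  if (length(scan_times) != n) {
    stop_format("scan_times length ", length(scan_times),
                " does not match ", n, " scans")
  }
  if (length(capnostat) != n) {
    stop_format("capnostat length ", length(capnostat),
                " does not match ", n, " scans")
  }
  if (any(scans < 0)) stop_format("scans contains negative intensities")
  structure(
    list(mz_axis = mz_axis, scans = unname(scans),
         scan_times = as.numeric(scan_times),
         capnostat = as.numeric(capnostat)),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf(
    "<spectrum_series> %d scans x %d m/z points [%.3f-%.3f], %.0f s\n",
    nrow(x$scans), length(x$mz_axis), min(x$mz_axis), max(x$mz_axis),
    max(x$scan_times) - min(x$scan_times) + diff(x$scan_times[1:2])
  ))
  invisible(x)
}

#' A subject- and maneuver-labelled breath recording
#'
#' @param subject_id Subject identifier (character scalar).
#' @param group Group label, `"case"` or `"control"`.
#' @param maneuver Breathing maneuver, `"quiet"` or `"forced"`.
#' @param replicate Replicate index (>= 1); quiet recordings use 1.
#' @param series A [spectrum_series()].
#' @param qc Optional QC report attached after [qc_sample()].
#' @return An object of class `breath_sample`.
#' @export
breath_sample <- function(subject_id, group, maneuver, replicate = 1L,
                          series, qc = NULL) {
  maneuver <- match.arg(maneuver, c("quiet", "forced"))
  group <- match.arg(group, c("case", "control"))
  replicate <- as.integer(replicate)
  if (replicate < 1L) stop_format("replicate index must be >= 1")
  if (!inherits(series, "spectrum_series")) {
    stop_format("series must be a spectrum_series")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         maneuver = maneuver, replicate = replicate, series = series,
         qc = qc),
    class = "breath_sample"
  )
}

#' @export
print.breath_sample <- function(x, ...) {
  cat(sprintf("<breath_sample> %s (%s) %s #%d, %d scans%s\n",
              x$subject_id, x$group, x$maneuver, x$replicate,
              nrow(x$series$scans),
              if (is.null(x$qc)) "" else
                if (isTRUE(x$qc$passed)) ", QC pass" else ", QC FAIL"))
  invisible(x)
}

#' Subjects-by-features matrix of normalized intensities
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   consensus feature; `NA` marks a missing (not-detected) signal.
#' @param mz Numeric vector of consensus feature m/z, one per column.
#' @param maneuver Maneuver label the matrix was built from.
#' @param subjects Subject identifiers (defaults to rownames of `values`).
#' @param group Optional factor/character of group labels per subject.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, mz, maneuver = c("quiet", "forced"),
                           subjects = rownames(values), group = NULL) {
  maneuver <- match.arg(maneuver)
  values <- as.matrix(values)
  if (length(mz) != ncol(values)) {
    stop_format("mz length does not match feature columns")
  }
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(values)))
  if (anyDuplicated(subjects)) stop_format("duplicate subject ids")
  if (any(values < 0, na.rm = TRUE)) {
    stop_format("normalized intensities must be >= 0")
  }
  rownames(values) <- subjects
  colnames(values) <- sprintf("%.4f", mz)
  if (anyDuplicated(colnames(values))) {
    stop_format("duplicate feature columns at 4-decimal precision")
  }
  structure(
    list(values = values, mz = as.numeric(mz), maneuver = maneuver,
         subjects = as.character(subjects), group = group),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$maneuver,
              100 * mean(is.na(x$values))))
  invisible(x)
}
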