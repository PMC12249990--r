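# Recording container and tabular artifact I/O.
#
# A breath recording is stored as a self-describing directory container
# with one dataset per field (mz_axis, scans, scan_times, capnostat) plus a
# JSON metadata sidecar, mirroring the one-dataset-per-field layout of
# instrument HDF5 exports. Datasets are tab-separated text with numbers
# written at full (round-trippable) precision, so read(write(x)) is exact.
# Feature matrices, endpoint tables, rankings and reports travel as UTF-8
# TSV with "." decimal separator.

DATASETS <- c("mz_axis", "scan_times", "capnostat", "scans")

#' Write a breath recording container
#'
#' @param sample A [breath_sample()].
#' @param path Directory to create (its parent must exist); conventionally
#'   named `<sample>.ptrrec`.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "breath_sample"))
  dir.create(path, showWarnings = FALSE)
  s <- sample$series
  writeLines(format_exact(s$mz_axis), file.path(path, "mz_axis.tsv"))
  writeLines(format_exact(s$scan_times), file.path(path, "scan_times.tsv"))
  writeLines(format_exact(s$capnostat), file.path(path, "capnostat.tsv"))
  rows <- apply(s$scans, 1L, function(r) paste(format_exact(r), collapse = "\t"))
  writeLines(rows, file.path(path, "scans.tsv"))
  meta <- list(subject_id = sample$subject_id, group = sample$group,
               maneuver = sample$maneuver, replicate = sample$replicate,
               format = "breathvoc-recording", format_version = 1L)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a breath recording container
#'
#' Fails with a structured format error naming the offending dataset on
#' missing datasets, shape mismatches, or a non-monotone m/z axis.
#'
#' @param path Directory written by [write_sample()].
#' @return A [breath_sample()].
#' @export
read_sample <- function(path) {
  if (!dir.exists(path)) stop_format("no recording container at ", path)
  for (d in c(DATASETS, "meta")) {
    f <- file.path(path, paste0(d, if (d == "meta") ".json" else ".tsv"))
    if (!file.exists(f)) stop_format(d, " missing")
  }
  num <- function(d) as.numeric(readLines(file.path(path, paste0(d, ".tsv"))))
  mz_axis <- num("mz_axis")
  scan_times <- num("scan_times")
  capnostat <- num("capnostat")
  lines <- readLines(file.path(path, "scans.tsv"))
  scans <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
                  nrow = length(lines), byrow = TRUE)
  if (is.unsorted(mz_axis, strictly = TRUE)) {
    stop_format("mz_axis not strictly increasing")
  }
  if (ncol(scans) != length(mz_axis)) {
    stop_format("scans shape mismatch with mz_axis")
  }
  if (nrow(scans) != length(scan_times)) {
    stop_format("scan_times shape mismatch with scans")
  }
  if (nrow(scans) != length(capnostat)) {
    stop_format("capnostat shape mismatch with scans")
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  breath_sample(meta$subject_id, meta$group, meta$maneuver, meta$replicate,
                spectrum_series(mz_axis, scans, scan_times, capnostat))
}

#' Write a feature matrix as TSV
#'
#' Rows are subjects, columns are consensus m/z formatted to four decimals;
#' missing entries are written as empty fields. Values are written at full
#' precision so the numeric round trip is lossless.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- colnames(fm$values)
  if (anyDuplicated(cols)) stop_format("duplicate feature columns")
  header <- paste(c("subject_id", "maneuver", cols), collapse = "\t")
  body <- vapply(seq_len(nrow(fm$values)), function(i) {
    vals <- format_exact(fm$values[i, ])
    vals[is.na(fm$values[i, ])] <- ""
    paste(c(fm$subjects[i], fm$maneuver, vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV file path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_format("no feature matrix at ", path)
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "subject_id" || header[2] != "maneuver") {
    stop_format("feature matrix header must start with subject_id, maneuver")
  }
  cols <- header[-(1:2)]
  if (anyDuplicated(cols)) stop_format("duplicate feature columns")
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  subjects <- vapply(parts, `[`, character(1), 1L)
  maneuver <- unique(vapply(parts, `[`, character(1), 2L))
  if (length(maneuver) != 1L) stop_format("mixed maneuver labels in one matrix")
  values <- t(vapply(parts, function(p) {
    v <- p[-(1:2)]
    v <- c(v, rep("", length(cols) - length(v)))  # trailing empties
    suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }, numeric(length(cols))))
  feature_matrix(values, as.numeric(cols), maneuver, subjects = subjects)
}

#' Write / read a subject-level endpoint table
#'
#' Tab-separated values with a header row; logical columns survive the
#' round trip.
#'
#' @param endpoints Data frame, one row per subject.
#' @param path TSV file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_endpoint_table <- function(endpoints, path) {
  data.table::fwrite(endpoints, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_table
#' @export
read_endpoint_table <- function(path) {
  if (!file.exists(path)) stop_format("no endpoint table at ", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
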