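# Tentative identification of consensus features as protonated compounds
# ([M+H]+) against a reference library within a ppm tolerance.

#' Theoretical [M+H]+ m/z of an elemental formula
#'
#' Sum of monoisotopic atomic masses plus the proton mass. Supported
#' elements: C, H, D, N, O, S, P, F, Cl, Br, Si.
#'
#' @param formula Elemental formula string, e.g. `"C2H6S"`.
#' @return Theoretical protonated m/z (numeric scalar).
#' @examples
#' theoretical_mz("C2H6S")  # dimethyl sulfide, 63.0263
#' @export
theoretical_mz <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(MONOISOTOPIC_MASS)) {
      stop("unknown element symbol: ", el, call. = FALSE)
    }
    total <- total + MONOISOTOPIC_MASS[[el]] * cnt
  }
  unname(total + PROTON_MASS)
}

#' Read a compound reference library
#'
#' Tab-separated file with columns `name`, `formula`, and optionally
#' `source`; the theoretical neutral mass and [M+H]+ m/z are computed from
#' the formula. The built-in library ships the breath-relevant compounds
#' this pipeline reports on.
#'
#' @param path Library TSV; defaults to the built-in library.
#' @return Data frame with `name`, `formula`, `neutral_mass`, `mz`,
#'   `source`.
#' @export
read_voc_library <- function(path = system.file("extdata",
                                                "voc_library.tsv",
                                                package = "breathvoc")) {
  lib <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("name", "formula") %in% names(lib))) {
    stop_format("library must have name and formula columns")
  }
  lib$mz <- vapply(lib$formula, theoretical_mz, numeric(1))
  lib$neutral_mass <- lib$mz - PROTON_MASS
  if (is.null(lib$source)) lib$source <- "library"
  lib[order(lib$mz), c("name", "formula", "neutral_mass", "mz", "source")]
}

#' Annotate one feature m/z against a library
#'
#' The nearest library [M+H]+ by absolute ppm error is reported as a match
#' only when within the tolerance; otherwise the nearest candidate is
#' reported with `within_tolerance = FALSE`. All within-tolerance
#' candidates are kept, ranked by |ppm|.
#'
#' @param mz Observed feature m/z.
#' @param library Data frame from [read_voc_library()].
#' @param tolerance_ppm Maximum allowed deviation (default 200 ppm).
#' @return A list with `mz`, `match` (compound name or `NA`), `formula`,
#'   `ppm` (signed error to the nearest candidate), `within_tolerance`,
#'   and `candidates` (data frame of all within-tolerance hits).
#' @export
annotate_feature <- function(mz, library = read_voc_library(),
                             tolerance_ppm = 200) {
  stopifnot(nrow(library) >= 1L)
  ppm <- (mz - library$mz) / library$mz * 1e6
  ord <- order(abs(ppm))
  best <- ord[1]
  within <- abs(ppm[best]) <= tolerance_ppm
  hits <- ord[abs(ppm[ord]) <= tolerance_ppm]
  list(
    mz = mz,
    match = if (within) library$name[best] else NA_character_,
    formula = if (within) library$formula[best] else NA_character_,
    nearest = library$name[best],
    ppm = ppm[best],
    within_tolerance = within,
    candidates = data.frame(name = library$name[hits],
                            formula = library$formula[hits],
                            mz = library$mz[hits], ppm = ppm[hits])
  )
}

#' Annotate a consensus axis
#'
#' @param consensus A `consensus_axis` data frame (or numeric vector of
#'   m/z).
#' @param library Data frame from [read_voc_library()].
#' @param tolerance_ppm Maximum allowed deviation (ppm).
#' @return Data frame with one row per feature: `mz`, `match`, `formula`,
#'   `ppm`, `within_tolerance`.
#' @export
annotate_features <- function(consensus, library = read_voc_library(),
                              tolerance_ppm = 200) {
  mzs <- if (is.data.frame(consensus)) consensus$mz else as.numeric(consensus)
  rows <- lapply(mzs, function(m) {
    a <- annotate_feature(m, library, tolerance_ppm)
    data.frame(mz = m, match = a$match, formula = a$formula,
               nearest = a$nearest, ppm = a$ppm,
               within_tolerance = a$within_tolerance)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
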