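# Instrument and method constants shared across modules.

#' PerMaSCal calibrant ions
#'
#' Reference m/z of the three permeation-source calibrant ions used for
#' per-spectrum mass-axis recalibration.
#'
#' @param mz Numeric vector of reference m/z values, strictly increasing,
#'   at least two entries.
#' @return An object of class `calibrant_set` (numeric vector of m/z).
#' @export
calibrant_set <- function(mz = c(21.0220, 203.94299, 330.85)) {
  if (length(mz) < 2L) {
    stop("a calibrant set needs at least two reference ions", call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("calibrant m/z values must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(mz), class = "calibrant_set")
}

#' Breath-phase tracer ions
#'
#' The water adduct of the hydronium ion ([H2O+H3O]+, m/z 37.038) tracks
#' exhaled humidity and marks exhalation phases; the three biogenic ions
#' (1,2-butadiene 55.03, dimethyl sulfide 63.02, isoprene 69.07) peak during
#' exhalation and corroborate the phase call. A scan is attributed to an
#' exhalation only when the water-adduct signal exceeds `water_threshold`
#' counts per second.
#'
#' @param water_adduct m/z of the water adduct ion.
#' @param biogenic Numeric vector of biogenic tracer m/z values.
#' @param water_threshold Water-adduct intensity threshold in cps.
#' @return An object of class `tracer_set`.
#' @export
tracer_set <- function(water_adduct = 37.038,
                       biogenic = c(55.03, 63.02, 69.07),
                       water_threshold = 2e5) {
  if (water_threshold <= 0) stop("water_threshold must be > 0", call. = FALSE)
  structure(
    list(water_adduct = water_adduct, biogenic = biogenic,
         water_threshold = water_threshold),
    class = "tracer_set"
  )
}

# [D2O + H3O]+ heavy-water/hydronium cluster used as normalization reference.
# Monoisotopic: 2*D (2.0141018) + O (15.9949146) + H3O+ (19.0178394).
REFERENCE_ION_MZ <- 39.0410

# Mass of a proton (Da), for [M+H]+ computation.
PROTON_MASS <- 1.007276466

# Monoisotopic atomic masses (Da) for formula parsing.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  D = 2.0141017780,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  F = 18.99840320,
  Cl = 34.96885271,
  Br = 78.9183376,
  Si = 27.9769265327
)

# Nominal TOF resolving power m/dm used by the synthetic generator and the
# m/z-dependent extraction windows.
TOF_RESOLUTION <- 1000

# Gaussian FWHM -> sigma conversion.
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Capnostat QC exceedance threshold (instrument units, baseline-subtracted).
CAPNOSTAT_LIMIT <- 3.5

# Calibrant residual acceptance margin (ppm).
CALIBRANT_PPM_LIMIT <- 100

# Minimum complete inhalation-exhalation cycles for a quiet recording.
MIN_CYCLES_QUIET <- 3L

#' Peak width of the synthetic instrument at a given m/z
#'
#' Gaussian sigma implied by a constant resolving power m/dm (FWHM = m/R).
#'
#' @param mz m/z value(s).
#' @param resolution Resolving power m over delta-m (FWHM definition).
#' @return Sigma in m/z units.
#' @export
peak_sigma <- function(mz, resolution = TOF_RESOLUTION) {
  mz / resolution * FWHM_TO_SIGMA
}

#' m/z-dependent extraction half-width
#'
#' Half-width of the signal-extraction (and peak-alignment) window around a
#' consensus m/z: five Gaussian sigmas at the nominal resolving power
#' (covering the peak plus the smoothing filter's sidelobe support),
#' clamped to the 0.015-0.4 m/z range. The lower clamp keeps narrow low-mass
#' windows wide enough to tolerate residual calibration error; the upper
#' clamp bounds the window for heavy ions (it binds above roughly m/z 188).
#'
#' @param mz m/z value(s).
#' @param lower,upper Clamp bounds in m/z.
#' @param resolution Resolving power used for the width model.
#' @return Half-width(s) in m/z units.
#' @export
extraction_half_width <- function(mz, lower = 0.015, upper = 0.4,
                                  resolution = TOF_RESOLUTION) {
  pmin(upper, pmax(lower, 5 * peak_sigma(mz, resolution)))
}
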