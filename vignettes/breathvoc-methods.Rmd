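---
title: "Methods: exhaled-breath VOC biomarker discovery with breathvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaled-breath VOC biomarker discovery with breathvoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Proton-transfer-reaction time-of-flight mass spectrometry (PTR-TOF-MS)
measures volatile organic compounds (VOCs) in exhaled breath in real time:
H3O+ primary ions transfer a proton to analyte molecules, which are then
resolved by flight time as protonated ions [M+H]+ at parts-per-billion
sensitivity. In a case-control breathomics study — here modelled on a
cystic lung disease cohort of 51 cases and 51 matched control women — each
subject provides one quiet-breathing recording (about 60 s, 12-16
exhalation cycles) and three forced-expiration recordings, and the goal is
to find m/z features whose normalized intensities discriminate cases from
controls or predict clinical, functional and radiological endpoints.

`breathvoc` implements the full path from raw spectrum series to evaluated
biomarker panels: mass-axis recalibration, quality control, breath-phase
selection, peak extraction and alignment, reference-ion normalization,
tentative annotation, descriptive statistics, and a resampled
gradient-boosting selection with leave-one-out evaluation. Because raw
clinical recordings of this kind are rarely shareable, the package also
ships a synthetic-cohort generator with planted ground truth, so that every
stage is testable end to end.

# The synthetic cohort

`generate_cohort()` emits, per subject, one 60 s quiet recording and three
30 s forced recordings of full-scan spectra (10-685 m/z, 1000 ms per scan)
plus a capnostat (CO2) channel — 408 recordings at the default study
design. Design choices, made once:

* **Mass axis.** Log-spaced grid, so a constant resolving power
  (m/dm = 1000, typical for compact TOF instruments) gives a constant
  three grid points per peak FWHM everywhere on the axis. Peaks are
  Gaussian, the standard TOF approximation.
* **Breath modulation.** Exhalation is a raised-cosine bump (3.2 s wide
  for quiet breathing, repeating at the subject's respiratory rate drawn
  from 12-16 breaths/min; a single 16-24 s dome for forced expiration).
  The smooth waveform yields unambiguous local maxima for the tracer-based
  phase detector, and the bump width guarantees — at 1 s scans — at least
  one scan above and one below the water-adduct threshold per cycle, so
  the planted cycle count is recoverable exactly.
* **Ions.** Calibrant ions (21.0220, 203.94299, 330.85, constant in
  time), the water adduct [H2O+H3O]+ at 37.038 (2e4 to 6.2e5 cps across
  the breath cycle, crossing the 2e5 cps threshold inside every cycle),
  biogenic tracers (1,2-butadiene 55.03, dimethyl sulfide 63.02, isoprene
  69.07), and the heavy-water normalization reference [D2O+H3O]+ at
  39.0410, computed from monoisotopic masses.
* **Planted VOC panel.** Twenty-one discriminative ions with group means
  and dispersions taken from published quiet-breathing area comparisons
  for this disease contrast (e.g. 7056.6 vs 8035.1 cps at m/z 44.99, 42.5
  vs 50.9 at 129.07). Dimethyl sulfide (63.02) is reserved as a tracer
  and cannot be planted; the generator rejects any planted m/z colliding
  with a reserved ion's extraction window. Subject-level latent areas are
  Gaussian around the group mean and shared across maneuvers, with 5%
  per-recording jitter and per-VOC missing-at-random dropout.
* **Endpoints.** Binary endpoints use a logistic link on standardized
  latent VOC levels (pneumothorax coupled to 103.08 and 133.10, tuned to
  about half the cases); quantitative endpoints use linear links with
  Gaussian noise (cyst-volume analog coupled to 129.07, distal-lumen area
  to 57.06, lung-function z-scores to their published predictor ions).
* **Mass drift and QC failures.** A uniform ppm distortion (default
  30 ppm, the typical calibrant error magnitude for this instrument
  class) multiplies all peak positions. A configurable fraction (default
  5%) of forced replicates is planted with a capnostat exceedance so that
  best-replicate selection and QC exclusion are exercised; quiet
  recordings are left clean so the default cohort stays complete.

What the generator does **not** emulate: ion-chemistry (proton-transfer
kinetics, fragmentation, humidity dependence), isotope patterns, the real
cohort's full ~200-feature spectrum, instrument drift within a recording,
or correlated noise. Passing tests therefore demonstrate that the
pipeline's logic is correct and calibrated under its stated assumptions,
not that it would meet any particular performance figure on real clinical
recordings.

`generate_feature_cohort()` bypasses the spectral stages and emits the
subjects-by-features matrices directly (default: 5 informative features
shifted 2 within-group SDs between groups among 50 noise features, 10%
missing cells, cross-maneuver correlation 0.7). It is the workhorse for
validating the selection stage at full cohort scale without the cost of
spectral synthesis.

# Per-sample processing

**Recalibration.** Every scan is recalibrated independently against the
three permeation-source calibrant ions. Each calibrant is located within a
±0.5 m/z search window; the centroid is the vertex of a parabola fitted to
log-intensity at the apex and its two neighbours — exact for a Gaussian
peak on any grid, and accurate to a few hundredths of a ppm at the
synthetic calibrant intensities. The correction is a degree-1 least-squares
fit of reference vs observed position in sqrt(m/z) space (flight time is
proportional to sqrt(m/z), so a linear time distortion is linear there);
with three calibrants the fit is over-determined and residuals are
reported in ppm. The corrected spectrum is resampled onto the common axis
by linear interpolation. A planted 150 ppm distortion is corrected to
residuals well below 1 ppm; the QC acceptance margin is 100 ppm.

**Quality control.** A sample passes when (i) the baseline-subtracted
capnostat maximum is at most 3.5 units (baseline = 5th percentile of the
trace), (ii) all calibrants were found with residual errors below 100 ppm,
and (iii) the recording contains at least three complete
inhalation-exhalation cycles. The cycle criterion is maneuver-aware: a
forced expiration is by design a single sustained exhalation, so it is
required to show at least one complete cycle rather than three — a flat
three-cycle rule would reject every forced recording. The capnostat is
used **only** for this sample-level check, never for phase gating, because
its response lags the water-adduct signal (the generator plants that lag).

**Exhalation selection.** A scan is attributed to exhalation iff the
water-adduct extracted-ion intensity exceeds 2e5 cps **and** the scan lies
within ±2 scans of a local maximum of at least two of the three biogenic
tracer traces. Local maxima are strict maxima of the running-mean-smoothed
trace over a centered 5-scan window, truncated at the recording edges
(without truncation, the first and last breath cycles of a recording could
never host a maximum and short recordings would lose cycles). Whether the
original method evaluated the local-maximum condition per scan or per
breath segment is not documented anywhere we know of; the 5-scan window is
a robust per-scan choice at 1 s scans and is configurable. Cycle count =
number of contiguous selected segments.

**Averaging, smoothing, peak picking.** Selected scans are averaged
arithmetically, then smoothed along the m/z axis with a Savitzky-Golay
filter (window 9 points, order 2 — at three points per FWHM the window
spans three peak widths, strong smoothing that preserves peak area by
construction of the filter). The smoothed spectrum may dip below zero at
peak flanks (the filter's negative sidelobes); integration downstream is
signed so these dips cancel instead of biasing areas. Peaks are strict
local maxima above a prominence floor of 3 median absolute deviations over
the median baseline; the centroid is the baseline-subtracted
intensity-weighted mean over the peak support and the area its trapezoidal
integral.

# Feature matrix

**Alignment.** Peak centroids from all retained samples are pooled,
sorted, and greedily grouped: a gap larger than the local matching
tolerance starts a new group. Groups present in strictly more than 50% of
samples become consensus features at the member median m/z.

**Extraction windows.** The matching tolerance and the extraction
half-width share one model: five Gaussian sigmas at the nominal resolving
power, clamped to [0.015, 0.4] m/z. Five sigmas, not three, because the
Savitzky-Golay sidelobes carry about 2% of a peak's mass beyond three
sigma and windowed recovery of a planted area is then no longer accurate
to 1%; with the 5-sigma window, extended by one grid point per side
against truncation, planted areas are recovered to within about 0.5%. The
upper clamp binds above roughly m/z 188, so the heaviest features (e.g.
the ion at 329.82) are integrated over ±0.4 m/z and slightly truncated —
a consistent, group-neutral bias. Windows with no intensity above the
noise floor yield a missing value, never zero; imputation is deferred to
the modelling stage.

**Normalization and averaging.** Each sample vector is divided by its
extracted heavy-water reference-ion signal ([D2O+H3O]+ at 39.0410; the
compound is standard, its m/z is computed from monoisotopic masses and is
configurable), making features dimensionless ratios invariant to overall
sensitivity. Per subject and maneuver one recording contributes: the
single quiet recording, or the best forced replicate — ranked by passing
QC, then detected cycle count, then total selected-scan water-adduct
signal, with ties going to the lowest replicate index. The forced matrix
uses the best replicate only, not the mean of three, mirroring how such
recordings are collected ("highest quality sample").

# Annotation

Features are tentatively identified as protonated compounds: the nearest
library [M+H]+ by absolute ppm error is a match when within ±200 ppm;
otherwise the nearest candidate is reported as not-within-tolerance. All
within-tolerance candidates are kept ranked by |ppm| (a deliberate
divergence from single-name reporting: ties are information). The built-in
library covers the breath-relevant compounds this pipeline reports on and
is a pluggable TSV; proprietary instrument libraries and full metabolome
databases are not redistributable and not required at build time.

# Statistics

**Group comparisons.** Quantitative variables take Welch's t-test (two
groups) or ANOVA when every group passes a Shapiro-Wilk normality gate at
alpha = 0.05 per group (the gate level is our choice; it is the
conventional one), otherwise Mann-Whitney U / Kruskal-Wallis. Categorical
variables take Pearson's chi-square, or Fisher's exact test when any
expected cell is below 5. The chosen test is always part of the output.
No multiple-testing correction is applied (a documented limitation, kept
for fidelity to the emulated analysis at alpha = 0.05). Under a simulated
null the realized type-I error of the full decision logic stays within
[0.03, 0.07] for both the Gaussian and the skewed path.

**Endpoints.** Obstruction, air trapping and gas-exchange impairment are
derived from lung-function z-scores at the conventional limits of normal:
z < -1.645 (lower) and, mirroring it, z > +1.645 (upper; the source
analysis says only "above the upper limit of normal", the symmetric z is
our choice).

**Selection.** Predictors are restricted to VOC features: calibrant ions
(within the extraction tolerance), the water-adduct tracer, the
normalization reference and everything below m/z 42 are excluded (the
boundary feature at 42.03, acetonitrile, is retained). Then, per endpoint
and maneuver: 1000 times (reduced to 200 in the shipped validation runs;
the estimate is a median, stable well before that), two thirds of the
subjects are drawn without replacement; the subsample is z-scored per
feature, missing cells are filled by round-robin chained ridge regression
(each incomplete feature regressed on all others, iterated to a 1e-3
tolerance or 10 rounds; ridge penalty 1e-2 per observation — a
deterministic stand-in for Bayesian ridge estimation that shares its
shrinkage structure), and a gradient-boosted tree ensemble is fitted
(200 trees, depth 3, learning rate 0.1, exact greedy splits; for small
cohorts the exact method also places thresholds at gap midpoints rather
than on observed class-edge values). Per-feature total-gain importance is
recorded; gain is the least frequency-biased of the standard importance
flavours. The median importance across iterations, ranked descending
(ties break by m/z), gives the per-maneuver ranking; the top 30 of each
maneuver are intersected, ordered by mean rank, and only features common
to both breathing conditions are retained. Degenerate single-class
subsamples are redrawn with a derived seed, at most 100 times.

**Evaluation.** The overlap set is assessed by leave-one-out
cross-validation: z-scoring and imputation are fitted inside each training
fold only, the held-out row is transformed with training parameters and
its missing entries filled at the training mean, and the held-out subject
is predicted. Classifiers report AUC over the pooled out-of-fold
probabilities (rank statistic, ties share ranks — cross-checked against
an independent ROC implementation) plus sensitivity, specificity, PPV and
NPV at a probability threshold of 0.5; regressors report the coefficient
of determination, maximal error, explained variance and RMSE. Importances
are finally recomputed on the full data restricted to the overlap
features, with the same hyperparameters as selection.

Leakage is guarded by construction and by test: a feature equal to the
label yields AUC 1 (the relationship is real and learnable), while
pure-noise features under permuted labels stay near chance — fold-internal
preprocessing does not encode the held-out label. Everything is
deterministic given the seed: iteration seeds are derived as base + i, and
the boosting runs single-threaded with no stochastic subsampling.

# Problem sizes used in the shipped validation

The package's own test runs use: the full 408-recording study design for
the cohort-count check; reduced spectral cohorts (4-8 subjects) for
end-to-end feature-matrix checks; and the feature-level generator at full
scale (102 subjects, 5 informative + 50 noise features, 2 SD shifts,
200 resampling iterations) for selection recovery, where all five planted
features are recovered in the cross-maneuver overlap, leave-one-out AUC
exceeds 0.9 on both maneuvers, and permuted labels fall back to chance.
These sizes are the package's choice of a thorough-but-routine validation
footprint; all of them are configurable upward.

# Known limitations

* Overlapping isobars are not deconvolved; a consensus feature is one
  integration window.
* No batch-effect or humidity correction beyond reference-ion
  normalization.
* The annotation library is small and curated; real studies should plug
  in a fuller library TSV.
* The synthetic generator's simplifications (above) mean absolute
  performance numbers on synthetic cohorts do not transfer to real data.
* Recordings are stored in a plain-text directory container (one dataset
  per field plus JSON metadata); vendor formats and mzML are out of
  scope.
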