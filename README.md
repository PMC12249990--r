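# breathvoc

Volatile organic compound (VOC) biomarker discovery from exhaled breath
measured by proton-transfer-reaction time-of-flight mass spectrometry
(PTR-TOF-MS).

PTR-TOF-MS records full-scan mass spectra of exhaled air in real time:
VOCs are ionized by proton transfer from H3O+ and detected as protonated
molecules [M+H]+. In a case-control breathomics study each subject
provides a quiet-breathing recording (~60 s, 12–16 exhalation cycles) and
repeated forced expirations, and the analysis must find m/z features whose
normalized intensities separate cases from controls or predict clinical
endpoints. `breathvoc` implements that analysis end to end, for
breathomics researchers and for anyone who needs a fully testable
reference implementation of this class of pipeline:

* **Per-recording processing** — per-scan mass-axis recalibration against
  permeation-source calibrant ions (degree-1 fit in √(m/z) space, the
  TOF-linear model), capnostat / calibrant-residual / cycle-count quality
  control, exhalation-phase selection (water-adduct ion at m/z 37.038
  above 2×10⁵ cps **and** a local maximum in ≥2 of 3 biogenic tracer
  ions), Savitzky–Golay smoothing, peak picking.
* **Feature matrix** — cross-sample peak alignment (features kept when
  present in >50% of samples), m/z-dependent extraction windows
  (±0.015–0.4 m/z), normalization to the heavy-water reference ion
  [D2O+H3O]+, one row per subject and maneuver (best forced replicate).
* **Annotation** — nearest [M+H]+ in a pluggable compound library within
  ±200 ppm.
* **Statistics** — Shapiro–Wilk-gated Welch/ANOVA vs
  Mann–Whitney/Kruskal–Wallis, chi-square vs Fisher; limit-of-normal
  endpoint derivation (z < −1.645 / z > +1.645).
* **Selection & evaluation** — the core statistic: per maneuver, draw 2/3
  of subjects 1000 times, z-score + chained-ridge-impute inside each
  draw, fit an XGBoost classifier/regressor, rank features by median
  total-gain importance; intersect the two maneuvers' top-30 lists; then
  leave-one-out cross-validation on the overlap set with AUC,
  sensitivity/specificity/PPV/NPV at probability 0.5 (or R², max error,
  explained variance, RMSE for quantitative endpoints).
* **Synthetic cohort** — a generator that emulates the full study design
  (51 cases + 51 controls × 4 recordings = 408 recordings) with planted
  VOC effects, mass drift, breath-cycle-modulated tracers, a delayed
  capnostat, and ground truth for every recovery test.

## Worked example

```r
library(breathvoc)

# a reduced synthetic cohort: 4 cases + 4 controls, 32 recordings
cfg <- synthetic_config(n_cases = 4, n_controls = 4, seed = 1)
cohort <- generate_cohort(cfg)
length(cohort$samples)
#> [1] 32

# recalibrate, QC, select exhalations, pick peaks, align, normalize
matrices <- process_cohort(cohort$samples)
matrices$quiet
#> <feature_matrix> 8 subjects x 29 features (quiet), 0.9% missing
sum(matrices$qc$passed)
#> [1] 32

# tentative [M+H]+ annotation of the consensus axis
head(subset(annotate_features(matrices$consensus), within_tolerance), 4)
#>          mz                 match        ppm
#> 4  42.03014          Acetonitrile  -87.62496
#> 6  48.04020 O-Methylhydroxylamine  -87.17006
#> 9  57.06004             Isobutene -172.44063
#> 10 63.01999      Dimethyl sulfide -100.12646

# biomarker discovery at full study scale on the feature-level generator:
# 102 subjects, 5 informative features (2 SD shift) among 50 noise features
fc <- generate_feature_cohort(seed = 1)
sel <- discover_biomarkers(fc$quiet, fc$forced,
                           fc$endpoints$group == "case",
                           selection_config(n_iterations = 200, seed = 1))
length(sel$overlap)          # features in both maneuvers' top 30
#> [1] 27
sel$eval_quiet
#> <eval_result> quiet: AUC 0.976, sens 0.863, spec 0.922, PPV 0.917, NPV 0.870
sel$eval_forced
#> <eval_result> forced: AUC 0.992, sens 0.941, spec 0.980, PPV 0.980, NPV 0.943
head(sel$ranking_quiet, 4)   # the planted features head the ranking
#>          mz median_importance rank top_k
#> 1 278.88674         0.2675092    1  TRUE
#> 2 261.60503         0.1793723    2  TRUE
#> 3  71.42599         0.1552764    3  TRUE
#> 4 353.74485         0.1471919    4  TRUE
```

The 29 consensus features are the 21 planted VOCs plus the calibrant,
tracer and reference ions; the exclusion rules (`exclusion_filter()`)
remove the non-VOC ions and everything below m/z 42 before any modelling.
The AUCs above are out-of-fold leave-one-out estimates; with permuted
labels the same models fall back to chance (see the test suite).

## Documentation

The methods vignette (`vignettes/breathvoc-methods.Rmd`) documents the
models, parameter choices, numerical decisions and known limitations.
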