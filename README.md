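# eegmicrostates

Resting-state EEG **microstate analysis** for two-group clinical studies, in
R. The brain's resting electrical field moves through brief (~40–120 ms)
quasi-stable topographic configurations — microstates, canonically labelled
A–D. Shifts in how long each configuration lasts (mean microstate duration,
MMD), how much of the recording it covers (RTT), how much signal variance it
explains (GEV) and how often it recurs (occurrence) are candidate markers of
disordered large-scale network dynamics, e.g. in substance-use disorders.
This package implements the full analysis chain such studies use, plus a
ground-truthed synthetic EEG generator so that every stage can be validated
without access to clinical recordings.

The chain:

* **Preprocessing** — zero-phase 2–20 Hz Butterworth band-pass, anti-aliased
  downsampling to 250 Hz, the first twenty artifact-free 2-s epochs,
  average reference.
* **Two-level clustering** — polarity-invariant *modified k-means* on the
  scalp maps at global field power peaks: assignment by
  argmax<sub>j</sub> (xᵀt<sub>j</sub>)², template update as the dominant
  eigenvector of the cluster's channel covariance, objective
  GEV = Σ (xᵢᵀt<sub>a(i)</sub>)² / Σ‖xᵢ‖², individual templates pooled and
  re-clustered per group, classes matched to canonical A–D by exhaustive
  permutation on spatial correlation.
* **Backfitting and parameters** — per-sample labelling by maximal |spatial
  correlation|; MMD / RTT / GEV / occurrence per class with edge-run
  handling.
* **Source contrasts** — standardized minimum-norm (sLORETA-style) inverse
  T = Kᵀ(KKᵀ + αH)⁺, power standardized by diag(TK) (zero localization
  error for noise-free single sources), voxelwise log₁₀ F-ratio group
  statistic, permutation max-statistic family-wise correction.
* **Group statistics** — mixed (split-plot) ANOVA, pooled two-sample
  t-tests (from raw data *or* from printed summary statistics), Bonferroni
  correction, Gaussian GLMs for covariate links, chi-square, post-hoc
  power.

## Worked example

Simulate a small two-group study (8 patients vs 6 controls, 30 s of
32-channel EEG each, patient classes A/B shortened by 2 ms) and run the
whole pipeline:

```r
library(eegmicrostates)
cfg <- pipeline_config(seed = 7, n_patients = 8, n_controls = 6,
                       duration_s = 30, n_epochs = 10, n_channels = 32,
                       restarts = 20, n_perm = 500, n_voxels = 60)
res <- run_pipeline(cfg, out_dir = "ms-demo")
subset(res$stats$t_table, parameter == "mmd_ms")
```

```
   class parameter mean_patient sd_patient mean_control sd_control   statistic
1      A    mmd_ms     36.16988   3.168663     36.11939   2.348965  0.03273602
5      B    mmd_ms     35.97094   2.913867     38.30681   2.967779 -1.47293064
9      C    mmd_ms     39.58668   1.450214     38.92679   2.600430  0.60757977
13     D    mmd_ms     37.79609   1.894492     38.09327   2.624582 -0.24698816
   df         p corrected_p
1  12 0.9744233    1.000000
5  12 0.1665093    0.666037
9  12 0.5547901    1.000000
13 12 0.8090923    1.000000
```

Each row compares one class's mean duration between groups with a
pooled-variance t (df = n₁+n₂−2 = 12) and a Bonferroni-corrected p over the
four classes. The injected class-B shortening shows up with the right sign
(−2.3 ms) but, at 14 subjects, is not significant — at the package's
default study size (55 vs 27) the same effect is detected reliably.
The ANOVA and source stages live in `res$stats$anova` and `res$source`:

```r
res$stats$anova$mmd_ms$interaction
#> mixed ANOVA group x class effect (F): statistic = 0.846, df = 3, 36, p = 0.4779
res$source$A
#> <ms_snpm> 60 voxels, 500 permutations, alpha = 0.05
#>   corrected |log-F| threshold = 1.6880; 0 suprathreshold voxels
```

All artifacts (tidy parameter CSV, templates, covariates, test tables,
source contrasts, a manifest with the full configuration) are written to
`ms-demo/`. A shell entry point with the same options is provided at
`inst/scripts/run-pipeline.R`.

`ttest_from_summary()` works directly from printed group summaries, e.g.
the class-A duration comparison of a published 55-vs-27 study:

```r
ttest_from_summary(37.42, 2.56, 55, 39.54, 4.37, 27)
#> pooled two-sample t (summary statistics): statistic = -2.767, df = 80, p = 0.007024
```

## Vignette

`vignettes/microstate-analysis.Rmd` documents the model, the generator's
design decisions (run-length law, amplitude envelope, template geometry,
noise model), the numerical choices (filter order, convergence tolerances,
degenerate-input handling) and known limitations.
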