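---
title: "Resting-state EEG microstate analysis: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting EEG is modelled as a sequence of *microstates*: brief
(roughly 40--120 ms) periods during which the spatial configuration of the
scalp potential field stays quasi-stable while its overall strength and
polarity fluctuate. Four recurring configurations (classes A--D) dominate
eyes-closed resting recordings: a right-anterior/left-posterior gradient
(A), its left-anterior/right-posterior mirror (B), an anterior--posterior
pattern (C), and a fronto-central focus (D).

`eegmicrostates` implements the standard two-level analysis chain:

1. **Conditioning** — zero-phase Butterworth band-pass (2--20 Hz),
   anti-aliased downsampling to 250 Hz, segmentation into the first twenty
   artifact-free 2-s epochs, average reference.
2. **Clustering** — at the *individual* level, the scalp maps at global
   field power (GFP) peaks are clustered by the polarity-invariant
   "modified k-means" into `k = 4` templates per subject; at the *group*
   level, all individual templates of a group are pooled and re-clustered
   into four group-mean classes, which are then matched to the canonical
   A--D configurations by exhaustive permutation search on spatial
   correlation.
3. **Backfitting** — every sample is labelled with the template of maximal
   polarity-invariant spatial correlation, and four parameters are derived
   per class: mean microstate duration (MMD, ms), ratio of total time
   covered (RTT), global explained variance (GEV) and occurrence (segments
   per second).
4. **Source analysis** — each subject's individual class templates are
   localized with a standardized minimum-norm inverse operator and the two
   groups are contrasted voxel-by-voxel with a log-F statistic under
   permutation max-statistic family-wise error correction.
5. **Group statistics** — mixed (split-plot) ANOVA with class as the
   within-subject and group as the between-subject factor, pooled-variance
   two-sample t-tests with Bonferroni correction over the four classes,
   Gaussian GLMs linking parameters to covariates, chi-square tests for
   proportions, and post-hoc power for two-sample designs.

### Modified k-means

For maps $x_i$ (zero-mean across channels) and unit templates $t_j$, the
assignment step labels each map with $\arg\max_j (x_i^\top t_j)^2$ — the
square makes the algorithm polarity-ignorant, as required for spontaneous
EEG where a topography and its reversal express the same generator
configuration. The update step replaces each template by the dominant
eigenvector of $\sum_{i \in j} x_i x_i^\top$. The objective is the global
explained variance
$\mathrm{GEV} = \sum_i (x_i^\top t_{a(i)})^2 / \sum_i \lVert x_i\rVert^2$,
monitored for convergence (relative change below `tol = 1e-6`) and
maximized over 50 random restarts seeded from the input maps. For $k = 2$
and small $n$ the implementation agrees with an exhaustive search over all
bipartitions to within $10^{-9}$ (see the test suite).

### Parameters

Runs are computed within epochs and never span epoch boundaries. Runs
touching an epoch edge are excluded from MMD and occurrence — a 2-s window
truncates roughly one run at each end, which would otherwise bias MMD
downward — but their samples still count for RTT and GEV (toggleable via
`exclude_edge_runs`). GEV is computed over *all* samples at the
backfitting stage (not only GFP peaks), since the parameters describe the
continuous recording; the per-class form is GFP-weighted squared spatial
correlation as a fraction of total squared GFP.

### Standardized minimum-norm localization

The inverse operator is $T = K^\top (K K^\top + \alpha H)^+$ with $K$ the
(average-referenced) lead field, $H$ the centering matrix and $\alpha$ a
Tikhonov term defaulting to 5% of the mean eigenvalue of $KK^\top$.
Estimated power is standardized by the diagonal of the resolution matrix
$TK$: $P_v = (Tm)_v^2 / (TK)_{vv}$. For $\alpha = 0$ and a noise-free
single-source map this estimator peaks exactly at the generating voxel
(the resolution matrix is symmetric positive semidefinite, so
$R_{wv}^2 \le R_{ww} R_{vv}$ with equality at $w = v$); the package
verifies this zero-localization-error property for every voxel of a
64-channel, 200-voxel synthetic lead field. Sources are fixed-orientation
scalars per voxel — a deliberate desk-scale simplification of the
3-orientation formulation that preserves the standardization principle.
The group statistic is the difference of group means of $\log_{10}$ power
(a log geometric-mean ratio); the familywise threshold is the upper-5%
order statistic of the permutation distribution of the maximum absolute
statistic over voxels, with exact enumeration whenever the number of
distinct relabelings does not exceed the permutation budget.

## The synthetic-data generator

No public resting EEG accompanies the study conditions this package
emulates, so every stage is validated against a ground-truthed generator
(`simulate_group_study()`). Its defaults *are* the study conditions: 55
patients vs 27 controls, 64 channels, 60 s eyes-closed at 250 Hz, four
classes with control mean durations 39.5/40.3/45.0/46.1 ms (the published
control-group values), patient shifts of −2 ms in classes A and B plus a
15% class C amplitude increase (the direction of the published effects),
signal-to-noise power ratio 5, and three covariates (drug-use frequency,
working-memory score, drug-word Stroop error rate) linked to per-subject
ground-truth parameters with standardized slopes of 0.4 — strong enough
for a GLM at $n = 82$ to recover the link reliably, weak enough to stay
realistic.

Design choices the generator had to make, and why:

* **Run-length law.** Durations are gamma-distributed (shape 2) around the
  per-class mean with no immediate self-transitions — a realistic spread
  (CV $\approx 0.7$) without the memoryless pile-up of very short runs an
  exponential law would give.
* **Within-run envelope.** Each run contributes its template times an
  amplitude envelope with a random polarity sign per run. The default
  envelope is a 95% plateau plus a 5% half-sine lobe: GFP then peaks once
  near each run's centre while the topography stays strong right up to the
  transition. This matters: an envelope that passes through zero mid-run
  (e.g. a raw 10 Hz oscillation, available as `envelope = "sine"`) leaves
  samples where noise dominates, fragments the backfitted label runs, and
  halves the recovered MMD — a property of max-correlation backfitting
  without temporal smoothing, not of this implementation.
* **Template geometry.** The four canonical-style maps are built from
  compact dipolar bump pairs placed so the set is nearly orthogonal
  (pairwise $|r| \lesssim 0.1$). Real microstate maps are broader and more
  mutually correlated; with strongly correlated maps, the *mixtures* that
  arise at filtered transitions resemble a third class and insert spurious
  short runs. Quasi-orthogonality keeps transition samples assigned to one
  of the two adjacent classes, so recovered durations track the generated
  ones. This is the main respect in which passing recovery tests on
  synthetic data does not certify equal accuracy on real recordings.
* **Noise.** Spatially and temporally white Gaussian, scaled to the target
  signal-power/noise-power ratio before filtering. Real EEG noise is
  spatially correlated and rhythmic; white noise is the more conservative
  choice for clustering (it projects onto all template directions
  equally).
* **What is not emulated.** Ocular/muscle artifacts (the epoch-rejection
  hook stands in for artifact screening), volume-conduction-realistic
  lead fields (the synthetic lead field is a smooth geometric stand-in on
  a 200-voxel grid, scaled down from the 6239-voxel grid used with real
  anatomy), and any microstate syntax beyond first-order transitions.

## Numerical choices

* **Band-pass realization.** Zero-phase (forward--backward) Butterworth,
  design order 3. Order is a genuine trade-off: order 2 leaves 1.1% of a
  50 Hz mains tone (too permissive), while steeper designs ring longer at
  the 20 Hz edge and visibly blur state transitions, biasing recovered
  durations downward by an extra 1--2%. Order 3 rejects 50 Hz to 0.11%
  and minimizes transition blur; the order remains a `bandpass()`
  argument.
* **Backfitting smoothing.** None by default: every sample is labelled
  independently. Per-sample labelling is a downward-biased duration
  estimator: filtered transitions spawn brief (1--2 sample) spurious
  segments (about 3--4 per second at the default conditions), so recovered
  class-mean durations run 8--15% short of the generating means, with the
  longer classes (C, D) nearest the upper end. Group *differences* are
  unaffected because the bias is common to both groups.
* **Degenerate inputs.** Zero-variance samples inherit the previous
  (or next) label; empty clusters are re-seeded from the worst-explained
  map; class-absent parameters are reported as `NA`, never zero; tied
  template-to-class matchings resolve to the lowest-index permutation.
* **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state (`withr::with_seed`); the pipeline derives stage
  seeds from one master seed, so identical configurations reproduce
  byte-identical artifacts.

## Problem sizes used in validation

The packaged validation suite runs the full pipeline on one 82-subject
study at the default conditions (about 4 minutes on one core), checks
effect directions on 100 generator replicates, permutation FWER on 200
null datasets of 27 subjects x 40 voxels at 500 permutations, ANOVA
calibration on 1000 null datasets of 40 subjects, the k-means oracle on
up to 12 maps, and localization on a 64 x 200 lead field. These sizes were
chosen to give stable Monte-Carlo estimates (binomial SE below 1.6
percentage points for the calibration checks) at desk-scale runtimes.

## Known limitations

* Backfitted MMD is a biased-down estimator near state transitions (no
  temporal smoothing); comparisons *between* groups are unaffected since
  the bias is common to both.
* The GEV reported for real analyses may be defined on GFP peaks only in
  some packages; here it is defined on all samples (documented above), so
  absolute GEV values are not directly comparable across conventions.
* The "log of F-ratio" source statistic is implemented as the log
  geometric-mean power ratio; commercial implementations add a variance
  smoothing constant whose value is not public.
* Whether subjects should be backfitted with their own group's templates
  or with templates clustered across both groups is a genuinely open
  choice; both are implemented (`template_scope` in `pipeline_config()`),
  defaulting to per-group templates.
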