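---
title: "Structure-function coupling in brain networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling in brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem this package addresses

In multiple sclerosis (MS), white-matter damage reshapes the structural
connectome while neuronal dynamics reshape the functional one, and how
tightly the two networks track each other — *structure-function coupling* —
is a candidate marker of cognitive impairment. This package implements a
complete analysis chain for that question: leakage-corrected amplitude
envelope correlation (AECc) functional connectivity from source-level MEG
time series; tract-length-stratified structural connectivity from
fractional anisotropy (FA) matrices; within- and between-subject coupling
statistics; covariate-adjusted group comparisons between healthy controls
(HC), cognitively preserved (CP) and cognitively impaired (CI) patients;
and ROC evaluation of coupling as a classifier of impairment. Because
clinical cohorts of this kind are not public, the package also ships a
synthetic cohort generator that reproduces the *statistical structure* of
such a study, so every stage is testable end to end.

## Functional connectivity: the corrected amplitude envelope correlation

For a pair of regional signals $x, y$ sampled at $f_s$:

1. **Band-pass filtering** by discrete Fourier transform: every frequency
   bin outside the pass band is set to zero and the inverse transform
   taken. The pass band is half-open, $f_{\mathrm{low}} \le f <
   f_{\mathrm{high}}$, so theta (4–8 Hz), alpha1 (8–10 Hz) and alpha2
   (10–13 Hz) partition 4–13 Hz without double-counting shared endpoints.
   The filter is brick-wall in frequency and exactly idempotent; its price
   is temporal ringing at sharp transients, which is immaterial for the
   long stationary resting-state segments it is applied to.
2. **Orthogonalization**: source-reconstructed MEG signals share
   instantaneous (zero-lag) components through imperfect spatial unmixing
   ("signal leakage"). The residual
   $y_{\perp} = y - \frac{\langle y, x\rangle}{\langle x, x\rangle}x$
   removes exactly that component.
3. **Envelopes**: the Hilbert amplitude envelope (magnitude of the
   analytic signal) of the filtered series.
4. **AECc**: the Pearson correlation of the seed envelope with the
   orthogonalized-target envelope. Because orthogonalization is
   directional, both directions are computed and averaged — the standard
   construction, and the only symmetric one. A perfectly collinear
   direction (zero residual) contributes 0 and is flagged with a warning
   rather than propagating NaN.
5. **Rescaling**: FC matrices are mapped through $(r + 1)/2$ onto
   $[0, 1]$ so downstream averages involve no negative weights.

Epoch handling follows the acquisition convention of 1250 Hz sampling and
13 consecutive artifact-free epochs of 16,384 samples (13.10 s): epochs
are concatenated first and the concatenated series filtered as a whole.
Whether the original analyses filtered per epoch before concatenation is
not knowable from the reported pipeline; filtering the concatenated
series follows the stated "analyzed as a whole" and accepts the small
epoch-boundary edge effects. Envelopes are correlated at the full
sampling rate; envelope downsampling (common elsewhere in the AEC
literature) is deliberately not applied, since it changes only the
effective sample count, not the expectation.

`fc_matrix()` computes all $\binom{k}{2}$ pairs. It exploits the
linearity of the Hilbert transform: the analytic signal of the residual
$y - \beta x$ is the difference of the per-channel analytic signals, so
the per-channel FFTs are computed once rather than once per pair. A test
verifies exact agreement with the naive `aecc_pair()` double loop.

## Structural connectivity and tract-length stratification

Structural edges carry the mean FA of the reconstructed tract; matrices
stay unthresholded and an edge is *present* iff FA $> 0$ (the floor is
configurable). Sparsity is the fraction of absent possible edges.
Tract-length quartile thresholds are computed from the lengths of all
present edges pooled across all healthy-control subjects — matching the
use of one pooled control histogram — with linear interpolation between
order statistics (position $(n-1)p + 1$, `quantile` type 7), stated so
results are bit-reproducible. Edges strictly below the 25th percentile
are short-range, strictly above the 75th long-range; edges exactly at a
threshold stay unclassified, mirroring the strict inequalities of the
published cutoffs (<96.765 mm, >172.056 mm). Each subject's own presence
mask is intersected with the group-level length classes: with
unthresholded per-subject matrices this is the only self-consistent
choice. The whole-brain SC scalar averages FA over present edges only
(absent tracts are missing tracts, not zeros); averaging over all cells
is available as an option.

## Coupling statistics

*Between-subject*: per subject, SC and FC are averaged over the edges of
one class; the averages are Pearson-correlated across the subjects of a
group (HC, or all patients pooled), with the two-sided p from the exact
$t$ transform on $n-2$ degrees of freedom. *Within-subject*: the
edge-value vectors of SC and FC over one class are Pearson-correlated
within each subject, giving one coupling value per subject per class. A
whole-brain (all present edges) coupling is included alongside short and
long because the classifier analysis evaluates it. Any correlation needs
at least 3 edges or subjects; fewer yields a flagged missing value that
is excluded listwise downstream.

## Group statistics, multiplicity, and classification

Group comparisons are least-squares linear models with group dummies plus
covariates (age and sex for coupling; age, sex and education — a binary
low/high indicator — for the separate SC/FC comparisons; the sets are
configurable, not hard-coded). The omnibus group effect is the partial F
test of the group factor given the covariates; adjusted means and all
pairwise contrasts come from the same fitted model via `emmeans`, with
unadjusted contrast p-values gated downstream by the Bonferroni alpha —
pairwise contrasts on the full covariate-adjusted model rather than
separate two-group refits, consistent with reporting adjusted means.
Bonferroni control divides the family alpha: 0.05/2 = 0.025 for the
parallel short/long analyses, 0.05/3 ≈ 0.017 for the three pairwise
group comparisons. Pearson vs Spearman for clinical correlations is an
explicit argument rather than an automatic normality decision, because
the original choice was made by histogram inspection.

Cognitive status follows the impairment rule: CI iff $z \le -2$ on at
least two of the seven cognitive domains (inclusive boundary), CP
otherwise; missing domain scores are an error, never imputed.

ROC analysis uses the rank-based (Mann–Whitney) AUC with ties counted
one half, oriented so that higher coupling predicts CI, and reported
as-is (an AUC below 0.5 is not flipped). The p-value against AUC = 0.5
uses the Hanley–McNeil standard error evaluated under the null; the
exact variance convention of the original SPSS analysis is not
published, so this standard choice is documented and an optional
permutation p is provided. The optimal cutoff maximizes sensitivity +
specificity under the rule "score ≥ cutoff predicts CI", with ties
broken toward the lower threshold.

## Pipeline order and gating

`run_pipeline()` executes the stages in the study's order: sparsity and
connection-count checks; whole-brain between-subject correlations per
band; a band gate (raw p < 0.05 in either group, configurable) so only
bands with a whole-brain SC–FC relation are explored further; short/long
between-subject correlations; within-subject coupling group comparisons;
clinical correlations and separate SC/FC comparisons only for coupling
measures that survive; ROC analyses; and post hoc cross-range,
FC-vs-FC and (when time series are present) relative-power checks.
Gated-out stages are logged as skipped, never silently absent. The
results bundle carries the configuration hash and seed, and the whole
chain is deterministic given both.

## What the synthetic generator emulates — and what it does not

The generator reproduces the data *shape* and the planted *effects* the
analysis is meant to detect, at the study's conditions by default:
40/46/33 HC/CP/CI subjects, 78 cortical nodes, 1250 Hz, 13 × 16,384
samples.

* **Tract lengths**: one shared right-skewed template (gamma, shape 3.5,
  scale $(\mathrm{high}-\mathrm{low})/6.3$, shifted to the lower range
  limit and clipped above) emulating the unimodal skewed control
  histogram; the fixed shape places the pooled quartiles near the
  published ~97/~172 mm cutoffs at the default 10–250 mm range.
  Subjects share the template up to Gaussian jitter (SD 2 mm), because
  group-level thresholds are applied to every subject.
* **FA**: declines linearly with length (base 0.62, slope 8×10⁻⁴ per mm,
  putting long-range FA near the reported ~0.42–0.46), with a planted CI
  deficit of 0.03 on long-range edges, per-subject global offsets
  (SD 0.02) that create between-subject variance in mean SC, edgewise
  noise (SD 0.03), clipping to [0, 1], and Bernoulli absent tracts
  (probability 0.1 per edge — probabilistic tractography with 100M seeds
  yields near-dense unthresholded matrices, and the Bernoulli form gives
  sparsity the between-subject variance its group comparison needs).
* **Coupling**: the planted envelope-correlation target on present edges
  is linear in FA about a fixed center (0.5) with group-specific slope
  (defaults HC 0.05, CP 0.15, CI 0.30), constant elsewhere, planted in
  the theta band only. No quantitative effect size for the CI excess is
  derivable from published group means alone, so the slope is a free
  parameter chosen once to give a clearly ordered CI > CP > HC effect;
  consequently the *magnitudes* of downstream F statistics and AUCs on
  synthetic cohorts exceed the published ones by design, and only signs,
  orderings and gating behavior are meaningful comparisons.
* **Signals**: channels are independent band-limited noise carriers
  amplitude-modulated by latent lognormal envelopes,
  $\exp(\sigma z)$ with $\sigma = 0.5$, where the Gaussian drivers $z$
  are low-pass filtered at 2 Hz and mixed through the matrix square root
  of the target correlation matrix. The lognormal link keeps the map
  from latent to realized envelope correlation sign-preserving and
  monotone; orthogonalization and the nonlinearity attenuate recovered
  AECc relative to the target, so tests calibrate recovery as a
  *monotone* relation, never as identity. Arbitrary planted matrices are
  projected to the nearest unit-diagonal positive-semidefinite matrix by
  eigenvalue clipping before mixing.
* **Two signal modes**: `planted_fc` (default) emits per-band FC matrices
  directly as planted target + observation noise (SD 0.05) on the raw
  scale — a model of the AECc estimate's distribution — while
  `timeseries` synthesizes the series themselves and leaves FC to
  `fc_matrix()`. A full-scale cohort of time series occupies ~16 GB, so
  cohort-level statistics use `planted_fc`, and the signal path is
  validated separately at the full series length on few channels. This
  split is what makes hundreds of Monte-Carlo pipeline replicates
  tractable.

Not emulated: sensor-level MEG, head models and beamforming, MRI
volumetrics and lesions, spatial autocorrelation of FA and FC beyond the
length dependence, realistic 1/f spectra, and any relation between the
cognitive z-scores and connectivity (clinical correlations are null by
construction). Passing tests therefore demonstrate correctness of the
estimators and the inferential chain under the planted model, not that
real MS data carry the planted effect.

## Numerical choices and degenerate inputs

* Band edges half-open; a tone exactly at a shared edge belongs to the
  upper band only. Brick-wall passthrough of a tone is exact only when
  the tone is periodic in the analysis window, so filter oracles use
  bin-aligned frequencies.
* Orthogonalization against an all-zero series is an error; a collinear
  residual inside AECc contributes a flagged 0.
* Asymmetric input matrices within 10⁻⁹ are symmetrized silently, beyond
  that with a warning; FA outside [0, 1] and present edges without a
  positive length are errors naming the offending cell.
* Group comparisons with a zero-variance outcome or a perfectly fitted
  model are returned as flagged degenerate results, not tested; a
  numerically negative group sum of squares (identical group means) is
  reported as F = 0, p = 1.
* Correlations require non-constant inputs and report which side (SC or
  FC) is constant.
* All simulations are deterministic functions of a config seed.

## Problem sizes used by the test suite

Monte-Carlo checks are sized to what the properties need: filter and
envelope oracles run on 10–40 s of signal; leakage suppression uses 100
draws of 20-minute series at 250 Hz (the null sampling error of an
envelope correlation is set by the envelope bandwidth, so a lower
sampling rate buys series length cheaply); planted-correlation recovery
uses the full 212,992-sample length at 1250 Hz on 8 channels over 20
replicates; null calibration of the coupling group test uses 500
reduced cohorts (15 per group, 78 nodes, theta only) and effect recovery
100 such cohorts through the entire pipeline.

## Known limitations

* The planted-FC mode bypasses the estimator when generating cohorts, so
  cohort-level tests validate the statistics given FC, and signal-level
  tests validate the estimator given signals; no test does both at
  cohort scale in one pass.
* The generator plants no spatial topology (edges are exchangeable given
  length), so network-topological analyses would find nothing to detect.
* The FFT band-pass assumes stationary segments; data with large
  transients would ring.
* `glm_group_compare()` fits homoscedastic linear models; group-specific
  variances are not modeled.
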