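# sfcoupling

Structure–function coupling analysis for brain networks: does the
functional network of an individual track their structural network, and
does that coupling mark cognitive impairment in multiple sclerosis (MS)?

The package is written for researchers who have, per subject, (a) a
structural connectome — a symmetric node × node matrix of mean fractional
anisotropy (FA) per white-matter tract, with matching tract lengths in
mm — and (b) source-level MEG time series (channels × samples) or
precomputed functional connectivity (FC) matrices, plus a subject table
with group labels, demographics and cognitive z-scores. Since such
clinical cohorts are rarely shareable, a synthetic cohort generator with
plantable effects makes the entire chain runnable and testable without
any data.

## The measures

**Functional connectivity** is the corrected amplitude envelope
correlation (AECc). For band-filtered signals \(x, y\) (brick-wall FFT
filter, half-open bands theta 4–8, alpha1 8–10, alpha2 10–13 Hz):

\[
\mathrm{AECc}(x,y) = \tfrac12\Big[
\mathrm{corr}\big(A(x),\, A(y_{\perp x})\big) +
\mathrm{corr}\big(A(y),\, A(x_{\perp y})\big)\Big],
\qquad
y_{\perp x} = y - \frac{\langle y,x\rangle}{\langle x,x\rangle}\,x,
\]

where \(A(\cdot)\) is the Hilbert amplitude envelope. The time-domain
orthogonalization removes zero-lag signal leakage; matrices are rescaled
through \((r+1)/2\) onto \([0,1]\).

**Edge classes**: tract lengths of all present edges pooled over healthy
controls define quartile thresholds; edges strictly below Q1 are
short-range, strictly above Q3 long-range.

**Structure–function coupling** of a subject is the Pearson correlation
between their FA and FC edge vectors over one edge class. Group-level
(between-subject) correlations relate subject-mean SC to subject-mean FC
across a group. Coupling is compared between healthy controls (HC),
cognitively preserved (CP) and impaired (CI) patients with
covariate-adjusted linear models (omnibus partial F, `emmeans` pairwise
contrasts, Bonferroni control), and evaluated as a CI-vs-CP classifier
with rank-based ROC/AUC and an optimal sensitivity+specificity cutoff.

## Worked example

```r
library(sfcoupling)

cfg     <- cohort_config(n_hc = 20, n_cp = 20, n_ci = 15, n_nodes = 40, seed = 7)
cohort  <- generate_cohort(cfg)
results <- run_pipeline(cohort)
results
#> <sfc_results>
#>   cohort: 55 subjects; config hash 83f60125; seed 7
#>   thresholds: short < 90.154 mm, long > 176.406 mm
#>   gated bands: theta
#>   coupling theta_short: F = 11.653, p = 0.0001 *
#>   coupling theta_long: F = 28.889, p = 0.0000 *
#>   ROC theta_whole: AUC = 1.000 (p = 0.000)
#>   ROC theta_short: AUC = 0.710 (p = 0.036)
#>   ROC theta_long: AUC = 0.847 (p = 0.001)
```

Reading this: short/long cutoffs came from the pooled control
tract-length quartiles; only the theta band passed the whole-brain
SC–FC gate (the generator plants coupling in theta only, so the gate
skipping the alpha bands is the expected behaviour); the within-subject
coupling group effect is significant for both edge classes (`*` = below
the 2-test Bonferroni alpha of 0.025); and coupling separates CI from CP
patients well here because the planted CI slope is deliberately strong.

```r
glance(results$coupling_tests$theta_long)
#> # A tibble: 1 × 7
#>   outcome     F   df1   df2             p     n covariates
#>   <chr>   <dbl> <dbl> <dbl>         <dbl> <int> <chr>
#> 1 r        28.9     2    50 0.00000000458    55 age+sex
```

`tidy(results)` returns every test as one row (statistic, raw p, the
alpha it is judged against, pass flag); `autoplot(results)` draws the
per-group coupling boxplots; `autoplot(results$roc$theta_long)` the ROC
curve; `report_results(results, "out/")` writes the delimited tables and
a human-readable report. Cohorts round-trip through plain-text
directories with `write_cohort()` / `read_cohort()`, and the signal path
is available directly via `fc_matrix()`, `aecc_pair()`,
`fft_bandpass()`, `hilbert_envelope()` and friends.

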