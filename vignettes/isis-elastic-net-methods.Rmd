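---
title: "Screening and stabilized elastic-net selection for methylation studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and stabilized elastic-net selection for methylation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isisen)
```

## The problem

Epigenome-wide association studies measure DNA methylation at hundreds of
thousands of CpG sites (p ≈ 485,000 on the 450K array) in cohorts of a few
hundred subjects. Two features make variable selection hard at this scale:
the dimensionality (p ≫ n by three orders of magnitude), and strong local
correlation — co-methylation between neighbouring probes can reach 0.98, so
any selected site arrives with a cloud of near-duplicates.

`isisen` implements a two-stage strategy for this regime, applied to an
ordinal metabolic-syndrome index: *sure independence screening* cuts the
feature space to a submodel of manageable size before a penalized
likelihood fit selects within it, iterating so that features missed by
marginal screening can be rescued; the selected set is then stabilized
over bootstrap resamples.

## The model

The response is the metabolic-syndrome index: the number of satisfied
component conditions (abdominal obesity, high fasting glucose, low HDL,
hypertension, hypertriglyceridemia — medication use counts toward the
matching condition), so \(y_i \in \{0, \dots, 5\}\). Rather than
dichotomizing at the conventional three-of-five threshold, the index is
modelled as binomial trials:

\[
y_i \sim \mathrm{Binomial}(m = 5,\ \pi_i), \qquad
\mathrm{logit}(\pi_i) = \beta_0 + \beta^\top x_i ,
\]

which uses the full ordinal information (the binary threshold is retained
for evaluation). Covariates are M-values, the base-2 logit of the Beta
methylation proportion, the standard analysis scale because Beta values
are compressed at the extremes. `beta_to_m()` clips at `eps = 1e-6` before
the logit so fully (un)methylated probes stay finite.

The fit minimizes the penalized objective

\[
\frac{1}{n} \,\mathrm{negloglik}(\beta_0, \beta)
  + \lambda\Bigl(w \lVert\beta\rVert_1
  + \tfrac{1-w}{2}\lVert\beta\rVert_2^2\Bigr),
\]

with `w = 0.5` by default — half lasso, half ridge — so that the penalty
keeps the solution sparse while shrinking correlated probes together
rather than picking one arbitrarily. The intercept is unpenalized.
Optimization is IRLS with a cyclic coordinate-descent inner loop on the
weighted least-squares subproblem (soft-threshold updates whose
denominator carries the ridge term), warm starts along a decreasing
\(\lambda\) path, active-set iteration with vectorized KKT sweeps, and a
step-halving guard that keeps the penalized objective non-increasing
across accepted IRLS steps. Columns are standardized to unit variance
before penalization (penalty fairness across probes of unequal variance);
coefficients are reported on the original scale.

## Screening

`sis_screen()` ranks features by absolute Pearson correlation with the
count response and keeps the top \(d\). The default submodel sizes follow
the usual sample-size rules, with natural logarithms and a floor of 1:

| outcome | rule | value at n = 659 |
|---|---|---|
| binary | \(\lfloor n / (4 \ln n) \rfloor\) | 25 |
| count | \(\lfloor n / (2 \ln n) \rfloor\) | 50 |
| continuous | \(\lfloor n / \ln n \rfloor\) | 101 |

Marginal screening misses features that are nearly uncorrelated with the
outcome marginally but informative jointly (e.g. a feature negatively
correlated with a selected one, whose effects cancel).
`isis_select()` therefore iterates: after each fit it ranks the remaining
features by correlation with the response-scale residual
\(y_i - m\hat\pi_i\), recruits the top \(d - |S|\), refits on the union,
and stops when the active set stabilizes (or after `max_isis_iter = 5`
iterations). Deviance residuals are available behind a flag, as is a
per-feature GLM ranking; the defaults are the correlation forms because
they are rank-equivalent on standardized data and orders of magnitude
cheaper at p in the hundreds of thousands.

## Tuning and refinement inside the selection step

Two design questions are genuinely open in this pipeline: how \(\lambda\)
is chosen at each refit, and what exactly counts as "selected". The
package's defaults differ from the most common reflexes, for reasons worth
spelling out.

**Why not cross-validated deviance.** With a strong ordinal signal the
binomial likelihood is nearly saturated: held-out deviance keeps
decreasing as the model grows, because extra correlated features cost
almost nothing out of sample. Both this package's `cv_lambda()` and
`glmnet::cv.glmnet()` (checked on the same draws) pick dense models at
`lambda.min` *and* `lambda.1se` in that regime. CV answers a prediction
question; selection needs an explicit dimension penalty. The default
tuning (`tune = "bic"`) is therefore BIC over the penalized path,
\(\mathrm{deviance}(\lambda) + \log(n)\,\mathrm{df}(\lambda)\), which is
also deterministic — valuable inside bootstrap loops. `tune = "cv"`
switches back to `cv_lambda()` (10-fold by default standalone, 5-fold
inside the screening loop), with `"min"` and `"1se"` rules.

**Why a refinement step.** The ridge component of the elastic net shrinks
correlated predictors *together*: under a block of within-correlation 0.9,
whenever the truly associated probe enters the path its block-mates enter
essentially simultaneously. The consequence is structural, not a tuning
artifact — no \(\lambda\) on the `w = 0.5` path has an active set equal to
the sparse truth, so no rule for choosing \(\lambda\) can deliver it. The
unpenalized refit separates the candidates cleanly: given the true probe,
a decoy reduces the deviance by roughly one unit, far below any
reasonable per-parameter penalty, while removing a true probe costs
hundreds. `refine = "bic"` therefore prunes the elastic-net active set by
backward elimination — one Newton refit per step, dropping the feature
with the smallest Wald \(|z|\), keeping the subset that minimizes
\(\mathrm{deviance} + [\log n + 2\gamma\log p]\,|S|\) along the
elimination sequence. The \(2\gamma\log p\) term is the EBIC correction
(\(\gamma = 0.5\) by default): after searching p features, plain BIC
under-penalizes, and spurious post-screening correlates at n = 659 clear
the \(\log n\) bar but not the EBIC one. `refine = "none"` reports the raw
active set, and with `d >= p`, one iteration, CV tuning and no refinement
the procedure collapses exactly to a single elastic-net fit on all
features — the "no screening" comparator in its literal form.

## Bootstrap stability selection

`bootstrap_select()` reruns the whole selection on B nonparametric
bootstrap resamples (rows drawn jointly with replacement, size n;
unstratified) and counts how often each feature is selected, in the
Bolasso tradition of intersecting or thresholding bootstrap supports. Two
thresholds are implemented: `half` keeps features selected in at least
half the replicates (`counts >= B/2`; the boundary is included because the
source descriptions alternate between "more than half" and "at least
half"), and `gap` cuts the sorted frequency sequence at its single largest
drop, selecting nothing (with a warning) when that drop is not unique.
`both` intersects them and reports both partitions. Per-replicate seeds
derive from the master seed by a counter scheme, so results do not depend
on execution order; a degenerate resample (e.g. constant response) is
recorded as an empty selection rather than aborting the run.

## Evaluation

`binary_auc()` is the Mann–Whitney estimator computed from mid-ranks
(ties count 1/2). For the ordinal index, `hand_till_auc()` averages the
two-class AUCs over all unordered pairs of observed classes,
\(M = \tfrac{2}{c(c-1)}\sum_{i<j}\hat A(i,j)\). Hand and Till define
\(\hat A(i,j)\) from per-class probability columns; this model emits a
single scalar score \(\hat\pi\), in which case \(A(i|j)\) and \(A(j|i)\)
coincide with the two-class AUC of that score (oriented so the higher
class is positive), and the definition reduces to the plain pairwise
average. `cv_evaluate()` wraps the full pipeline in seeded unstratified
k-fold cross-validation — selection and tuning run on training folds
only — scoring held-out subjects by \(\hat\pi\) and reporting per-fold and
mean AUCs for the 0–5 index and its ≥ 3 dichotomy, plus the selected-set
size. A test fold containing a single class yields `NA` for that AUC and
is excluded from the mean with a warning.

## The synthetic benchmark

Because the motivating cohort's methylation matrix is not distributable,
`sim_design()` generates a surrogate with the one property that matters
most here: strong local correlation. Columns form equicorrelated Gaussian
blocks (\(x = \sqrt\rho\, z_{\mathrm{block}} + \sqrt{1-\rho}\,\varepsilon\),
blocks independent, unit variance by construction; block size 10,
\(\rho = 0.9\) by default, 0.98 available as the observed co-methylation
extreme). `sim_mets_scenario()` plants the benchmark study: n = 659
subjects, four nonzero coefficients \((6.6, 2.2, 3.5, -6.3)\) — the
reference effect sizes for this problem — placed in four distinct blocks
so every true feature has nine correlated decoys, intercept 0, and
\(y_i \sim \mathrm{Binomial}(5, \pi_i)\). `p` defaults to 2000 for
desk-scale work; 484,548 reproduces the full array.

What the generator does *not* emulate: the bimodal marginal distribution
of real Beta values, heterogeneous and distance-decaying correlation,
batch effects, and cell-type composition. Tests passing on this benchmark
demonstrate the selection mechanics — screening, grouping, pruning,
stabilization — under idealized correlation, not robustness to those
artifacts, which upstream preprocessing is expected to remove.

## Numerical choices and degenerate inputs

- Convergence: outer IRLS stops when the maximum absolute coefficient
  change falls below `tol = 1e-7` (default; `max_iter = 1000`).
  Path scans used only to rank \(\lambda\)s or to seed the pruning step
  run at a scan tolerance of `1e-5` and at most 25 IRLS iterations per
  grid point; every reported fit is computed at the configured tolerance.
- Probabilities are clipped at `1e-9` so the likelihood stays finite under
  separation; a constant response pins the intercept at the clipped
  boundary with a warning.
- \(\lambda_{\max} = \max_j |x_j^\top(y - \bar y)| / (nw)\) on
  standardized columns; the grid is geometric with
  `lambda_min_ratio = 0.01` when p > n (else `1e-4`). Pure ridge
  (`w = 0`) has no finite all-zero penalty; the grid falls back to the
  `w = 0.001` formula with a warning.
- Ties in every ranking break by ascending feature index; zero-variance
  columns rank last. CV ties resolve toward the larger (sparser)
  \(\lambda\).
- KNN imputation operates in probe space with `k = 10`, Euclidean distance
  over mutually observed samples rescaled by \(\sqrt{n/\text{overlap}}\);
  fewer than k usable neighbours triggers a warning and uses all
  available, none is an error naming the probe.
- The MetS thresholds follow the printed inequalities literally (strict
  `>` for waist and blood pressure, `>=` for glucose and triglycerides,
  `<` for HDL); subjects with missing components are excluded by error,
  never imputed.

## Problem sizes used by the test suite

The package's checks run the benchmark at n = 659, p = 2000, B = 50
bootstrap replicates and ten study replicates — large enough that all
four planted features must survive bootstrap thresholding while decoys
must not, yet small enough for routine desk runs. Unit-level oracles
(trial-expansion likelihood identity, unpenalized-IRLS agreement at
\(\lambda = 0\), brute-force AUC enumeration) use instances of tens of
subjects where exhaustive computation is exact.

## Limitations

- The binomial-trials model treats the five MetS components as
  exchangeable Bernoulli draws with a shared \(\pi_i\); it ignores that
  the components are heterogeneous and correlated within subject.
- Backward elimination is greedy; with extreme collinearity (\(\rho\) at
  0.98 and small n) the Wald ordering can prune a true feature before its
  decoy. The bootstrap layer is the intended mitigation.
- Screening guarantees (the "sure screening" property) are asymptotic;
  at fixed n the iterative rescue step is a heuristic, bounded by
  `max_isis_iter`.
- The CLI and file formats handle dense TSV matrices; at the full
  485k-probe scale users should expect memory pressure (a 659 × 485k
  double matrix is ≈ 2.4 GB) and favour the in-memory API.
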