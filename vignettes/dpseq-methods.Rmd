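---
title: "Methods: double Poisson differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double Poisson differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpseq)
```

## The problem

RNA-seq read counts for a gene across biological replicates are commonly
modeled as negative binomial (NB): `Var(Y) = mu + mu^2 * phi` with
`phi >= 0`. That variance can never fall below the mean, but real count
matrices contain genes whose replicate variance does — underdispersion,
concentrated at low counts. An NB-based test must inflate those genes'
variances to the Poisson level or above, losing power exactly where the
data are most regular.

`dpseq` analyzes two-group designs with Efron's double Poisson (DP) model
alongside the NB. The DP density in its approximate form is

\[
f_{\mu,\theta}(y) \;=\; \theta^{1/2} e^{-\theta\mu}
\left(\frac{e^{-y} y^{y}}{y!}\right)
\left(\frac{e\mu}{y}\right)^{\theta y},
\]

with the two \(y = 0\) factors read as 1 (so \(f(0) = \sqrt\theta\,
e^{-\theta\mu}\), the continuous limit of the density). The exact pmf
multiplies \(f\) by a normalizing constant \(c(\mu,\theta)\) close to 1.
Mean \(\approx \mu\); variance \(= \mu/\theta\). \(\theta = 1\) recovers the
Poisson exactly; \(\theta > 1\) is underdispersion; \(0 < \theta < 1\)
overdispersion.

### The normalizing constant

Two evaluations of \(1/c\) are provided: a truncated summation of \(f\)
over a support window centered on the mode (20 SDs on each side, widened
adaptively until the log density falls 14 orders of magnitude below the
peak — the overdispersed right tail decays like \(\exp(-\theta y\log y)\),
slower than Gaussian), and the closed-form expansion
\(1/c = 1 + \frac{1-\theta}{12\mu\theta}(1 + \frac{1}{\mu\theta})\).
The closed form is accurate to well under 1% for moderate-to-large means
(about \(\mu \ge 30\) across \(\theta \in [0.05, 20]\) with
\(\mu\theta \ge 2\)) but degrades sharply at small \(\mu\), so
`dp_log_pmf(exact = TRUE)` and the sampler always use the summation, and
the likelihood code uses the closed form only where it has been verified
accurate (\(\mu \ge 10\), \(\mu\theta \ge 3\), \(\theta \le 20\)),
summation elsewhere (strided when the window exceeds 512 integers; the
summand is smooth on that scale and the midpoint error is below `1e-3`
relative, far inside the optimizer's noise).

## Normalization

Counts are scaled by per-sample size factors with unit geometric mean;
normalized counts `Y/s` estimate the underlying expression. TMM is the
default (reference = sample whose upper quartile is closest to the mean
upper quartile; 30% M-trim, 5% A-trim, inverse-variance weights — the
method's canonical settings, computed via edgeR), with total-count,
upper-quartile, median, and median-of-ratios ("deseq") selectable. Genes
with zero counts in either member of a TMM pair are excluded from the
trimmed mean, as their log-ratios are undefined.

## The dispersion cascade

Dispersion is assumed shared between the two groups (defensible at 3
replicates per group); every stage pools all `n = KJ` samples.

1. **Moments initialization.** Pooled mean \(\mu_i\) = mean of normalized
   counts times the mean size factor; pooled variance \(\sigma^2_i\) = the
   df-weighted within-group variance of normalized counts rescaled to the
   count scale, which removes any group-mean difference and so works under
   the alternative too. Then \(\phi^{init} = (\sigma^2-\mu)/\mu^2\)
   (floored at `1e-8` when \(\sigma^2 \le \mu\): the NB cannot represent
   underdispersion, and the floor is the conventional "effectively
   Poisson" sentinel) and \(\theta^{init} = \mu/\sigma^2\), clipped to
   `[1e-4, 1e4]`. Genes with all-zero counts are removed (their moments
   are undefined); genes expressed in only one group are kept.

2. **Gene-wise likelihood.** One-dimensional bounded maximization over the
   log dispersion (golden-section, tolerance `1e-8`, bounds as above),
   with per-sample means fixed at the fitted group means times each
   sample's size factor, so every observation keeps its own depth. The
   returned value is the best of the interior optimum, both bounds, and
   the initializer — a flat or monotone likelihood lands exactly on a
   bound and a failed search can never do worse than its start. The
   objective includes a Cox–Reid adjustment, \(-\tfrac12\log\) of the
   Fisher information of each estimated group mean. Without it the
   profile likelihood ignores the two degrees of freedom spent on the
   group means and overestimates \(\theta\) (underestimates variance) by a
   factor approaching \(n/(n-K)\); for the DP family with saturated group
   means the adjustment reduces exactly to the Gaussian REML correction.
   In null calibrations this term is the difference between a ~10% and a
   ~5% empirical type-I error, and it is the same device the NB shrinkage
   literature uses for the identical reason. `cr = FALSE` restores the
   plain profile likelihood.

3. **Trend.** Lowess of log gene-wise dispersion on log mean, span 0.3,
   evaluated at every gene and clipped to the family bounds. Gene-wise
   values pinned to a bound (every underdispersed gene sits exactly on the
   NB floor) carry no information and would drag the whole trend to the
   boundary, so the regression is fit only on estimates at least a decade
   clear of the bounds and interpolated to the remaining genes. Below 50
   informative genes the median is used instead.

4. **Shrinkage.** MAP under a log-normal prior: location
   `m0 = median(log trend)`, width `tau = 1.4826 * MAD(log genewise - log
   trend)` floored at 0.25, both fitted on the informative genes. The
   prior term is the log of the LN density taken on the dispersion scale;
   its \(-\log\theta\) component places the effective log-scale mode at
   \(m_0 - \tau^2\), a deliberate conservative pull (toward larger DP
   variances) that grows with prior uncertainty. The alternative
   parameterization — a normal prior density on the log dispersion — was
   evaluated and rejected: under strong between-gene dispersion
   heterogeneity the prior is weak and that parameterization leaves the
   null test visibly anticonservative, while the dispersion-scale MAP
   keeps both the DP and Mix modes near the nominal level.

5. **Window scan.** Genes ranked by pooled mean (ties broken by gene id)
   are binned into windows of width 1 count; windows holding fewer than 20
   genes are merged forward (a small final remainder merges backward),
   since medians over a handful of genes are unstable. Within a window,
   genes split into I-type (shrinkage ≥ trend) and II-type (shrinkage <
   trend); each gene's final dispersion is the larger (NB) or smaller
   (DP) of its own shrinkage value and its type's median — for either
   family the direction that enlarges the implied variance, guarding the
   test against anticonservative dispersion estimates.

## The test

For gene *i* the Wald statistic is
\(W = |\mu_{1} - \mu_{2}| / \sqrt{\sigma^2_{1} + \sigma^2_{2}}\), referred
to the standard normal, two-sided. The group variances come from the final
dispersion through the family's variance law evaluated at the group mean.
By default (`variance_of_mean = TRUE`) they are the variances *of the
group means* — the single-observation model variance divided by the
replicate number, size-factor adjusted — which is the scale the Wald
construction requires: with the raw single-observation variance the null
statistic is \(N(0,1)/\sqrt{J}\) and the test's size collapses to
\(\sim 10^{-3}\) at \(J = 3\). The raw-variance reading remains available
via `variance_of_mean = FALSE`.

Mode `"Mix"` takes the per-gene minimum of the DP and NB p-values as the
final p-value, then applies BH — mildly anticonservative by construction
(a union of two 0.05-level tests), accepted as the method's design. DEGs
are genes with `padj < 0.05` and fold change strictly outside
`[0.67, 1.5]` (fold change = normalized treatment mean over control mean;
`0/0` is 1 and `x/0` is `Inf`, which counts as exceeding the upper
threshold).

## The simulator

`simulate_dataset()` draws every count from the exact DP pmf by inverse
CDF over the truncated support, given per-gene `(mu, theta)` from either
`synth_params()` (means log-uniform on `[1, 1e4]`; `log theta ~ N(0,
0.7)`, giving a roughly even split of under- and overdispersed genes) or
`estimate_params()` (pooled means and gene-wise DP MLEs from a real
matrix). A chosen number of DE genes receive a fold change on the
treatment mean — `|log2 FC|` uniform on `[0.585, 2]` with random sign by
default, i.e. 1.5× to 4×, spanning upward from the DEG-calling threshold —
while `theta` stays shared between groups, matching the estimation
assumption. Size factors are simulated as 1: depth variation is the
normalizer's job, and simulating it would only test TMM again. Two seed
streams (truth vs count draws, the second derived by a fixed offset) keep
the truth table stable.

What the generator does *not* emulate: sample-to-sample depth and
composition effects, outlier samples, correlated genes, zero inflation,
and single-cell bimodality. Passing tests on these simulations therefore
demonstrate calibration and power *under the DP generative law with
independent genes*, not robustness to those real-data complications.

## Evaluation harness

`confusion_metrics()` reports FPR/TPR at a significance level (empty
strata give `NA`, never 0), optionally stratified by the pooled-moments
dispersion class — classification uses the *observed* counts, as one would
on real data, not the generating `theta`. `roc_auc()` sweeps unique
p-values with tie groups collapsed, making the trapezoid AUC equal to the
Mann–Whitney pairwise probability with half-credit for ties;
`pr_curve()` defines precision at recall 0 as the precision of the
top-ranked tie group. `compare_methods()` accepts named per-gene p-value
tables from any method (genes missing from a table are scored `p = 1`,
with a message) and returns a tidy method × stratum metric table.

## Numerical and design choices, collected

- All likelihood work in log space; `lgamma` for factorials; counts up to
  `1e6` cannot overflow.
- NB pmf with `phi < 1e-10` is evaluated as Poisson (the exact limit),
  avoiding `gamma(1/phi)` overflow.
- Dispersion bounds: `phi` in `[1e-8, 1e4]`, `theta` in `[1e-4, 1e4]`;
  boundary values are legitimate outputs.
- The DP sampler refuses to sample if its truncated support misses mass
  (relative tail above `1e-12`), rather than silently truncating.
- Window width is defined on normalized-mean counts and configurable;
  occupancy minimum 20.
- The analysis path contains no randomness: identical inputs give
  identical results.
- With a zero denominator the Wald statistic is 0 when the means agree
  and `Inf` (p = 0) when they differ; both-zero group means give fold
  change 1.

## Problem sizes used by the test suite

The packaged checks run null calibrations on ten 2,000-gene datasets
(two groups of three replicates), a 2,000-gene dispersion-recovery study
(`theta ~ LN(log 1.5, 0.5)`), power grids at `theta` in {0.5, 1, 3} ×
`mu` in {50, 200, 1000} with 300 genes and five replicate datasets per
cell, and sampler checks at 10⁵ draws — sizes chosen so the whole suite
exercises every stage at meaningful scale while remaining a
few-minutes-scale run on a laptop.

## Known limitations

- Two groups only; no covariates, no multi-factor designs.
- Dispersions are assumed equal across groups.
- The normal reference for W ignores the residual uncertainty of the
  shrunken dispersions; at very small replicate numbers with weak
  shrinkage the raw-p type-I error can sit slightly above nominal (the
  Mix mode more so, by construction).
- The DP mean is only approximately `mu` (exact up to the normalizing
  constant's drift), so extreme parameter corners (`mu < 1` with large
  `theta`) are better served by the exact pmf than by moment reasoning.
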