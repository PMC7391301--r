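---
title: "Methods and design notes for rbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rbscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbscreen)
```

This vignette documents the statistical models behind the three analysis
stages, the parameters that matter, what the synthetic-data generators do
and do not emulate, and the numerical and design choices made where more
than one reasonable option existed.

## 1. Differential hub co-expression scanning

### Model

The unit of analysis is a *hub*: a node of the interaction network with
more than 4 partners (degree ≥ 5, tunable via `min_partners`). The
disruption statistic for hub $h$ with usable partner set $P$ is

$$S(h) = \frac{1}{|P|}\sum_{p \in P}\left|\,r(h,p \mid A) - r(h,p \mid B)\,\right|,$$

the mean absolute between-condition difference of hub--partner Pearson
correlations. Absolute expression level cancels out of $S$; only the
co-variation of a hub with its partners matters, which is the point of
the method. Since $r \in [-1, 1]$, $S \in [0, 2]$.

The null model is a permutation of the condition labels across samples,
preserving the two group sizes. Alternatives (bootstrap resampling,
parametric draws) exist; label permutation is the standard
exchangeability null for a two-condition correlation-difference
statistic and is what the package implements. The empirical p-value uses
add-one smoothing, $p = (1 + \#\{S_\text{perm} \ge S_\text{obs}\})/(1 +
n_\text{perm})$, so $p > 0$ always and the smallest attainable p at the
default 1000 permutations is $1/1001$.

Consensus calling runs the test `n_runs = 3` times, each on a stratified
random subsample of `subsample_fraction = 2/3` of the samples per
condition (ceiling rounding: 21 tumours and 12 normals subsample to 14
and 8), and intersects the per-run significant sets. Consensus is
monotone in `alpha`: raising it can only grow each run's set and hence
the intersection. The per-run significance level defaults to
`alpha = 0.05`; it is exposed because no single value is canonical.

Partners absent from the expression matrix, or with zero variance in
either condition, are dropped from the partner mean and the usable count
is recorded; a hub with no usable partner gets an `NA` score and is
flagged rather than silently scored 0, so downstream steps can exclude
it explicitly.

### Skeleton extraction and cross-species confirmation

Large interaction networks are first reduced to their
high-edge-betweenness skeleton: the top
$\lceil \text{retain\_fraction} \cdot |E| \rceil$ edges by edge
betweenness centrality are kept (ties broken deterministically by edge
order) and degree-0 nodes removed. The retained fraction defaults to
0.2; it is a config parameter because no universal retention threshold
exists. At `retain_fraction = 1` the operation only prunes pre-existing
singletons. Betweenness comes from igraph; the test suite checks the
kept edge set against a brute-force all-shortest-paths oracle.

Cross-species confirmation intersects two disrupted-hub sets through an
ortholog map filtered to one-to-one pairs; many-to-many pairs are
dropped (reported via message) because a single confirmed identity is
required, and unmapped hubs are skipped rather than fatal.

### Computational notes

Permutation scans are vectorised: for each hub, all permuted group
assignments are encoded as an indicator matrix and every permuted
correlation is computed from cross-products in a handful of matrix
multiplications. A 100-hub scan at 3 runs × 1000 permutations on 120
samples completes in a few seconds on one CPU. Permuted groups with
zero variance for a partner (possible only with degenerate data) yield
`NA` and are dropped from that permutation's mean.

## 2. Pooled shRNA dropout-screen scoring

The scoring chain is: per-sample total-count normalisation (target
$10^7$; the normalisation method is a config choice since several are in
use), log10 transform with pseudocount 0.1 (zeros must be representable,
and reported normalized read counts in such screens go as low as 0.1),
robust-Z masking of outlier tumour replicates, then either Z-score or
log-ratio-cutoff dropout calling.

**Robust-Z masking.** Per (shRNA, cell line), the robust Z across tumour
replicates is $(x - \text{median}) / (1.4826 \cdot \text{MAD})$.
Replicates with $|Z| > 5$ are outlier candidates; at most 2 of 6 are
excluded (largest $|Z|$ first, ties broken by sample order), and the cap
additionally guarantees ≥ 4 replicates always remain. When the MAD is 0
with all values equal there is nothing to exclude; when the MAD is 0
with unequal values (at least four identical values), the scale falls
back to the mean absolute deviation times 1.2533, its normal-consistency
constant — the median/MAD estimator itself is a choice, as "robust Z"
admits several definitions. One non-obvious property worth recording:
with 6 replicates the MAD's 50% breakdown point bounds the third-largest
attainable $|Z|$ at about $2/1.4826 \approx 1.35$, so at threshold 5 no
more than two replicates can ever be flagged and the exclusion cap only
binds at lower thresholds (where the tests exercise it).

**Dropout calling.** The averaged retained-tumour/T0 ratio is
log10-transformed (pseudocount on both numerator and denominator) and
standardised across all shRNAs *within* a cell line; an shRNA drops out
at $z < -1.96$ (two-tailed 5%). Standardisation presumes roughly
Gaussian log ratios, so an advisory omnibus skewness--kurtosis check
(D'Agostino--Pearson $K^2$; implemented from the standard formulas, as
no installed package provides it) warns — but does not abort — when the
distribution departs from normality. When it does, the cutoff-based
caller is the intended path: an shRNA scores at log ratio ≤ −0.69
(fivefold reduced growth; log base 10 is used throughout, making
"fivefold" $\log_{10}(1/5) = -0.699$, and the conventional printed
−0.69 is applied verbatim). A gene is a per-line hit with ≥ 2 scoring
shRNAs; tiers count hit lines (high ≥ 3, medium = 2, low = 1 in a
4-line design).

**Fisher validation.** `fisher_exact_2x2()` uses the probability-mass
two-sided rule (sum of hypergeometric probabilities of tables at most as
probable as the observed one), delegated to `stats::fisher.test` and
verified in the tests against a full enumeration oracle.

## 3. Median-effect synergy quantification

The median-effect model is $f_a/(1-f_a) = (D/D_m)^m$: $D_m$ is the dose
of half-maximal effect (EC50), $m$ the sigmoidicity. Fits are ordinary
least squares on the linearised form; the fit correlation `r_fit` is
reported as a diagnostic. Fractions affected are $F_a = 1 -
X_\text{combo}/X_\text{ctl}$ for growth readouts (cell number,
day-0-normalised radiance); an apoptotic index is accepted directly as a
fraction in $[0, 1]$. Raw $F_a$ values at or beyond 0 or 1 carry no
usable dose information on the logit scale, so for fitting they are
clamped to $[0.005, 0.995]$ and flagged; raw values are always retained
for reporting.

The Combination Index at a combination's observed $F_a$ is
$\mathrm{CI} = \sum_i D_i / D_{x,i}$ with
$D_{x,i} = D_{m,i}(f_a/(1-f_a))^{1/m_i}$ — the mutually exclusive form,
which is the CompuSyn default and the convention under which the
package's in-vivo worked example (combination doses 3 and 0.001 dose
units against single-drug equivalents 16 and 0.24) gives CI 0.19; the
non-exclusive cross term $\prod_i D_i/D_{x,i}$ is available behind
`exclusive = FALSE`. CI is invariant to rescaling any drug's dose axis
together with its $D_m$. $\mathrm{DRI}_i = D_{x,i}/D_i$ exceeds 1
exactly when the combination reaches the effect with less drug. Reported
tables round CI to 2 decimals and DRI to 2 significant figures, with raw
values kept.

*Potent synergy* requires at least one point with $F_a > 0.7$ and
$\mathrm{CI} < 0.7$ in **every** tested orientation (which drug was
varied); both inequalities are strict, matching the printed thresholds.

**Three drugs.** A fixed-ratio pair is treated as a single entity whose
dose is the *sum* of the component doses (the entity's dose unit is a
genuine choice; the sum keeps DRI interpretable in the original units).
The entity gets its own median-effect fit from pair-alone rows, and the
triple's CI is $D_\text{pair}/D_{x,\text{pair}} +
D_3/D_{x,3}$. When the two component drugs share a slope $m$, a
Loewe-additive pair is itself exactly median-effect with
$D_{m,\text{pair}} = (\sum_i w_i/D_{m,i})^{-1}$ at composition weights
$w_i$, which is what makes the generator's ground truth analytic. The
pair ratio may not drift more than 1% across rows.

## 4. What the generators emulate — and what they do not

`sim_expression()` builds independent hub/partner blocks as bivariate
normals on the log scale with the target correlation, 21 tumours and 12
normals by default. Normality is the minimal assumption consistent with
Pearson-correlation analysis; real microarray data add heavier tails,
probe effects, batch structure, and correlation *between* hubs, none of
which is modelled. Passing recovery tests therefore demonstrate
correctness of the statistic and its calibration under the assumed
model, not robustness to array artefacts. Correlations must lie strictly
inside (−1, 1); $|r| = 1$ is rejected as a degenerate covariance.

`sim_screen()` draws negative-binomial (Poisson-gamma) counts — the
standard pooled-screen model — with one T0 and 6 tumour replicates per
cell line. Defaults: mean T0 count 1000 (a 10,000-shRNA library at the
$10^7$ normalisation target), dispersion 0.2 (typical pooled-screen
overdispersion), and a log-normal per-shRNA abundance spread
(sdlog = 1), since pooled libraries are never uniform; the spread
cancels in tumour/T0 ratios. Depletion scales the tumour mean of
affected genes' shRNAs by `depletion_factor`; injected outliers multiply
individual cells by `outlier_factor` and are recorded in the truth. Not
modelled: PCR jackpotting, barcode cross-contamination, variable
infection multiplicity, or correlated replicate effects.

`sim_dose_response()` produces exact median-effect single-drug curves
with multiplicative log-normal measurement noise (`cv_noise`), and
combination rows whose $F_a$ solves the Loewe relation
$\sum_i D_i/D_{x,i}(f_a) = 1/\alpha$, making the ground-truth CI exactly
$1/\alpha$ — which is what lets round-trip tests assert recovery within
1% (noiseless) and 10% (5% CV, 3 replicates). The solver brackets
$f_a$ in $(10^{-9}, 1-10^{-9})$ and fails loudly when all doses are far
outside the response range. Real dose-response data deviate from the
median-effect form at the extremes; the generator does not model that.

All generators take a mandatory seed, are pure functions of their
arguments, and restore the caller's RNG state.

## 5. Problem sizes and numerical conventions

The test and acceptance suites use: 100 hubs × 5 partners at 60 + 60
samples with 1000 permutations × 3 runs for hub-recovery; 200 hubs at
21 + 12 samples for null calibration (Kolmogorov–Smirnov statistic
< 0.1); a 10,000-shRNA null screen for the |Z| > 1.96 rejection
fraction (binomial 99% band around 0.05); 20-node random graphs for the
betweenness oracle; and 7-dose two-fold dilution series for
median-effect round trips. These sizes give stable statistics in
seconds on a single CPU.

Conventions worth restating: log base 10 everywhere in the screen
stage; pseudocount 0.1; permutation p-values add-one smoothed; outlier
ties broken by largest |Z| then input order (deterministic);
`ceiling()` rounding in subsampling; strict inequalities at the
−1.96, −0.69, 0.7 thresholds, matching their printed definitions.

## 6. Known limitations

* The hub scan assumes two conditions; multi-group designs are out of
  scope.
* Hub statistics treat hubs independently; overlapping partner sets are
  not modelled and no multiplicity correction is applied beyond the
  consensus-intersection design itself.
* The screen scorer requires exactly one T0 sample per cell line and
  ≥ 4 tumour replicates.
* Median-effect fits are unweighted least squares on the logit scale;
  points near the clamp bounds get full weight. With ≤ 2 usable doses
  the fit is refused rather than extrapolated.
* The pair-as-entity three-drug CI is exact only when the paired drugs
  share a median-effect slope; otherwise the entity fit is an
  approximation (flagged by a depressed `r_fit`).
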