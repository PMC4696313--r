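---
title: "Differential variability analysis with entrovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variability analysis with entrovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrovar)
```

## The problem

Classical case/control analysis of expression matrices asks whether a
feature's *magnitude* differs between conditions.  Many biologically
interesting features instead change their *variability*: a gene tightly
regulated in healthy tissue may become erratically expressed in tumours
while its mean barely moves.  `entrovar` quantifies per-feature
dispersion under each condition with two complementary statistics and
tests whether their difference is larger than chance.

Both condition matrices must have features as rows — with identical
labels in identical order — and samples as columns.  Every analysis is
per-row and the two conditions may have different sample counts.

## The metrics

For one feature and one condition, let $x_1, \dots, x_n > 0$ be the
sample values and $x = \sum_i x_i$.

**Normalized Shannon entropy.**
$$SE = \frac{-\sum_{i=1}^n \frac{x_i}{x}\log_2 \frac{x_i}{x}}{\log_2 n}
\in [0, 1].$$
The values are read as an unnormalized discrete distribution over the
samples.  A constant feature has uniform proportions and $SE = 1$; a
feature dominated by one sample has $SE$ near 0.  Note the resulting
convention: **lower** entropy means **more** dispersion.  $SE$ is
invariant to rescaling all values (proportions are unchanged) but not
to additive shifts, which is why the shift mechanism below must be used
deliberately.

**Coefficient of variation.**
$$CV = s / |\bar{x}|,$$
with $s$ the sample standard deviation ($n-1$ denominator).  Scale-free
and unbounded above; it loses meaning as the mean approaches zero,
another reason the package insists on positive data.

**Differences.**  For a feature measured under two conditions,
$DSE = |SE_1 - SE_2|$, $DCV = |CV_1 - CV_2|$ and $DE =
|\bar{x}_1 - \bar{x}_2|$ (the plain mean difference, included as a
familiar point of comparison).  $DSE \in [0,1]$; the other two are
nonnegative.

## P-values

**DCV — Fligner–Killeen on the log scale.**  A difference in CV is, to
first order, a difference in log-scale spread, so the package tests
homogeneity of variances between the two groups of log-transformed
values.  Among the classical homogeneity tests the Fligner–Killeen
statistic (median-centered absolute deviations, ranked and mapped to
one-sided normal scores, compared across groups against a
$\chi^2_{k-1}$ reference) has the best reputation for robustness to
non-normality, and that is what `fligner_killeen_pvalue()` computes via
`stats::fligner.test`.  The statistic depends on the log values only
through ranks of absolute deviations, so the base of the logarithm is
irrelevant; the natural log is used.  Ties receive mid-ranks.

**DE — Welch t-test.**  Two-sided, unequal variances.  This is a
convenience baseline, not a substitute for moderated differential
expression models.

**DSE — permutation test.**  No standard reference distribution fits
DSE: across a range of real datasets its observed distribution is far
from normal, $t$, $F$ and $\chi^2$ shapes, and entropy is not well
enough correlated with variance for a variance test to stand in.  The
package therefore resamples: pool the $n_1 + n_2$ values, repeatedly
permute the pool, split it into groups of sizes $n_1$ and $n_2$,
recompute DSE, and report the proportion of permuted DSE values at
least as large as the observed one ($DSE$ is nonnegative, so this is a
one-tailed test in the absolute entropy difference).

Three deliberate choices here:

* *Estimator.*  The default is the plain proportion `count / nperm`,
  which can be exactly 0.  `bias_correct = TRUE` switches to
  `(count + 1) / (nperm + 1)`, the finite-sample-valid variant; it is
  off by default so that the default output matches the plain
  proportion definition.
* *Canonical pooling.*  The pooled vector is sorted before the
  permutation stream is applied, and each permutation assigns the
  first $\min(n_1, n_2)$ positions to one group.  A uniformly random
  split into groups of sizes $\{n_1, n_2\}$ has the same distribution
  whichever group is named first, so the test is unchanged — but the
  seeded result becomes exactly invariant to swapping the two
  conditions and to sample order within a condition, which makes
  reproducibility checks trivial.
* *Per-row substreams.*  In `run_analysis()` a single user seed
  governs all rows: row $i$ uses the derived seed
  $(48271\,\mathrm{seed} + 16807\,i) \bmod (2^{31}-1)$, so results do
  not depend on the order in which rows are evaluated and any single
  row can be recomputed in isolation.

**Multiplicity.**  Raw p-values are adjusted over all *tested* rows
(rows reported as `NA` carry no test and do not inflate the count) with
Bonferroni, Holm, Hochberg, Benjamini–Hochberg (default) or
Benjamini–Yekutieli, via `stats::p.adjust`.  Hommel is deliberately
omitted.  Adjustment happens before any top-`n` filtering: the
hypothesis count is the number of rows analyzed, not displayed.

## Positivity and the shift argument

Entropy and the log-transform require strictly positive data, and CV
degrades near zero means, so `run_analysis()` rejects matrices with
non-positive entries.  Real preprocessed matrices often contain zeros
or small negatives; the `shift` argument adds a per-matrix constant
before anything else happens.  `"auto"` resolves to 0 when the matrix
minimum $m$ is already positive, and otherwise to $|m| + d$ with $d$
the smallest strictly positive entry (1 if none exists) — a data-scaled
margin that guarantees strict positivity.  Because entropy is not
shift-invariant, results depend on the shift; the resolved values are
attached to the result (`attr(res, "shift")`) and logged by the CLI so
they can be reported.

## Missing values

Non-finite entries are dropped per row and per condition before any
computation, and the entropy normalization uses the count of values
actually retained.  A row left with fewer than two finite values in
either condition cannot support any of the statistics; it is reported
as `NA`, sorted last, excluded from the multiplicity count, and
flagged with a warning.

## Output types and ordering

`otype` selects the column schema: `"v"` (the two per-condition
statistics), `"bv"` (plus their absolute difference), and `"p"`,
`"pa"`, `"bp"`, `"bpa"` (plus raw and adjusted p-values).  `"p"`/`"pa"`
sort ascending by raw/adjusted p; all other types sort descending by
the difference.  Ties are broken by row label in C-locale order, so a
fixed seed yields byte-identical output files.  `ntop` truncates after
sorting.

## The synthetic generator

`generate_pair()` draws a feature-by-sample pair from a log-normal
model: every case entry is $\mathrm{LN}(\mu, \sigma)$; a fraction of
rows is differentially variable (control log-sd multiplied by
`variance_ratio`), a disjoint fraction differentially expressed
(control log-mean shifted by `mean_shift`), the rest null.  Defaults —
1000 rows, 20 samples per condition, $\mu = 2$, $\sigma = 0.5$, 10%
DV rows with ratio 3, 10% DE rows with shift 1 — mirror a modest
two-arm expression study with strong but not caricatural effects.
Log-normality matches both the positivity requirement and the log
transform used by the DCV test.

The generator deliberately does **not** emulate probe effects, batch
structure, sample-level size factors, count noise, or correlation
between features.  Passing calibration and power checks on this model
demonstrates that the statistics and tests behave as designed on
independent, positive, log-scale-Gaussian data; it does not certify
behavior under batch confounding or heavy-tailed count noise.

## Validation design and problem sizes

The test suite recomputes every metric against independently coded
oracles (an explicit-loop entropy in natural logs, a from-definition
Fligner–Killeen statistic, hand-coded step-up/step-down adjustments)
and checks the sampled permutation p against exhaustive enumeration of
all $\binom{6}{3}$ splits at $n_1 = n_2 = 3$.  Calibration uses 2000
null rows for the permutation test (1000 permutations each) and 10,000
replicates for the Fligner–Killeen and Welch tests at 100 samples per
group; the power check uses 1000 rows with 10% DV rows at ratio 3.

The 100-per-group choice for the variance-test calibration is
deliberate: the Fligner–Killeen reference is asymptotic, and with two
groups of 20 it is measurably conservative (rejection near 0.038 at
$\alpha = 0.05$ over 10,000 null replicates — a property of the
$\chi^2$ approximation itself, reproduced exactly by the
from-definition oracle).  At 100 per group the approximation is
adequate and the nominal level is held.  Users with small groups
should expect DCV p-values to be mildly conservative, never
anti-conservative, at typical microarray sample sizes.

## Numerical choices

* A constant vector is detected explicitly and given entropy exactly 1,
  rather than trusting that all floating-point proportions round
  identically; all other entropies are clamped into $[0, 1]$ against
  last-ulp overshoot.
* The Fligner–Killeen statistic is undefined when every pooled absolute
  deviation is equal (e.g. both groups constant); the package returns
  $p = 1$ with a warning, since such data carry no evidence of
  heterogeneity.
* The Welch test is likewise undefined when both groups are constant;
  equal constants give $p = 1$, unequal constants $p = 0$, each with a
  warning.
* `ntop` larger than the row count keeps all rows; p-value ties and
  difference ties order by label so output never depends on the
  original row order beyond the labels themselves.

## Limitations

Two conditions only, no paired designs, no normalization or batch
correction — input matrices are assumed preprocessed.  DE via the Welch
test is intentionally simple.  Permutation p-values have resolution
`1/nperm` and (by default) can be exactly zero; with the default 1000
permutations, adjusted DSE p-values below `0.001 * m / rank` are not
resolvable.  Results of entropy-based metrics depend on any additive
shift applied, so shifted and unshifted runs are not comparable.
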