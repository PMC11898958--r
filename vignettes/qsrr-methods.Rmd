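---
title: "QSRR modelling of biomimetic chromatography data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSRR modelling of biomimetic chromatography data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrrop)
```

## The problem

Biomimetic chromatography characterizes small molecules by their retention
on stationary phases coated with biomolecules. Three systems matter here:
a C18 reversed phase (lipophilicity, reported as the chromatographic
hydrophobicity index CHI\_C18, a scale of roughly 0–110), an immobilized
artificial membrane (phospholipid affinity, CHI\_IAM), and a human serum
albumin column (plasma-protein binding, reported both as the log
retention-derived affinity LogK\_HSA and as a percent bound, %HSA). For
organophosphate pesticides these endpoints are proxies for bioaccumulation
and membrane interaction, which is why a structure–retention model of them
is informative beyond chromatography itself.

A quantitative structure–retention relationship (QSRR) links each measured
endpoint to calculated molecular descriptors by multiple linear regression
(MLR), with the descriptor subset chosen by a genetic algorithm (GA). The
package implements the full pipeline — index transforms, descriptor
pruning, GA-MLR selection, internal/external validation, applicability
domain, exploratory clustering — against the packaged 18-compound
organophosphate endpoint table (`load_retention_table("builtin:op18")`)
and against synthetic data.

## Chromatographic index transforms

Fast-gradient indices are defined by calibration: reference standards with
known index values are run, a least-squares line maps retention time to
the index scale (`fit_calibration()`, `index_from_retention()`). Reference
index values for calibration standards are user-supplied data (a CSV with
columns `name,t_r_min,ref_value`); the package deliberately does not ship
literature calibration values.

The two HSA columns of the endpoint table are linked by a logistic
transform with a 101 denominator:

$$\log k_{HSA} = \log_{10}\frac{\%HSA}{101 - \%HSA}, \qquad
  \%HSA = \frac{101 \cdot 10^{\log k}}{1 + 10^{\log k}}.$$

This functional form is not printed alongside published endpoint tables;
it was established by consistency: it is the only affine-log candidate
that reproduces, after half-up rounding to two decimals, every LogK\_HSA
value in the packaged 18-row table from its %HSA partner (the test suite
checks all 18 rows). It should be treated as reverse-engineered
convention, exact for this scale but worth re-verifying on data from other
laboratories. A consequence of the 101 denominator is that %HSA values
live in (0, 101), with 50.5% at log k = 0.

Display rounding is half-up at two decimals, matching the precision of
printed index tables (base R's `round()` is half-even, which would differ
on exact .005 boundaries).

## Descriptor pruning and auto-scaling

Descriptor software emits thousands of columns, many uninformative or
redundant. `prune_descriptors()` removes, in a fixed order: constant
columns; near-constant columns; then, from every pair with |Pearson r| at
or above 0.95, one column. Choices the rule text leaves open, decided
here:

* **Near-constant** means the modal value occupies more than 95% of
  entries, or the sample standard deviation is below $10^{-8}$ times the
  value range — the convention of common descriptor software, and
  configurable.
* The correlation threshold is applied to |r|, so strong *negative*
  correlation also triggers removal; redundancy is about shared
  information, not sign.
* The **tie-break** drops the later column in input order (deterministic
  and order-stable); a variance-preferring alternative is available. With
  18 compounds, correlation estimates are noisy, so no data-driven
  tie-break can be trusted much anyway.
* Pruning is applied once per descriptor matrix, not per endpoint.

`autoscale()` standardizes columns to zero mean and unit sample standard
deviation; it is enforced before clustering so that indices on different
numeric scales (CHI ~100, log k ~1) contribute equally.

## GA-MLR descriptor selection

Candidate models are binary inclusion masks over descriptors ("1" include,
"0" exclude), constrained to a fixed subset size — default 2 descriptors,
the size of all three packaged reference equations, which is also about
the most an 18-compound dataset can support. GA settings default to a
population of 10, 500 generations, and a mutation rate of 0.20 read as a
per-gene flip probability (a "rate of 20" only makes sense as 20%;
probabilities above 1 do not). Selection is a fitness-ranked tournament of
size 2, crossover is uniform, elitism keeps the single best chromosome, so
the best-so-far fitness trace is non-decreasing by construction.

The fitness function is leave-one-out $Q^2$ on the training set. With
n = 12 training compounds, training $R^2$ alone rewards overfitting;
LOO-based fitness is the simplest robustness-oriented choice and is the
default (`fitness = "r2"` is available). Internally the LOO residuals for
fitness come from the exact PRESS identity $e_{(i)} = e_i/(1 - h_{ii})$,
which makes a fitness evaluation one QR decomposition; evaluated subsets
are cached, so on small pools the GA effectively enumerates. The public
`loo_cross_validate()` does genuine refits per fold and is tested against
the PRESS-driven path and an independent brute-force oracle.

All randomness flows through one seed recorded in the returned model's
metadata; two runs with the same seed are bit-identical.
`exhaustive_select()` scores every subset and is the benchmark: on
18-compound, 20-descriptor problems with a planted two-descriptor signal
at 10% relative noise, the GA matches exhaustive search in at least 9 of
10 seeds (tested).

## Validation metrics

`validate_qsrr()` reports the standard OECD-style suite: training $R^2$
and RMSE, leave-one-out $Q^2_{LOO}$ and RMSE, external $R^2$, external
RMSE, and Lin's concordance correlation coefficient

$$CCC = \frac{2\sum(y_o - \bar y_o)(y_p - \bar y_p)}
 {\sum(y_o - \bar y_o)^2 + \sum(y_p - \bar y_p)^2 + n(\bar y_o - \bar y_p)^2},$$

which penalizes both scatter and systematic shift and is bounded by the
absolute Pearson correlation. Published formula listings for this metric
sometimes carry a stray leading "1 −" and a mis-set mean term that would
push values outside [−1, 1]; this package implements the standard Lin
form above.

Two conventions are configurable because the field is not unanimous:

* The external $R^2$ denominator is centred on the **external-set mean**
  by default (the form most tables print); `ext_center = "training"`
  gives the training-mean variant (the $Q^2_{F2}$-style choice).
* The critical leverage is $h^* = 3p/(n-1)$ with $p$ = number of
  descriptors, intercept **not** counted (so $h^* = 6/11$ for a
  two-descriptor model trained on 12 compounds); `count_intercept = TRUE`
  switches to $3(p{+}1)/n$. Leverage itself always uses the
  intercept-augmented design.

The train/validation split is "systematic" by default: compounds sorted
by the endpoint, every third rank starting from rank 2 assigned to
validation (12 + 6 for 18 compounds). This spreads validation compounds
across the response range while keeping the global minimum and maximum in
training, so external prediction never extrapolates. A seeded random
split is available.

The applicability domain (`williams_assessment()`) flags a compound
in-domain when leverage ≤ h\* and |standardized residual| ≤ 3, boundaries
inclusive. The standardized residual divides by the RMSE of the
compound's own set — common Williams-plot practice; a studentized variant
was considered and rejected to keep training and validation residuals on
directly comparable scales.

Acceptability (`assess_acceptability()`) applies the two published
thresholds for models of this class: training $R^2 > 0.6$ and external
$R^2 > 0.5$.

## Exploratory analysis

`hierarchical_cluster()` clusters compounds on auto-scaled endpoints with
Ward linkage on Euclidean distances (`hclust` method `ward.D2`), the most
common choice for heat-map dendrograms; single/complete/average linkage
are available. The default column set is CHI\_C18, CHI\_IAM, LogK\_HSA —
the three independent measurements; %HSA is a deterministic transform of
LogK\_HSA and is excluded to avoid double-weighting the protein-binding
axis. `cut_tree()` cuts at a requested k, or at the largest gap between
successive merge heights. On the packaged table the gap rule yields two
groups and k = 3 reproduces a low/medium/high bioaccumulation ordering
(with Dichlorvos and Naled, the classic low-lipophilicity members, in the
low group); which of 2 or 3 is "right" genuinely depends on unstated
linkage and column choices, so group count is treated as a soft,
qualitative observation, not a tested constant. Group names low/medium/
high are assigned by ranking cluster means of CHI\_C18.

## Synthetic data

The generators exist so that every downstream stage is testable without
commercial descriptor software. They emulate exactly the statistical
structure the GA-MLR analysis assumes, and nothing more:

* `generate_descriptors()`: standard-normal base columns; optional
  correlated blocks built from a shared latent factor
  ($X = \sqrt\rho F + \sqrt{1-\rho}\,E$, the simplest controllable
  correlation structure); optional near-duplicate columns (base +
  Normal(0, 0.01)) guaranteed to trip the 0.95 pruning threshold.
* `generate_response()`: a sparse linear signal on a random support
  (planted duplicates excluded), coefficient magnitudes within ±20% of a
  chosen scale with random signs, Gaussian noise specified absolutely or
  relative to the signal standard deviation.
* `generate_endpoint_table()`: Gaussian-copula endpoint tables with
  CHI\_C18 in [20, 110], CHI\_IAM in [15, 45], the two correlated at
  about 0.9 — matching the empirical correlation of the packaged table —
  log k in [−0.5, 1.3] correlated with CHI\_IAM at about 0.7, and %HSA
  computed exactly from log k. Copula mapping attenuates target
  correlations slightly (a few hundredths at these levels), which the
  sampling-check tests allow for.

What passing on synthetic data does **not** show: real descriptor
matrices have heavy-tailed, discrete and block-structured columns far
from Gaussian; real responses are not exactly linear and their noise is
not homoscedastic. Synthetic recovery results are a correctness check of
the machinery, not evidence about chromatographic practice.

## Problem sizes and numerical choices

Simulation-based tests run at deliberately small scale — 18 compounds and
tens of descriptors, mirroring the motivating dataset; the GA benchmark
uses 10 seeds over a 190-pair search space, and the 3-sigma residual
check uses one simulated design of n = 10⁴. Degenerate inputs fail
loudly: constant responses, rank-deficient designs, under-determined
fits, all-identical calibration times, and empty pruning results are
errors, not warnings. OLS solves use QR, not normal equations (the
normal-equations route appears only as an independent test oracle).

## Limitations

The three packaged reference equations carry printed coefficients only;
the underlying descriptor values are from commercial software and are not
redistributable, so those equations serve as prediction fixtures and the
published fit statistics are not recomputable here. With n = 18, every
statistic downstream of the split has high variance; the package
reproduces procedures faithfully, but inference at this scale warrants
the caution the original analysis itself advises.
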