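# qsrrop

QSRR (quantitative structure–retention relationship) modelling of
organophosphate pesticides characterized by biomimetic chromatography.

Biomimetic HPLC retains compounds on stationary phases coated with
biomolecules, so retention mimics biological partitioning: a C18 reversed
phase measures lipophilicity (the chromatographic hydrophobicity index
CHI_C18), an immobilized artificial membrane measures phospholipid
affinity (CHI_IAM), and a human serum albumin column measures
plasma-protein binding (LogK_HSA / %HSA). For organophosphate
pesticides — neurotoxic agrochemicals whose bioaccumulation tracks these
very properties — QSRR models explain which structural features drive
each kind of binding.

The package is aimed at chromatographers and cheminformaticians who have
(a) measured endpoint tables and (b) descriptor matrices from any
descriptor software, and want a reproducible, validated modelling
pipeline:

* **Index transforms** — gradient calibration against reference standards
  (`fit_calibration()`, `index_from_retention()`) and the logistic
  plasma-protein-binding transform
  `logk = log10(pct / (101 − pct))` with its exact inverse
  (`logk_from_percent_hsa()`, `percent_hsa_from_logk()`).
* **Preprocessing** — removal of constant, near-constant and
  |r| ≥ 0.95-correlated descriptors (`prune_descriptors()`);
  auto-scaling (`autoscale()`).
* **GA-MLR** — genetic-algorithm subset selection (population 10,
  per-gene mutation 0.20, 500 generations, subsets of 2 by default) over
  ordinary least-squares models, with leave-one-out Q² as fitness
  (`ga_select()`, `fit_mlr()`, `exhaustive_select()` as benchmark).
* **Validation** — the seven-metric suite R², RMSE_TR, Q²_LOO, RMSE_LOO,
  R²_EXT, RMSE_P and Lin's concordance CCC_EXT (`validate_qsrr()`), the
  systematic 12/6 train/validation split, acceptability thresholds
  (R² > 0.6, R²_EXT > 0.5), and applicability-domain assessment with
  critical leverage h* = 3p/(n−1) and Williams-plot export.
* **Exploration** — endpoint correlation matrices and Ward clustering of
  auto-scaled endpoints with heat-map export.
* **Synthetic data** — descriptor matrices with correlated blocks and
  planted near-duplicates, sparse linear responses with known truth, and
  endpoint tables with realistic ranges and correlations, so the whole
  pipeline is testable end to end.

The published 18-compound organophosphate endpoint table ships as a
fixture (`load_retention_table("builtin:op18")`), as do the three
published two-descriptor model equations (`reference_qsrr_models()`).

## Worked example

End-to-end run on synthetic data with a planted two-descriptor signal
(10% relative noise), exactly as the GA-MLR analysis assumes:

```r
library(qsrrop)

X  <- generate_descriptors(18, 40, block_correlation = 0.3,
                           n_redundant = 5, seed = 11)
ds <- generate_response(X, support_size = 2, effect_scale = 3,
                        noise_sd = 0.1, relative_noise = TRUE, seed = 12)

pruned <- prune_descriptors(X)
print(pruned$report)
#> Descriptor pruning: 40 -> 35 columns
#>   constant: 0, near-constant: 0, correlated (|r| >= 0.95): 5

sp <- split_train_validation(data.frame(y = ds$y), "y")   # 12 + 6
g  <- ga_select(pruned$matrix[sp$train, ], ds$y[sp$train],
                ga_config(seed = 13), endpoint = "y")
cat("selected:", g$selected, "| planted:", ds$true_support, "\n")
#> selected: D002 D026 | planted: D002 D026

rep <- validate_qsrr(g$model,
                     pruned$matrix[sp$train, ],      ds$y[sp$train],
                     pruned$matrix[sp$validation, ], ds$y[sp$validation])
print(rep)
#> QSRR validation report: endpoint y
#> training n = 12, external n = 6
#> descriptors: D002, D026
#>
#>   r2_tr       0.9967
#>   rmse_tr     0.2644
#>   q2_loo      0.9929
#>   rmse_loo    0.3890
#>   r2_ext      0.9849
#>   rmse_p      0.5227
#>   ccc_ext     0.9932
#>
#> Acceptability (R2 > 0.6 and R2_EXT > 0.5): PASS
```

The pruning stage removed exactly the five planted near-duplicate
columns; the GA recovered the planted descriptor pair; the report shows
tight internal (Q²_LOO) and external (R²_EXT, CCC_EXT) agreement, as it
should at this noise level. On the packaged measured table:

```r
tab <- load_retention_table("builtin:op18")
round(correlation_matrix(tab), 3)
#>          chi_c18 chi_iam logk_hsa
#> chi_c18    1.000   0.898    0.515
#> chi_iam    0.898   1.000    0.649
#> logk_hsa   0.515   0.649    1.000
```

Lipophilicity and phospholipid affinity are tightly coupled; albumin
binding correlates only weakly — the signature of specific binding-pocket
interactions on the HSA phase.

A thin command-line front end over these functions is installed at
`system.file("cli", "qsrrop.R", package = "qsrrop")` with subcommands
`indices`, `prune`, `select`, `validate`, `explore` and `simulate`.

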