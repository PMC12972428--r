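# onsetrisk

Multi-task Cox modelling of **disease onset acceleration**: how much
earlier in life age-associated conditions arrive for an individual,
predicted jointly for many conditions from tabular traits.

The package is aimed at biostatisticians and epidemiologists working
with biobank-style cohorts (traits measured once, diagnoses accruing
over decades, administrative censoring). Its core is a neural Cox model
with one encoder per trait group (demographics, basic body, summary and
spatial body composition, blood biomarkers) and a shared head emitting
one log-risk per condition, trained **from birth as temporal baseline**
by minimizing

```
g^d(θ) = −(1/N_{E^d=1}) Σ_{i:E^d_i=1} [ h^d_θ(x_i) − log Σ_{j∈R^d(T^d_i)} exp(h^d_θ(x_j)) ]
l(θ)   = (1/|D|) Σ_d g^d(θ) + λ‖θ‖²
```

with risk set `R^d(t) = {i : T^d_i ≥ t}` (Breslow ties). Around the
model sits the full analysis chain:

* seeded center-based train-val / internal-test / external-test splits
  with 5-fold cross-validated hyperparameter selection;
* Harrell's C-index, exact and batched (counts summed across seeded
  batches; exact when `batch_size ≥ n`);
* sex- and condition-specific risk quartiles, Kaplan-Meier curves and
  log-rank stratification tests;
* inter-condition quartile correlations with Bonferroni masking, UPGMA
  clustering on cosine distance, and graph export;
* prognostic adjusted Cox models per condition pair (assessment
  baseline, 120-month horizon, pre-existing diagnoses excluded) with
  Schoenfeld proportional-hazards diagnostics;
* gradient saliency maps per sex and condition;
* a Weibull proportional-hazards cohort generator with known
  ground-truth log-risk, so every stage is testable end to end.

## Worked example

Simulate a cohort with three planted disease clusters, train the model,
and run the downstream analyses:

```r
library(onsetrisk)

cfg <- generator_config(n_individuals = 4000, n_conditions = 6,
                        n_latent = 3, cluster_strength = 1, seed = 7)
sim <- generate_cohort(cfg)
sim$cohort
#> <cohort> 4000 individuals, 15 traits (bb:4 bbc:3 blood:6 demog:2)
sim$outcomes
#> <outcome_table> 4000 individuals x 6 conditions, baseline=birth, 15741 events

split    <- make_splits(sim$cohort, "ext", seed = 7)
stats    <- fit_preprocess(sim$cohort, split)        # train-val statistics only
features <- apply_preprocess(sim$cohort, stats)

arch  <- arch_config(names(features$blocks), n_conditions = 6, k = 16)
model <- build_model(arch, as.list(features$widths),
                     conditions = sim$outcomes$conditions, seed = 7)
tr <- which(split$role == "trainval" & split$fold != 1)
va <- which(split$role == "trainval" & split$fold == 1)
model <- train_fold(model, features, sim$outcomes, tr, va,
                    train_config(epochs = 25, lr = 2e-3,
                                 batch_size = 512, seed = 7))

scores <- predict_log_risk(model, features)
itest  <- which(split$role == "internal_test")
ci <- sapply(1:6, function(d)
  batched_cindex(scores[itest, d], sim$outcomes$time[itest, d],
                 sim$outcomes$event[itest, d], seed = 7)$c_index)
round(setNames(ci, sim$outcomes$conditions), 3)
#> cond_1 cond_2 cond_3 cond_4 cond_5 cond_6
#>  0.651  0.663  0.672  0.670  0.674  0.671
```

An internal-test C-index near 0.67 says that for two random comparable
individuals, the model puts the higher score on the one diagnosed
earlier about two times out of three — close to the ceiling the
generator's own true log-risk attains on this cohort. Quartiles of the
score stratify onset sharply:

```r
bins  <- fit_quartile_bins(scores, sim$cohort$sex, split)
quart <- assign_quartiles(scores, sim$cohort$sex, bins)
lr <- logrank_test(sim$outcomes$time[, 1], sim$outcomes$event[, 1], quart[, 1])
#> log-rank chi-square 798.4 (df 3), p = 9.48e-173

res <- correlation_cluster(quart, ci, sim$cohort$statin_user)
res
#> <correlation_cluster_result> 6 conditions, family 36, per-test p <= 0.00139,
#>   10 entries zeroed, 5 edges
cutree(res$tree, k = 3)
#> cond_1 cond_2 cond_3 cond_4 cond_5 cond_6
#>      1      1      2      1      3      2
```

The cut recovers most of the planted cluster structure (conditions 1
and 4 share a latent factor, as do 3 and 6). `run_all_pairs()` then
fits the prognostic adjusted Cox matrix, and `gradient_saliency()` +
`normalize_saliency()` rank input traits per condition.
`run_pipeline(run_config(...))` chains all stages and writes delimited
artifacts plus a JSON manifest; a thin command-line front end lives at
`inst/cli/onsetrisk.R`.

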