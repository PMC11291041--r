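# pchaz

Time-to-event prediction for tabular clinical cohorts, built around a
piecewise-constant-hazard (PC-Hazard) neural survival model and the
supporting machinery a realistic clinical pipeline needs: random-forest
imputation of missing covariates, a two-stage *focused-training* ensemble,
rank-combined nested model selection, tie-adjusted evaluation metrics, and
quartile-grid counterfactual treatment choice. It is aimed at
biostatisticians and clinical researchers modelling outcomes such as ALS
survival or all-cause mortality under anticoagulation, where event-time
distributions are heavily right-skewed, covariates are incomplete, and Cox
regression's fixed proportional-hazards ratio is a poor fit.

## The model

Follow-up is partitioned by a grid `0 = τ₀ < τ₁ < … < τ_m` (cuts at
duration quantiles). A feed-forward network maps a patient's covariates
`x` to non-negative interval hazards `λ₁(x), …, λ_m(x)` (softplus outputs)
and is trained on the exact piecewise-exponential negative log-likelihood

    ℓ(t, d) = −d·log λ_k + Σ_{j<k} λ_j Δ_j + ρ λ_k Δ_k ,

where `k` is the interval containing `t`, `Δ_j = τ_j − τ_{j−1}` and
`ρ = (t − τ_{k−1})/Δ_k`. Survival is `S(t|x) = exp(−H(t|x))`, log-linear
between cuts; the predicted time is the exact median crossing `S = 0.5`.
A Royston–Parmar spline model (restricted cubic spline on the log
cumulative hazard; Weibull PH at zero internal knots) serves as the
parametric baseline in model selection.

Around the model:

* **Imputation** (`missforest_impute`) — iterative per-column random
  forests, least-missing column first, stopped when the imputed matrix
  first degrades, averaged over 10 independently seeded rounds; optional
  use of `log(duration)` + event as predictors; leakage-safe single-patient
  imputation for validation rows (`impute_validation_patient`);
  mask-and-score accuracy evaluation (`mask_and_score`).
* **Focused-training ensemble** (`ensemble_predict`) — predict a median
  `t₁`, fine-tune a copy of the model for 200 extra epochs on training
  patients with *measured* survival within `t₁ ± 70%`, then re-predict.
* **Selection** (`nested_tune`, `rank_select`) — outer 80/20 split, 10
  random 80/20 inner folds with median-aggregated per-patient curves,
  configurations ranked by concordance + median absolute difference (MAD) +
  normalised MAD and combined by lowest rank sum, searched in stages.
* **Bagging** (`train_bag`, `bag_predict`) — 10 models on random 80%
  subsamples; prediction is the pointwise-median curve.
* **Counterfactuals** (`quartile_grid`, `best_treatment`) — synthetic
  patients from all combinations of per-covariate quartile medians; the
  recommended treatment level maximises predicted median survival.
* **Synthetic cohorts** (`generate_cohort`, `als_like_preset`,
  `af_like_preset`) — AFT-form generators with right-skewed survival,
  censoring, MCAR/MAR/outcome-dependent missingness and
  treatment-by-covariate interactions, plus the latent truth for oracle
  metrics.

## Worked example

```r
library(pchaz)

ds  <- generate_cohort(als_like_preset(1000, seed = 7))   # skewed, censored, incomplete
ds
#> <survival_dataset> 1000 patients, 7 covariates, 799 events (80%), 823 missing cells

imp <- missforest_impute(ds, imputation_config(rounds = 5, trees = 50, seed = 1))
train <- imp; test <- generate_cohort(als_like_preset(300, seed = 8))
test_imp <- missforest_impute(test, imputation_config(rounds = 5, trees = 50, seed = 2))

enc <- encode(train)
fit <- fit_pchazard(enc, train$durations, train$events,
                    hazardnet_config(hidden = c(32, 32), epochs = 100, m = 10, seed = 1))

enc_te <- encode(test_imp, fit_stats = enc)               # frozen training stats
curves <- lapply(seq_len(test$n), function(i) predict_curve(fit, enc_te$matrix[i, ]))
meds   <- sapply(curves, function(cv) as.numeric(median_survival(cv)))

concordance(curves, test$durations, test$events)
#> [1] 0.6673
mad_metrics(meds, test$durations, test$events)
#> <metric_report> c_index=NA mad=15.078 nmad=0.602 (n=230, 70 censored excluded)

p <- ensemble_predict(fit, train, enc_te$matrix[1, ],
                      ensemble_config(window = 0.7, extra_epochs = 200, min_cohort = 50))
p
#> <ensemble_prediction> t1=26.39 t2=22.81 (focused n=442)
```

Concordance 0.67 means the model orders a random comparable patient pair
correctly 67% of the time (0.5 is chance); MAD 15.1 months is the median
absolute gap between predicted and observed survival over the 230 patients
whose death was observed; the ensemble's stage-2 fine-tuning on the 442
training patients who actually died within ±70% of the first prediction
nudges the final estimate.

The same pipeline is scriptable end to end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","pchaz.R",package="pchaz"))') \
    simulate --preset als --n 1000 --seed 1 --out cohort.csv --schema-out schema.yaml
```

(subcommands: `simulate`, `impute`, `tune`, `train`, `predict`,
`evaluate`, `counterfactual`, `run`), or in R via `run_pipeline()` with a
single YAML/list configuration, which also writes a structured event log
used by the leakage audit.

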