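---
title: "Methods: piecewise-constant-hazard prediction with focused training and forest imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piecewise-constant-hazard prediction with focused training and forest imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The survival model

`pchaz` treats time-to-event prediction as estimation of a patient-specific
hazard that is constant within intervals of a discretization grid. The grid
`0 = τ₀ < τ₁ < … < τ_m` is placed at the `j/m` quantiles of the observed
durations (`make_grid`), so each interval holds a comparable share of the
observed times; the paper-style alternative of equal-width intervals wastes
resolution in the long right tail of skewed event distributions. A
feed-forward network (ReLU hidden layers, optional dropout and batch
normalisation, softplus outputs so hazards are non-negative by
construction rather than by clamping) maps an encoded covariate row to the
`m` interval hazards. Training minimises the *exact* piecewise-exponential
negative log-likelihood

$$\ell(t,d\mid\lambda) = -d\,\log \lambda_k \;+\; \sum_{j<k}\lambda_j\Delta_j
\;+\; \rho\,\lambda_k\Delta_k,$$

with `k` the interval containing `t`, `Δ_j` the interval widths and `ρ` the
fractional position of `t` in its interval. Because the likelihood is exact
(not the discretised cross-entropy approximation), the fitted model has a
closed-form survival curve `S(t|x) = exp(−H(t|x))` that is log-linear
between cuts, and the predicted median is the exact solution of
`S(t) = 1/2` within the crossing interval. If the curve never reaches 1/2
on the grid, the last interval's hazard is extrapolated and the prediction
is *flagged*, never capped: downstream uses (e.g. using predictions as a
phenotype in association analyses) need honest values.

Optimisation uses mini-batch Adam (default batch 256, learning rate 0.01).
These defaults are placeholders in the sense that the tuned architectures
of the motivating analyses are not public; they are exposed in
`hazardnet_config` and searched by `nested_tune`. All training is
deterministic given the configuration seed; the package derives every
internal random stream from one master seed through a labelled hash
(`derive_seed`), so adding a stream never perturbs existing ones.

The parametric baseline is a Royston–Parmar flexible parametric model: a
restricted cubic spline `s(log t)` on the log cumulative hazard with
proportional-hazards covariate effects, internal knots at log-event-time
quantiles. With zero internal knots `s` is linear and the model is exactly
Weibull PH — the test suite exploits this equivalence by checking
log-likelihood agreement with a direct Weibull maximum-likelihood fit to
`1e-4`. Monotonicity of the fitted `s` is checked on the data range after
fitting; violations flag the model with a warning rather than silently
reshaping it.

"Number of knots", as a tuning axis, means the number of hazard intervals
`m` for the deep model and the number of internal spline knots for the
parametric one — the only knot-like quantity each family has.

## Encoding conventions

Continuous covariates are standardised with the *population* (1/n)
standard deviation — an arbitrary but documented convention the worked
examples depend on. Categorical covariates are one-hot encoded over **all**
levels with no reference drop: downstream models carry their own bias
terms, and keeping every level avoids silent reference-level dependence
across refits. Validation data are always transformed with the frozen
training statistics (`encode(..., fit_stats = )`); the pipeline logs this
as a structured event so the leakage audit can assert it.

## Imputation

`missforest_impute` is an iterative random-forest imputer. One round:
initialise missing cells with the column mean/mode, then sweep the
covariates in ascending order of missing count, fitting a forest per
column on the rows where it is observed and predicting its missing cells;
the sweep repeats until the change in the imputed matrix *first increases*
(the classical stopping rule of this family of imputers, which the
motivating work cites without restating) or a sweep cap is reached. Final
values average 10 independently seeded rounds — mean for continuous cells;
for categorical cells, where a mean is undefined, a majority vote with
ties broken to the lowest level index.

The forests are a compact CART implementation (compiled; bootstrap
resampling, random feature subsets, exact variance/Gini split search).
One deliberate deviation from forest folklore: the `mtry` floors are
raised to 3 (regression) / 2 (classification). After one-hot expansion a
clinical table often has under ten predictors, and `mtry = 1` starves the
single informative predictor — with it, a covariate duplicated up to noise
cannot be recovered to within one standard deviation, which is the
behaviour a sensible imputer must have.

Two outcome-related choices:

* In `include_outcome` mode the outcome enters the predictor set as
  `log(duration)` plus the event indicator; the log matches the skewed
  scale on which survival is modelled.
* `impute_validation_patient` runs the imputation on the training cohort
  plus *exactly one* validation patient and returns only that patient's
  row, so validation patients never see each other. The patient's own
  outcome never feeds the imputation, even in `include_outcome` mode —
  at prediction time it is unknown. Implementation: the patient's
  outcome-predictor entries are set to the training means while training
  rows contribute their true outcomes. (The alternative — erroring
  whenever a validation patient lacks an outcome in `include_outcome`
  mode — would contradict the point of prediction-time imputation.)

`mask_and_score` measures imputation accuracy the way the motivating
analyses do: per round, a fixed number of *observed* cells per covariate
are masked uniformly at random, re-imputed, and pooled across rounds;
continuous covariates are scored by Pearson correlation with a two-sided
zero-correlation p-value, categorical ones by accuracy.

## Focused-training ensemble

The ensemble rests on the hypothesis that training patients with survival
similar to a test patient's are the most informative for it. Stage 1
predicts a median `t₁`. Stage 2 copies the model (the stage-1 object is
never mutated — it is reused across test patients) and continues training
for 200 extra epochs on the *focused cohort*: training patients with an
observed event and duration in `[t₁(1−f), t₁(1+f)]`, `f = 0.7` by default.
The multiplicative window is deliberately dynamic: its absolute width grows
with `t₁`, compensating for the thin right tail of skewed event
distributions so focused cohorts have roughly comparable size everywhere.
Censored rows are excluded by default ("measured survival"); an
`include_censored` switch admits censored rows whose censoring time falls
in the window, for users who read the cohort definition more liberally.
If the focused cohort is smaller than `min_cohort` (default 50), stage 2
is skipped and the stage-1 prediction stands, flagged as a fallback.

Fidelity-versus-cost: the per-patient focused cohort implies per-patient
fine-tuning, which is the default semantics. For batch prediction an
optional cache shares one fine-tuned model among patients whose `t₁` agree
to `cache_digits` significant figures (default 2). The grid and encoding
are frozen in stage 2; durations outside the frozen grid are clamped in
the likelihood and extrapolated in curve evaluation. Stage 2 restarts a
fresh optimiser state (the original optimiser state of stage 1 is not
public information; a fresh Adam state with the stage-1 — or a
configured — learning rate is the reproducible choice). When combined with
the 10-model bag in the pipeline, stage 2 is applied per bag member and the
final prediction is the median of the member stage-2 medians, composing
the two aggregation rules in the only order that keeps each member's grid
frozen.

## Evaluation and model choice

`concordance` is the time-dependent, tie-adjusted form: over pairs
`(i, j)` with `d_i = 1` and `T_i < T_j` — plus pairs tied on time where
`i` died and `j` was censored — a pair counts as concordant when
`S(T_i|x_i) < S(T_i|x_j)`, and tied predictions count 0.5. The upstream
literature's exact tie conventions vary; this package documents its rule
precisely and verifies it against a brute-force pair enumeration so
results are reproducible even if a different convention is assumed
elsewhere. `mad_metrics` evaluates only patients with observed events:
`mad` is the median absolute difference between predicted and observed
time, `nmad` divides each difference by the observed time so short and
long survivors weigh equally.

`rank_select` ranks configurations on the three metrics (mean ranks for
ties — the standard convention; the choice only matters for exactly tied
metric values), sums the ranks, and picks the minimum; ties break by
concordance, then mad, then configuration order, logged.

`nested_tune` holds out 20% once (outer), then evaluates each
configuration inside the remaining 80% by ten *independent random* 80/20
splits — not a partition, following the "selected at random with a fresh
seed per round" description of the motivating work. Aggregation across
folds is the one genuinely ambiguous point: folds hold out different
patients, so "median-aggregated fold curves" cannot mean a single shared
median curve. The implementation aggregates per patient — a patient held
out in several folds gets the pointwise median of its fold curves — and
scores all patients held out at least once. The staged search (family →
layers → learning rate → knots, each stage freezing the previous winner)
turns a `k₁×k₂×k₃×k₄` grid into `k₁+k₂+k₃+k₄` evaluations; stages that do
not apply to the winning family (layers and learning rate for the
parametric model) are skipped and logged. The full multi-thousand-model
grid of the motivating work is not reproduced — its exact contents are
not public — but the staged mechanism is configuration-complete.

## Counterfactual treatment choice

`quartile_grid` manufactures synthetic patients from all combinations of
per-covariate representatives: each continuous covariate contributes its
four within-quartile medians (an interior representative avoids the
boundary ambiguity of using quartile cut points; a switch to boundaries is
a one-line change), each categorical covariate its levels, and the
treatment column is excluded so it can be varied per synthetic patient.
`best_treatment` duplicates a patient once per treatment level and
recommends the level with the largest predicted median survival, reporting
all per-level medians, the margin over the runner-up, and extrapolation
flags (never suppressed). Recommendations are raw predicted medians, not
survival differences at a horizon, matching the absolute-prediction
philosophy of the package. No causal adjustment is attempted: the training
data's treatment assignment is taken as given, and confounding by
indication is explicitly out of scope.

## Synthetic cohorts: what they emulate, what they do not

`generate_cohort` draws covariates independently, forms a linear predictor
on *centred* covariates (so the marginal median stays at the family's
stated location), and generates survival in accelerated-failure-time form:
`log T = location + lp + noise`. AFT generation is the default precisely
because it violates proportional hazards — the assumption the package's
model family is designed not to make; a Weibull option covers the PH-like
case. Censoring is administrative-uniform over a window; missingness is
injected per covariate as MCAR (uniform), MAR (logistic in a fully
observed covariate) or outcome-dependent (logistic in the latent log
survival time, negative slope by default: short survivors are more often
missing, the structure that makes outcome-blind imputation hard). The
logistic intercept is calibrated by root-finding so the realised rate
matches the configured one.

The ALS-like preset states a world chosen once: log-normal survival with
median 30 months and log-sd 0.9 (so roughly 6–10% of patients survive
past four times the median — the long-tail shape that motivates focused
training), seven covariates in the roles age / sex / C9orf72 / site of
onset / diagnostic delay / functional-decline slope / diagnostic
certainty with effect sizes giving an oracle (true-linear-predictor)
concordance near 0.72, a censoring window giving ~20–25% censoring, ~60%
outcome-dependent missingness on the slope covariate (mirroring how often
a decline slope is actually computable at diagnosis) and light MCAR/MAR
missingness elsewhere. The AF-like preset has milder skew (median 4
years, log-sd 0.5), a three-level anticoagulant treatment with a
qualitative treatment-by-renal-function interaction, and drops censored
rows by default. What the generators do **not** emulate: correlated
covariate blocks, measurement error, informative (non-administrative)
censoring, cohort heterogeneity, or any numeric match to real cohort
distributions. A green test on these fixtures establishes that the
machinery recovers the structure it targets — not that any clinical
cohort would yield a particular accuracy.

## Numerical choices and degenerate inputs

* Grids collapse duplicate quantile cuts with a logged reduction of `m`;
  requesting more intervals than distinct durations is an error.
* `pchazard_nll` errors on an event in a zero-hazard interval (infinite
  loss) and on times beyond the grid; internal training clamps
  frozen-grid overruns instead, and curve evaluation extrapolates the
  last hazard.
* Median extrapolation with a flat (zero-hazard) tail is an error — the
  median is genuinely undefined there.
* Pointwise medians of monotone curves are monotone; `bag_predict` clips
  only on numerical wiggle and logs when it does.
* The Royston–Parmar optimiser starts from the exponential fit
  (`s(x) = log(rate) + x`), uses analytic gradients, and penalises
  non-monotone spline proposals at event times during optimisation.
* Ties: modal-level ties in categorical aggregation and prediction break
  to the lowest level index; rank ties share mean ranks; recommendation
  ties (exactly equal medians) resolve to the first level by argmax and
  report a zero margin.

## Known limitations

Interval censoring, left truncation, time-varying covariates and effects,
competing risks, calibration metrics (e.g. Brier score), and
multiple-imputation variance propagation are out of scope — the last
deliberately, since pooling rules that assume normally distributed
imputation estimates do not hold for forest imputation. The concordance
and imputation engines are O(n²) in pairs and O(sweeps × columns × trees)
respectively; they are sized for cohorts of thousands, not millions.
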