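# userlift

Does a model that predicts a person's day-to-day subjective state — stress or
happiness self-reported on a Likert scale — from passive smartphone sensing
actually beat the trivial guess that the person is always at their usual
state?

People report remarkably little day-to-day variation relative to the
variation *between* people. A predictor can therefore look excellent against
a **population baseline** (one constant guess for everybody: the pooled mode
or mean) while adding nothing over the **personal baseline** (each person's
own most frequent state for classification, their own mean level for
regression). `userlift` implements the evaluation framework that makes this
distinction explicit, together with the full sensing pipeline needed to
exercise it.

## The statistic

For user *u* with personal baseline error *b<sub>u</sub>* and model error
*m<sub>u</sub>* (percent incorrect for binary prediction, RMSE in Likert
units for level prediction, both under leave-one-out cross-validation for
the model),

> lift<sub>u</sub> = b<sub>u</sub> − m<sub>u</sub>

Positive lift means the model out-predicts per-person constant guessing.
Whether the cohort's **mean lift is greater than zero** is tested with a
one-sample sign-flip permutation test: under the null each user's lift is
symmetric about zero, the statistic is the mean, and for *n* ≤ 20 users all
2<sup>n</sup> sign patterns are enumerated exactly (patterns tying the
observed mean count toward the p-value); larger cohorts use seeded Monte
Carlo with an add-one correction. No distributional assumptions are made.

## What the package provides

* **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): GPS traces
  around recurrent dwelling locations (home at night, work at midday, brief
  transit segments) plus Likert self-reports with configurable
  between-user/within-user variance, under a null regime (state independent
  of mobility) or a planted-signal regime, with ground truth retained.
* **Ingest** (`read_locations()`, `read_responses()`, `build_day_records()`,
  `filter_participants()`): CSV readers, daily averaging of same-day
  reports, threshold binarization, and the standard inclusion filter
  (≥ 30 labeled days with ≥ 35 GPS observations each).
* **Daily mobility features** (`extract_mobility_features()`): two per-user
  clusterings — a BIC-selected Gaussian mixture over all samples (≤ 20
  components) and K-means over stationary samples (speed < 1 km/h) — then
  15 per-day feature columns: fraction of the day not stationary, mean/SD of
  consecutive displacements, log location variance, circadian movement,
  location entropy, minimum-enclosing-circle radius, time fractions at the
  home/work/night clusters, day log-likelihood + AIC + BIC under the user's
  mixture, and clusters visited.
* **Baselines and models** (`personal_baseline()`, `population_baseline()`,
  `loocv_personal()`, `loocv_population()`): constant-guess baselines, and
  penalized logistic regression, RBF-kernel SVM, random forest (binary) or
  lasso / elastic net (regression) under LOOCV with inner 10-fold
  hyperparameter selection.
* **The evaluation** (`user_lift()`, `permutation_test_lift()`,
  `evaluate_cohort()`): per-user lifts, descriptive statistics, the
  sign-flip test, and a summary table per task and model family.
* **Orchestration** (`run_pipeline()` and friends; a thin CLI at
  `inst/cli/userlift-cli.R`): staged runs with manifests for byte-identical
  reruns.

## Worked example

Simulate a 12-user cohort whose daily stress is partly driven by mobility
(effect size 1.5 Likert units per SD of the away-from-home fraction), run
the full pipeline, and test the mean lift:

```r
library(userlift)

cfg <- cohort_config(n_users = 12, n_days = 40, effect_size = 1.5, seed = 7)
ev  <- simulate_and_evaluate(cfg, task = "binary", family = "logistic_l2",
                             max_K = 6, hyper_mode = "once")
ev
#> <ul_eval> user-lift evaluation
#>    task      family n_users avg_personal_baseline_error avg_model_error
#>  binary logistic_l2      12                      31.875        18.54167
#>  avg_user_lift      p_value
#>       13.33333 0.0004882812

lift_descriptives(ev$per_user$user_lift)
#> # A tibble: 1 × 7
#>       n  mean   p05    q1 median    q3   p95
#>   <int> <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1    12  13.3  2.75  6.88   12.5    20  24.7

ev$tests[[1]]
#> <ul_perm_test> mean lift = 13.33, p = 0.0004883 (exact, 4,096 sign patterns)
```

The personal baseline alone gets 68% of days right, but the mobility-driven
model removes a further 13 percentage points of error on the average user,
and the exact sign-flip test (4,096 sign patterns over 12 users) confirms
the mean lift is positive. With `effect_size = 0` the same pipeline returns
lifts scattered around zero and non-significant p-values — the situation in
which a comparison against the *population* baseline would still look
flattering and would mislead.

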