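---
title: "Evaluating personalized state-prediction models with user lift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating personalized state-prediction models with user lift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(userlift)
```

## The problem

Smartphone-sensing studies repeatedly collect a person's GPS trace alongside
Likert-scale self-reports of subjective state (stress, happiness). A natural
machine-learning exercise is to predict the daily state from daily mobility.
The catch is that people report little day-to-day variation relative to the
variation between people: a constant guess tailored to each person — their
most frequent state for classification, their mean level for regression —
is already hard to beat. A model compared only against a *population*
baseline (one constant for everybody) can therefore look strong while being
useless for any individual.

`userlift` operationalises the individual-centric comparison. For each user
$u$, with personal-baseline error $b_u$ and model error $m_u$ in the same
metric (percent incorrect, or RMSE in Likert units),

$$\mathrm{lift}_u = b_u - m_u,$$

and the cohort-level question is whether the mean lift exceeds zero.

## The sign-flip permutation test

Under the null hypothesis that the model adds nothing, each $\mathrm{lift}_u$
is symmetrically distributed about zero, so its sign is exchangeable. The
test statistic is the mean lift. For $n \le 20$ users the test is exact: all
$2^n$ sign patterns are enumerated and

$$p = \frac{\#\{s \in \{-1,1\}^n : \tfrac1n\sum_i s_i\,\mathrm{lift}_i \ge \overline{\mathrm{lift}}\}}{2^n}.$$

Patterns that tie the observed mean count toward $p$ (so all-zero lifts give
$p = 1$, and $p$ is valid rather than anti-conservative). The enumeration
uses meet-in-the-middle subset-sum counting — a pattern's mean reaches the
observed mean exactly when the sum of its flipped lifts is $\le 0$ — which
makes $n = 20$ (a million patterns) effectively instant. Beyond the cap the
test switches to seeded Monte Carlo over `n_permutations` sign draws with
the add-one correction $p = (1 + \#\{\text{resampled} \ge \text{observed}\})/(1+B)$,
again guaranteeing validity. Ties in floating point are absorbed by a
relative tolerance of $10^{-9}$ on the flipped-subset sum.

Design choices here were genuinely open: the one-sample sign-flip scheme is
the standard exact permutation construction for a symmetric-null mean
comparison (a Wilcoxon signed-rank test would add a rank transformation and
an assumption the framework deliberately avoids); the $\ge$ tail convention
and the Monte-Carlo add-one correction keep both modes conservative; the
enumeration cap of 20 balances exactness against runtime.

## Baselines and models

* **Personal baseline** — per user: mode of the daily binary labels (ties
  broken to the negative class; either choice has equal error, so the
  tie-break only fixes determinism) or mean of the daily levels. Evaluated
  in-sample over the user's qualifying days, matching the framing of a fixed
  constant guess; a leave-one-out variant (`loocv = TRUE`) exists for strict
  out-of-sample comparability.
* **Population baseline** — the pooled mode/mean applied to everyone, with a
  per-user error breakdown.
* **Models** — penalized logistic regression, RBF-kernel SVM and random
  forest for the binary task; lasso and elastic net for regression. Personal
  models train only on the user's own remaining days; population models pool
  all users' days. Errors come from leave-one-out cross-validation, with
  hyperparameters chosen by inner 10-fold cross-validation on each training
  set (`hyper_mode = "nested"`). A `"once"` mode selects hyperparameters a
  single time per dataset before the outer loop — slightly optimistic, but
  appropriate for large simulation sweeps, and it is what the package's own
  calibration studies use. Features are standardized with training-fold
  statistics only; constant columns get unit scale. Hyperparameter grids are
  deliberately small (5 penalty values; 3 mixing values for elastic net;
  3×3 for the SVM; 3 `mtry` values) and configurable. Regression predictions
  are not clipped to the Likert range by default (`clip_to_scale` enables
  it). Training sets that lack two observations of a class fall back to the
  constant predictor for that fold, with a message.

## Daily mobility features

Each retained user's trace is projected to a local planar frame
(equirectangular about the user's median coordinate; within a 50 km span
distances match haversine to well under 0.5%). Samples are split into
stationary/moving by thresholding the speed derivative at 1 km/h — unless
the source data already carry a moving flag, which is passed through. Two
clusterings follow:

* the **full clustering**: diagonal-covariance Gaussian mixtures fitted to
  all samples for orders 1…20, keeping the BIC-minimizing order (ties to
  fewer components). Twenty is the assumed ceiling on locations a person
  frequents during a study. Fitting is delegated to mclust, whose
  deterministic model-based hierarchical initialisation replaces random
  restarts; for long traces the initialisation runs on a seeded subsample of
  300 points. All-identical samples get a single component with a floored
  covariance.
* the **stationary clustering**: K-means over stationary samples with K
  selected by BIC under a spherical-Gaussian reading of the K-means solution
  (shared variance $\mathrm{WSS}/(d(n-K))$, $(K-1) + Kd + 1$ parameters),
  mirroring the full clustering's selection because no K is canonical here.

Semantic clusters are defined by dwell windows: *home* is the mixture
component holding the most samples between 11pm and 6am, *work* between 11am
and 4pm, and the *night cluster* is the stationary cluster with the most
samples between midnight and 6am. Dwell is measured in sample counts, not
interval weights, because traces are deliberately not interpolated to
regular sampling; under regular sampling the two coincide. An empty window
leaves the id undefined and zeroes the corresponding fraction features.

The per-day vector has 15 columns for the 14 documented features (AIC and
BIC are reported separately): fraction not stationary; mean and SD of
consecutive-pair displacements (pairs more than 10 minutes apart are skipped
so overnight gaps do not dominate); $\ln(\sigma^2_x + \sigma^2_y +
\varepsilon)$ with $\varepsilon = 10^{-12}\,\mathrm{m}^2$ flooring
zero-variance days; circadian movement — the Euclidean distance between the
day's stationary-cluster time-fraction vector and the user's study-long mean
fraction vector; the entropy of the day's fraction vector (nats); the exact
minimum-enclosing-circle radius (convex hull plus candidate-circle
enumeration, which is exact because the optimal circle is determined by at
most three hull points); fractions of the day's samples at the home, work
(maximum mixture responsibility) and night (nearest centroid) clusters; the
day's log-likelihood under the user's mixture with AIC $= 2m - 2\ell$ and
BIC $= m\ln n_{day} - 2\ell$, using $m = 5K - 1$ free parameters (K−1
weights, 2K means, 2K diagonal variances — the parameter convention is
documented because no canonical one exists); and the counts of distinct
full/stationary clusters visited.

The user's mean fraction vector averages over all qualifying study days,
*including* the day being featurized — the literal reading of "average
fraction of a day spent in each cluster during the study". This leaks a
little information across days; `exclude_current_day = TRUE` computes the
leave-one-day-out variant for users who prefer strict separation.

## The synthetic cohort generator

The generator emulates the statistical structure this analysis assumes, with
ground truth retained so recovery is testable. Each user gets a home, a work
and optionally further recurrent locations in a planar frame (converted to
latitude/longitude by the inverse equirectangular map about a configurable
origin, so downstream distance code is exercised realistically). A day is a
piecewise-constant hourly dwell schedule — home with probability 0.95 in the
11pm–6am window, work with probability 0.9 in 11am–4pm, weighted draws
elsewhere — with six-minute transit segments between differing consecutive
hours sampled at the same rate and flagged moving, plus isotropic GPS noise
(20 m default). GPS timestamps are distinct random seconds within the day.

The latent daily state of user $u$ on day $d$ is

$$\mathrm{level}_{ud} = \mathrm{clamp}\big(\mathrm{round}(\mu_u + \beta\,s_{ud} + \varepsilon_{ud})\big),$$

with $\mu_u \sim N(\text{scale midpoint}, \sigma_b)$ clamped to the scale,
$\varepsilon_{ud} \sim N(0, \sigma_w)$, and $s_{ud}$ the within-user z-score
of the fraction of the day's samples away from home — itself the complement
of one of the pipeline's own features, which guarantees a learnable signal
when $\beta > 0$. Each report adds integer-rounded $N(0, \sigma_r)$ noise,
clamped; same-day reports share the latent level, so the daily-averaging
step in ingest has real work to do. Defaults (20 users × 40 days, 5-point
scale, 2 reports/day, 40 GPS observations/day, 3 locations, $\sigma_b = 1.0$,
$\sigma_w = 0.7$, $\sigma_r = 0.5$, $\beta = 0$) encode the regime the
framework targets — cohorts of a few dozen users followed for one-to-few
months with much larger between- than within-user variance; no published
numeric variance ratio exists, so the ratio is a design choice here, checked
in the tests against a direct simulation oracle of the same label model.
Identical configuration and seed give bit-identical cohorts.

What the generator does *not* emulate: realistic human-mobility processes
(no heavy-tailed excursions, no weekly seasonality), non-uniform missingness,
scale drift, or report-time reactivity. Passing calibration and power checks
on these cohorts therefore demonstrates correctness of the pipeline and the
test's operating characteristics under the assumed structure, not
performance claims about any real dataset.

## Numerical and degenerate-input conventions

Day boundaries are local civil midnight in one configurable study timezone
(UTC default). A daily mean exactly at the binarization threshold counts as
the positive class. Days with a label but fewer than 35 GPS observations
are dropped entirely — the inclusion filter is a conjunction. Duplicate
response timestamps are both averaged. In BIC selections, exact ties go to
the smaller model. Zero-time-difference GPS pairs with distinct coordinates
have undefined speed and are flagged moving and counted as anomalies.
Single-point days yield zero displacement, zero entropy and a zero-radius
enclosing circle; days with fewer than two usable samples are dropped with a
message.

## Simulation study sizes

The package's own calibration studies (in the test suite) use: 100 random
small cohorts for baseline optimality; 50 random lift vectors (n ≤ 12,
B = 10,000) for exact-vs-Monte-Carlo agreement; 1,000 replicates of 20
standard-normal lifts for type-I calibration; and 50 seeded cohorts of 20
users × 40 days each for the null-regime and planted-signal end-to-end
checks, run with the scaled-down analysis settings (mixture order capped at
6 where the generator plants 3 locations, one penalized model family,
once-per-dataset hyperparameters). These sizes are the package's simulation
design: large enough to pin the operating characteristics, small enough to
run at desk scale.

## Known limitations

Table-level results from the motivating real-world datasets are not
reproducible here because those datasets cannot be redistributed; the
package reproduces the lift arithmetic on their published summary errors and
the qualitative findings on synthetic cohorts. The permutation test's tail
convention and tie handling are documented choices among valid alternatives,
so third-party p-values need not match bit-for-bit. The circadian-movement
mean distribution leaks the featurized day by default (see above). The
population-model LOOCV is quadratic-cost in cohort days and is the slowest
path in the package; it is optional for the lift test, which only needs
personal models.
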