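# breastdose

Estimating the radiation dose absorbed by breast tissue during a chest
CT examination, and benchmarking how well machine-learning regressors
recover that dose from routine patient data.

Scanner-reported dose metrics (DLP, CTDIvol) describe machine output,
not organ dose; reference organ dosimetry (Monte Carlo transport) is
too slow for clinical use. This package implements a lightweight
personalized surrogate and the analysis pipeline around it, aimed at
medical physicists and ML-for-dosimetry researchers.

## The model

For a patient with weight *W* (kg), height *H* (m), mammographic breast
thickness *BT* (mm), age *A* (y), and exam dose-length product *D*
(mGy·cm), the internal radiation dose (mGy) is

    IR = k · D · BODY,   BODY = 0.40·F1 + 0.30·F2 + 0.30·F3

with F1, F2, F3 min–max normalizations of BMI = W/H², BT, and A over a
reference cohort (clamped to [0, 1]), and *k* an empirical scale
calibrated so the cohort mean dose equals a reference value (default
9.76 mGy). Around this dose model the package provides:

* a synthetic 653-patient cohort generator (truncated marginals +
  Gaussian copula) emulating a single-scanner mammography/chest-CT
  population;
* a from-scratch particle swarm optimizer (PSO) for mixed
  integer/continuous hyperparameter spaces;
* a five-family tree-ensemble benchmark (xgboost boosting, classical
  least-squares CART boosting, extremely randomized trees, AdaBoost.R2,
  random forest) tuned by PSO against 5-fold cross-validated MSE and
  scored by held-out MSE / MAE / MAPE / R²;
* a LIME-style local surrogate explainer reporting per-feature signed
  contributions in mGy.

The two boosting families run on a compiled exact-CART base learner
(`src/cart.cpp`) that reproduces `rpart`'s greedy anova fit.

## Worked example

The `analysis/` scripts run the full study in order. Stage 2 output on
the stage-1 cohort:

```
Calibrated k = 0.101472 (cohort mean dose pinned to 9.76 mGy)
IR: mean 9.760 mGy | sd 5.433 | range 0.65-62.50 mGy

Train/test comparability report (unstratified split, seed 42):
 split   n mean_ir min_ir max_ir
 train 522   9.799 0.6478  62.50
  test 131   9.603 1.6897  28.71
```

`k` converts DLP·BODY into mGy; the split report shows the 522/131
partition is comparable in dose despite being unstratified. Stage 3
(PSO tuning, ~5 min on one CPU) prints the benchmark table:

```
        model    mse    mae mape_pct     r2
       gboost 0.8569 0.5266    5.901 0.9620
      xgboost 0.8856 0.4225    4.347 0.9608
 randomforest 1.2898 0.7549    9.541 0.9429
   extratrees 1.3042 0.7846    9.660 0.9422
     adaboost 1.9764 0.9116   10.607 0.9125
```

Gradient-boosted families lead, every family clears R² 0.91, and MAPE
stays near a few percent of the true dose. Stage 4 explains single
predictions; for the highest-DLP test patient:

```
Patient P0497 (DLP 554.0 mGy.cm, true dose 26.73 mGy):
  model prediction: 20.077 mGy | surrogate: 19.020 mGy | intercept: 8.569
  total_dlp > 0.29             value   553.96  contribution +6.930
  0.02 < breast_thickness <= 0.72 value  50.61  contribution +1.995
  bmi > 0.59                   value    34.16  contribution +1.272
```

Conditions are quartile intervals on the standardized feature scale;
contributions are mGy added to (or removed from) the local surrogate's
prediction, and a high DLP dominates — as the dose model demands.

Programmatic use mirrors the scripts:

```r
library(breastdose)
cohort <- generate_cohort(cohort_config(n = 653), seed = 1)
stats  <- normalization_stats(cohort)
params <- dose_model_params(k = calibrate_k(cohort, stats), stats = stats)
lab    <- label_cohort(cohort, params)
bench  <- run_benchmark(lab, control = pso_control(seed = 1))
bench$results
```

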