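---
title: "Modelling and predicting breast absorbed dose in chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and predicting breast absorbed dose in chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastdose)
```

## The problem

The scanner-reported dose-length product (DLP, mGy·cm) of a chest CT
examination measures machine output, not the dose any particular organ
absorbs. Breast tissue is radiosensitive and sits in the beam during
thoracic scans, so a patient-specific estimate of breast absorbed dose
(mGy) is clinically useful — but the reference methods (Monte Carlo
photon transport on segmented anatomy) are far too slow for routine
use. `breastdose` implements a lightweight surrogate chain:

1. a closed-form **dose model** that converts DLP into a personalized
   breast dose using anthropometric correction factors;
2. a **synthetic cohort generator**, because the hospital cohort the
   model was developed on is not publicly available;
3. a **benchmark** that tunes five tree-ensemble regressors with a
   from-scratch particle swarm optimizer (PSO) to predict the
   model-derived dose from raw patient features;
4. a **local surrogate explainer** that attributes a single prediction
   to feature intervals.

## The dose model

For a patient with weight $W$ (kg), height $H$ (m), mammographic breast
thickness $BT$ (mm), age $A$ (years) and exam DLP $D$:

$$\mathrm{IR} = k \cdot D \cdot \mathrm{BODY}, \qquad
\mathrm{BODY} = 0.40\,F_1 + 0.30\,F_2 + 0.30\,F_3,$$

where $F_1, F_2, F_3$ are min–max normalizations of BMI $= W/H^2$, $BT$
and $A$ over a reference cohort, clamped into $[0,1]$ for out-of-range
queries. BODY is therefore a convex combination: it is 0 only for a
patient at all three cohort minima and 1 only at all three maxima.

Two modelling choices deserve comment:

* **Weighted sum, not product.** A pure product $F_1F_2F_3$ zeroes the
  dose whenever a single factor sits at its cohort minimum, which
  contradicts any plausible dose distribution (every scanned patient
  absorbs some dose). The weighted-sum BODY is the default; the product
  form remains available via `dose_model_params(form = "product")` for
  comparison.
* **Calibration of $k$.** The empirical scale is not known a priori.
  `calibrate_k()` pins the cohort mean dose to a reference value
  (default 9.76 mGy, a representative mean breast dose for chest CT);
  the closed form `k = target / mean(D_i · BODY_i)` makes the
  calibration exact to machine precision. The min/max normalization
  statistics are computed over the full labelling cohort (labels
  predate the train/test split) and persist with the parameters.
* A degenerate feature range (min = max) raises an error rather than
  silently returning a mid-scale factor, since it indicates a broken
  reference cohort.

Physically one may object that higher BMI should *attenuate* dose to
deep tissue; the model instead increases IR with normalized BMI. The
model is implemented as specified and this open modelling question is
deliberately not resolved here.

## The synthetic cohort

`generate_cohort()` draws patients from truncated marginals coupled by
a Gaussian copula:

| feature | marginal | default |
|---|---|---|
| weight | truncated normal | mean 73.1 kg, sd 15, range 46–133 |
| height | truncated normal | mean 1.59 m, sd 0.06, range 1.47–1.77 |
| age | truncated normal | mean 58.6 y, sd 12, range 33–88 |
| breast thickness | truncated normal | mean 50 mm, sd 12, range 25–80 |
| DLP | lognormal bulk + exponential tail | median 205, sdlog 0.25 on [68.81, 550]; 2% tail, scale 130 on [550, 914.5] |

The truncated-normal location parameters are solved numerically so the
*realized* means match the configured ones (asymmetric truncation would
otherwise bias them). Rank-correlation targets are placed on weight as
the body-size driver — weight–height 0.3, weight–breast-thickness 0.4,
weight–DLP 0.5 (automatic exposure control raises DLP with body size).
Targets quoted for BMI in the source material are mapped onto weight
because BMI is a derived quantity.

The two-component DLP marginal reflects how single-protocol chest-CT
DLP histograms actually look: a tight routine bulk plus a sparse,
decaying tail of extended-coverage or repeat acquisitions. Its two free
parameters (bulk sdlog, tail fraction/scale) were calibrated once
against three published summary statistics of the reference cohort —
mean dose 9.76 mGy, dose range roughly 1–53 mGy, and the test-set dose
standard deviation (≈ 5.5 mGy) implied by the published MSE and $R^2$
through $\mathrm{var} = \mathrm{MSE}/(1-R^2)$ — and then frozen. A
single truncated lognormal cannot match all three at once: the
published maximum lies almost 8 implied standard deviations above the
mean.

What the generator does **not** emulate: scanner protocol parameters
(kV, mA, pitch) as separate variables, measurement noise in the
anthropometrics, multi-center heterogeneity, and the true (unknown)
joint distribution of the hospital cohort — the copula targets are
assumptions. Passing benchmarks on this cohort therefore demonstrate
that the pipeline recovers a dose signal of realistic shape and
dependence structure, not that the trained models transfer to any
real population.

Labels are noiseless by default (the dose is a deterministic function
of the features), which makes the learning task a pure function
approximation; `label_noise_sd > 0` in the config emulates sub-1
$R^2$ regimes.

## The PSO benchmark

`pso_optimize()` is a textbook global-best particle swarm over mixed
integer/continuous boxes: velocity update
$v \leftarrow wv + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$,
inertia $w = 0.7$, $c_1 = c_2 = 1.5$, velocities clamped to half the
dimension range, positions clamped to bounds, log-scale dimensions
optimized in $\log_{10}$ space, integer dimensions rounded at
evaluation time. Defaults are 10 particles and 20 iterations. Two
engineering details:

* **Warm start.** The first particle starts at the model family's
  library-default hyperparameters, so the tuned cross-validated score
  can never be worse than the default configuration's.
* **Anti-stagnation restart.** After each iteration the worst-scoring
  particle is re-seeded uniformly. Without it the swarm contracts and
  small integer lattices stop being explored; with it, a 49-point
  integer lattice with a well-separated optimum is solved to the
  exhaustive-search minimum in well over 90% of seeds at a
  10-particle × 10-iteration budget. Near-tied objective basins
  (differences of order 0.01) remain hard for any stochastic search.

The tuning objective is the 5-fold cross-validated MSE **on the
training split only**. The source protocol tuned against the test set;
that leaks model selection into evaluation, and is available only
explicitly via `objective = "test"` in `tune_and_fit()`, documented as
methodologically unsound.

Five families are benchmarked, all with internal random state 42:
xgboost gradient boosting (standing in for categorical boosting — the
features are all numeric, so categorical handling is moot), classical
least-squares CART boosting and AdaBoost.R2 (implemented in-package
over a compiled exact-CART base learner, since no installed package
provides these regressors; the tree matches `rpart`'s greedy anova
fit, which the test suite asserts), extremely randomized trees, and
random forest (both via `ranger`). AdaBoost.R2 feeds case weights into
the tree fit directly instead of resampling, making each boost round
deterministic.

Search ranges (the problem sizes of the tuning study) are: xgboost
iterations 50–500, depth 2–10, learning rate 0.01–0.5 (log); classical
boosting estimators 50–250, depth 2–8, learning rate 0.01–0.5 (log),
min split 2–10; extra trees / random forest 50–300 trees, depth 2–14,
node size 1–10; AdaBoost 30–150 estimators, learning rate 0.05–1
(log), base depth 2–8. For the xgboost family, exact greedy splits
are used rather than histogram binning: with 653 numeric rows the
exact method is cheap and measurably more accurate on this smooth
target. MAPE is stored as a fraction and printed as percent.

## The local explainer

`explain_instance()` follows the LIME recipe for tabular data:
standard-normal perturbations in z-score space (the training
distribution, not the instance, is the sampling center), exponential
kernel weights $\exp(-d^2/\kappa^2)$ with $\kappa = 0.75\sqrt{d}$,
and a weighted ridge regression (penalty $10^{-3}$, intercept
unpenalized) of the model's predictions on quartile-bin membership
indicators. Kernel weights are normalized to mean one before the fit:
for an instance far outside the training bulk the raw weights
underflow uniformly, and an absolute penalty would otherwise swamp the
weighted design and shrink every contribution to zero. Reported conditions are one- or two-sided inequalities on
the standardized scale ("`total_dlp > 0.70`"), contributions are in
prediction units (mGy), and the top 5 features are refit as the final
surrogate so that intercept + contributions equals the surrogate
prediction exactly. Bin boundaries carry a $10^{-9}$ tolerance so a
value equal to a training quartile lands in the lower bin. A singular
weighted design escalates the ridge penalty tenfold with a message.

For an instance lying far outside the training bulk (several standard
deviations in one feature), the z-space kernel concentrates its mass
on the few nearest samples, the instance's own bin indicator becomes
nearly constant among them, and the attribution for that feature grows
unstable — a known property of this class of explainer; conditions and
additivity remain valid, but contributions for extreme outliers should
be read with care.

Local DLP contributions can be negative for mid-range DLP instances
even though the dose is globally increasing in DLP; with a surrogate
fitted to bin indicators this is expected behaviour whenever the
instance's bin sits below the weighted average, and cannot be
distinguished from genuine model behaviour without the original data.

## Problem sizes, seeds, and reproducibility

The study-scale analyses use the 653-patient cohort, an 80/20 split
with seed 42 (522 train / 131 test), 10 particles × 20 PSO iterations,
and 5-fold CV; unit tests exercise the same code paths on cohorts of
100–300 patients with 3–4 particles and 2–3 iterations. Every
stochastic function takes an explicit seed; `run_pipeline()` fans a
single master seed out to stage seeds via fixed offsets, so any stage
can be re-run independently. Objective evaluations inside
`tune_and_fit()` are memoised by rounded position, which saves refits
after the swarm converges without changing the evaluation count
contract.

## Known limitations

* The dose model is a surrogate with the structure of the source
  material, not a dosimetric ground truth; its labels inherit every
  assumption above.
* The cohort generator's dependence structure and DLP tail are
  educated defaults, not estimates from data.
* Best hyperparameters and numeric explanation contributions are
  data- and model-specific and are not expected to match any published
  configuration.
* The PSO is a single-swarm global-best variant; no constriction
  factor, neighbourhood topologies, or parallel evaluation.
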