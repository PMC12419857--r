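---
title: "Methods: biological aging, multimorbidity and life expectancy with agepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological aging, multimorbidity and life expectancy with agepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agepath` estimates how biomarker-measured biological aging relates to the
accumulation of physical, psychological and cognitive disorders and to
survival. This vignette is the package's own account of the models it
fits, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real cohorts.

## Biological-age scores

**Klemera–Doubal (KDM-BA).** Each biomarker $x_i$ is regressed on
chronological age within sex, giving intercept $q_i$, slope $k_i$ and
residual RMSE $s_i$ (note: we follow the standard Klemera–Doubal
convention in which $q$ is the intercept and $k$ the slope of
$x_i \approx q_i + k_i \cdot CA$; some descriptions list the symbols in
the opposite order). The score is the inverse-variance-weighted mean

$$\mathrm{KDM} = \frac{\sum_i (x_i - q_i)\,k_i/s_i^2 + CA/s_{BA}^2}
{\sum_i (k_i/s_i)^2 + 1/s_{BA}^2},$$

which returns chronological age exactly for a person lying on every
regression line. $s_{BA}$ is implemented as
$\sqrt{R^2 \,\mathrm{Var}(CA)}$ from a multiple regression of age on all
biomarkers — the verbal definition "the square root of the age variance
explained by the biomarker set" taken literally — with an override for
users who prefer the fuller Klemera–Doubal variance correction.
Biomarkers whose slope-to-noise ratio $|k_i|/s_i$ collapses (their weight
vanishes) or whose $s_i$ is numerically zero (their weight explodes) are
flagged at training time.

**PhenoAge.** The linear predictor $xb$ (nine markers plus chronological
age, C-reactive protein log-transformed, weights shipped as a versioned
CSV of the published training coefficients) maps to a 120-month mortality
risk under a Gompertz hazard with $\gamma = 0.0076927$ per month, and the
risk maps to the age at which a reference population attains it,
$141.50225 + \ln(-0.00553 \ln(1-\text{risk}))/0.090165$. Numerically we
evaluate the outer logarithm through $u = -\ln(1-\text{risk}) =
e^{xb}(e^{120\gamma}-1)/\gamma$ rather than through the risk itself: for
moderately large $xb$ the risk rounds to 1.0 in double precision while
$u$ remains exact, and the identity "outer log argument = 1 gives
141.50225 exactly" then holds to machine precision. The error guard fires
only where $u$ itself degenerates ($xb \to -\infty$, underflow or
overflow).

**Acceleration.** The exposure of interest is the residual from an OLS
regression of biological age on chronological age (pooled across sex by
default; a stratified option exists because the source description does
not state which was used). Residuals sum to zero and are uncorrelated
with age by construction; "accelerated" means residual $> 0$, and models
use either the SD-standardized residual or quartiles (Q1 referent, ties
at a cutpoint falling to the lower quartile). Scores beyond 5 SD of the
cohort mean are flagged and excluded before modeling, and participants
missing any score biomarker are not scored: imputation is reserved for
covariates.

## Multimorbidity states and panels

The state space is progressive: none (1) → single (2) → dual (3) →
triple (4), with death (5) reachable from the diseased states. A
participant's level is the count of distinct disorder domains (physical,
psychological, cognitive) ever present; domains never clear.
The direct none → death edge is excluded from the model graph, and
participants observed only as none → death are dropped (with a count
in the panel's exclusion report) — with so few such cases a separate
baseline intensity for that edge is not stably estimable.
Two or three domains recorded on the same date are split into consecutive
single-level jumps one day apart, ordered physical → psychological →
cognitive, because a continuous-time chain has no multi-level jumps. The
multistate model runs on years since baseline with baseline age as a
covariate (the age timescale is reserved for the life-expectancy models);
treating baseline age as fixed rather than time-varying is a documented
limitation.

## The multistate likelihood

Transition intensities are proportional:
$q_{rs}(z) = q^0_{rs} \exp(\beta_{rs} \cdot z)$ on the allowed edges,
giving an upper-triangular generator $Q(z)$. Interval-censored panel
contributions are $\log P(\Delta t)[s_{prev}, s_{next}]$ with
$P = \exp(\Delta t\, Q)$; an exactly observed death at $T$ contributes
$\log \sum_s P(T - t_{prev})[s_{prev}, s]\, q_{s,D}(z)$ over transient
states with a death edge. The matrix exponential uses uniformization
(a Poisson-weighted series in the substochastic matrix $I + Q/q_{max}$,
truncated below $10^{-13}$, with log-space weights so large $q_{max}
\Delta t$ cannot underflow). Because only one row of $P$ enters each
contribution, the series is propagated as a row vector, and the exact
score is accumulated alongside it from the sparse directional derivative
of each edge — a full likelihood-and-gradient pass costs about as much as
one likelihood evaluation. BFGS maximizes the likelihood from crude
occurrence/exposure starting rates (deterministic given the data);
standard errors come from central differences of the analytic gradient at
the optimum. Intensities are capped at $e^{4}$ per year inside the
objective so a runaway line search cannot explode the series; the cap is
far outside any plausible estimate. Tests verify the two-state closed
form, the Chapman–Kolmogorov identity, agreement with a dense-series
matrix exponential, the gradient against finite differences, parameter
recovery within 3 SE, and convergence of the covariate-free MLE to the
occurrence/exposure estimator on fully observed paths.

## Association models

Logistic fits (baseline prevalence) and Cox fits (incident disorder,
multimorbidity and mortality in the baseline disorder-free subset, plus
mortality within each baseline state) use the full adjustment set (age,
sex, ethnicity, BMI category, smoking, alcohol, diet score, physical
activity, Townsend deprivation, income band, four air-pollution
measures). Cox models use Efron tie handling. Quartile fits keep Q1 as
referent and report a p-for-trend from the ordinal quartile score 1–4
(the continuous-exposure alternative was also plausible; the ordinal
score is the default). Dose–response curves place the exposure in a
Harrell restricted cubic spline — four knots at the 5/35/65/95th
percentiles by default, configurable since the source leaves knots
unstated — and report $HR(x) = \exp(\eta(x) - \eta(0))$ with delta-method
bands; acceleration $= 0$ (the accelerated/non-accelerated boundary) is
the default reference. Separation of the exposure is an error; a
diverging adjustment covariate in a sparse stratum is a warning, and the
pipeline records and skips a stratum fit that fails rather than aborting
the run.

## Multiple imputation

Missing covariates are imputed $m = 20$ times by default: ordinal
variables (income, education, and other ordered factors) by
proportional-odds logistic draws from predicted category probabilities
(binary factors reduce to plain logistic); continuous variables that may
be negative (deprivation index) by regression-based conditional normal
draws with posterior parameter draws, rejected at the plausibility bounds
and clamped after a capped retry; non-negative continuous variables
(physical activity, diet score, air pollution) by mean substitution.
Which covariates enter each imputation model is not specified at the
source; the default predictors are age and sex, configurable. Estimates
are pooled on the log scale by Rubin's rules with total variance
$\bar W + (1 + 1/m) B$ and small-sample degrees of freedom
$(m-1)(1 + \bar W /((1+1/m)B))^2$; when $B = 0$ the reference
distribution is normal.

## Life expectancy and years of life lost

A Royston–Parmar model places a restricted cubic spline (default 4 df,
i.e. 3 internal knots at quantiles of log event ages) on the log baseline
cumulative hazard as a function of log age, with proportional covariate
effects and delayed entry at baseline age. Residual life expectancy at
age $a$ is $\int_a^{100} S(t|z)/S(a|z)\,dt$, evaluated by composite
5-node Gauss–Legendre quadrature on 1-year panels (quadrature error far
below $10^{-6}$ years); years of life lost is the difference versus the
disease-free referent at the same age. CIs come from seeded parametric
simulation of the parameter vector (default $B = 1000$ draws in the
standalone functions), applied jointly to group and referent so their
correlation is preserved.

Two numerical points deserve note. First, when every subject enters at
age 45 or later, the absolute level of the cumulative hazard is only
weakly identified — the spline family can nearly absorb an additive shift
of $H$ — so all reported quantities are conditional (on survival to the
conditioning age), which is what the data identify; with flexible splines
the information matrix can be poorly conditioned and occasional
simulation draws degenerate, so draws are clamped to the feasible range
$[0, 100 - a]$ and degenerate draws are dropped from the quantiles.
Second, fits are initialized at a crude exponential hazard
($\log H = \log \hat\lambda + \log t$), which is robust under left
truncation where generic initial values fail.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not any real cohort's marginals. Baseline age is truncated normal (mean
56.4, SD 8.1, range 37–73), 54% female. Each biomarker follows a linear
age trend with a sex offset and Gaussian noise, calibrated to the
magnitudes typical of a mid-life Western cohort; C-reactive protein is
generated on the log scale to keep it positive. A single standard-normal
**latent frailty** enters every biomarker additively (loading × frailty ×
residual SD) and every transition multiplicatively
($\exp(\text{loghr} \times \text{frailty})$, 0.25 on progression edges,
0.35 on death edges). This shared frailty is the minimal structure that
makes biological-age acceleration genuinely prognostic — the property the
pipeline must detect; setting `frailty_sd = 0` removes the link, which a
test verifies. Disorder progression runs from age 25 with constant
intensities calibrated so the baseline state mix is roughly 18% none /
55% single / 23% dual / 3% triple; death intensities are Gompertz in age
(slope 0.09/yr), switched on at enrolment (the cohort conditions on being
alive at baseline), simulated piecewise-constant on a 1-year grid, and
calibrated to roughly 8% deaths over the default 13.6-year follow-up.
Disorder-domain identity is assigned exchangeably at each upward jump;
the generator encodes no domain-specific correlation structure because
the available state counts do not constrain one. Missingness is MCAR at
per-column rates echoing typical covariate missingness (an age-dependent
MAR switch exists); outcome and date columns are never masked.

What passing tests therefore show: the estimators recover the parameters
of data generated under their own assumptions (proportional intensities,
proportional hazards, linear biomarker-age trends, MCAR covariates), the
oracles confirm the arithmetic, and the pipeline reproduces the expected
direction and ordering of effects. What they do not show: robustness to
real-data violations — non-proportional hazards, informative missingness,
measurement error in disorder dates, or domain-specific progression —
none of which the generator emulates.

## Problem sizes and runtime choices

Unit tests run at the smallest sizes that make their statistical bands
sharp (thousands of rows); the end-to-end and calibration checks use a
20,000-participant cohort, 200 permutation replicates at $n = 2000$ for
null-coverage, and 5 imputations with a reduced life-table age grid in
the full-pipeline run — the directional claims checked there do not
depend on the imputation count, and $m = 20$ remains the analysis
default. The acceptance script (`scripts/acceptance.R`) reruns the whole
pipeline at $n = 20{,}000$ from a single seed and writes every headline
quantity as JSON.

## Known limitations

- Baseline age is a fixed covariate in the multistate model; a
  time-varying age effect would need the age timescale there too.
- The generator's disorder intensities are age-constant before baseline;
  only mortality carries Gompertz age dependence.
- No hidden-Markov misclassification layer, semi-Markov sojourn effects,
  or competing-risks structure.
- Bounded-normal imputation clamps after a capped number of rejection
  retries, which slightly inflates boundary mass when bounds are tight.
- The landmark sensitivity and complete-case sensitivity reuse the main
  estimators; they are design filters, not different models.
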