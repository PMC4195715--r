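---
title: "Cohort simulation of type 2 diabetes and regression-based external validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort simulation of type 2 diabetes and regression-based external validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcohort)
```

## The model

`t2dcohort` tracks the *fraction* of a homogeneous diabetic cohort occupying
each health state, advanced deterministically in annual cycles for up to 40
years. This is the cohort (Markov) alternative to patient-level
microsimulation: far faster and easier to verify, at the cost of plugging
cohort-*mean* covariates into non-linear risk equations (see Limitations).

Three component layers evolve together:

1. **Microvascular tracks.** Retinopathy, nephropathy and neuropathy are
   independent forward-only chains (none → intermediate stage(s) → end
   stage). Each transition has a baseline annual probability, optionally
   rescaled by a power-law biomarker modifier
   $(x/x_{\mathrm{ref}})^{k}$ — HbA1c by default, SBP for
   macroalbuminuria progression. The annual transition matrix is
   row-stochastic with the diagonal as residual; a modifier that pushes a
   row's off-diagonal sum above 1 is an error, not a silent clamp.

2. **Macrovascular risk equations.** Annual first-event probabilities for
   MI, IHD, CHF, stroke and PVD come from one of three pluggable parametric
   families, all reduced to the same discrete-cycle form
   $p(t) = 1 - \exp\{-(H(t{+}1) - H(t))\}$:

   | family | cumulative hazard / risk | lineage |
   |---|---|---|
   | `weibull` | $H(t) = e^{\beta'x}\, t^{\rho}$, $\rho > 0$ | UKPDS-OM1 |
   | `gompertz` | $H(t) = e^{\beta'x}(e^{\theta t}-1)/\theta$ | UKPDS-OM2 |
   | `logistic_annual` | $p = \mathrm{logit}^{-1}(\beta'x)$ directly | OM2 event types fitted as annual logits |
   | `fiveyear_risk` | $p_5 = \mathrm{logit}^{-1}(\beta'x)$, then $p_1 = 1-(1-p_5)^{1/5}$ | Swedish NDR 5-year CVD risks |

   The clock $t$ is diabetes duration by default (UKPDS convention) and
   `age` where an equation declares it. The Gompertz increment is computed
   through `expm1`, so $\theta \to 0$ degrades gracefully to the constant
   hazard $e^{\beta'x}$; the test suite checks Weibull $\rho = 1$, Gompertz
   $\theta = 10^{-8}$ and the constant hazard agree within $10^{-6}$.

3. **Mortality.** Per-cause annual probabilities (e.g. CVD and non-CVD
   death) combine by the complement product $1 - \prod_i (1 - p_i)$ and are
   attributed to causes in proportion to $-\log(1-p_i)$ (hazard shares,
   exact for a single cause).

### The annual cycle order

The within-cycle order is fixed for reproducibility, because discrete-time
results depend on it: (1) microvascular steps, with new entries into each
downstream state accrued to cumulative incidence among survivors; (2)
macrovascular event probabilities accrue among survivors without a prior
event of that type; (3) mortality reduces the alive fraction; (4)
event-history prevalences, age and diabetes duration advance. No half-cycle
correction is applied — progression is defined on annual evaluation, and a
half-cycle correction would change the quantity being validated. All
cumulative incidences are reported on the of-initial-cohort scale, the
scale on which trials report cumulative incidence; survivors-only
prevalence is deliberately not an output (prevalence endpoints are excluded
at the filtering step for exactly this mismatch).

Event-history covariates (prior MI, stroke, …) are prevalence *fractions*
updated each cycle with the incident fraction,
$h' = h + (1-h)\,p$, and enter linear predictors multiplied by their
coefficient — the expected-value approximation, which is the only coherent
cohort-level reading of indicator covariates. Whether a cohort engine
should feed incident events back into the history covariates at all is a
genuinely open design point; this engine does, because freezing baseline
history would systematically understate late-horizon risk, and the choice
is isolated in one step of `advance_one_year()`.

### Subgroups, trajectories, pooling

A study is simulated separately for each subgroup — by default the four
gender × smoking cells, but the architecture takes any number of cells
(age strata are handled as separate `strata`, each its own unit of
analysis) — and pooled as the weighted average of the per-year endpoint
maps. Treatment effects are applied as additive biomarker deltas reaching
full effect in year 1 and flat thereafter (`build_trajectory()`); an
explicit per-year path overrides this when a study reports one. Missing
baseline fields are taken from the `risk_profile()` defaults, which play
the role of a declared donor profile; any study-specific imputation should
be recorded in the study configuration's description.

## Coefficients are configuration, not code

The published UKPDS-OM1, UKPDS-OM2 and Swedish NDR coefficient sets are
licensed publications and are not redistributed here. The package instead
fixes a versioned YAML schema (`t2dcohort-bundle/1`) with
`event_id`/`family`/`coefficients`/`transforms`/`shape`/`time_scale` per
equation. Transcription workflow: copy each published equation's
coefficient column into `coefficients` (centering offsets such as
"HbA1c − 6.72" become `transforms` entries), set `family` and `shape` from
the published functional form — which OM2 events are Gompertz versus
annual-logistic is taken from the source at transcription time, the schema
does not hard-code it — and declare `time_scale`. An NDR bundle lists the
events and mortality causes it borrows from a UKPDS bundle in `fallback`
(there are no complete Swedish NDR mortality equations, so UKPDS mortality
is used there). `read_bundle()` validates the schema and rejects unknown
families. The packaged `make_toy_bundle()` sets are clearly-labelled
synthetic stand-ins used by all tests; likewise the `default_tracks()`
microvascular baseline probabilities are synthetic placeholders of
plausible magnitude pending transcription of the published NIH/DiDACT
values.

## The validation pipeline

`run_validation()` simulates each stratum's subgroups to the longest
endpoint horizon, pools, reads each endpoint's predicted cumulative
incidence at its own horizon and pairs it with the observed value. Each
endpoint × stratum × time point is a separate validation point.
`filter_endpoints()` applies the two inclusion rules — a matchable single
model outcome (composites are excluded) reported as a cumulative incidence
(survivor-prevalence endpoints are excluded) — and logs every exclusion
with its reason. The packaged `study_registry()` records the 12 studies
(167 endpoints, 89,320 participants) and the dependency rule table:
WESDR, Rochester, UKPDS 33 and UKPDS 80 are dependent under every equation
set; the two NDR cohorts are dependent only under the NDR equations; the
remaining six studies are always independent.

## Concordance statistics

`fit_concordance()` regresses predicted on observed by OLS (base `lm()`),
with sandwich standard errors. The robust covariance is computed in the
package because the exact small-sample convention matters for
reproducibility: cluster scores are summed by source study and the CR1
factor $\frac{G}{G-1}\cdot\frac{n-1}{n-k}$ applied; with `cluster =
"none"` every point is its own cluster and the factor reduces to HC1,
$n/(n-k)$. The slope, intercept and $R^2$ — the quantities one compares —
are unaffected by the SE flavour. Clustering defaults to study rather than
study × stratum, since the dependence to be absorbed is multiple outcomes
from one data source; both are available through the points' `study_id`
column. $R^2$ is reported only for the intercept-included fit; the
no-intercept variant ($\hat\beta_1 = \sum XY / \sum X^2$) reports an
*uncentered* $R^2$ under its own name, since the centered statistic is not
bounded in $[0,1]$ without an intercept.

## What the synthetic fixtures emulate — and what they do not

`make_toy_study()` closes the loop: observed endpoint values are the
model's own pooled predictions perturbed by a known multiplicative bias and
lognormal noise, so the true concordance of the generated points is known
by construction (bias $b$ with no noise gives a no-intercept slope of
exactly $1/b$; bias 1 gives the identity). `make_synthetic_points()` draws
$X$ uniformly and sets $Y = \beta_0^* + \beta_1^* X + \varepsilon$,
truncated to $[0,1]$ with a per-point truncation flag so exact-recovery
tests can drop censored rows. Fixture biomarkers span plausible T2DM
ranges (HbA1c 6–11%, SBP 120–170 mmHg) purely for realism.

Passing these tests demonstrates that the arithmetic of the engine and the
statistics is right: probabilities conserved, incidences monotone, the
regression recovering known truth. It does *not* show that the synthetic
coefficients predict real patients — that is precisely what the external
validation against transcribed published endpoints is for, and it requires
the real coefficient bundles and the per-endpoint observed table, neither
of which ships with the package.

## Numerical choices and problem sizes

Probabilities are computed via `expm1`/`log1p` to keep tiny hazards exact;
row-stochasticity and occupancy conservation are enforced to $10^{-12}$;
the engine is compared to a straight-line per-year oracle at $10^{-12}$
relative tolerance over 15–20-year horizons; OLS is checked against the
closed-form normal equations at $10^{-10}$. The test suite runs 200-seed
replicates (n = 120–167 points each) for slope-recovery coverage and
unbiasedness — sizes chosen so each property check completes in seconds
while estimating the coverage rate to about one percentage point. Seeded
fixtures save and restore the caller's RNG state, so generation is
bit-reproducible without side effects.

## Known limitations

* Cohort-mean covariates inside non-linear equations bias event rates
  relative to integrating over the patient distribution; simulating
  gender × smoking (and, where data allow, age) subgroups mitigates but
  does not remove this. No distributional integration is attempted.
* Organs progress independently given shared covariates; cross-organ
  coupling (e.g. nephropathy raising CVD risk beyond shared biomarkers) is
  not modelled except through equations that include albuminuria or eGFR
  covariates.
* Regression and remission transitions, acute episodes, and eye-level
  versus person-level retinopathy distinctions are out of scope.
* Costs, utilities, treatment intensification to HbA1c goals and
  probabilistic sensitivity analysis are outside this package's scope —
  it is the outcomes engine and its validation harness only.
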