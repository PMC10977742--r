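---
title: "A ten-state Markov model of BMI-category dynamics and type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A ten-state Markov model of BMI-category dynamics and type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bmidiab` implements a continuous-time Markov model of adult weight dynamics
and type 2 diabetes onset. The living state space crosses five BMI
categories — normal weight (< 25 kg/m²), overweight (25–30), obesity classes
I (30–35), II (35–40) and III (≥ 40) — with diabetes status, giving ten
states. Direct transitions move one BMI category up or down (diabetes status
unchanged) or from non-diabetic to diabetic within a BMI category. Diabetes
is absorbing: long-term sustained remission is a marginal event at
population scale, so no diabetic-to-non-diabetic transition exists.

Transition intensities are piecewise constant in age and calendar time and
follow a proportional-hazards structure,

$$ q_{rs}(t) = q_{rs}^{(0)} \exp\{\beta^\top x(t)\}, $$

with baseline intensities $q^{(0)}$ referring to men aged 50 and over before
calendar year 1995, and covariates sex, age class (< 25, 25–49, ≥ 50) and
calendar period (before 1995, 1995–2004, 2005 onwards). To keep the model
identifiable and parsimonious, rates are shared: one progression intensity
for OW→OBI, OBI→OBII and OBII→OBIII; one regression intensity for the three
obesity regressions (overweight→normal has its own); one diabetes-onset
intensity for obesity II and III; covariate effects are shared across each
of these groups, all regressions (including OW→NW) carry a single covariate
group, and BMI transitions are identical with and without diabetes. Diabetes
onset carries a single age effect (< 50 vs ≥ 50) shared across BMI
categories. That yields 8 baseline intensities and 19 hazard ratios — 27
free parameters (`make_params()`, `pack_params()`).

Two biological activation rules complete the intensity structure: the
diabetes-onset intensity is exactly zero before age 25 in overweight/obese
states and before age 40 in normal weight, encoded directly in the generator
(`build_intensity_matrix()`) so that one segmented matrix-exponential
product handles all time-inhomogeneity. BMI progression starts at age 3,
everyone normal weight and non-diabetic at that origin.

### Conventions

Printed rates such as 4.80% are interpreted as transition *intensities* per
person-year (0.0480/yr), not annual probabilities: probabilities would not
compose over observation intervals, while intensities define a proper
generator whose interval transition matrix is `expm(Q t)`. Ages are whole
years (`age = year − birth_year`); age intervals are half-open `[a, b)`;
period boundaries sit at January 1 of 1995 and 2005; the 2005–2014 period is
carried forward indefinitely for projections, reflecting the assumption that
recent trends continue. Survey data carry only years, so mid-year effects
are ignored. Periods are evaluated at exact calendar dates (converted to
ages per birth cohort), not at interval midpoints — the data do not resolve
anything finer.

## Estimation from interval-censored panel data

Each survey respondent contributes one interval: normal weight,
non-diabetic at age 3, and the observed state at the survey age. The
likelihood is the product over respondents of
$P[\mathrm{NW} \to s_{\mathrm{obs}}](3, a_{\mathrm{obs}})$, where $P$ is the
product of segment matrix exponentials over the constant-covariate segments
of `make_segments()`. Respondents sharing sex, birth year and survey year
share that matrix product, and distinct (generator, duration) pairs are
exponentiated once per likelihood evaluation — the caching that makes
desk-scale fitting feasible (a survey of 10,000 respondents collapses to
roughly 1,300 observation keys and a few hundred distinct exponentials;
one likelihood evaluation costs ~20 ms).

`fit_model()` maximises the likelihood over the 27 log-scale parameters with
BFGS, starting from 0.01/yr baselines and unit hazard ratios. Standard
errors come from the inverse observed information (central-difference
Hessian); confidence intervals are log-normal. Mortality is deliberately
absent from estimation: the survey observes survivors only, and mortality
enters the analysis in the projection step.

### What is (and is not) identified at desk scale

With single intervals all starting at age 3, age, period and cohort effects
are entangled; the reference cell (men ≥ 50 before 1995) is populated only
through the late-life person-time of the oldest cohorts. At n = 10,000 the
likelihood develops a flat ridge along baseline × age-HR trade-offs:
profile-level intensities (the identified functionals) are recovered to
sampling noise, while the decomposition into baseline and age hazard ratios
carries log-scale standard errors of 0.2–0.6, occasionally larger, and
near-equal local optima can sit ~1 log-likelihood unit apart. Recovery tests
therefore compare estimates to the generating truth *relative to the fit's
own standard errors*, and fitted baselines should be read jointly with their
age hazard ratios. At the scale of the original survey (~98,000 records) the
ridge tightens by an order of magnitude.

`fit_model()` flags parameter groups without data support (no diabetic
observations, no exposure to a period, a single sex) rather than failing.

## The synthetic survey generator

`generate_panel()` emulates the structure of the French biennial health
surveys (ESPS): nine waves 1998–2014, ages 15–90 with mean 44.7 and SD 18.7
(truncated normal, the published moments), 51.5% men, one observation per
respondent. Trajectories are simulated exactly (competing exponential
clocks per covariate segment, `sim_endpoints_cpp`), so the generator and
the likelihood share no numerical machinery beyond the generator matrices
themselves; agreement between simulated endpoint frequencies and
`transition_probability()` is itself a two-route check. A configurable
0.1% of under-40 normal-weight respondents declare non-type-2 diabetes to
exercise the cleaning rule. Mortality thinning is off by default so that
parameter-recovery experiments are unbiased (matching the estimation step,
which ignores death); an optional life-table thinning flag exists for
realism studies.

What the generator does *not* emulate: household sampling design and
weights, non-response, self-report measurement error, repeated appearances
of individuals across waves, and the true (unpublished) joint birth-year ×
age distribution. Passing recovery tests therefore demonstrates correctness
of the likelihood and optimizer under the model, not robustness to survey
artefacts.

The synthetic life table is Gompertz, $q(a) = 1 - e^{-\alpha e^{\beta a}}$
with defaults $\alpha = 2\times10^{-5}$, $\beta = 0.095$ (life expectancy
≈ 83 years; a 0.7 multiplier on $\alpha$ for women adds ≈ 4 years), constant
across calendar years. Cohort sizes default to a constant 800,000 births a
year. These are deliberately simple stand-ins for national tables: the
pipeline's *numbers* under them are not the published French prevalences,
but its *contrasts* (scenario effects, relative changes, lifetime-risk
orderings) reproduce the published behaviour, which is what the tests
assert.

## Projection and scenarios

`project_cohorts()` advances every birth cohort needed for the requested
years in annual steps through an 11-state generator (10 living states plus
absorbing death), with death intensity $-\log(1 - q_x)$ times a per-state
mortality hazard ratio. Annual stepping matches the life table's resolution;
the $O(\Delta t^2)$ splitting error of freezing covariates and mortality
within a year is far below the uncertainties that matter here. The per-state
mortality ratios default to 1 (no excess mortality) and live in
configuration: the published analysis used literature values from its
supplementary material that are not printed in the main text. Prevalence
denominators are the living population aged 18 and over by default. Cohorts
enter at age 3 at full size (child mortality before 3 is ignored — it
affects numerator and denominator alike).

A scenario (`scenario_spec()`) multiplies all move-up intensities by
$1-\delta$ and all move-down intensities by $1+\gamma$ from a start year
(default 2022), leaving diabetes onset and mortality untouched. The
published configurations are `standard_scenarios()`: a 22% move-up decrease
(scenario 1), a 33% move-down increase (scenario 2), and their combination
(scenario 3). `find_required_change()` inverts the monotone lever →
prevalence map by bisection (tolerance 0.1 percentage point of prevalence);
`scenario_grid()` emits the full $(\delta, \gamma)$ surface with relative
reductions against both the base-year prevalence and the status-quo
end-year prevalence, since published surfaces can be read against either
baseline.

## Lifetime risk

`lifetime_risk()` augments the chain with two absorbing death states (death
with and without prior diabetes) and reports the terminal mass of "ever
diabetic" at age 110 for an individual alive and non-diabetic at the start
(default age 25 in 2022), conditioning on that start rather than on cohort
survival from birth. Period effects stay at their 2005-onward levels for all
future years; mortality beyond the life table's last calendar year is
extrapolated at that year's hazards, and the residual living mass at the
horizon is negligible (of order 10⁻³ at age 110 under the default synthetic
table, and vanishing if the horizon is pushed past the table's last age). The
`constrain_bmi = TRUE` variant zeroes all BMI transitions, giving the
"remaining in their category all their life" risk.
`population_lifetime_risk()` mixes per-category risks over a starting
distribution such as the projected 2022 distribution of 25-year-olds
(`reference_start_distribution()`; the printed men's shares total 100.1%
through rounding and are renormalized).

## Numerical choices

* Matrix exponentials use scaling-and-squaring (Padé) via RcppArmadillo;
  the test suite cross-checks them against an independent uniformization
  implementation and Monte-Carlo simulation.
* The likelihood rejects (as $-\infty$) any parameter point whose segment
  products leave $[0,1]$ — for extreme intensities the exponential loses
  validity before it loses finiteness — and the optimizer additionally
  works inside $|\log \theta| \le 20$.
* Structurally impossible observations (probability 0) contribute
  $-\infty$ and are reported with their observation keys.
* Zero-probability ties in simulation (total exit rate 0) simply hold the
  state to the segment end.
* Degenerate inputs: a zero-length observation interval yields the identity
  matrix; an empty stratum is omitted from goodness-of-fit tables; a
  non-bracketing objective in `find_required_change()` returns a boundary
  report instead of an error.

## Problem sizes used by the tests

The packaged experiments run at desk scale, chosen so the full suite and
the acceptance script complete comfortably on one CPU: recovery fits use
n = 10,000 synthetic respondents (the acceptance experiment's sample size),
supporting tests use 400–4,000; Monte-Carlo oracles use 10⁴–10⁶ replicates;
projections in tests cover 2022–2025/2027 with cohorts back to the 1910s–
1930s. None of these sizes is a statement about the method's limits — the
likelihood cost is governed by distinct observation keys, not records, so
survey-scale data fit in the same time.

## Limitations

BMI is categorical (no within-category drift); transitions never skip a
category; diabetes has no remission; estimation ignores mortality-driven
selection of survey respondents (as the two-step design implies); the
synthetic mortality and cohort tables are stand-ins, so absolute projected
prevalences differ from the published French figures even at the published
parameter values; and the fitted model should only be interpreted for ages
15 and over, the range the surveys observe.
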