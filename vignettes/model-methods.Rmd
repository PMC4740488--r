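---
title: "Model and methods: MRI-guided thrombolysis for wake-up stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: MRI-guided thrombolysis for wake-up stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wakeupcea)
```

## The decision problem

Thrombolysis with tissue-type plasminogen activator (tPA) is recommended for
acute ischemic stroke only within 4.5 hours of onset. For the roughly one in
five ischemic strokes first noticed on awakening ("wake-up strokes"), the
onset time is unknown and guidelines withhold tPA. A DWI-FLAIR mismatch on
MRI — a lesion visible on diffusion-weighted imaging but not yet on FLAIR —
is an imperfect marker that the stroke is younger than 4.5 hours. This
package implements a micro-simulation that weighs an MRI-based treat-on-
mismatch rule against the status quo of no treatment, in health
(modified Rankin Scale outcomes, quality-adjusted life years) and cost
(2013 US dollars) terms.

## Model structure

Each simulated patient passes through three stages.

**Onset and delays.** A true onset age at wake is drawn as
`sleep_minutes × B`, where `B` is the *fraction of sleep remaining* at
onset: uniform on [0, 1] in the base case, or a beta distribution in
scenario analyses. Note the axis: small fractions mean onset close to wake
time, so Beta(3, 5) (mean 3/8) is skewed *toward* wake. Treatment, if any,
starts after a delay chain of wake-to-hospital (51 min), door-to-needle
(77 min) and additional MRI acquisition/interpretation time (30 min) —
158 min in total. With uniform onset over 8 h of sleep, the fraction of
patients whose onset age at treatment start is below 270 min is
`(270 − 158)/480 = 23.3%` in closed form; `prob_onset_age_below()` and
`band_probabilities()` expose these closed forms as deterministic oracles
against which the Monte-Carlo path is tested. The base case uses fixed
(expected-value) delays; a stochastic mode draws gamma delays anchored at
the base mean with dispersion matched to the reported interquartile range
by root-finding on the shape (see *Numerical choices*).

**Acute outcome.** The mismatch test is positive with probability equal to
its sensitivity (0.62) for truly early strokes (onset age at treatment
< 270 min) and `1 − specificity` (1 − 0.78) otherwise; positives are
treated. Every patient draws an mRS category (0–6). Untreated patients use
the untreated-arm outcome distribution, whose favorable (mRS 0–1) mass is
0.451. For treated patients the favorable probability is transformed on the
odds scale, `p' = OR·o/(1 + OR·o)` with `o = p/(1 − p)`, using the odds
ratio of the time band containing their onset age at treatment: 1.75
(0–180 min), 1.26 (181–270), 1.00 (271–360). Onset-to-treatment times can
exceed 360 min (up to 638 min in the 8-hour scenario); the schedule extends
the boundary value 1.00 indefinitely, which is what reproduces the
scenario-level favorable-outcome shares. The odds ratio applies to the
*untreated* favorable mass (the trial contrasts are tPA vs control); the
treated arm's distribution only supplies the conditional splits within
{0, 1} and {2..6}. Symptomatic intracranial hemorrhage is not an explicit
patient-level event — its sequelae are embedded in the treated-arm mRS
distribution — but `population_sich_increase()` provides the
population-level side calculation (wake-up share × treated share × sICH
rate among treated).

**Lifetime Markov model.** Survivors enter an annual-cycle state-transition
model over mRS 0–5 plus death. Each cycle: recurrent stroke with
probability 0.051, fatal in 19% of cases, survivors moving to a worse
living state with equal probability (mRS 5 has no worse living state and
stays); otherwise background non-stroke death from the life table with the
state's hazard ratio (1, 1, 1.11, 1.27, 1.71, 2.37 for mRS 0–5) applied on
the hazard scale, `q' = 1 − (1 − q)^HR`, which keeps probabilities valid at
high ages. Living states accrue their utility (0.8, 0.8, 0.65, 0.5, 0.35,
0.2) and annual cost ($5,293 for mRS 0–3, $13,557 for mRS 4–5, plus $20,079
per recurrence). Cycle *t* is discounted by `1.03^−t`; acute-phase costs
(hospitalization $11,462 untreated / $18,182 treated, MRI $488 under the
MRI strategy) are added undiscounted at entry.

## Design choices where the design was open

* **Event order within a cycle** — recurrence is resolved before background
  mortality. The model's sources do not pin this down; the order is fixed
  for determinism, and because fatal recurrence replaces (rather than
  stacks with) background mortality in that cycle, the recurrent-stroke
  case fatality is interpreted as "death within the year of recurrence".
* **Accrual at death** — patients dying in a cycle accrue that full cycle's
  utility and cost (`simulation$cycle_accrual = "full"`); `"none"` is
  available as a switch. No half-cycle correction is applied, mirroring
  common micro-simulation defaults.
* **Eligibility is evaluated at treatment start**, i.e. onset age at wake
  plus the full 158-min chain — not at hospital arrival. Only this reading
  reproduces the scenario eligibility fractions (23.3% / 31.1% / 46.7% in
  closed form for 8/6/4-hour sleep); arrival-time evaluation would give
  45.6% for the 8-hour case and is rejected.
* **Door-to-needle composition** — some summaries quote a single 103-min
  door-to-needle figure that already includes the MRI time. The default
  here keeps the two components separate (77 + 30 = 107 min total
  in-hospital), which is the only composition consistent with the
  eligibility closed forms above. The alternative reading is available via
  the configuration file (`door_to_needle_minutes: 73`).
* **Common random numbers (CRN)** are on by default for strategy
  comparisons: both arms share the onset/delay draws, the latent uniform
  behind the diagnostic test, the uniform behind the mRS draw, and the
  lifetime stream (per-cycle uniforms are drawn for the whole cohort so the
  arms stay aligned even when survival differs). Marginal distributions are
  untouched; only the variance of the deltas shrinks. `crn = FALSE`
  restores independent arms.

## Synthetic inputs and what they imply

Two inputs required by the lifetime model are not reproducible from public
summaries and are shipped as declared synthetic stand-ins (provenance
`"synthetic"`, surfaced in run manifests):

* **mRS outcome vectors** (`placeholder_mrs_distribution()`): calibrated
  only in the untreated favorable aggregate (0.451); mass over mRS 2–6
  follows a fixed declining 5:4:3:2:1 scheme and the treated arm equals the
  untreated arm. Every acute-phase result reported by the package depends
  only on the favorable aggregate and the conditional splits, not on the
  placeholder's tail shape.
* **Life table** (`synthesize_life_table()`): Gompertz–Makeham, annual
  death probability `1 − exp(−(a + b·c^age))` with defaults a = 2·10⁻⁴,
  b = 3·10⁻⁵, c = 1.1, identical sex columns, capped at age 110. These
  produce a plausible survival curve for a 65-year-old cohort.

Consequently the *absolute* lifetime outputs (life years, QALYs, costs, and
therefore full-simulation ICERs, tornado endpoints, the PSA acceptability
percentages and the specificity frontier value) are internally consistent
but not comparable to any published absolute figures; the acute-phase
percentages and all arithmetic/structural properties are. The test suite
takes exactly this stance: scenario percentages are checked against closed
forms, while the lifetime machinery is checked by properties — a
deterministic cohort-expectation engine (`cohort_expectation()`, a
transition-matrix product with the same event semantics) must agree with
the Monte-Carlo engine within 0.5%, a no-mortality configuration must
reproduce the discounted-annuity closed form exactly, CEAC curves must be
complementary, and the threshold search must bracket its sign flip.

## Sensitivity-analysis apparatus

`psa_default_spec()` lists every uncertain parameter with its family and
range. Fitting (`fit_psa_distribution()`):

* **gamma** (costs, times): mean anchored at the base value, shape chosen by
  root-finding so the ratio of the two central quantiles matches the stated
  range (95% interval, or IQR for the two timing rows reported as IQRs).
  With the mean anchored, the fitted quantiles reproduce the stated ratio,
  not necessarily the stated endpoints — an over-determined fit otherwise.
* **beta** (probabilities, utilities): mean anchored, concentration chosen
  so the central-interval *width* matches. Some utility rows have base
  values on or outside their stated ranges; there the mean-anchored fit is
  infeasible and the fit falls back to pure two-quantile matching, flagged
  by `anchored_mean = FALSE`.
* **lognormal** (odds and hazard ratios): quantile-matched; the log-scale
  midpoint of the stated interval is the log-median (for the early-window
  OR this midpoint is log 1.7506 ≈ log 1.75, i.e. consistent with the base
  value).
* **dirichlet** (the mRS outcome vector): concentration = base vector × an
  effective sample size of 100 (configurable); drawn jointly and
  independently of the other parameters.

One-way analysis re-runs both strategies at each range endpoint with the
same seed and CRN, so a parameter set to its base value returns the
base-case ICER exactly. The threshold search bisects the sign of the NMB
difference (NMB = wtp × QALYs − cost, wtp $100,000/QALY by default) to a
0.5-unit bracket. The PSA shares one patient stream across draws, so with
an all-fixed specification every draw is identical and the acceptability
curve is a step function.

## Problem sizes and numerical choices

Scenario percentages are simulated at n = 10⁵ patients, at which the
Monte-Carlo standard error of a percentage near 45% is ≈ 0.16 points and
every comparison against a closed form is made at tolerances several times
that. Demonstration analyses in the documentation use smaller cohorts
(10³–10⁴) per evaluation for the iterated analyses (tornado, two-way,
threshold, PSA), each configurable upward. Root-finding tolerances are
10⁻¹⁰ on the transformed scale; band probabilities sum to one within
10⁻¹²; mRS vectors are validated to sum to one within 10⁻¹². ICERs are
only formed when both deltas are positive (or both negative); dominance
and sub-floor QALY differences are carried as labelled markers rather than
divisions.

## Known limitations

* Lifetime absolute values rest on the synthetic life table and mRS
  placeholder above; treat them as internally consistent model output, not
  as estimates transferable to any real cohort.
* tPA contraindications other than onset time, category-specific
  likelihood ratios for more than two onset-age classes, and mechanistic
  circadian onset models are out of scope.
* The recurrence process is stationary (no age or time-since-stroke
  dependence), and recurrent strokes never improve the mRS state.

## A worked base case

```{r base-case}
params <- default_parameters()
cea <- compare_strategies(params, n = 20000, seed = 1)
tidy(cea)[, c("strategy", "pct_mrs01", "pct_treated",
              "pct_inappropriately_treated", "qalys", "cost")]
glance(cea)
```

```{r ceac, fig.width = 6, fig.height = 4}
psa <- run_psa(params, draws = 100, n_per_draw = 2000, seed = 1,
               wtp_grid = seq(0, 2e5, 2e4))
autoplot(psa)
```
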