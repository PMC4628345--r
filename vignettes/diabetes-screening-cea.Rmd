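---
title: "A Markov cohort model for the cost-effectiveness of population-based type 2 diabetes screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of population-based type 2 diabetes screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

## The question the model answers

In 2001 Brazil screened 22.1 million adults aged 40 and over for type 2
diabetes with a single fingerstick capillary glucose test, detecting about
345,000 previously undiagnosed cases. Was that money well spent? `dmscreen`
implements the decision-analytic machinery needed to ask that question of a
one-time population screening program: a Markov cohort model of diabetes
complication progression, a screening front-end that advances the moment of
diagnosis, lifetime discounted cost and QALY accounting, and a one-way
sensitivity / scenario engine. The comparison throughout is *screening vs.
no organized screening*, from the public health care system's perspective,
reported per true case of undiagnosed diabetes.

## Model structure

### Health states

A person with diabetes progresses along five complication tracks, each a
small Markov chain with annual cycles:

* **renal**: normal → microalbuminuria → clinical nephropathy → end-stage
  renal disease (ESRD, absorbing);
* **neuropathy**: normal → peripheral neuropathy → lower-extremity
  amputation (LEA, absorbing);
* **retinal**: normal → photocoagulation → blindness (absorbing);
* **CHD**: none → {angina | history of cardiac arrest / myocardial
  infarction}, fed by a Weibull incidence function of time since diabetes
  onset, `CHD(t) = [F(t) − F(t−1)] / [1 − F(t−1)]`;
* **stroke**: none → first-year post-stroke → post-stroke history, fed by
  an annual first-stroke probability by age, sex and hypertension status
  (a table by default; a Framingham-type risk equation,
  `R10 = 1 − s0^exp(lp)` annualized, is available).

Death is cause-tagged: background mortality from a life table, stroke case
fatality (0.142 immediately, 0.092 in the first year), CA/MI case fatality,
and an ESRD excess mortality.

### The factorized cohort engine

Cross-track interactions enter only through shared covariates (age, sex,
hypertension, treatment status, disease duration) and through survival.
Conditional on being alive, the five track distributions therefore remain
independent, and the joint occupancy over the 324 compound states is the
product of the per-track marginals with the alive mass. The engine exploits
this: each stratum carries an alive scalar plus five small marginal vectors,
and each cycle applies (1) background mortality, (2) acute events with case
fatality — the per-track death exits multiply into a joint survival factor —
and (3) chronic one-step track transitions. This is exact for this model
structure, not an approximation; the test suite checks it against an
individual-level Monte Carlo simulation of the same joint model at
n = 10^6 (agreement within three standard errors), and mass is conserved to
1e-12 every cycle.

Cycle-order conventions: mortality acts on start-of-cycle occupancy; a track
advances at most one state per cycle, with flows computed from start-of-step
occupancy; costs and QALYs accrue on end-of-cycle occupancy. No half-cycle
correction is applied.

### Duration bands run on disease duration

The nephropathy→ESRD and neuropathy→LEA probabilities are banded by years
in disease (e.g. 0.004/yr in the first band rising to 0.074/yr after
20 years). The engine indexes these bands by **years since onset**, not
years since diagnosis. The distinction matters only when diagnosis moves:
indexing by the diagnosis date would make earlier detection *advance the
band clock itself*, mechanically increasing late-stage incidence in the
screened arm — a pure lead-time artifact in which detection looks harmful
while the underlying biology is unchanged. The band gradients are
disease-duration gradients in their source cohorts, so the duration clock is
the faithful reading. The lookup API (`transition_prob()`) is unchanged: it
takes completed years within the band.

## Screening and the onset-time convention

Screening is a one-time event at cycle 0. Undiagnosed cases test positive
with sensitivity 0.68; disease-free persons test positive with probability
1 − 0.89; all positives receive a confirmatory work-up (US\$ 2.97) that
clears false positives, and every screen costs US\$ 1.16. Repeat screening
is deliberately unsupported.

Without screening, clinical diagnosis occurs `lead_time_years` (10) after
onset. The pipeline adopts the screening-module convention that undiagnosed
cases at screening have had diabetes for
`lead_time_years − detection_benefit_years` years (5 in the base case):
detected cases are diagnosed at screening, i.e. `detection_benefit_years`
earlier than they would have been clinically, and screen-missed cases stay
on the clinical clock. The detection-benefit sensitivity analysis therefore
moves the assumed onset time and the advancement jointly — varying "the time
between onset and screening" — which is how the quantity is defined for the
program being modelled. The cohort generator also offers a uniform onset mix
over the whole pre-diagnosis window (`onset_years_at_screening = NULL`) for
population-level uses such as screening-yield calculations.

The pre-screening years are simulated as a burn-in with untreated hazards;
because the stratum mass *is* the prevalence observed alive at screening,
burn-in survival is conditioned away (background mortality cancels exactly;
track-death exits reweight the marginals).

Treatment begins in the diagnosis cycle, in both arms: intensified glycemic
control multiplies the four microvascular hazards
(microalbuminuria, nephropathy, peripheral neuropathy, photocoagulation) by
the configured hazard multipliers (0.70 each, a documented assumption in the
25–35% trial range), with *no* macrovascular effect in the base case; and,
for hypertensives, intensified hypertension control replaces standard
control (the "moderate" vs "tight" probability strata) and reduces stroke
risk by 44% and CHD risk by 13%.

## Economics

Costs fall in six ledgers, all in 2001/2002 US\$, discounted at 5%/yr:
standard diabetes treatment (post-diagnosis), complication costs (one-time
charges on events and annual charges on occupancy, e.g. ESRD US\$ 9,527/yr,
post-stroke care US\$ 462/yr), the screening program itself (cycle 0 only),
incremental intensified control, background medical care (US\$ 94/person/yr
for everyone alive), and a one-time cost of death (US\$ 304). QALYs weight
occupancy by a no-complication baseline utility (0.78) minus additive
per-state decrements, the standard additive-decrement convention for
comorbid states; death is 0. International-dollar figures are obtained as
`US$ × 2.35 / 0.59` (market, then PPP rate); rounding — half away from
zero — happens only at the report layer.

The ICER is the per-case incremental cost over incremental QALYs of
screening vs no screening, with dominance flagged when the deltas disagree
in sign. Screening and confirmation costs of the *entire* screened
population, including the disease-free majority and false-positive
work-ups, are amortized over the true cases.

## What the shipped fixture is — and is not

`brazil_params()` loads `inst/extdata/brazil_2001.yaml`. The transition
probabilities, test characteristics, complication costs, background care and
death costs, discount and currency rates are the published program inputs.
Several internals of the original simulation model were never published, so
the fixture carries documented assumptions (flagged in its `meta` block):

* utility weights (baseline 0.78; e.g. ESRD 0.51, blindness 0.55) — chosen
  at plausible levels low enough that a +20% sensitivity scaling keeps every
  weight below 1;
* the Weibull CHD model (shape 1.2, scale 45y: a duration-rising hazard
  of roughly 1.5–2.5%/yr) and the CA/MI event split (50% of CHD events,
  case fatality 0.30, 40% of deaths without hospitalization);
* the synthetic stroke table (log-linear in age, sex-specific, ×1.9 for
  hypertension);
* ESRD excess mortality 0.18/yr (dialysis-era survival), structurally
  necessary: without it, ESRD person-years at US\$ 9,527/yr dominate every
  ledger;
* treatment costs: standard glycemic care US\$ 80/yr rising to 200/yr
  after ten years since diagnosis (the oral-agents-to-insulin escalation),
  intensified *incremental* cost 180/yr narrowing to 60/yr (intensive
  control front-loads drugs and monitoring that standard care later adopts),
  and US\$ 24/yr incremental intensified hypertension control;
* the hypertension-conditional undiagnosed-diabetes prevalence ratio (1.6).

These assumptions were set once, to place the base case in the reported
regime — incremental cost dominated by earlier treatment, with complication
savings a partial offset — and frozen. Consequences of this honesty:
absolute magnitudes (the ICER level, cumulative incidence levels, Table-5
style totals) are *not* comparable to the original publication figure by
figure, and the package does not pretend otherwise. What is reproducible,
and tested, is the arithmetic printed in the publication (ICER algebra, PPP
conversions, cost per case, the WHO threshold) and the directional behavior
of the whole apparatus.

## The synthetic cohort

`generate_cohort()` emulates the screening-eligible population: five-year
entry bands 40–79 with geometrically declining weights, a 52/48 female/male
split, and the published prevalence surfaces for undiagnosed diabetes,
hypertension, smoking and hypercholesterolemia (step-interpolated onto model
ages; the hypertension band starting at 35 covers ages 40–44). Expected mode
partitions mass exactly by prevalence products; sampled mode draws a
multinomial reproducibly from a seed. Smoking and hypercholesterolemia ride
along as stratum fractions and enter only the stroke risk equation (exactly,
by mixture over the binary combinations). What the generator does *not*
emulate: household or geographic structure, participation behavior,
secular trends, or correlation between risk factors beyond the
hypertension-diabetes ratio — so passing tests say nothing about those
features of real data.

`generate_life_table()` provides a Gompertz stand-in for the national life
table (`q(a) = 1 − exp(−level·e^{slope·a})`, absorbing at 99).
`estimate_incidence_from_prevalence()` re-implements the standard
illness-death inversion used to derive incidence from prevalence surveys;
it is the exact inverse of `project_prevalence()`, and the tests verify the
round trip to 1e-8.

## Numerical choices

* Expected-value cohorts are deterministic; every stochastic path (sampled
  cohorts, the Monte Carlo oracle) takes an explicit seed.
* Simulation stops at an age cap of 95 or when alive mass falls below
  1e-12.
* Ages, onset years and cycle counters are integers; band lookups use
  completed years, half-open at band edges (`0–11` covers completed years
  0 through 11).
* Probabilities out of `[0, 1]`, utilities above the baseline, negative
  costs and non-covering band systems are rejected at load time with the
  offending key named.
* Problem sizes used by the shipped tests: expected-mode cohorts of 10^4 to
  10^5 (per-case results are invariant to the size), Monte Carlo
  cross-checks at n = 10^6, the full 19-scenario battery in a single run.

## Known limitations

* **Detection-benefit response.** The published sensitivity table shows the
  ICER *falling* as the detection benefit grows. With treatment effects
  expressed as constant hazard multipliers — the scope of this package —
  extending the early-treatment window always adds the youngest
  disease-duration years, which carry the lowest CHD and stroke hazards, so
  the QALY response is concave while incremental treatment cost stays
  roughly linear: the model yields a mildly *rising* ICER in the benefit.
  Reproducing the published direction appears to require the cumulative
  glycemic-burden machinery of the original model, which is out of scope
  here. The corresponding acceptance check is left failing rather than
  papered over, and `delta_qaly` is verified to increase in the benefit.
* One screening round only; periodic re-screening is not modelled.
* No statin treatment, no participation/uptake model, no labelling
  disutility for false positives (they are cleared at confirmation and
  charged only the work-up).
* Recurrent events are not modelled: one stroke, one CA/MI, and absorbing
  end-states per track.
* The additive utility-decrement combination can, in principle, understate
  utility for extreme comorbidity profiles; with the shipped decrements the
  sum stays below the baseline for all plausible occupancies.
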