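---
title: "A deterministic benefit–harm model of organized mammographic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic benefit–harm model of organized mammographic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenqaly)
```

## The model

`screenqaly` compares two hypothetical cohorts of 100,000 women followed from
age 50: one invited to organized biennial mammographic screening between ages
50 and 69, one not invited. Both cohorts evolve on a discrete annual grid
under competing breast-cancer and other-cause mortality; all quantities are
real-valued expectations (a deterministic cohort life table, not a
microsimulation). The balance of screening is expressed in
quality-adjusted life years (QALYs):

$$\text{net QALYs} = \text{LYG} \times \text{mortality transfer}
  - \text{HUV losses} + \text{HUV gains},$$

where LYG is the difference in person-years lived between the two cohorts,
HUV losses accrue from false-positive screening results and from treating
overdiagnosed cancers, and HUV gains come from the less aggressive treatment
of cancers detected at an earlier stage.

### Cohort projection

Annual breast-cancer mortality, other-cause mortality and breast-cancer
incidence probabilities are obtained from rates per 100,000 women-years by
direct division; no exponential transform is applied because the rates are
small (at most a few percent) and the arithmetic elsewhere in the model is
population-rate based. Other-cause mortality is all-cause minus
breast-cancer mortality, clamped at zero with a warning should a noisy input
make the difference negative.

Within each annual cycle deaths are applied first; new breast-cancer cases
then arise from the surviving never-diagnosed pool. The alternative order
(incidence first) changes incident-case counts by well under one percent at
these rates; the chosen order is fixed so that runs are exactly reproducible
and documented. Person-years for an age-year use the trapezoidal convention
`(n_alive(a) + n_alive(a+1))/2`; a start-of-year convention is selectable via
`person_years_convention` in `project_cohort()`.

Women whose breast-cancer death is averted (and overdiagnosed women) are not
tracked as a separate compartment: they simply remain in the cohort and die
at other-cause rates, which is exactly what the two-cohort difference plus
the never-diagnosed pool encodes.

### Screening benefit

Screening reduces breast-cancer mortality proportionally on a per-age basis
through a *reduction curve* `r(a)`. Two shapes are supported:

* `trapezium_curve(max)`: zero at age 50, rising linearly to the maximum at
  age 56, flat through 71, declining to zero at 75. Published descriptions of
  this shape sometimes speak of a plateau over ages 55–70 and sometimes of
  knots at 56 and 71; the knots take precedence here and all four are
  configurable arguments.
* `read_reduction_curve(path)`: any tabulated `age,reduction` curve, linearly
  interpolated between tabulated ages and zero outside them — the route by
  which microsimulation-derived curves (which extend the effect past age 75)
  enter the model. The bundled file of this kind contains invented
  placeholder values for format testing only, and scenarios built on it
  refuse to run unless placeholders are explicitly allowed.

The *mortality transfer* (default 0.8) is the proportion of the
breast-cancer-specific gain that survives as an all-cause mortality gain —
less than one when, for example, radiation therapy adds cardiac and
lung-cancer deaths. It multiplies total (and per-age) LYG as a scalar; it
deliberately does not modify mortality rates, matching the net-QALY formula
above.

A flat maximum of 40% over the screening ages translates into a much smaller
*total* reduction (prevented breast-cancer deaths over all ages 50–85 divided
by baseline breast-cancer deaths), because deaths after the curve's support
are unaffected; `total_mortality_reduction()` reports this number.

### Harms

**False positives.** Two counting methods are provided. The per-round method
takes 4.5% of first-round and 2.5% of consecutive-round examinations with
75% attendance; the cumulative method applies an observed risk of 0.147
false positives per woman invited at 50, allocated across rounds in
proportion to the numbers screened (the data behind the cumulative figure
are per-woman totals, so the allocation is a modelling convention — total
losses are invariant to it). Each false positive costs the time integral of
its health-utility decrement: 0.025 for the first month, then 0.0125 for the
remainder of three years, i.e. `0.025/12 + 0.0125*35/12 = 0.0385417` QALYs.
A 37-month reading ("three years *after* the first month") is selectable.
False-positive losses are not survival-weighted by default — recall ages are
45+ years before the relevant mortality, and the effect is below 1% — but a
`truncate` flag enables it.

**Overdiagnosis.** The default model keeps the non-overdiagnosed incidence
fixed at its pre-screening level and declares a fixed proportion OdP of all
screen-detected cancers (including the added ones) overdiagnosed. Solving
`O = OdP (S + O)` gives `O = OdP·S/(1−OdP)` per age — convex and superlinear
in OdP, which is why doubling the assumed OdP more than doubles the
overdiagnosed count. Two alternatives are provided: proportionality to the
pre-screening incidence itself, and separate proportions of screen-detected
DCIS and invasive cancers (which collapses to the default when the two
proportions are equal). Each overdiagnosed woman accrues the expected
treatment harm of the overdiagnosed-treatment mix (0.4712 HUV over 10 years
under the bundled registry) spread over a 10-year yearly profile,
survival-weighted on other-cause mortality and truncated at the follow-up
horizon. The profile's yearly shape is uniform by default because only
10-year cumulative harms are published with precision; a front-loaded
geometric shape (ratio 0.7) is available, and only truncation-sensitive
results depend on this choice.

The screen-detected base `S` comes, by default, from incident cases times a
screen-detected share (`sd_share`, default 0.6375 = attendance 0.75 ×
episode sensitivity 0.85, the value implied by the synthetic generator's
defaults and re-derivable from generated histories). The alternative source —
0.6% of examinations at each round — is retained, but over ten rounds it
implies more screen-detected cancers than the entire baseline incidence of
the screening ages, so it cannot be combined with the fixed-incidence
overdiagnosis constraint; it is kept for harm accounting that does not need
that constraint.

### Less aggressive treatment

Non-overdiagnosed screen-detected cases gain the difference between the
expected 10-year treatment harm of their counterfactual (symptomatic)
presentation and their actual (screen-detected) one. Cases split into three
benefiting groups: DCIS that would have stayed DCIS (sized by the DCIS share
among interval cancers, 5–7%, default midpoint 6% — a proxy, since the DCIS
share of symptomatic cancers is unobservable), DCIS that would have
presented invasive (the remainder of the 19% screen-detected DCIS share),
and invasive cancers treated earlier. Accrual uses the same
survival-weighting and truncation as overdiagnosis harm, so the two sides of
the treatment ledger are symmetric. Negative per-case gains are permitted
and reported, not silenced.

The four detection-mode-by-histology treatment mixes default to synthetic
stand-ins (registry distributions are not public): screen-detected invasive
cancers receive systemic therapy less often than symptomatic ones, and DCIS
is treated almost exclusively surgically. Every mix is overridable.

## Scenarios, outputs and sensitivity analysis

`model_a()` (trapezium 40%, OdP 15%), `model_b()` (trapezium 20%, OdP 50%)
and `model_miscan()` (tabulated curve and age-specific OdP) share an 80%
transfer and follow-up to 85. The per-scenario false-positive methods follow
the pattern of published per-scenario losses (cumulative for the first two,
per-round for the third), which conflicts with one published assumption
table; a different `fp_model` can be passed to any preset.

`run_scenario()` returns a per-age ledger obeying
`net(a) = lyg_transferred(a) − fp_loss(a) − od_loss(a) + treatment_gain(a)`
exactly at every age, its cumulative trajectory, and the *turning age*: the
first age at which cumulative net QALYs become and remain non-negative
(robust to non-monotone toys; identical to the first crossing on the
monotone-after-crossing trajectories the model actually produces).
`tornado_sweep()` re-runs a scenario with one parameter at a time moved to
its bounds; `horizon_extension()` differs two runs in the follow-up horizon,
which requires rate schedules covering the extended ages —
`extend_schedule()` holds the last published rate constant for that purpose,
an assumption the user accepts explicitly. No discounting is implemented
anywhere, and no discount parameter is exposed.

## The synthetic-history generator

`generate_histories()` emulates the individual-level data of an organized
screening program: biennial invitations, Bernoulli attendance at 75%,
first/consecutive-round false-positive draws, cancer onset from the baseline
incidence schedule, detection-mode assignment, histology, treatment-regimen
draws, and optional competing mortality. Every data-derived model input —
cumulative false-positive risk per invitee, screen-detected share,
DCIS shares, treatment mixes — is re-derived empirically from the histories
(`histories_to_inputs()`), so the full pipeline runs with no external data,
and the generator doubles as a stochastic micro-simulation oracle for the
deterministic projection.

Design choices worth noting:

* Cancer onset is driven by the incidence schedule and a detection-mode
  split (screen-detected with probability attendance × episode sensitivity
  0.85 while covered by the program), not by a per-examination detection
  rate. A 0.6%-per-screen draw over ten rounds would exceed the baseline
  incidence it must stay consistent with; tying onset to incidence keeps the
  generator overdiagnosis-free by construction. Episode sensitivity is the
  one generator parameter with no published anchor; 0.85 is a realistic
  value for modern two-view mammography programs.
* Women exit screening after a breast-cancer diagnosis.
* All draws flow from one seed, applied age-by-age over the whole
  population; a run is exactly reproducible for a fixed configuration, but
  changing `n_women` redraws everyone (per-woman random substreams were
  rejected as disproportionate for an oracle).
* The generator emulates event streams, not tumor biology: no tumor growth,
  stage progression, lead-time or calendar-period structure. Agreement
  between generator and deterministic model therefore validates the
  *arithmetic* of the deterministic model, not its epidemiological realism.

## Inputs, problem sizes and reproducibility

The bundled rate tables carry pre-screening (1980–1985) Norwegian
breast-cancer incidence and mortality by five-year age group. The bundled
all-cause mortality file is a clearly labelled *synthetic* Gompertz schedule
(rate `= 100{,}000 \times 0.0026\, e^{0.088(a-50)}`, ages 50–100) calibrated
to generic Norwegian female life-table facts — remaining life expectancy at
50 near 34 years — because the cohort life table used in published analyses
is only available in external supporting material. Headline results with the
synthetic schedule land within about ten percent of published values;
supplying the authoritative table via `read_rate_table()` is the route to
exact reproduction.

The test suite exercises the deterministic model at full scale (100,000
women, ages 50–85 or 50–95 — the model is 36 arithmetic steps, so scale is
free) and the stochastic oracle at 200,000 to 1,000,000 women, sizes at
which Monte-Carlo standard errors are small enough to detect arithmetic
errors while keeping a full run in tens of seconds.

## Limitations

* The model is an expectation calculus: no variance, no individual
  heterogeneity in attendance or risk, no calendar-period effects.
* Overdiagnosis proportions are age-constant in the two simple presets;
  age-specific proportions require a tabulated file.
* Treatment mixes and the all-cause schedule default to synthetic stand-ins
  and are the main sources of deviation from published figures.
* The per-round and cumulative false-positive methods are both faithful to
  their definitions yet imply totals differing by roughly a third; published
  loss figures are consistent with each method in different scenarios, and
  about 1% of the per-round published loss remains unexplained by either
  reading of the decrement profile. The discrepancy is documented rather
  than absorbed into a fitted constant.
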