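---
title: "An early health-economic model of regenerative therapeutics in age-related hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An early health-economic model of regenerative therapeutics in age-related hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arhlce)
```

## The decision problem

Regenerative therapeutics for age-related hearing loss (ARHL) — small
molecules, gene and cell therapies aimed at restoring cochlear hair cells
and their synapses — are in development but not yet on the market. Before
efficacy data exist, early health-technology assessment can bound what such
a therapy could be worth to a payer: how many QALYs and how much cost the
current care pathway leaves on the table (headroom), how that value shrinks
under less-than-perfect efficacy or restricted eligibility (scenarios), and
the maximum price at which the therapy would remain cost-effective
(threshold / ceiling price).

`arhlce` implements this as an annual-cycle Markov cohort model of the UK
NHS hearing-care pathway from a healthcare perspective. A cohort enters at
age 50 and is followed until death (operationalized as a maximum age of
110, which contributes less than 0.1% of discounted totals). Both costs
(2018 GBP) and QALYs are discounted at 3.5% per year, and cost-effectiveness
is expressed as incremental net monetary benefit (iNMB) at a
willingness-to-pay of £20,000/QALY:

$$\mathrm{iNMB} = (Q_n - Q_c)\,\lambda - (C_n - C_c),$$

with \(n\) the novel-therapy strategy and \(c\) current care.

## States and transitions

Eleven mutually exclusive states: normal hearing; mild, moderate, severe
and profound hearing loss, each unaided or with a hearing aid (HA);
profound loss with a cochlear implant (CI); and death. Severity is
PTA-classified and, under standard care, never improves; profound loss is
absorbing among severities. Annual severity transition probabilities come
in three age bands (50–59, 60–69, 70+); the oldest band is applied to all
ages from 70 up, while all-cause mortality varies by single year of age and
competes first in every cycle (every living state moves to death with the
age-specific probability `q`, and follows the severity/pathway composition
otherwise).

Two quirks of the published transition table are handled in
`repair_severity_table()`. The mild-hearing-loss rows print stay
probabilities near 0.09 where every other row's diagonal is near 1 — an
apparent exponent typo, corrected by multiplying the diagonal of any row
whose total mass is below 0.5 by ten. Each row is then renormalized to sum
to one (several printed rows sum to 0.999–1.0004). All repairs are logged
and the log is attached to the parameter object.

### Care-pathway mechanics

The pathway probabilities (HA uptake by severity, CI candidacy for
profound loss, annual HA non-use, annual CI non-use/failure) are treated as
*per-cycle* transition probabilities, the natural reading of a
state-transition matrix over these eleven states:

* every cycle, unaided occupants of a hearing-loss state take up a hearing
  aid with the severity-specific probability (0.30 mild, 0.52 moderate,
  0.71 severe/profound), incurring an evaluation plus device cost
  (binaural/monaural mix);
* profound entrants and unaided profound occupants draw CI candidacy
  (0.60) first — implantation takes precedence over hearing aids;
* HA users abandon the device with the severity-specific annual non-use
  probability (0.13 mild, 0.30 otherwise), returning to the unaided state
  (and may take up an aid again later, which is costed as a new fitting);
* CI users revert to unaided profound loss with probability 0.03 per year
  (non-use or device failure) and stop accruing maintenance.

Both choices are configurable (`settings$uptake_timing = "incident"`
restricts uptake to incident entrants into a severity;
`settings$ha_nonuse = "mixture"` models non-use as a within-state utility
mixture instead of a state flow). We verified that the incident/mixture
variant understates lifetime standard-care costs by roughly half relative
to the published pathway totals, while the per-cycle mechanics reproduce
them; the per-cycle variants are therefore the defaults.

The CI pathway parameters for a contralateral hearing aid (uptake 0.58,
non-use 0.03) are carried in the parameter set but are neutral in this
implementation: the CI state's single utility (0.61) already summarizes
CI-user quality of life, and the costed CI schedule (candidacy, device,
maintenance, upgrades, complications) does not itemize contralateral aids.

## Rewards

Each living state accrues a per-cycle utility
\((1 - p_{FI})\,u_{base} + p_{FI}\,u_{FI}\), mixing the state's base HUI-3
utility with its functional-impairment (FI) utility by the
severity-specific probability of impairment in activities of daily living
(0.18 normal up to 0.26 moderate+). The CI state uses a flat 0.61 with no
FI term. Because non-use is modeled as an explicit flow back to the
unaided states, HA-state occupants accrue the full aided utilities.

Costs combine one-off events (HA fitting £389.90 expected = £54 evaluation
plus the 58%/42% binaural/monaural device mix; assessments not leading to
an aid, £54 for 30% of mild and 5% of moderate+ non-recipients; CI
implantation £34,844 = candidacy £5,308 + device £22,919 + first-year
maintenance £6,617, with a 4% expected major complication at £10,292;
candidacy assessments without implantation at 0.40/0.60 per implant) and
recurring flows (HA aftercare £26/year, CI maintenance £945/year from the
second year, processor upgrades £5,445 at implant anniversaries 5, 10, …).
Hearing aids are replaced after five years of continuous use at the
fitting cost — no replacement interval is published, and aligning it with
the processor-upgrade cadence is the package's calibration choice (set
`costs$ha_refit_interval = 0` to disable). Device "vintages" are tracked
alongside the occupancy vector to time replacements and upgrades; implant
vintages decay exactly (death and device failure), hearing-aid vintages by
the aggregate retention of the HA pool. Normal hearing costs nothing.

**Timing.** Events occur at cycle start; occupancy rewards are measured
post-transition. Cycle 0 holds the entry distribution (all normal hearing
by default — no entry mix is published, and the assumption is exposed in
the configuration) and accrues event costs only; cycles `t >= 1` accrue
utilities and recurring costs discounted by \(1.035^{-t}\). No half-cycle
correction is applied by default (`settings$half_cycle_correction`
switches it on). This convention reproduces the published QALY totals to
within a few percent; including the entry year would overstate them by
roughly one utility-weighted year.

## Mortality

Death probabilities come either from a two-column lifetable (age, annual
probability) or from a Gompertz–Makeham hazard
\(\mu(a) = c + b\,e^{g(a-50)}\) integrated over each year of age. The
bundled default (`c = 2e-4`, `b = 2.252e-3`, `g = 0.1`) was fitted once so
that remaining life expectancy at age 50 is 33.0 years, matching UK
2016–18 national life tables (sexes combined), and is frozen in the
fixture. Hearing loss does not modify mortality.

## The novel therapy

A `therapy_scenario()` is an eligibility set (subset of mild…profound), a
recovery rule, a per-administration response probability, and a
per-administration price. Therapy is administered to each cycle's
*incident* entrants into an eligible severity (and to any cohort members
entering the model with hearing loss), with 100% uptake — the headroom
convention. Responders move per the recovery rule; non-responders continue
into standard-care device uptake and are not re-dosed while they remain at
that severity; anyone progressing again is treated again. Administrations
are counted regardless of response, and each administration carries the
£54 hearing evaluation at presentation (switchable via
`costs$charge_evaluation_on_therapy`) plus the scenario price.

Recovery rules: `to_normal` returns responders to the at-risk
normal-hearing state (re-progression follows the normal row — progression
rates in later years are unaffected by treatment). `back_1` and `back_2`
move responders back exactly one or two severity bands: a two-band
recovery clears a moderate (two-band) deficit to normal, a one-band
recovery leaves severe patients moderate, and so on. A mild deficit has no
intermediate band; its only possible improvement is full restoration,
which the scenario definitions reserve for the full-recovery rule, so mild
responders keep their mild classification under the partial rules. This
reading keeps the partial-recovery scenarios distinct from the headroom
scenario (allowing mild→normal under `back_1` makes them coincide, because
almost all incident hearing loss presents as mild) and reproduces the
published ordering of all six scenarios. A memoryless cohort cannot
distinguish "retreat on any later progression" from dose-limiting
variants; patients with an existing hearing aid who partially recover keep
the device.

## Probabilistic sensitivity analysis

Each PSA draw samples a full parameter set:

* severity transition rows — Dirichlet with concentration `mean × ESS`
  (default ESS 100; structural zeros are preserved exactly, so impossible
  transitions stay impossible);
* pathway probabilities and cost-side proportions — Beta parameterized as
  two-category Dirichlets with the same ESS; functional-impairment
  probabilities, published without standard errors, use an assumed SE of
  0.05;
* utilities — Beta from the published means and SEs; FI and aided
  utilities carry no SEs, so FI values are sampled as decrements below the
  (sampled) base utility and aided values as increments above it, each
  Beta with SE 0.03 (the SE of the mild–severe base utilities). This
  preserves the orderings FI ≤ base and aided ≥ unaided in every draw, so
  every sampled set passes full validation;
* unit costs — Gamma with a 10% coefficient of variation (shape
  `1/cv²`, scale `mean·cv²`); the zero-priced therapy is fixed, as are the
  discount rate and the mortality schedule.

Draws are keyed by `(seed, draw index)`, so strategies evaluated with the
same `psa_spec()` share parameter sets draw for draw (common random
numbers), which removes most Monte-Carlo noise from incremental
quantities. Interval summaries use inclusive linear-interpolation
percentiles (the spreadsheet convention).

The ESS default of 100 is a judgment call — no concentration is published —
and is exposed in `psa_spec()`. The sampled intervals are somewhat wider
than the published ones; means are unaffected.

## Analyses

`run_headroom()` values the perfect therapy (all severities, full
recovery, zero price, efficacy 1) against standard care. `run_scenarios()`
evaluates the six published scenarios against a shared standard-care arm.
`threshold_search()` finds the per-administration price at which the mean
iNMB crosses zero: because price enters each draw's cost linearly (price ×
discounted administrations, with cohort dynamics independent of price),
the search bisects the exact per-draw relation
\(\mathrm{iNMB}(p) = \mathrm{iNMB}(0) - p \bar a_{disc}\) to a £50 iNMB
tolerance, using common random numbers across price evaluations. The root
is defined on the *mean* iNMB, with percentile intervals reported
alongside. Both the per-administration ceiling price and the per-person
lifetime spend (price × mean administrations per person) are reported; the
published per-person figure at 50% efficacy corresponds to the
per-administration quantity (one administration is one treatment course),
which is what the acceptance summary reports.

## Numerical choices and problem sizes

The cohort engine is exact linear algebra on the 11-state occupancy vector
— no sampling — so traces are bit-stable across runs. The test suite
validates it against an independent individual-level microsimulation of
200,000 patient paths through the same matrices, requiring agreement
within binomial sampling error at every cycle and state. Reproduction
checks in the test suite run a 3,000-iteration PSA; the acceptance script
runs the full 10,000. Severity rows are repaired to sum to one within
1e-12; composed transition matrices are validated to row-sums of one
within 1e-10; negative composed probabilities are an internal assertion
error.

## What the model does and does not capture

The synthetic cohort reproduces the published study conditions: all-normal
entry at 50, three-band progression, UK-calibrated mortality, and the
printed pathway, utility and cost tables. It does not model bilateral
implantation, waiting lists, sex differences, hearing-loss-associated
excess mortality, adverse events of the (hypothetical) therapy, or
indirect and societal costs — all outside the published model's scope.
Passing reproduction checks therefore says the implementation matches the
published model's arithmetic under its stated assumptions, not that the
assumptions match any real cohort.

Known limitations: the standard-care QALY level sits slightly above the
published point estimate (about 16.3 vs 15.59, with the published 95%
interval reaching 16.09) while incremental QALYs, costs and savings match;
the discrepancy traces to the published model's implied discounted
life-years being lower than those of a UK-2016–18-calibrated mortality
schedule, and is documented rather than calibrated away. The published gap
between the one-state and two-state recovery scenarios is reproduced
through the exact-band recovery reading described above; the underlying
dose-history mechanics of the original spreadsheet are not printed and
cannot be recovered from the text.
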