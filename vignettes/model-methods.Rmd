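---
title: "Model and methods: mouthwash cost-effectiveness for postoperative pneumonia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: mouthwash cost-effectiveness for postoperative pneumonia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouthwashCEA)
```

## The decision problem

Postoperative pneumonia after abdominal surgery is common, costly and
deadly, and rates in low- and middle-income settings run well above those
in high-income countries. Two doses of preoperative chlorhexidine mouthwash
decolonise the lower respiratory tract and, in cardiac surgery, reduce
pneumonia risk. This package implements a 30-day decision-tree
cost-effectiveness model, from the South African healthcare provider
perspective, comparing mouthwash against no mouthwash in abdominal surgery
patients. A single decision tree (no time cycles, no discounting, no
half-cycle correction) is appropriate because the condition resolves within
the 30-day horizon and readmission is rare within it.

## The tree and its parameters

Every patient undergoes surgery, then develops postoperative pneumonia or
not; is cared for on a general ward or in a critical care unit (CCU);
within critical care may receive mechanical ventilation (MV); and by day 30
has either died or been discharged. That yields twelve terminal pathways
per arm (`enumerate_pathways()`), whose joint probabilities are products
along the branches and sum to one.

The comparator arm's eleven branch probabilities come from two prospective
surgical cohorts and expert opinion; where event/total counts exist the
model uses the full-precision fraction (for example 39/931 for pneumonia),
falling back to the printed two-decimal value otherwise, and the loader
rejects any printed value that disagrees with its counts beyond the
two-decimal rounding band (±0.005).

The intervention arm is derived, not observed: mouthwash is assumed to
reduce pneumonia incidence with a relative risk reduction (RRR) of 0.3 — a
deliberately conservative discount of the 0.52 cardiac-surgery estimate —
and, in the absence of any abdominal-surgery trial data, the same factor is
applied to the critical-care admission, ventilation and critical-care
mortality probabilities of pneumonia patients. Patients without pneumonia
are assumed to fare identically in both arms, as is ward mortality among
pneumonia patients. The parameter table prints a "reduced by RRR"
annotation on some no-pneumonia intervention rows, but the identical-arms
assumption is the one carried through here: it is the only reading
quantitatively consistent with the published incremental cost (a 30% cut
to no-pneumonia critical-care admission would roughly triple the saving).
The intervention-arm ventilation probability is likewise derived as
0.25 × 0.7 = 0.175 and treated as fixed in the probabilistic analysis,
matching its published distribution tag.

## Costing

Each pathway's per-patient cost is assembled from 2020
international-dollar unit costs (`pathway_cost()`):

* procedure cost for every patient (cancels in differences, kept so
  absolute per-arm costs are meaningful);
* the two-dose chlorhexidine cost ($3) in the mouthwash arm only;
* a pneumonia episode cost ($3,752) once per pneumonia patient;
* the class mean length of stay times the ward ($71/day) or CCU
  ($1,210/day) rate, using the six leaf classes of the published
  length-of-stay table;
* a mechanical ventilation cost ($89) once per ventilated patient — the
  source prints a single value with no per-day annotation;
* the pandemic per-patient cost ($254) when the COVID-19 overlay is active.

Two modelling choices deserve emphasis. First, decedents accrue the full
mean length-of-stay cost of their class, because no outcome-stratified
stays are published; this is the presumed main source of the ≈1% gap
between this implementation's arm costs and the published $3,958/$3,675,
and the documented tolerances (±$40 per arm, ±$15 on the difference)
absorb it. Second, ward transfers are not costed as separate states: the
time transferred patients spend in each location is assumed symmetric
across directions, so transfer costs cancel and the six leaf classes
suffice.

One published sensitivity row resists this leaf-class reading: the
aggregate "pneumonia, critical care unit" stay (18.99 days) is varied in
the one-way analysis with sensitivities implying a joint probability close
to the pneumonia–CCU–MV pathway rather than the no-MV leaf. The original
spreadsheet evidently costed that aggregate row differently; this package
maps the aggregate bound onto the no-MV leaf (the only CCU leaf not
already covered by the MV-stay bound) and does not treat that row's
printed values as reproduction targets.

## Scenarios

Scenario 1 is the pandemic-free base case. Scenario 2 overlays COVID-19:
the control-arm pneumonia probability rises and every patient in both arms
accrues the $254 pandemic cost. The overlay increment is applied *before*
the RRR derivation, so the intervention arm inherits a proportional share —
algebraically, overlay-then-derive equals derive-then-overlay with the
increment scaled by (1 − RRR), a property the tests exercise.

The stated increment is +1.8 percentage points (`absolute_pp` mode), but
the published scenario-2 pneumonia proportions (0.045 vs 0.031) imply an
increment near +0.28 points; the package implements both
(`calibrated` mode, default increment 0.0028) and every report echoes which
mode produced it, without guessing which the original spreadsheet intended.
Note also that with the overlay active this package's per-arm expected
costs include the $254 add-on, whereas the published scenario-2 per-arm
costs evidently exclude it; the add-on cancels in the cost difference
either way.

## Currency transfer

Costs reach 2020 international dollars through a market-basket transfer
(`basket_index()`, `adjust_cost()`): the ratio of basket totals —
UK $8,759 over South Africa $4,519, printing as 1.94, with 10.8 for the
USA — divides source-setting costs, combined with source-currency
inflation to 2020 and purchasing-power-parity conversion. The source does
not state the order of operations; the default here is inflate, then PPP,
then basket, and the order is configurable with every step logged in a
per-item audit trail. The published adjusted-cost column is **not**
reproducible row by row from the printed factors (different rows imply
different conversion routes), so the model consumes the printed adjusted
values as its canonical cost fixture and the currency module is validated
only against the 1.94 index and the pneumonia-cost row (±2%). Because no
inflation rates are printed, the bundled editable inflation fixture uses a
flat health-cost inflation series calibrated so that single verifiable row
reproduces; users with authoritative series can replace the fixture.

Rand figures are display-only: one configurable factor, default 17.35,
fits every dollar/Rand pair in the published results tables. (A gel-cost
aside elsewhere in the source implies ≈6.7; a single results-consistent
factor is used and the discrepancy noted here.)

## Deterministic sensitivity analysis

The RRR sweep and the $289 gel-cost dominance threshold use the base RRR;
all other one-way variations and the extreme cases use the conservative
RRR 0.01, at which the incremental benefit is pinned at
0.01 × 39/931 ≈ 0.0004 whenever the varied parameter is not the pneumonia
probability — an identity the tests check exactly. Which arm a one-way
variation touches is part of the row key, and overriding an
intervention-arm parameter replaces its RRR-derived value.

The dominance break-off search (`breakoff_search()`) brackets a sign
change in the incremental cost by doubling steps from the base value (up
to ten doublings each direction) and bisects to ±$0.5 for costs and ±0.05
days for stays; a parameter whose incremental cost never changes sign in
range returns a flagged `NA` rather than a fabricated threshold. The
published conservative-RRR threshold ($11) is not exactly the gel cost
plus the incremental saving, presumably spreadsheet rounding; a ±$3
tolerance is applied to that check.

Extreme cases follow the published bound assignments: `no_mv` zeroes every
ventilation probability; the best case for mouthwash puts the intervention
arm's pneumonia, CCU and MV probabilities and its pneumonia stays at their
lower bounds with the bed-day and pneumonia costs at their upper bounds;
the worst case reverses them. The intervention-arm reading of the
probability bounds is forced by the published incremental benefits
(0.0119 = 39/931 − 0.03 and −0.0081 = 39/931 − 0.05).

## Probabilistic sensitivity analysis

Each of the 10,000 iterations draws all parameters simultaneously:
probabilities with counts from Beta(events, total − events) — the simplest
scheme consistent with the published events/total columns, with a
+0.5/+0.5 continuity correction for all-or-nothing counts; the
expert-opinion ventilation probability from a beta with a configurable
effective sample size (default 39, the pneumonia cohort size); fixed
expert-opinion probabilities as point masses; and costs from gamma
distributions with shape 1/cv² and scale mean·cv², so every draw mean
equals its base value. The source assigns gamma distributions but no
variances; the default coefficient of variation is 0.2, configurable per
run and echoed in the output metadata. A consequence worth stating
plainly: the published PSA mean costs ($5,067/$5,302) exceed the base-case
means by roughly 28%, implying unpublished skew or hyperparameters, and
are therefore not reproduction targets; the package checks instead the
properties that are forced — degenerate distributions collapse onto the
base case, the mean incremental effect converges to RRR × E[pneumonia
draw] ≈ 0.012, acceptability probabilities are proper.

Draws are independent across parameters (no correlation structure is
described); complements are formed after drawing, so every branch remains
valid. The RRR derivation is re-applied to each draw. One root seed feeds
deterministic per-parameter substreams, so adding or removing a parameter
leaves the other streams untouched, and a fixed seed reproduces the draw
table bitwise.

Cost-effectiveness acceptability uses net monetary benefit
NMB = λ·Δe − Δc over a willingness-to-pay grid from $0 to $30,000 per unit
reduction in pneumonia proportion (the published plots span that range
without stating a step; $250 is used). Whether the original curves counted
ties as successes is unstated; here draws with NMB exactly zero count one
half. The effect axis is deliberately the raw proportion reduction, not
QALYs, matching the source.

## Synthetic data and the microsimulation oracle

`simulate_cohort()` routes individual patients through the tree by
independent Bernoulli draws and costs them with the same pathway costing
as the cohort model; at 200,000 patients its estimates agree with the
analytic expectations within three Monte-Carlo standard errors, which is
the package's brute-force check that the closed-form tree is evaluated
correctly. Length of stay is deterministic at the class mean by default so
the oracle matches the analytic model exactly in expectation; a
gamma-distributed per-patient mode exists for stress tests.

`synthesize_cohort_tables()` emulates the surgical-cohort event-count
tables by hierarchical binomial sampling — pneumonia events become the
denominator of the downstream pneumonia nodes, and so on — and the counts
feed back through the loader for parameter-recovery tests: across 100
replicate cohorts of 931 patients, the 95% beta credible interval for the
pneumonia probability covers the truth at nominal rates. The generator
reproduces only the count structure the model consumes; it does not
emulate patient covariates, hospital clustering, or the cohorts' inclusion
criteria, so passing these tests says nothing about such structure in real
data.

## Problem sizes and numerical conventions

Default sizes, chosen as standard practice for models of this scale:
10,000 PSA iterations; 200,000 microsimulated patients for oracle
comparisons; 100 replicate synthetic cohorts of 931 patients for coverage.
Probability conservation is enforced at 10⁻⁹ when evaluating an arm and
tested at 10⁻¹²; dominance classification treats exact ties as an
indeterminate ICER (0/0) or a flagged infinite one (x/0). All internal
arithmetic is full precision; rounding happens only at display.

## Known limitations

The effectiveness evidence is extrapolated from cardiac surgery; nothing
here strengthens it. The decedent length-of-stay convention and the
aggregate CCU-stay sensitivity row are irreducible ambiguities of the
source, handled by documented tolerances rather than resolved. The
currency utilities can validate only what the source prints; most adjusted
costs are consumed as given. And the PSA's cost dispersion is an artifact
default (cv = 0.2), not an estimate — conclusions that depend on cost
tails should treat it as a knob, not a finding.
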