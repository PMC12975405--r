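---
title: "Cost-utility modelling conventions in markovcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling conventions in markovcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

`markovcea` evaluates whether a community wellness program that improves
cardiovascular risk factors in older adults is worth its budget. This
vignette is the package's own account of the model: what is assumed, which
conventions are configurable, why the defaults are what they are, and what
the synthetic data can and cannot demonstrate.

## The decision problem

Participants in a housing-based wellness program receive annual health
assessments recording age, sex, diabetes status, total cholesterol,
systolic blood pressure (SBP), antihypertensive medication use, and
smoking. Between entry and exit the observed pattern is: medication use
rises sharply (e.g., from 6% to 40% for males without diabetes), SBP holds
at its baseline level instead of drifting upward, and smoking declines by
2–3 percentage points. The economic question is what those changes are
worth in quality-adjusted life years (QALYs) and whether the program's
cost per participant justifies them, against a counterfactual in which
none of the changes occur and SBP rises by 12 mmHg, the standard
projection for this age range over the modelled exposure.

The analysis is stratified into four groups — males and females, with and
without diabetes — because diabetes amplifies the risk attached to the
other factors, and each stratum gets its own transition matrices.

## Model structure and assumptions

The cohort model has five states: healthy, stroke, myocardial infarction
(MI), congestive heart failure (CHF), and death, with one-year cycles over
a 20-year horizon and 3% annual discounting of all costs and effects. The
structural assumptions, enforced by a transition mask, are:

* no recovery: once any event occurs the cohort member never returns to
  the healthy state;
* single-event pathways: stroke can progress to MI, CHF or death; MI to
  CHF or death; CHF only to death; death is absorbing;
* the whole cohort starts healthy.

The no-recovery and single-event restrictions make the model
conservative: survivors of an event cannot accrue a second acute event's
costs, so the intervention's benefit (fewer first events) is, if anything,
understated.

State utilities default to 0.85 (healthy), 0.70 (MI), 0.65 (stroke), 0.60
(CHF) and exactly 0 (death). A QALY is a utility-weighted life year; life
years use weight 1 for every alive state, so QALYs can never exceed life
years — an invariant the test suite checks on random matrices.

## From risk factors to transition probabilities

The healthy row is built per stratum and scenario from four
proportional-hazards risk functions (first stroke, first MI, incident CHF,
non-cardiovascular death). Each function carries a reference profile
`x₀`, a coefficient vector `β`, and a baseline risk `R₀` over its horizon
`t`; the risk at profile `x` is `1 − (1 − R₀)^exp(β·(x − x₀))`, annualized
by the constant-hazard conversion `1 − (1 − R)^(1/t)`. The conversion is
the standard actuarial choice when only a cumulative risk is available; it
is exactly inverted by annual compounding, which the tests verify to
1e-12.

Two design choices deserve emphasis:

* **The default coefficient tables are package-authored and calibrated,
  not transcriptions.** The published general-population cardiovascular
  risk functions require HDL cholesterol, which the health assessment does
  not collect, and the original analysis does not state which function
  variant fed each event. The defaults therefore use
  literature-plausible log-hazard slopes over exactly the seven collected
  factors, with per-event baseline risks calibrated so that the
  counterfactual base-male profile (age 66.2, cholesterol 162 mg/dL, SBP
  141 mmHg, 27% smoking, 6% medicated) reproduces the published
  counterfactual healthy row: stroke 0.0070, MI 0.0090, CHF 0.0100, death
  0.0198 per year. Their provenance string labels them synthetic, and
  `read_coefficients()`/`write_coefficients()` swap in any other table
  without touching the engine.
* **Antihypertensive treatment is protective (β = −0.15) in the
  defaults.** In observational scores, "treated" is a risk marker with a
  positive sign at given SBP. Here medication uptake is the intervention's
  main effect, and the analysis treats appropriate medication as causally
  beneficial; a positive sign would invert the modelled direction of the
  program. Users reproducing an observational score should supply their
  own table.

Scenario construction follows the source rules in `scenario_spec()`: the
intervention uses exit medication, smoking and cholesterol with observed
(baseline-level) SBP; the counterfactual freezes everything at baseline
except SBP, which takes the projected +12 mmHg value. Both scenarios
evaluate at entry age with a time-homogeneous matrix, matching the single
printed matrix convention; risk factors enter as stratum means, including
fractional values for the binary factors (the risk function is evaluated
at the cohort-average profile rather than averaged over profiles — a
deliberate simplification that mirrors the source analysis).

## Row residuals and validation policy

Printed transition rows in this literature frequently fail to sum to 1 —
in the published counterfactual matrix the healthy row leaves 0.0485
unaccounted and the stroke row 0.3254, plausibly mass destined for an
unprinted post-stroke state. `validate_matrix()` makes the resolution
explicit rather than silent: `error` rejects, `renormalize` (the model
default) rescales each row, `residual_to_self` honours printed
off-diagonal values and grows the diagonal, and `residual_to_extra_state`
routes residuals to a declared auxiliary absorbing state. Every validated
matrix records its policy, renormalization warns, and the warning
propagates into the pipeline log and report footers. No policy is asserted
to be "what the original authors did", because that cannot be determined
from the printed rows.

## Reward timing and discounting

With annual cycles the accrual convention matters at the several-percent
level. The engine exposes three: `cycle-start` (default; occupancy at the
start of cycle *t* earns that cycle's reward, discounted by
`(1+r)^-(t-1)`), `cycle-end`, and `half-cycle` (the mean of start and end
occupancy at `(1+r)^-(t-1/2)`). Cycle-start is the default because the
source results show no sign of half-cycle correction; the convention is
stamped on every trace since reported totals depend on it. Under
cycle-start with no events, the 20-year 3% life-year total is the
geometric series (1 − 1.03⁻²⁰)/(1 − 1.03⁻¹) = 15.3238.

The published per-stratum QALY totals (e.g., 6.1 discounted counterfactual
QALYs for base males) cannot be pinned to a unique combination of row
policy, reward timing and starting convention, so the package reports its
own totals next to the published ones as a labelled diagnostic rather than
asserting agreement; the acceptance script emits
`table_matrix_counterfactual_qaly` with the convention flags that produced
it.

## Costs

`program_cost_per_participant()` rebuilds the panel budget: wages, a 33%
fringe rate on wages, operating items, and a 10% indirect rate on total
direct charges, divided by the 100-participant panel. One ledger
convention is built in: the computed fringe line is carried at whole
dollars — the precision budget line items are entered at — which makes the
indirect charge exactly 10% of the dollar-valued direct charges
($11,042.40 on $110,424) and reproduces every printed subtotal. The grand
total implied by those subtotals is $121,466.40; the published grand total
is $0.60 higher, an inconsistency in the source table that the package
surfaces rather than resolves (the per-participant figure, $1215, is
unaffected).

Healthcare costs accrue per cycle as state-maintenance costs on occupancy,
acute-event costs on the cycle's transition flows (death transitions
included, applied once to the transitioning mass), and the program cost
per participant-year on the alive mass, all discounted with the engine's
convention. The original analysis drew its state and event cost values
from literature sources without printing them, so the default
`cost_schedule()` is an explicitly flagged placeholder: running it
requires `allow_placeholder = TRUE`, warns, and the warning lands in the
report footer. Program cost accrues per participant-year while alive, the
reading most consistent with a per-year program fee; a one-time accrual
can be had by setting the schedule's program cost to zero after cycle one
via a custom schedule.

ICERs are computed unrounded and displayed with round-half-up dollar
rounding (`round_half_up()`), the convention that reproduces the published
ratio rows from the published incremental costs and gains for seven of the
eight printed ratios; the eighth (female-diabetes cost-per-QALY) is one
dollar off under any rounding rule and is documented rather than asserted.
Degenerate comparisons never divide: a positive cost with non-positive
gain is flagged `dominated/undefined`, a non-positive cost with
non-positive gain is flagged for cost-saving interpretation.

The long-term care break-even helper `ltc_breakeven()` returns
`incremental_cost / (monthly_cost × months)` — the utilization reduction
whose avoided cost offsets the program. It is exposed as a formula; the
source discussion's 8.2-percentage-point figure is not derivable from its
printed inputs and is not asserted anywhere.

## The synthetic cohort generator

`generate_cohort()` emulates the four strata's published means and
proportions: truncated-normal draws for age, SBP and cholesterol
(inverse-CDF sampling, so a fixed seed is byte-reproducible), Bernoulli
draws for the binary factors, and one-directional exit transitions —
smokers quit with the rate implied by the baseline and exit proportions,
non-smokers never start; medication starts and never stops. Exit
cholesterol shifts each participant by the stratum mean change; exit SBP
and age repeat baseline, since both scenarios evaluate at entry age and
the observed SBP target equals the baseline mean. Per-stratum random
substreams derive from the master seed and the stratum label, so removing
one stratum leaves the others' draws untouched.

The dispersions are generator settings, not observations: the source
reports no variances, so the defaults (age 8 y, SBP 15 mmHg, cholesterol
35 mg/dL) are plausible population spreads for an older adult cohort,
chosen once and fully configurable. Consequently the generator
demonstrates pipeline correctness — parameter recovery, determinism,
range safety — but not distributional fidelity to the real cohort: real
assessments have skewed SBP, correlated risk factors, attrition over an
average 5.4-year tenure, and missingness, none of which are modelled
(tenure dynamics are deliberately out of scope). Passing tests show the
machinery is right, not that the synthetic cohort is the study population.

## Numerical choices

* Occupancies, flows and costs are kept in full double precision;
  rounding happens only in report formatting.
* Annualized probabilities are clamped to [0, 1] with a logged warning,
  never silently.
* A profile whose summed healthy-row event probabilities exceed 1 is an
  error (the profile implies an impossible matrix), not a clamp.
* The engine is cross-checked against `matrix_power_oracle()`, which
  recomputes totals via exponentiation-by-squaring matrix powers — a
  genuinely different accumulation path — with agreement required to
  1e-9 over 1000 random structurally valid matrices.
* Problem sizes in the test-suite and acceptance script (2000 records per
  stratum for recovery checks, 100 seeds, 1000 oracle matrices) were
  chosen to put Monte-Carlo error well below the tolerances being
  checked while keeping a full run in tens of seconds.

## Known limitations

* Transition probabilities are evaluated at stratum-mean profiles; within-
  stratum heterogeneity (and Jensen-gap effects of the convex risk
  function) is not propagated.
* The default time-homogeneous matrix holds entry-age risk constant for
  20 years, matching the printed single-matrix convention; the
  age-updating mode (`build_transition_matrices_aging()`, or
  `age_update: true` in a run config) advances age each cycle and
  predictably shortens modelled survival.
* Default healthcare costs are placeholders; absolute cost and ICER
  outputs are only meaningful once a sourced `cost_schedule()` is
  supplied.
* No probabilistic sensitivity analysis; the deterministic engine and
  seed-stable generator are the harness such an analysis would be built
  on.
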