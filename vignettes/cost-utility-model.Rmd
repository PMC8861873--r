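---
title: "A Markov cost-utility model for digital therapeutic care in low back pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for digital therapeutic care in low back pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbpcea)
```

## The decision problem

Non-specific low back pain (LBP) is episodic: untreated phases of low or
high impact on quality of life alternate with treatment, temporary
remission and — for a fraction of patients — lasting recovery. German
statutory health insurance now reimburses prescription digital
therapeutic care (DTC) apps for LBP at a price above that of the usual
six-session block of face-to-face physiotherapy (TAU). The app promises
better long-term self-management (more patients stay pain-free) but
suffers higher monthly attrition. `lbpcea` implements the
decision-analytic model behind this trade-off and reproduces the
reference cost-utility evaluation for the German setting.

## Model structure

The model is a discrete-time Markov cohort model over seven states:

| state | meaning |
|---|---|
| `LOW` | untreated low-impact LBP |
| `HIGH` | untreated high-impact LBP |
| `T_W1_4`, `T_W4_8`, `T_W8_12` | months 1–3 of a 12-week treatment program (tunnel states) |
| `REMISSION` | temporary, spontaneous symptom relief |
| `HEALTHY` | lasting recovery; absorbing |

The treatment states are *tunnels*: each can be occupied for exactly one
cycle and entered only from its predecessor (or, for `T_W1_4`, from the
untreated states). This encodes time-in-treatment and lets monthly
attrition act at the two interior transitions. Dropouts are split by
`dropout_split()`: half enter remission, and the rest return to
untreated LBP in fixed 82.2%/17.8% low/high proportions, reflecting the
stability of individual pain trajectories. Only patients completing the
third treatment month can transition to `HEALTHY`, with probability
0.10 under DTC versus 0.05 under TAU — the app's assumed advantage in
inducing lasting behaviour change. There is no death state: all-cause
mortality is negligible for this middle-aged population over horizons
of a few years.

A cohort of 10,000 patients starts as 5320 / 1120 / 3560 in
`LOW` / `HIGH` / `REMISSION`.

## Cycle accounting and discounting

Cycles are calendar months (12 per year), matching the three monthly
treatment phases; the default 3-year horizon is therefore 36 cycles.
Costs and utilities accrue per cycle on life-table (half-cycle)
corrected memberships, `(raw[t] + raw[t+1]) / 2`, identically for costs
and QALYs. Discounting uses 3% per year compounded continuously per
cycle, `(1.03)^(-t/12)` at cycle index `t`, with cycle 0 undiscounted.
Both conventions are configurable (`cycles_per_year` in the ledger;
the raw trace is exposed for alternative accrual schemes), and the
defaults were fixed once by cross-checking the full published result
set — base case, every horizon and attrition scenario, and the
sensitivity endpoints — which this combination reproduces to a few
tenths of a percent. Under a 4-week (13 cycles/year) reading no
residual-mass or discounting variant comes close, so we treat the
monthly convention as the model's definition, not an approximation.

## Residual row mass

The published transition inputs leave three rows incomplete: `LOW` sums
to 0.95, `HIGH` to 0.90, and TAU's end-of-treatment row to 0.95. The
package resolves these by explicit, recorded policies
(see `build_transition_matrix()`):

* **Untreated rows** (default `renormalize_non_treatment`): the
  treatment-entry probabilities are stated assumptions (75% / 80%) and
  stay fixed; the remaining destinations are scaled proportionally to
  fill the row. A `self_loop` alternative adds the deficit to the
  stay-put probability instead.
* **End-of-treatment row** (default `trajectory_split`): the deficit
  returns to `LOW`/`HIGH` in the same 82.2%/17.8% trajectory
  proportions used for dropouts; `to_remission` is available as an
  alternative. The trajectory split is the only resolution consistent
  with the published incremental results, and it mirrors the model's
  own dropout logic.

Every applied resolution is logged in the matrix's `"resolutions"`
attribute.

## Values

Utilities are annual QALY weights (0.61–0.806); a cycle contributes
`utility / 12` QALYs per person. Per-state cycle costs (2021 Euro,
societal perspective) bundle direct components (consultations,
pharmacotherapy, diagnostics, the treatment program itself) with
indirect absenteeism costs valued by the human capital approach at the
gross daily wage `3092 / 21 = 147.24`. Derived costs are recomposed by
closed forms — e.g. the TAU six-session physiotherapy block
`6 × 21.11 × 1.10 + 10 = 149.33` and the DTC first-treatment-month cost
`239.96 + 20.47 + 21.36 + 16.81 + 29.24 + 147.24 = 475.08` — and
rounded half-up to cents, matching every published derived value. The
untreated-state costs (441.72 / 588.96) and the TAU first-month cost
(377.85) are carried as printed primitives: their exact absenteeism
decomposition is under-specified, so only their program components are
substituted during sensitivity sweeps. The app price is carried at
€239.96, the only value consistent with the 475.08 decomposition;
later price levels (~€296) circulate elsewhere and are reachable
through the sensitivity machinery.

## Outputs

`run_strategy()` yields per-person discounted cost and QALY totals with
per-state breakdowns; `incremental_outcomes()` compares strategies on
unrounded internals and classifies the result on the cost-effectiveness
plane (`icer()`): a proper ICER in the north-east quadrant, dominance
labels elsewhere. South-west outcomes (cheaper, less effective) are
labelled comparator-dominant to match the reference reporting
convention but carry `strict = FALSE`, since strict dominance does not
hold there. A zero effect difference returns an `undefined_ratio`
signal rather than an error.

```{r base}
params <- base_parameters()
dtc <- run_strategy(params, "DTC")
tau <- run_strategy(params, "TAU")
incremental_outcomes(dtc$totals, tau$totals)
```

## Scenario suite

`published_scenarios()` covers the base case, horizons of 2/4/5 years
(A.1–A.3) and alternative app attrition rates (B.1: lowered to the TAU
rates; B.2/B.3: 14%/30% after each of the first two months), with
attrition overrides recomposed through `dropout_split()`:

```{r scenarios}
scenario_suite(params)$table
```

Two behaviours are worth noting. Longer horizons favour the app: its
extra `HEALTHY` patients stop generating costs, so it turns dominant
from year four. And at 30% attrition (B.3) the app strategy is *more*
costly and less effective — the comparator dominates strictly; the
magnitude of the incremental cost agrees with the reference table,
where the same figure is printed with a negative sign.

## Sensitivity analysis

`one_way_dsa()` reruns the full pipeline with one parameter at its low
and high bound, each routed through its linkage (app price and
physiotherapy volume recompose the first-treatment-month state costs;
raw-scale probability bounds are recomposed into full rows before
matrix construction). Dominant outcomes have no finite ICER, so rows
are ordered by the signed sentinel `delta_cost / delta_qalys`, which is
negative exactly when the intervention dominates; the tornado sorts by
descending sentinel range with lexicographic tie-breaks. The app
reimbursement price and the number of physiotherapy sessions emerge as
the two dominant drivers.

## The microsimulation oracle

`simulate_individuals()` draws individual trajectories from the same
transition matrices and is the package's independent cross-check: the
cohort trace is the exact expectation of these trajectories, so
occupancies must agree within binomial standard errors and value totals
within Monte-Carlo standard errors (the test suite checks 4 SEs at
n = 100,000). Initial states are apportioned deterministically
(largest remainder), so transitions are the only source of randomness,
and each cycle is valued at the mean of its start- and end-state values
to mirror the life-table correction. The generator emulates sampling
variation around the cohort expectation only: it has no individual
covariates, no heterogeneity in transition probabilities, and no
parameter uncertainty (the reference analysis explicitly declined a
probabilistic sensitivity analysis for lack of distributional data).
Agreement between the two engines therefore validates the cohort
arithmetic, not the external validity of the inputs.
`perturb_parameters()` complements it by drawing structurally valid
random ledgers within the sensitivity bounds for property testing.

## Numerical choices and limitations

* Matrices are validated to row sums within 1e-12 and entries in
  \[0, 1\]; cohort mass is conserved to 1e-9 over 65 cycles.
* Monetary values are kept in full double precision internally and
  rounded half-up to cents only at serialization boundaries.
* `healthy_at_horizon` reports the raw (uncorrected) final-cycle
  membership rounded half-up, since patient counts are integers.
* The published per-year consultation counts depend on an unstated
  counting convention; `resource_utilization()` documents its own
  convention (one GP plus one specialist contact per person-cycle in a
  consultation-incurring state) and only the convention-free *ratio*
  between strategies is asserted in tests.
* Problem sizes in the shipped tests — 36–65 cycle traces, 100,000
  microsimulated individuals, 10–25 perturbed ledgers — were chosen as
  the smallest sets that make the statistical checks sharp.
* Out of scope by design: death and comorbidity states, inpatient /
  rehabilitation / injection pathways, probabilistic sensitivity
  analysis, net-monetary-benefit curves, and re-derivation of the
  utility weights from survey instruments.
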