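---
title: "A Markov cohort cost-utility model of ECT versus esketamine in treatment-resistant depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of ECT versus esketamine in treatment-resistant depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdcea)
```

## The decision problem

Adults whose major depression has failed at least two adequate antidepressant
courses (treatment-resistant depression, TRD) can be offered
electroconvulsive therapy (ECT) or intranasal esketamine added to an oral
antidepressant. `trdcea` implements a discrete-time Markov cohort model that
compares the two strategies as cost per quality-adjusted life-year (QALY),
re-implementing a published UK cost-utility analysis as tested, configurable
code. A cohort enters at age 45, fully depressed, and is followed in 30-day
cycles for 35 years (420 cycles) from a societal or a healthcare
perspective, with 3.5%/year discounting of both costs and QALYs and the NICE
willingness-to-pay range of £20,000–£30,000 per QALY as the benchmark.

## States and transitions

The published state labels are kept: **A** depression on index treatment,
**B** remission after index treatment, **C** depression re-treated with the
index therapy after a relapse, **D** depression on standard treatment (the
destination of non-remitters), **E** remission on standard treatment, **F**
remission on standard treatment after completing esketamine maintenance, and
**G** death (absorbing). Because costs depend on time since entering
remission, B is expanded into tunnel states where needed:

* *ECT, main model*: remitters receive standard antidepressant care in a
  single state B (relapse 0.108/cycle, back to C for another ECT course).
* *ECT, maintenance model*: remitters receive maintenance ECT as a
  two-phase tunnel — month 1 (weekly sessions), then an ongoing phase
  (two sessions/month) — with relapse 0.0300/cycle from either phase.
* *Esketamine*: remitters taper through six monthly tunnel states B1–B6
  (relapse 0.0724/cycle each); month-6 survivors move to F on standard
  treatment. Relapse from F (0.232/cycle, the standard-treatment rate)
  returns to C for re-treatment at a higher dose.

A and C are single-cycle treatment states: an 8-session ECT course or the
esketamine induction fits inside one 30-day cycle, and the remission
probabilities (0.696 ECT, 0.392 esketamine) are printed per cycle. Their
occupancy therefore resolves every cycle into first remission, death, or
the residual mass, which moves to D. All listed exit probabilities of a
state are applied simultaneously as one stochastic row; the residual
defines the stay/advance transition, and rows whose listed exits exceed 1
are rejected by name. E relapses to D (standard treatment continues; no
re-treatment is triggered from that pathway). Depression states share a
flat per-cycle mortality of 0.00304; remission states use lifetable
mortality in 5-year age bands (0.000180/cycle at 45–49 up to 0.00285 at
75–79). The band table ends at 79 and the default horizon at age 80; the
engine refuses longer horizons rather than extrapolate.

## Deriving the transition inputs

Source trials report event proportions over heterogeneous windows. They are
converted to 30-day probabilities through the constant-hazard pair

$$r = -\ln(1-P)/t, \qquad p = 1 - e^{-rt'},$$

implemented in `prob_to_rate()`, `rate_to_prob()` and `rescale_prob()`,
with a relative-risk multiplier applied on the rate scale for the excess
mortality of TRD (`mortality_with_relative_risk()`; 1.35 × the rate implied
by 11.6% all-cause mortality over 4.5 years). Time is counted in days
throughout, with one month = 30 days (the cycle), six months = 182.5 days
and one year = 365 days; these conventions reproduce the printed inputs
0.108, 0.0300, 0.0724, 0.107 and 0.00304 at three significant figures
(`analysis/01_transition_inputs.R`), whereas month-based counting does not.
Two caveats are documented rather than "fixed": the standard-treatment
relapse probability 0.232/cycle does not follow from its source summary
(64.6% over 3.1 months gives ≈0.28 under any convention), and the ECT
remission probability 0.696 cannot be checked because the source treatment
duration is only loosely stated. The printed per-cycle values are the
authoritative inputs; the conversion chain exists for verification,
sensitivity work and synthetic-data recovery, and the engine never
re-derives inputs silently.

## Utilities

Annual utilities are 0.81 (remission) and 0.57 (depression). Per-cycle
accrual uses annual/12 (0.0675 and 0.0475), not the display-rounded 0.07
and 0.05 sometimes shown alongside them: 0.07 × 12 = 0.84 would overstate
the remission utility by 4%, and lifetime QALY totals near 15 are only
consistent with the annual values. The rounded pair remains available via
`utilities$use_rounded_cycle` for comparability. Death accrues nothing.

## Costing

The societal perspective sums four components per state and cycle: direct
healthcare, productivity loss, informal care, and travel to treatment
visits; the healthcare perspective keeps only the first. Productivity loss
is valued by the human-capital approach at the general wage (full-time
£2,340/month, part-time £680, plus 12% payroll tax on income between
£702.01 and £3,863): in depression,
$0.54\,V_{ft} + 0.13\,(V_{ft}-V_{pt}) = £1611$/cycle for the unemployed and
part-time fractions; in remission $0.23\,V_{ft} = £583$/cycle. It is zero
from the retirement age (65). These two numbers equal the printed
difference between the under-65 and 65-plus cost columns for every state
row (at whole-GBP precision), which is the model's internal consistency
check; the 65-plus column is treated as authoritative
"societal-minus-productivity" rather than re-derived.

The direct/informal/travel split inside the 65-plus totals is not printed
anywhere, so it is an explicit, documented calibration rather than a hidden
constant. Travel is £18.80 per attendance times the visits implied by each
phase's schedule (8 for acute ECT/esketamine cycles, 4/2/1 across the
maintenance phases). Direct costs were fitted once, by bounded least
squares against the three published *undiscounted* healthcare-perspective
totals, with unit-cost anchors (ECT session £558, esketamine £163/28 mg,
GP/psychiatrist/nurse fees) and the cap direct ≤ 65-plus total − travel.
The fit pushes the intensive-treatment states to their cap — informal care
≈ 0 while patients attend treatment several times a week, which is
clinically sensible — and leaves state D (chronic depression on standard
treatment) at £580 direct with the remainder informal care. The whole split
is overridable in configuration and re-checked by
`calibrate_direct_costs()`, which errors on negative residuals.
Healthcare-perspective results therefore inherit calibration uncertainty
and are interpreted qualitatively (ICER below £20,000 in the main model,
above £30,000 in the maintenance model), not as exact reproductions.

## Discounting, and a documented inconsistency in the reference tabulations

Both streams are discounted at 3.5%/year. Two conventions are implemented:
`per_cycle_continuous` (default), $(1+d)^{-t/12}$ for cycle $t$, and
`annual_step`, $(1+d)^{-\lfloor t/12\rfloor}$. Cycle 0 is never discounted,
and no half-cycle correction is applied by default (a flag enables it).

Fixing the default required confronting an inconsistency in the published
tables this model is calibrated against. The model reproduces their
no-discounting rows (within 0.1–1%) and, under the default convention,
their properly discounted 5-year-horizon rows (within 0.05%). But the
published 35-year *discounted* totals sit only ~2.5% below the published
undiscounted ones, which is arithmetically impossible for a near-uniform
35-year accrual stream at 3.5%/year (compound discounting must remove
roughly 40%); no convention can bridge that. The original spreadsheet's
discounting evidently failed at the long horizon. This package applies
compound discounting correctly, so its discounted lifetime totals (e.g.
ECT main model ≈ £322k / 9.89 QALY) are substantially below the published
≈ £454k / 14.85, while undiscounted and 5-year results agree closely, and
every qualitative conclusion (dominance pattern, threshold
classifications) is unchanged. The maintenance-model societal ICER
computed here (≈ £28.6k/QALY) is close to the published £27,070 because a
near-flat discounting error largely cancels in a ratio.

## Sensitivity scenarios

`scenario_catalog()` enumerates the published one-way analyses: 1a/1b
productivity loss doubled/halved (societal only — healthcare totals are
bit-identical to base, which is tested); 2a–2d ECT six or twelve sessions
per cycle (± one session fee, plus travel under the societal perspective);
3 esketamine remission 0.5; 4 ECT remission 0.5 (both apply to states A and
C); 5 second-treatment remission 0.9 (state C only, both arms); 6 five-year
horizon; 7 utilities 0.3/year during ECT treatment and 0.85/year for
remission after esketamine or on standard treatment; 8 esketamine continued
for as long as remission lasts (the tunnel loops at the months-2–5 cost and
F becomes unreachable); 9 no discounting.

Two scenario definitions were genuinely open and were resolved by
computation. For scenario 7, assigning 0.85 to state E in both arms and to
the esketamine tunnel and F — but *not* to the ECT arm's post-ECT remission
state B — reproduces the published QALY deltas (+0.19 main-model ECT,
+0.16 maintenance, +0.28 esketamine); upgrading B as well overshoots
threefold, so B keeps 0.81. For scenario 8, the implementation reproduces
the main-model tabulation (+£2.5k esketamine cost, +0.15 QALY); the
maintenance-model tabulation of the same arm prints a *lower* esketamine
cost with identical healthcare totals and QALYs, which is internally
inconsistent (it matches what one would get by charging the tunnel at its
65-plus cost), so its above-£30,000 ICER for that row is not reproduced.

## Synthetic data and the microsimulation oracle

`simulate_trial()` draws i.i.d. Bernoulli outcomes over a stated follow-up
window — the exact statistical structure the derivation chain assumes —
and `recover_parameters()` runs that chain on observed proportions. Exact
proportions recover the printed inputs at three significant figures;
at the real source-trial sizes the binomial-propagated 95% intervals
achieve nominal coverage (tested over 500 seeded replicates at n = 50).
This shows the estimation pipeline is correct, not that the source trials
themselves were unbiased; heterogeneity, dropout and non-constant hazards
in real trials are outside what the generator emulates.

`microsimulate()` pushes individuals through per-cycle categorical draws
using the same transition, costing, utility and discounting code paths as
the cohort engine, so any disagreement isolates the cohort recursion
itself. Agreement is required within 3 Monte-Carlo standard errors at
n = 200,000 in the acceptance checks (unit tests use 10-year horizons at
n = 4,000 to stay fast; the full-size check and the 500-replicate coverage
experiment run in the acceptance test file). Both samplers take one
explicit seed and restore the caller's RNG state.

## Numerical choices and degenerate inputs

Occupancy rows must sum to 1 within 1e-9 at every cycle (property-tested
over jittered bundles); death occupancy is non-decreasing and exactly zero
when all mortality is zeroed. With remission certain and relapse and
mortality zeroed, discounted QALYs equal the analytic annuity
$u_d/12 + u_r/12\sum_{t=1}^{N-1}\gamma^t$, $\gamma = 1.035^{-1/12}$, to
1e-9 — the closed-form limit used to pin the accrual accounting (one
depressed cycle then remission: 0.79 QALYs over an undiscounted year).
Residual-zero transition rows (e.g. remission probability 1) are legal;
only rows exceeding probability mass 1 are errors. ICERs are computed only
when the incremental signs agree and ΔQALY ≠ 0; dominance verdicts and
threshold flags use the net-monetary-benefit rule so all four quadrants of
the cost-effectiveness plane classify correctly.

## Known limitations

* Cohort homogeneity: no individual covariates, time-on-treatment effects
  or adverse-event disutilities — the structural assumptions of the
  original analysis are kept deliberately.
* The healthcare perspective rests on the calibrated direct-cost split;
  its ICERs are classification-grade, not point reproductions.
* The published discounted lifetime tabulations are internally
  inconsistent (see above); this package reproduces the consistent subset
  (undiscounted and short-horizon rows) and documents the divergence
  rather than emulating the error.
* No probabilistic sensitivity analysis; the scenario set is the published
  deterministic one.
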