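---
title: "Methods: a five-state Markov cohort model for HME cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-state Markov cohort model for HME cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmecea)
```

## The model

`hmecea` evaluates three management strategies for patients after total
laryngectomy — a third-generation heat and moisture exchanger (HME), a
second-generation HME, and no HME — with a closed-cohort Markov model.
Five mutually exclusive health states are tracked: three sputum-impact
(SPUI) severity levels, recurrent cancer, and death. The SPUI states are
defined on the CASA-Q sputum-domain score (0–100, higher is better):
no/mild at 94 and above, moderate at 64 up to (but excluding) 94, severe
below 64. Both boundary scores classify upward into the milder band,
following the inequalities as printed; `classify_spui()` applies them as
a strict partition of `[0, 100]`.

The cohort starts at age 67 with a fixed SPUI split
(0.075 / 0.525 / 0.400) and is propagated over ten one-year cycles:
`occupancy(t+1) = occupancy(t) %*% M(t)`. Each cycle matrix `M(t)`
combines four ingredients:

* a strategy-specific 3×3 SPUI transition matrix,
* background mortality `q(a)` looked up in a life table at the cohort's
  current age (`age_varying_mortality = TRUE` by default; a switch
  freezes it at the starting age, since the source description does not
  say whether mortality was aged),
* an annual recurrence probability `p` applying equally to all SPUI
  states, and
* an annual recurrence-specific death probability `q_rec`.

Competing risks within a cycle are ordered death → recurrence → SPUI
movement and combined multiplicatively: from a SPUI state,
`P(death) = q`, `P(recurrence) = (1−q)p`, and
`P(s→s') = (1−q)(1−p)·M[s,s']`. From recurrence, background and
disease-specific mortality act as independent hazards,
`P(death) = 1−(1−q)(1−q_rec)`. No ordering is stated in the source; the
multiplicative composition was chosen because it keeps every row
stochastic without renormalization and matches common practice in
cost-effectiveness modelling. Recurrent cancer never returns to a SPUI
state and death is absorbing.

## Outcome accrual

Costs and QALYs accrue on start-of-cycle occupancy, discounted at 2%
per year with exponent equal to the cycle index (cycle 0 undiscounted).
The published totals cannot discriminate between discounting or
half-cycle conventions without the unpublished transition inputs, so
both choices are explicit settings: `half_cycle_correction = FALSE` by
default, with the start/end average available for exploration.

Per cycle and strategy:

* annual SPUI state costs and the recurrent-cancer cost (¥7,435,931/yr)
  accrue per cycle of occupancy;
* event costs accrue as occupancy × events per person-year × cost per
  event (skin irritation ¥150, mucus plug ¥27,500, pulmonary infection
  ¥451,754);
* the end-of-life care cost (¥1,297,316) is charged once, on the mass
  newly entering death that cycle. Charging recurrence per cycle and
  death once follows the labels of the two costs ("annual" vs
  "end-of-life care"); both behaviours are localized in
  `accumulate_outcomes()`.

Utilities come in two modes. `NET` (default) uses the published
per-strategy state utilities that already fold in expected event
disutilities; this is faithful to the printed inputs, whose underlying
event rates were not published. `COMPOSE` rebuilds the utility as
`base − Σ rate·disutility` (floored at 0) for coherence experiments.
Expected event counts are reported undiscounted, matching how secondary
outcomes are usually tabulated ("events per patient over 10 years").

## Synthetic inputs and what they do (not) show

The transition matrices, recurrence risk, recurrence mortality, life
table and per-person-year event rates behind the original analysis were
published only in supplementary material not reproduced here. The
synthetic-data module fills these slots once, with values chosen on
clinical-ordinal grounds, and tags every configuration slot `PRINTED`
or `SYNTHETIC` in a fill report:

* SPUI matrices preserve the ordering the comparative results imply
  (third generation retains the most mass in milder states; no HME
  drifts toward severe). Retention of the no/mild state is 0.85 / 0.70 /
  0.55 across strategies.
* Recurrence probability 0.04/yr and recurrence mortality 0.35/yr are
  plausible values for post-laryngectomy cancer follow-up.
* The life table is Gompertz-style: `q(67) = 0.013` growing 9%/yr,
  clamped at 1 — in the range of published all-cause mortality for the
  late 60s and steep enough to matter over the horizon.
* Event rates are derived, not free: within each strategy they are
  proportional to the published 10-year per-patient event counts and
  scaled so that `Σ rate·disutility` reproduces the published
  net-utility decrement (0.0252 / 0.0392 / 0.0386). This makes `COMPOSE`
  mode agree with `NET` mode exactly and pins the rates to two printed
  anchors; their absolute scale remains synthetic. The no-HME skin
  irritation rate is structurally zero (no adhesive).

Consequently the package's base case reproduces the *structure* and
*qualitative* conclusions of the original analysis (both ICERs below
¥5,000,000/QALY; fewer infections and mucus plugs, more skin irritation
with the third-generation device), but not its printed totals — those
are carried separately in `published_base_case()` and used only for
arithmetic identity checks (`Δ = intervention − comparator`,
`ICER = ΔC/ΔQALY`, which match the printed incrementals to well under
0.05%, the slack of printed-input rounding). Passing tests therefore
demonstrate correctness of the machinery on realistic inputs, not
recovery of the unpublished parameter values. The panel generator
emulates the 40-patient × 3-moment cross-over structure (first-order
Markov, uniform score emission within each state's band); it does not
model sequence, washout or carry-over effects, which the source study's
description does not detail.

## Sensitivity analyses

**One-way (OWSA).** Each declared parameter is set to 80% and 120% of
base (probabilities clipped to `[0, 1]`), the full deterministic model
is rerun, and entries are sorted by ICER swing. Perturbing one entry of
a row-stochastic structure rescales the remaining entries
proportionally, the standard treatment that keeps rows on the simplex.
When a bound produces dominance, a signed ICER is meaningless, so the
swing falls back to the net-monetary-benefit difference at the
configured willingness-to-pay, flagged per row. `threshold_search()`
locates the parameter value where the ICER crosses the threshold by
scanning a 21-point grid for a sign change of `ΔC − λ·ΔQALY` (equal in
sign to `ICER − λ` whenever ΔQALY > 0) and refining by bisection to a
relative tolerance of 1e-6; with multiple crossings the first is
returned with a warning. Under the synthetic transition matrices the
third-generation device stays cost-effective across the entire
plausible range of its no/mild retention probability, so no retention
threshold analogous to the originally reported one exists here; the
bundled threshold example instead varies the intervention's no/mild
state cost, which crosses the ¥5,000,000 threshold within
¥0.68–5 million.

**Probabilistic (PSA).** Distributions are assigned by moment matching:
Gamma for costs (`shape = μ²/σ²`, `scale = σ²/μ`), Beta for quantities
in (0, 1) (`ν = μ(1−μ)/σ² − 1`, `α = μν`, `β = (1−μ)ν`), Dirichlet for
the initial split and each transition-matrix row, `FIXED` for
structural constants. Where no spread is reported σ defaults to 20% of
the mean; an infeasible Beta spread is shrunk to 0.95 of its bound with
a warning. Dirichlet concentration uses observed transition counts when
a panel is supplied, otherwise `mean × 40`, anchoring spread to the
size of the source cross-over study. Draws are independent across
parameters (no correlation information is available). Each of the 2,000
seeded iterations reruns the full deterministic model for all three
strategies; acceptability curves count, at each willingness-to-pay on a
¥0–15M grid (¥250k steps), the strategies attaining the strictly
highest net monetary benefit, splitting exact ties equally, so
probabilities sum to 1 by construction. Percentile intervals
(2.5th/97.5th) use linear interpolation between order statistics.

## Numerical choices and verification scale

* Row-stochasticity and cohort-mass conservation are asserted at 1e-9;
  matrices are stochastic by construction, so observed errors are at
  machine precision.
* The deterministic engine is cross-checked against an independent
  individual-level microsimulation of 10,000 patients walking the same
  cycle matrices: realized-path occupancy per cycle (compared by
  root-mean-square z-score over the five states against its Monte-Carlo
  standard error), and discounted totals via an exact competing-risk
  factorization — because death and recurrence hazards are
  SPUI-state-independent, the alive/recurrence/death masses have closed
  forms and only the 3-state SPUI mix needs simulating, which removes
  the rare-state cost noise that would otherwise swamp a 1% comparison
  at this sample size.
* Transition estimation is validated by parameter recovery on generated
  panels (30 → 3,000 pairs; errors within 3 binomial standard errors at
  3,000).
* The PSA uses 2,000 iterations and the microsimulation 10,000
  patients; both run in seconds and give Monte-Carlo error well below
  the tolerances checked.
* Degenerate inputs are handled explicitly: an all-`FIXED` PSA
  reproduces the base case bit-identically; a zero QALY difference
  yields an `UNDEFINED` ICER flag rather than a division; ages beyond
  the life table clamp to its last entry; an origin state with no
  observed pairs is an estimation error naming the state.

## Limitations

Beyond the synthetic stand-ins discussed above: no tunnel states or
time-since-recurrence stratification; no half-cycle correction in the
default analysis; costs restricted to devices, three adverse events,
recurrence care and end-of-life care (no broader resource use); no
parameter correlations in the PSA; and no value-of-information
analysis. Utilities sourced from a non-Japanese population are carried
as printed.
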