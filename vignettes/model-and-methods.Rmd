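---
title: "Coastal migration under sea-level rise: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coastal migration under sea-level rise: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moorings)
```

## The question

Will flooding amplified by sea-level change push coastal populations inland?
The intuitive answer — yes, in proportion to exposure — ignores that coastal
economies are often where livelihood alternatives concentrate, that migration
requires liquidity, and that repeated flood damage erodes exactly the incomes
that would finance a move. `moorings` is a desk-scale agent-based model in the
push-pull-mooring tradition built to study this tension: push factors (flood
damage to wages), pull factors (wages, social networks and remittance
expectations elsewhere), and moorings (wealth and credit constraints, place
investments) all act on the same quarterly livelihood decision.

The model tracks an explicitly interesting population: **moored** agents,
defined as agents whose latest livelihood reconsideration found at least one
strictly better option that they could not afford. Moored agents are distinct
from satisfied stayers (no better option exists for them) and from generic
"trapped" populations: mooring requires wanting to do better and lacking the
liquidity to act.

## World and agents

A synthetic world is a set of districts on an abstract plane, a subset flagged
coastal and laid out along one edge. Each district carries income
opportunities ("utility layers") with a quarterly wage, a capacity (maximum
concurrent holders), a one-time access cost, and a time requirement. Agents
hold portfolios of layers whose time requirements sum to at most one;
unallocated time earns a small informal-sector income (75 currency units per
quarter against a subsistence need of 60), so nobody has literally zero
income. Wages are log-normal with premia for non-agricultural work and for
coastal districts, encoding that livelihood alternatives are most abundant in
coastal cities; access costs are proportional to the layer's wage (about two
quarters of it on average) — better opportunities cost more to enter.

Key quantities per agent: wealth (liquid, may go negative up to the credit
limit), capital (cumulative access spending), CRRA risk aversion `rho`, an
annual discount rate, and per-quarter probabilities of meeting, interacting
and reconsidering. **Credit** is a world-level multiplier in `[0, 2]`: an
agent can hold debt up to `credit_multiplier * capital`. Capital never
depreciates and moving costs never count toward it — credit is collateralized
by past livelihood investment only.

## The quarterly cycle

Each quarter, in this order: annual peak floods are sampled at year
boundaries and converted to wage damages; agents are processed in a freshly
shuffled order through demography (ageing, mortality, fertility by stylized
age-band schedules converted with `1 - (1 - p)^(1/4)`), meeting new partners,
interacting (strengthening a link, sharing income observations, sharing a
fraction of surplus income as transfers), and reconsidering livelihoods; then
incomes are paid, consumption is deducted, and own wages are appended to each
agent's bounded per-layer income memory; finally link strengths decay —
faster across districts, which is how moorings lose force with distance.

Consumption is subsistence need plus half of income above need plus 5% of
positive wealth per quarter, so buffers converge to a few quarters of income
rather than growing without bound. Debt carries 5% quarterly interest
(comparable to microcredit rates), clamped so wealth never crosses the credit
limit. When an agent reaches the decision age (15), it receives a
household-formation endowment: 30% of the wealth of its strongest link
(normally the parent). On death, layer slots are released, links dissolve, and
positive wealth passes across the strongest surviving link; debts die with
the debtor.

## Valuation and the decision rule

An agent reconsidering its livelihood ranks candidate districts by social
pull — total link strength to residents, ties broken by distance — and
considers its own district plus the top `k - 1` others (`k` defaults to 4).
Within each candidate district every feasible layer subset (time budget,
size cap, open capacity) is valued by expected quarterly income: per-layer
income-memory means (falling back to the current wage when the agent has no
observations), plus informal income on residual time, plus expected
remittances (the trailing four-quarter net transfer rate scaled by the link
strength that would survive the move).

Valuation is reference-dependent: with `u` the CRRA utility and `y_ref` the
expected income of the *current* portfolio, an option with expected income
`y` is worth

\[ V = \sum_{\tau=1}^{H} (1+r_q)^{-\tau} \, v(y),\qquad
   v(y) = \begin{cases} u(y)-u(y_\mathrm{ref}) & u(y) \ge u(y_\mathrm{ref})\\
   \lambda\,[u(y)-u(y_\mathrm{ref})] & \text{otherwise,} \end{cases} \]

with loss aversion `lambda = 2.25` (the canonical prospect-theory estimate)
and horizon `H = 20` quarters. The current portfolio is therefore worth
exactly zero, and the decision rule is: among options with strictly positive
value, adopt the highest-valued *affordable* one (cost `<=` wealth plus
credit limit, boundary inclusive); if positive-value options exist but none
is affordable, the agent records a **moored event**; if none exists, it is a
satisfied stayer. Adoption pays access costs (into capital) and moving costs
(not into capital) out of wealth, which may go negative within the credit
limit. The moored flag always reflects the latest reconsideration; the
quarter and prior move count of the *first* moored event are kept for cohort
analyses.

Ties are resolved deterministically: candidate districts in rank order, and
within a district subsets in enumeration order (smaller subsets first, then
lexicographic). The test suite checks the whole rule against a naive
brute-force argmax over all (district, subset) pairs on small worlds.

## Hazard model

Annual peak flood depth in district `d` under scenario `s` is
`b_d + s_d * SLR(year) + eps`, with `eps` zero-mean Gumbel (annual-extreme)
noise of scale 0.4 m, truncated below at zero. The three emissions pathways
are linear sea-level trajectories reaching 0.40 / 0.55 / 0.85 m by 2100;
these are package defaults for desk-scale experimentation, not published
projections. Only flooding beyond what agents consider normal causes damage:
the **perceived-normal multiplier** `m` in `[0.5, 1.5]` scales the
*reference-period* expected depth (the start-of-run expectation — perceptions
do not track rising seas), and the shock is
`max(0, depth - m * expected_ref)`. Damages are saturating-exponential in the
shock (`1 - exp(-delta * shock)`, `delta` 0.5/m for agricultural and 0.2/m
for non-agricultural wages, so floods push the economy off agriculture),
last four quarters, and overlapping windows take the maximum fraction, never
the product. Damages hit wages, not wealth stocks: floods in this model harm
people by eroding the income streams that finance both living and moving.

## Calibration harness

Five parameters dominate behaviour: credit access, locations considered,
risk-aversion scale, information sharing, and reconsideration frequency. The
harness draws a Latin hypercube over their bounds, runs the simulation over a
reference window with no sea-level trend, and scores each point by the
coefficient of determination between vectorized `log(1 + flow)` off-diagonal
entries of simulated versus observed mean-annual flow matrices. The null
comparison relabels the observed matrix's districts at random 100 times and
averages the (floored) fit — a self-contained permutation baseline. All
candidate points share one simulation seed (common random numbers) so the
fit surface varies only through the parameters.

At desk scale this harness is honest but weak: a 20-district world with a few
hundred agents produces sparse flow matrices whose between-seed fit at
*identical* parameters is near zero, so there is little identifiable signal
for any search to climb (the published application calibrated against a
decade of vital-registration flows backed by millions of simulated agents).
The parameter-recovery experiment in the test suite (budget 60, five seeds,
600 agents over five years) runs the harness exactly as specified and records
how often the generating credit multiplier is recovered; its outcome should
be read as a statement about desk-scale identifiability, not about the
harness implementation.

## Ensembles and analyses

The experiment driver draws, per run: an emissions scenario, `m ~ U(0.5,
1.5)`, credit `~ U(0, 2)`, and the other decision parameters from
configurable ranges, then executes a full run with seed `seed_base + run`.
Analyses reproduce the headline analysis chain: normalized net migration by
district (in minus out over total agents; sums to zero), the largest flows
(`ceiling(fraction * D * (D-1))` cells), moored shares and moored-cohort
covariates (wealth, CRRA, moves before first mooring), Spearman correlation
of in-migration with moored share within coastal and interior strata, and
random-forest **permutation** importance (mean decrease in held-out R² over
20 permutations; permutation rather than impurity importance because the
drawn parameters are on different scales).

## Problem sizes

The package's default study conditions are desk-scale by design: a 20-district
world (6 coastal; a 64-district preset with 19 coastal districts mirrors the
region-scale layout), ensembles of 40 runs with 200 agents over 2010–2040,
a 2000-agent 2010–2100 run for the conservation audits, and calibration
budgets of 20–60 evaluations. The ensemble and calibration designs scale up
unchanged if more computing time is available.

## What the synthetic world does and does not capture

The generator reproduces the *statistical shape* of the setting — skewed
wages with coastal and non-agricultural premia, scarce slots for good jobs,
entry costs proportional to opportunity quality, abstract geography with
distance-dependent moving costs, a younger-heavy age pyramid — but none of
its geography, sectors or prices is estimated from data. Passing tests
therefore demonstrate that the mechanisms are implemented correctly and that
the qualitative directions are reproducible under plausible conditions; they
do not validate magnitudes for any real coastline. Several simplifications
matter: no land market or housing, no permanent submergence or salinity (the
hazard acts only through wages), no sex-structured demography, one shared
macro-economy with fixed base wages, and a flat informal sector.

## Numerical and design choices

* Incomes are floored at 0.01 before the CRRA transform; utilities are
  computed with `expm1` so the `rho -> 1` limit is exact to first order.
* Affordability is boundary-inclusive, and a zero-cost option is affordable
  for any agent.
* The income memory is a bounded FIFO of eight observations per (agent,
  layer) with exact running sums; updates are evaluated inside the population
  environment so R does not copy the arrays each quarter.
* Life histories carry a quarter-0 baseline snapshot so that flow matrices
  rebuilt from histories reproduce the engine's move log exactly, including
  first-quarter moves.
* Every stochastic entry point takes a seed and restores the caller's RNG
  state; identical seeds give byte-identical runs, experiments and
  calibrations.

A known limitation concerns the direction of the credit–mooring
relationship. Because credit enters affordability linearly (wealth plus
`credit_multiplier` times capital), raising the multiplier mechanically
relieves the binding constraint for every capital-holding agent, and in
desk-scale ensembles the moored share *falls* with credit access even
though mean wealth rises. Mechanisms that could reverse this —
credit-financed entrenchment in saturated local labor markets, deeper
leverage cycles after repeated flood shocks — exist in the model (capacity
limits, wage-proportional access costs, interest on debt) but do not
outweigh the direct relief effect at these population sizes. The test suite
measures this direction honestly rather than asserting it.

Three realism choices deserve emphasis because they shape the credit
results. Informal income prevents an artefactual class of permanently
destitute agents (with zero income there is no saving path back into the
formal economy, and with zero capital, credit policy cannot touch them).
Consumption proportional to income keeps liquidity scarce enough that
affordability genuinely binds. Interest on debt makes credit a double-edged
instrument: it finances profitable access investments but drags on heavily
leveraged agents after flood shocks. All three are fixed configuration with
documented defaults, and all can be switched off.
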