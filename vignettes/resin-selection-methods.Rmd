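---
title: "Optimization-based resin and cut-point selection: model and methods"
author: "resinopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimization-based resin and cut-point selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Early downstream process development screens many chromatography resins in
parallel microscale (robocolumn) experiments.  For each candidate resin $r$
of each separation step $s$, run under each operating condition $c$ (a
pH / loading-salt combination), the screen records the loaded mass
$lm_{srcp}$ of every protein species $p$ and the mass $cm_{srcpt}$
collected in each time interval $t$ of a stepwise salt-gradient elution.
The species are the target protein plus product-related impurities
(e.g. aggregates and fragments).

Choosing a process means fixing, at every step, one (resin, condition)
pair and one pooling window — the start and finish cut-points between
which eluate is collected.  Two criteria compete: **yield**

$$Y = \frac{CM_{ls,dp}}{LM_{fs,dp}},$$

the target mass pooled at the last step $ls$ over the target mass loaded
at the first step $fs$, and **purity**

$$P = \frac{CM_{ls,dp}}{\sum_p CM_{ls,p}},$$

the target's share of the final pool.  Wide windows collect more target
but also more impurity; narrow windows do the opposite.

## Forward mass model

Screens are run one step at a time, so no experiment measures a
multi-step train directly.  The package bridges steps with the constant
**load-collection-ratio** assumption: the fraction

$$lcr_{srcpt} = \frac{cm_{srcpt}}{lm_{srcp}}$$

of a protein's load that elutes in interval $t$ is taken to be
independent of the load amount and of the other species.  At the first
step the model uses the measured masses directly; at every later step the
load is the previous step's pool and the predicted collected mass is
$M_{srcpt} = lcr_{srcpt} \cdot LM_{sp}$ over the selected window.  A load
twice the calibration load therefore elutes exactly twice the calibration
mass per interval — the property `evaluate_decision()` reproduces and the
acceptance script measures.

This assumption is the model's main idealization.  It ignores
load-dependent saturation (overloading shifts breakthrough), displacement
effects between species, and any pH/conductivity carry-over between
steps; it is most defensible in the linear (analytical-load) regime the
screens are run in.

Consecutive steps are linked by operating compatibility: the effective
eluent salt concentration at the upstream finishing cut-point may not
exceed that at the downstream starting cut-point.  Intervals without a
recorded concentration are made comparable by `effective_salt()`:
load/wash intervals sit before the gradient and count as 0 mM, and
regeneration intervals carry the last elution concentration forward.
This choice is what lets a solution start collecting during load/wash
(flow-through capture) while still being orderable against the next
step's gradient.

## The optimization model

Selection is encoded with binaries $Z_{src}$ (condition choice, one per
step), $X^s_{st}$ and $X^f_{st}$ (start/finish cut-points, one each per
step), the interval indicator $X_{st}$ defined by the recursion

$$X_{st} = X_{s,t-1} + X^s_{st} - X^f_{s,t-1},$$

and the joint indicator $W_{srct} = X_{st} \cdot Z_{src}$, linearized by
gating rows.  The recursion makes the selected intervals a contiguous
block from the start-marked interval to the finish-marked interval,
*inclusive of the start interval*; an inverted pair of cut-points drives
$X$ negative and is infeasible — with one exception: a start cut placed
immediately after the finish cut encodes the all-zero, *empty* window.
Collecting nothing is operationally meaningless (and would let the solver
"satisfy" any purity floor vacuously), so the model adds one row per
step, $\sum_t X_{st} \ge 1$, restricting decisions to genuine windows
with start $\le$ finish.  Mass balance rows fix first-step masses
to the data, apply the ratio prediction at later steps through big-M
rows, pool per-step totals, and carry each pool to the next step's load.
The purity requirement is kept in mass form,
$CM_{ls,dp} \ge \varepsilon \sum_p CM_{ls,p}$, avoiding any division.

Two implementation choices depart from the obvious transcription, both
recorded here deliberately:

* **Implied-integer relaxation.**  $X$ and $W$ are declared continuous in
  $[0,1]$.  Given binary cut-points and condition choices, the recursion
  determines $X$ uniquely and the gating rows pinch $W$ to exactly
  $X \cdot Z$, so every solution is integral in them; removing them from
  the branching space cuts full-scale solve times roughly threefold.
  `extract_decision()` verifies integrality of every selection variable
  on every solve, so a violation of this argument would surface loudly.
* **Valid cuts.**  The disaggregated rows $W \le X$, $W \le Z$ and the
  aggregation equality $\sum_{rc} W_{srct} = X_{st}$ (exactly one
  condition is active) are added alongside the aggregated big-M gating
  rows.  They change no integer solution but tighten the LP relaxation
  substantially.

Big-M constants are never a single "large number": each ratio row uses
$U = lcr_{srcpt} \cdot \overline{LM}_{sp}$, where the loaded-mass bound
$\overline{LM}_{sp}$ is the largest first-step experimental load,
propagated unchanged along the train (interval ratio sums never exceed
1, so pools cannot grow).  Gating rows use the count of summed binaries.
A dedicated test confirms the bounds dominate every mass an exhaustive
enumeration ever observes, and that artificially shrinking one changes
an optimum — i.e. the bounds are active guarantees, not decoration.

## Solving the fractional program

For a fixed purity floor $\varepsilon$ the problem maximizes a ratio of
two affine functions over a mixed-integer polyhedron — a mixed-integer
linear *fractional* program.  It is solved with **Dinkelbach's
algorithm**: with parameter $f \ge 0$, solve the MILP

$$\max\; CM_{ls,dp} - f \cdot LM_{fs,dp},$$

then update $f \leftarrow CM^*/LM^*$ until the optimal value (the
*residual*) is within $\delta$ of zero.  The package initializes $f = 0$,
which makes the first MILP maximize pooled target mass outright and
guarantees a feasible starting ratio; the denominator is always positive
because loaded masses are required to be strictly positive.  The $f$
iterates increase strictly and the residuals decrease — both are asserted
on every run.  Defaults: $\delta = 10^{-9}$ mg (absolute, on the
mass-scale residual), at most 50 iterations with a loud failure status,
and a 0% MILP optimality gap so each iterate is a proven optimum.  The
tolerance is deliberately tight: terminating at a looser $\delta$ leaves
the incumbent only $\delta/LM$-optimal in yield, whereas with exact MILP
solves one further iteration lands on the exact optimum with a residual
at numerical zero.  In
practice two to three iterations suffice.  When every first-step
experiment loads the same target mass the denominator is a constant and a
single MILP solves the problem; `solve_fixed_load()` implements that
special case and the suite checks it agrees with the general route.

Since the constraint set is independent of $f$, the model is built once
per $\varepsilon$ and only the objective is updated between iterations.

MILPs are solved by HiGHS via `scipy.optimize.milp`, behind an abstract
model container (`milp_model()`), through a bundled Python helper kept
alive as a persistent worker process; hundreds of small solves in a sweep
then cost milliseconds each rather than an interpreter start-up.

## Mapping the frontier

The bi-objective problem is scalarized by the **ε-constraint method**:
purity becomes the constraint above, yield is maximized, and $\varepsilon$
sweeps a grid — by default 90% to 99% in steps of 1% (ten solves),
overridable everywhere.  A solution of the scalarized problem is only
guaranteed *weakly* Pareto-optimal when optima are non-unique, so the
sweep post-filters its points: `filter_dominated()` retains exactly the
maximal set under the componentwise order and collapses duplicates, and
is itself tested against a quadratic reference filter on random clouds.
Infeasible floors are recorded and skipped, not errored.

## The enumeration oracle

The decision space is finite:
$\prod_s |\{(r,c)\}_s| \cdot T_s(T_s+1)/2$ window/condition combinations,
filtered by salt linking.  `oracle_max_yield()` and `oracle_pareto()`
evaluate *all* of them with the same forward simulation and take exact
optima.  The oracle is deliberately free of pruning so its correctness is
self-evident, and it aborts loudly beyond a decision budget (default
$5 \times 10^6$) rather than sampling; a full-scale CEX+MM campaign
(about $3 \times 10^7$ decisions) exceeds the budget by design — the
oracle exists to certify the MILP route on reduced instances, which the
central test does on 25 seeded instances at four purity floors each,
demanding agreement to $10^{-9}$.

## Synthetic campaigns

Because real screening tables are proprietary, the package ships a seeded
generator.  Elution is modelled as a Gaussian peak in effective salt —
the standard idealization of gradient chromatography — discretized onto
the elution intervals and scaled so a `recovery` fraction (default 0.95)
of each load is collected, with a small `flowthrough_frac` (default 0.02)
placed uniformly over load/wash intervals.  Peak centers and widths are
perturbed multiplicatively per (resin, condition), one draw shared by all
species, so condition chemistry shifts whole chromatograms and
identically-parameterized species remain genuinely co-eluting; no
condition dominates by construction.  `separability_knob()` moves
impurity centers a chosen distance from the target's center, from
indistinguishable (maximum purity = load purity) to near-baseline
separation.  Peak weights below `weight_floor` (default $10^{-6}$ of the
recovered mass) are reported as exact zeros and the remainder
renormalized, emulating an assay's limit of quantification: real HPLC
tables contain zeros below the LOQ, not arbitrarily small tail masses,
and sub-picogram entries only manufacture meaningless near-ties for the
optimizer.

`preset_cex_mm()` mirrors the structure of an industrial two-step
Fc-fusion screen: a CEX step (8 resins × 2 conditions, 17 intervals,
0–300 mM gradient starting at T4 after two load and one wash interval)
feeding a mixed-mode step (3 resins with 7/8/12 conditions, 29 intervals,
0–1000 mM gradient plus two regeneration intervals), loading a mixture of
86.2% monomer (target), 10.6% aggregates and 3.2% fragments.  Default
peak parameters (monomer 150 mM, aggregates 260 mM, fragments 60 mM;
widths 35–50 mM) were chosen once as a plausible mid-gradient separation
with overlapping shoulders — hard enough that yield and purity genuinely
trade off.

What the generator does *not* emulate: measurement noise in HPLC
quantification, load-dependent (nonlinear) adsorption, pH effects
distinct from salt, or inter-protein displacement.  Tests passing on
synthetic data therefore certify the *optimization machinery* — data
model, mass balance, MILP correctness, frontier logic — not the fidelity
of the constant-ratio assumption to any particular real process.

## Numerical choices and degenerate inputs

* Masses are mg, salt is mM, intervals are 1-based labels T1…T$n$; no
  unit conversion layer exists.
* Inside the MILP, masses are rescaled so the largest first-step load
  sits at $10^4$: solver feasibility and optimality tolerances are
  absolute, and the rescaling makes them about $10^{-11}$ relative to the
  data, which is what lets the oracle-agreement tests demand $10^{-9}$.
  Load-collection ratios (and scaled masses) below $10^{-8}$ are treated
  as exact zeros in the model: solver presolve routines drop or mangle
  matrix coefficients that small, and an explicit documented zero
  (physically, $\sim 10^{-12}$ of the load) is strictly safer.  Reported
  metrics are unaffected — they always come from the full-precision
  forward simulation.
* Purity of an empty pool (zero collected mass) is undefined; it is
  returned as `NA` with an `empty_collection` flag rather than 0/0.  In
  the MILP the mass-form purity row is vacuously satisfied by an empty
  pool, and the oracle treats it the same way, so the two routes agree.
* Salt-linking comparisons carry a $10^{-9}$ mM slack; purity floors are
  enforced exactly in the MILP and checked with $10^{-9}$ slack when
  recomputed in floating point.
* Ties between optimal decisions are legitimate (the MILP may return any
  optimum); reported metrics are always recomputed from the decision by
  forward simulation, and the sweep's dominance filter removes whichever
  weakly dominated representatives result.  The oracle breaks ties
  lexicographically by (resin, condition, start, finish) per step, so its
  answers are reproducible.
* Mass conservation on input is validated with $10^{-8}$ mg slack to
  absorb text-format round-trips.

## Problem sizes used in the shipped checks

Unit and acceptance tests run on two-step instances with 2–4 condition
pairs and 6–7 intervals per step (decision spaces of a few thousand,
small enough for the oracle to enumerate) plus one full-scale synthetic
CEX+MM campaign, for which a complete fractional solve takes roughly half
a minute on a single CPU.  The frontier sweeps in the examples use the
default ten-point grid.

## Known limitations

* The constant-ratio assumption is calibrated per condition from a single
  load level; its accuracy under industrial column loading must be
  verified at scale.
* Impurities not quantified in the screen (HCP, DNA, virus) are outside
  the purity definition.
* The integrated model chains steps only through mass and a monotone
  salt-compatibility constraint; buffer exchange, concentration and hold
  steps are not modelled.
* Resin cost and productivity are not objectives; the frontier is
  yield–purity only.
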