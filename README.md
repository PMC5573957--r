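# resinopt

Optimization-based selection of chromatography resins, operating
conditions and elution pooling cut-points for protein purification
process development.

## The problem

High-throughput screening (HTS) campaigns test many candidate resins in
parallel microscale chromatography experiments: for each separation step
*s*, resin *r* and operating condition *c* (a pH / loading-salt
combination), the screen records the loaded mass *lm* of every protein
species and the mass *cm* collected in each time interval *t* of a
salt-gradient elution.  Process developers must turn those tables into
decisions — which resin to run at each step of a multi-step train, under
which condition, and between which cut-points to pool the eluate — while
trading off two criteria for the target protein *dp*:

- **yield**  Y = CM<sub>ls,dp</sub> / LM<sub>fs,dp</sub> (target mass pooled at the last step over target mass loaded at the first), and
- **purity**  P = CM<sub>ls,dp</sub> / Σ<sub>p</sub> CM<sub>ls,p</sub> (the target's share of the final pool).

Because screens are run one step at a time, multi-step performance is
predicted with the constant **load-collection-ratio** assumption:
the fraction lcr = cm/lm of a protein's load eluting in each interval is
independent of the load amount, so a later step loaded with mass LM is
predicted to elute lcr·LM per interval.  Consecutive steps must also be
salt-compatible: the eluent concentration at the upstream finishing
cut-point may not exceed that at the downstream starting cut-point.

resinopt encodes this as a mixed-integer program (binary condition and
cut-point choices, linear mass balances, a mass-form purity floor
CM<sub>ls,dp</sub> ≥ ε·Σ<sub>p</sub>CM<sub>ls,p</sub>), maps the
yield–purity trade-off by the **ε-constraint method**, and solves each
fixed-ε subproblem — a mixed-integer linear *fractional* program — with
**Dinkelbach's algorithm**, i.e. a short sequence of MILPs
max CM − f·LM with f updated to the incumbent ratio until the residual
vanishes.  MILPs are solved to a 0% optimality gap by HiGHS
(`scipy.optimize.milp`) behind an abstract backend.  An exhaustive
enumeration oracle certifies the whole pipeline on small instances, and a
seeded synthetic-data generator emulates a two-step CEX → mixed-mode
campaign so everything is testable without proprietary data.

## Installation and requirements

```sh
R CMD INSTALL .
```

Requires the R packages `jsonlite` and `yaml`, plus a `python`
interpreter with `numpy` and `scipy` (≥ 1.9) on the PATH — the MILP
backend drives HiGHS through `scipy.optimize.milp` via a bundled helper
script, kept alive as a persistent worker so repeated solves cost
milliseconds.  Run the tests with:

```r
testthat::test_dir("tests/testthat", package = "resinopt",
                   load_package = "installed")
```

## Worked example

```r
library(resinopt)

# a synthetic two-step campaign: 8 CEX resins x 2 conditions (17
# intervals), 3 mixed-mode resins with 7/8/12 conditions (29 intervals),
# loading 86.2% monomer, 10.6% aggregates, 3.2% fragments
ds <- generate_hts(preset_cex_mm(seed = 1))
ds
#> HTS chromatography dataset
#>   steps:    CEX -> MM 
#>   proteins: monomer, aggregate, fragment (target: monomer)
#>   CEX     8 resin(s), 16 (resin, condition) pair(s), 17 intervals
#>   MM      3 resin(s), 27 (resin, condition) pair(s), 29 intervals

rt <- compute_ratios(ds)

# one fractional solve: maximum yield subject to >= 95% purity
res <- solve_milfp(ds, rt, eps = 0.95)
res
#> Dinkelbach fractional solve (eps = 0.95 )
#>   status: converged 
#>   iterations: 2 
#>   yield = 0.7742, purity = 0.9663

# the chosen train, window phases and salt ranges
res$decision
#>   step resin condition start finish
#> 1  CEX RCEX4   CCEX4-1     1     13
#> 2   MM  RMM2    CMM2-8    10     13
window_label(ds, "CEX", 1, 13)
#> [1] "Load, Wash, Elution (0-200 mM NaCl): T1-T13"
```

A converged solve means the decision provably maximizes yield among all
resin/condition/window combinations meeting the purity floor: here 77.4%
of the loaded monomer survives the two-step train at 96.6% purity (the
CEX step is pooled from load through the 200 mM elution interval, the
mixed-mode step from 200 to 300 mM), and the Dinkelbach residual reached
zero after 2 MILPs.  Sweeping ε maps the whole frontier:

```r
front <- run_mode(ds, "integrated", eps_grid = seq(0.90, 0.99, 0.01))
front
#> Pareto frontier: 4 nondominated solution(s)
#>   eps yield purity iterations
#>  0.90 77.4%  96.6%          2
#>  0.97 77.0%  97.7%          2
#>  0.98 76.9%  98.2%          2
#>  0.99 76.4%  99.8%          2
report_front(front)
write_pareto(front, "results/")   # pareto.csv + Dinkelbach traces
```

(The full-scale ten-point sweep above solves twenty MILPs and takes a few
minutes on one CPU; the reduced instances in the test suite solve in
fractions of a second.)

Single-step frontiers (`run_mode(ds, "single:CEX")`) drop the linking
constraint; `oracle_max_yield()` / `oracle_pareto()` recompute small
instances by brute force.  The same operations are scriptable from a
shell via `exec/resinopt` (`simulate`, `validate`, `optimize`, `oracle`,
`report` subcommands).

## Package layout

- `R/hts_data.R`, `R/io.R` — data model, validation, CSV/YAML exchange
- `R/synthetic.R` — seeded campaign generator and the CEX+MM preset
- `R/milp.R`, `R/backend.R` — abstract MILP container and the HiGHS bridge
- `R/model_builder.R` — the constraint system and big-M policy
- `R/dinkelbach.R` — fractional solver (and the equal-load special case)
- `R/pareto.R`, `R/reporting.R` — ε sweep, dominance filter, exports
- `R/oracle.R` — exhaustive enumeration oracle
- `vignettes/resin-selection-methods.Rmd` — model, assumptions, design
  choices and limitations
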