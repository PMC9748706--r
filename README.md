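# ohpgame

Tripartite evolutionary game dynamics of online healthcare platform (OHP)
adoption.

## The problem

An online healthcare platform succeeds only if three bounded-rational
populations move together: **doctors** decide whether to *join* the platform,
**patients** whether to *use* it, and **platforms** whether to *provide*
standardized services — full doctor-qualification inspection and full
investment in information protection. Each side's incentive depends on what
the other two are doing: doctors fear reputation and data-leakage losses on
a sloppy platform, patients weigh time and money saved against misdiagnosis
and privacy risk, and the platform weighs inspection and protection costs
against economic and reputational returns. `ohpgame` is for modellers and
health-systems researchers who want to study which adoption regimes are
evolutionarily stable and which interventions (inspection strength,
protection investment, cost reductions) tip the system from collapse to
full adoption.

## The model

Strategy shares live on the unit cube: `x` (doctors joining), `y` (patients
using), `z` (platforms providing). Payoffs come from a 2×2×2×3 tensor built
from 23 scalar parameters; in *not provide* cells the platform only exerts
inspection strength `α ∈ (0,1)` and protection strength `β ∈ (0,1)`, so
losses scale with `(1−α)` and `(1−β)`. Each population follows replicator
dynamics

```
dx/dt = x(1−x)(P11 − P12),   dy/dt = y(1−y)(P21 − P22),   dz/dt = z(1−z)(P31 − P32)
```

where `P11, P12, …` are the conditional expected payoffs of each pure
strategy against the current mixed population. The eight cube corners
V0(0,0,0) … V7(1,1,1) are always fixed points; the package classifies them
(and any interior root E(x\*, y\*, z\*)) by the real parts of the Jacobian
eigenvalues, reading asymptotic stability as the multi-population notion of
an evolutionarily stable strategy (ESS).

Two equation variants are provided: `matrix_derived` (default; brackets
derived from the payoff tensor) and `as_printed` (the literal closed-form
equations, whose doctor component lacks a `(1−z)` gate on the
reputation-loss term). See the methods vignette for why both exist.

## Worked example

```r
library(ohpgame)
g <- ohp_game()          # baseline parameters, alpha = beta = 0.9
summary(g)
```

```
Equilibria of the replicator system (matrix_derived variant)

 name      x      y      z  residual   eig1    eig2    eig3        classification
   V0 0.0000 0.0000 0.0000 0.000e+00 -0.300 -2.4000 -4.0000 asymptotically-stable
   V1 1.0000 0.0000 0.0000 0.000e+00  4.000  0.1000 -2.1000                saddle
   ...
   V7 1.0000 1.0000 1.0000 0.000e+00 -3.000 -5.0000 -6.9000 asymptotically-stable
   E1 0.3595 0.6688 0.1265 3.436e-15  1.031 -0.5156 -0.5156                saddle

Evolutionarily stable states: V0, V7
```

The baseline regime is bistable: universal abandonment V0 is always locally
stable (walking away is self-reinforcing once rare participation makes
joining, using and providing each unprofitable), and under high inspection
and protection strength full cooperation V7 is stable too, separated by the
saddle E1. A mixed start flows to full adoption:

```r
tr <- simulate(g, init = c(0.5, 0.5, 0.5), horizon = 30)
tr
#> OHP strategy trajectory: 501 points over t = [0, 30], matrix_derived variant, lsoda integrator
#> converged to (1, 1, 1) by t = 3.18
```

Weakening inspection flips the outcome, and the weaker it is the faster
doctors leave:

```r
run_scenarios(scenario_library()[c("fig1_alpha_low", "fig1_alpha_mid", "fig1_alpha_high")])
#>          scenario x y z converged time_to_tol match
#> 1  fig1_alpha_low 0 0 0      TRUE        22.5  TRUE
#> 2  fig1_alpha_mid 0 0 0      TRUE        23.0  TRUE
#> 3 fig1_alpha_high 1 1 1      TRUE         3.2  TRUE
```

`scenario_library()` ships 20 named scenarios in eight families — low /
medium / high inspection strength `α` and protection strength `β` (0.1,
0.5, 0.9), doctor and patient initial shares 0.2 / 0.9, and low / medium /
high levels of registration cost `c1`, time cost `c2`, reputation loss
`c3` and patient usage cost `h1` — each annotated with its expected
qualitative limit.

A command-line launcher (`inst/scripts/ohpgame`) exposes `simulate`,
`equilibria`, `sweep` and `check` subcommands over YAML parameter configs;
`ohp_cli()` is the same entry point from R.

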