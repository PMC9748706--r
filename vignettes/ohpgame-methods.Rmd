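---
title: "Methods: the tripartite OHP adoption game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tripartite OHP adoption game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohpgame)
```

## The model and its assumptions

Three large populations interact around an online healthcare platform
(OHP). Doctors either *join* or stay out; patients either *use* the
platform or go to hospital; the platform either *provides* standardized
services — complete doctor-qualification inspection and complete
information-protection investment — or does not. The state is the triple of
strategy shares $(x, y, z) \in [0,1]^3$.

Payoffs are given by a $2\times2\times2$ matrix of triples (23 scalar
parameters; see `?ohp_params`). The structural assumptions are:

* a doctor who stays out earns 0 in every cell; a patient who stays out
  always gets the hospital benefit $e_2$, which strictly exceeds the
  platform's pure health benefit $e_1$;
* when the platform provides, inspection and protection are complete, so
  none of the $(1-\alpha)$/$(1-\beta)$-scaled losses or compensations
  arise; when it does not, it exerts only inspection strength
  $\alpha \in (0,1)$ and protection strength $\beta \in (0,1)$, pays the
  scaled costs $\alpha t_1 + \beta t_2$, and the residual risks
  $(1-\alpha)$, $(1-\beta)$ fall on doctors (reputation loss $c_3$, leakage
  loss $c_4$), patients (health loss $h_2$, disease- and
  identity-information leakage $h_3$, $h_4$) and the platform itself
  (compensations $F_1, F_2, F_3, G$ and, in the join+use cell, reputation
  loss $N$);
* all agents are bounded-rational imitators, which motivates replicator
  dynamics: a strategy's share grows at rate proportional to the gap
  between its conditional expected payoff and the population average,
  $\dot s = s(1-s)\,(P_{\text{active}} - P_{\text{complement}})$.

Because each velocity carries the factor $s(1-s)$, all eight cube corners
are fixed points regardless of parameters, and the cube is forward
invariant. Payoffs are unitless: replicator dynamics are invariant to a
common positive rescaling of any one player's payoffs, a property the test
suite exploits.

## The two equation variants

The closed-form equations printed for this model disagree with the payoff
matrix in one term: the doctor equation carries the reputation loss as
$y(1-\alpha)c_3$, while the matrix places that loss only in *not provide*
cells, which yields $y(1-z)(1-\alpha)c_3$. The two coincide exactly on the
$z = 0$ face (and when $c_3 = 0$ or $\alpha \to 1$); the patient and
platform equations agree with the matrix everywhere. We treat the payoff
matrix as the authoritative primitive — it is the model's definition, and
the conditional-expectation derivation from it is mechanical — so
`variant = "matrix_derived"` is the default. The literal closed forms
remain available as `variant = "as_printed"` throughout (dynamics,
Jacobians, equilibrium search) so either reading can be probed; we do not
guess which the original authors intended.

A related piece of surrounding prose asserts that each population's mean
fitness is positive on the open interval; this is not generally true and is
treated as non-normative.

## Stability analysis

At a corner the Jacobian is diagonal — every off-diagonal entry carries a
factor $s(1-s) = 0$ — and its eigenvalues are the signed incentive
brackets $(1-2s_i)B_i$. Classification uses eigenvalue real parts: all
negative is *asymptotically stable*, which we take as the multi-population
operationalization of an evolutionarily stable strategy (the 1-D sign
condition on $P'$ generalizes ambiguously to three populations; Lyapunov's
indirect method is the standard reading). All positive is *unstable*, mixed
is *saddle*, and any real part within $10^{-9}$ of zero is labelled
*non-hyperbolic* rather than force-classified, because linearization is
inconclusive there.

Non-hyperbolicity is not an edge case to be engineered away: at $x = 0$,
$z = 1$ the patient bracket vanishes identically (with no doctors on a
providing platform, using and not using both pay $e_2$), so the corners
V5(0,1,1) and V6(0,0,1) are non-hyperbolic for *every* admissible parameter
set. Consistency checks between classification and perturbation fate
therefore apply to hyperbolic corners only.

Two universal structural facts are worth noting and are tested as
properties: V0(0,0,0) is asymptotically stable for every parameter set with
strictly positive $c_1$, $h_4$, $t_1$, $t_2$ (non-adoption is always
locally absorbing — the deepest obstacle to platform promotion), and
V7(1,1,1) is stable exactly when $r_1 - c_1 - c_2 > 0$,
$e_1 - e_2 + e_3 - h_1 + L > 0$ and the platform's full-adoption bracket is
positive.

The interior point $E(x^*, y^*, z^*)$ solves the three bracket equations
simultaneously. Existence is not guaranteed and is reported per parameter
set: `interior_equilibrium()` runs a seeded 50-point Latin-hypercube
multi-start (Gauss–Newton via `pracma::fsolve`), accepts roots at bracket
residual below $10^{-8}$, discards face solutions, and deduplicates at
radius $10^{-4}$. Under the baseline an interior saddle exists and sits on
the boundary between the V0 and V7 basins.

## Numerical choices

* **Integration.** Continuous time (the model is written as ODEs; figure
  labels indexing initial values at "1" are read as $t = 0$ initial
  conditions, not a discrete map). `deSolve::ode` with lsoda,
  `atol = 1e-10`, `rtol = 1e-8`, 501 output points over a default horizon
  of 50 time units — long enough that every shipped scenario settles well
  within it. States are clipped to $[0,1]$ at each RHS evaluation and on
  output; pre-clip excursions are bounded by the solver's interpolation
  accuracy (observed $< 10^{-8}$), and anything larger raises a warning. A
  fixed-step Euler integrator (`integrate_trajectory_euler`, step
  $10^{-3}$) serves as an independent cross-check; endpoint agreement is
  asserted at $10^{-4}$ sup-norm on converging runs.
* **Convergence detection.** A trajectory "converges" to the corner nearest
  its terminal state if it stays within $10^{-3}$ (sup-norm) of it over the
  trailing 10% of the time span; `time_to_tol` is the first time from which
  the distance stays below tolerance.
* **Degenerate inputs.** $\alpha, \beta \in \{0, 1\}$ are rejected (loss
  terms degenerate at the endpoints); states outside the cube beyond
  $10^{-9}$ are domain errors; `e1 >= e2` is rejected.
* **Jacobians.** Analytic partials are the default; the finite-difference
  check uses central differences on the polynomial extension of the RHS,
  which is valid just outside the cube and keeps second-order accuracy at
  faces and corners.

## What the scenario generator emulates — and what it does not

The source analysis reports only qualitative simulation outcomes; its
numeric parameter values are not published. The baseline here
(`baseline_params()`, see `?ohp_params` for the 23 values) is therefore the
package's own, chosen once to satisfy every inequality regime the
qualitative narratives require, and the scenario families are derived from
it by single-parameter overrides:

* $\alpha$ and $\beta$ at 0.1 / 0.5 / 0.9 (the stated low / medium / high
  levels), with the baseline at the high level;
* initial doctor and patient shares at 0.2 and 0.9 against a mixed
  (0.5, 0.5, 0.5) default start;
* cost levels defined relative to the sign-flip points of the relevant
  incentive bracket rather than by ad-hoc magnitudes: *low* is half the
  smaller of the bracket's corner flip (zero at full adoption) and start
  flip (zero at the mixed start), so the incentive is positive from $t=0$;
  *high* is twice the larger, so exit is forced even at full adoption. The
  pure corner-flip rule was not used on its own because at half the corner
  flip the early-time incentive at the mixed start can still be negative,
  and in this doctor-led system an early doctor dip drags patients and
  platform down before adoption can build — the expected limit would then
  depend on a race the rule does not control. *Medium* time cost is
  $1.25\times$ the corner flip (full adoption destabilized, exit gentle);
  *medium* usage cost is the start flip itself (patient incentive exactly
  balanced at $t=0$, with the platform's early rise breaking the tie toward
  adoption, giving the narrated dip-then-adopt path). Reputation loss $c_3$
  vanishes from the bracket at $z=1$, so its corner flip is taken at
  $(y{=}1, z{=}0)$.

The baseline's magnitudes (costs and benefits of order 2–20) make the
system *doctor-led*: patients need doctors and the platform needs both, so
collapse propagates from doctor exit. That is also why one narrated outcome
cannot hold in this model: under medium protection strength the narrative
has doctors and platforms abandoning while patients keep using, but with
$x \to 0$ and $z \to 0$ the patient bracket is forced to
$-(1-\beta)h_4 < 0$, so $y \to 0$ as well. The shipped scenario
(`fig2_beta_mid`) therefore asserts the doctor and platform limits and
leaves the patient coordinate unspecified. Medium-level transient shapes
(rise-then-fall) are reproduced on a best-effort basis and never asserted,
since they depend on unpublished magnitudes.

Random parameter sets for property tests (`sample_params()`) draw every
cost, benefit and compensation uniformly on $(0.1, 10)$ — the magnitude
range the baseline inhabits, bounded away from the degenerate zero-cost
edge — and $\alpha, \beta$ on $(0.05, 0.95)$, rejecting until $e_1 < e_2$.

**What passing scenarios do and do not show.** The library demonstrates
that the model *can* produce every narrated qualitative regime under a
documented admissible parameterization — not that these parameter values
describe any real platform, and not that the narrated outcomes are the only
ones the model admits. Nothing here is estimated from data; the model
remains a stylized deterministic mean-field description with no population
structure, no noise (no finite-population or Moran dynamics), and no
time-varying parameters.

## Problem sizes used in the checks

The automated checks use 1,000 random (parameter, state) samples for the
equation cross-checks, 200 parameter sets × 10 perturbations for the
universal-V0 property, all 20 scenarios at horizon 50 for the qualitative
reproduction, 5 perturbations per hyperbolic corner across the deduplicated
scenario parameter sets for classification consistency, and a 0.01-resolution
grid scan of the cube as the independent locator of the interior root.

## Known limitations

* ESS is identified with local asymptotic stability; no global
  basin-of-attraction computation beyond sampled trajectories, and no
  center-manifold analysis at the structurally non-hyperbolic corners.
* The interior-root search is a multi-start local method; with 50
  Latin-hypercube starts it reliably finds the single interior root of the
  regimes studied here, but it cannot certify absence in general.
* The `as_printed` doctor equation is reproduced verbatim, including its
  disagreement with the payoff matrix; results under that variant should be
  interpreted accordingly.
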