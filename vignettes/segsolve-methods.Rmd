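---
title: "Methods: solving Stackelberg evolutionary games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solving Stackelberg evolutionary games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segsolve)
```

## The game and its assumptions

A Stackelberg evolutionary game couples one rational player to a population
of evolving followers.  The followers are described by a fitness-generating
function `G(v, u, x, m)`; substituting the resident trait `v = u_i` yields
the per-capita growth rate of type `i`, so the Darwinian dynamics are

$$\dot x_i = x_i \, G|_{v=u_i}, \qquad
  \dot u_i = \sigma_i \, \partial G/\partial v|_{v=u_i}.$$

The solver layer makes three standing assumptions: follower traits are
scalar (one evolving trait; further types may be present with frozen
traits), the leader plays a constant scalar action `m` on a closed
interval, and the leader's objective `Q(m, u, x)` is finite and
differentiable at the ecological equilibrium `x*(m, u)`.  Transient-payoff
and time-varying-control formulations are intentionally out of scope: all
leader solutions here are constant actions evaluated at eco-evolutionary
equilibrium.

The evolutionary speed `sigma` is treated as a constant per type.  This is
the conventional simplification; a speed proportional to population size
(as in the canonical equation of adaptive dynamics) is available through
`sigma_mode = "linear_x"` in `gfun_model()`.  No other density dependence
of the speed is offered, since no canonical functional form exists.
Because all equilibrium quantities (`x*`, `u*`, every leader strategy) are
independent of `sigma`, the choice affects only trajectories; the built-in
models default to `sigma = 1`, which makes ecological and evolutionary
time scales comparable and keeps test integrations short.

## Ecological equilibria

`ecological_equilibrium()` must return the *stable, reachable* equilibrium,
not merely a root.  It enumerates all subsets of extant types, Newton-solves
`G_i = 0` on each subset (other types pinned at zero, numerical Jacobian,
damped steps kept positive), and screens candidates by three conditions:
extant populations positive, absent types unable to invade
(`G_j <= 0`), and all eigenvalues of the ecological Jacobian of
`x_i G_i` with non-positive real part (tolerance `1e-7`).  The all-extinct
state passes only when no type can grow from rarity.  If several
candidates survive — a genuinely multistable ecology — the tie is broken
by forward integration of the ecological subsystem from `init_x`
(default: the model's carrying-capacity scale), which is the observable
"equilibrium reached from here".  Subset enumeration is exponential in the
number of types but the package targets the one- and two-type models for
which it is exact and cheap; integration is only a fallback.

## Singular strategies, ESS classification, branches

`ess_solve()` reduces the coupled problem to a scalar root-find: the
selection gradient along the resident-equilibrium manifold,
`g(u) = \partial G/\partial v|_{v=u,\,x=x^*(m,u)}`, evaluated on a 41-point
uniform grid over the trait bounds, with roots bracketed by sign changes
and polished by `uniroot` to `1e-12`.  Two non-obvious details:

* **Refinement next to exact zeros.**  Symmetric models have `g(0) = 0`
  identically.  Just above a pitchfork the two new roots sit inside the
  grid cells adjoining `u = 0` and produce no sign change between original
  grid values; the grid is therefore refined tenfold in the two cells
  around every exact zero.  Without this, branches would appear only once
  they had drifted a full grid cell away from the centre.
* **Boundary candidates.**  When the gradient points outward at a closed
  trait bound (e.g. the resistance trait at `u_R = 0` under a negligible
  dose, where the cost of resistance dominates), the bound itself is a
  pinned singular strategy and is classified by the invasion test alone.

Each candidate is classified three ways: curvature
`\partial^2 G/\partial v^2` (central difference, step `1e-4`), a 401-point
grid invasion test with tolerance `1e-9`, and convergence stability.  An
entry is an ESS only if the invasion test passes and the curvature is
non-positive.  Convergence stability is decided by the sign of the
resident-manifold gradient on both sides of the candidate (`u* ± 1e-4`,
one-sided at bounds): the strategy is convergence stable iff the
monomorphic trait flow returns to it.  Under this definition the central
singular strategy of the fisheries model *loses* convergence stability
above the bifurcation — trajectories run to the outer branches, as the
package's own integration tests verify.  Descriptions of such a point as a
"convergent stable minimum" identify it as a branching-type point; we
report the monomorphic flow honestly and flag the point through the
combination `classification = "min"`, `is_ess = FALSE`.

`ess_branch_diagram()` assembles branches by nearest-neighbour
continuation (greedy matching in increasing trait distance, jump bound
10% of the trait range, unmatched solutions opening new branches) and
locates bifurcations by bisecting the curvature sign change along a branch
to `1e-6` in `m`.  A sign change at which the number of singular
strategies jumps by two is labelled a pitchfork.  After the ESS splits,
the two outer branches are reported as separate monomorphic ESS entries —
the coalition (ESSet) interpretation of the pair is left to the caller,
and dimorphic coalition dynamics are not solved.  When the leader's
response intersects both symmetric branches the two Nash solutions are
payoff-equivalent; `nash_solve()` returns the branch asked for and attaches
the mirrored twin.

## Leader strategies

`leader_best_response()` scans 201 grid actions (warm-starting the
equilibrium solves along the grid) and refines the best cell with
`optimize`; exact payoff ties are broken toward the smaller, less
aggressive action, and a flat objective returns the lower bound with a
warning.

`nash_solve()` runs in three phases: (1) damped alternation
(`u <- u*(m)`, `m <- m*(u)`, damping 0.5) until the step falls below
`2e-3` of the action range — this selects the branch and gets close; (2)
the fixed point is then a root of `psi(m) = m*(u*(m)) - m`, bracketed
around the damped iterate and solved by `uniroot` to `1e-11` (the damped
map alone contracts too slowly near the fixed point for tight tolerances);
(3) the stationarity condition `dQ(m, u, x*(m, u))/dm = 0` (trait held at
the solved ESS, then re-tracked) is polished to root tolerance so that
reported first-order residuals vanish to `1e-5` even on payoff scales of
10^3.  A fixed point pinned at an action bound is accepted as such.

`stackelberg_solve()` maximizes the bilevel payoff along each ESS branch of
the diagram.  The bilevel objective is only piecewise smooth: every branch
segment contributes its refined interior maximum, its endpoints, and every
detected bifurcation action as candidates.  This matters in the fisheries
game, where the optimum sits exactly at the pitchfork — the payoff climbs
along the central branch up to `m_c` and falls along the outer branches
beyond it, so the maximizer is a kink, not a stationary point.  The solver
reports `at_bifurcation = TRUE` and `foc_residuals()` returns `NA` for the
Stackelberg condition there rather than pretending a derivative exists.

`theorem41_check()` measures `du*/dm` (central difference, step `1e-4`,
one-sided per branch at a bifurcation), `dQ/du`, `dQ/dx` and `dx*/du` and
reports which coincidence case holds.  Population sensitivities are
computed on the model's population scale (`x / x_scale`): on raw counts of
order 10^4 a finite difference of a quantity that vanishes analytically
would be dominated by solver noise, while on the normalised scale the
envelope property is resolved to below `1e-5`.

## The built-in games

**Fisheries** (`fisheries_model()`): defaults `r = 1` (per time),
`K_max = 10^4` (biomass), `sigma_K = 0.55`, `sigma_H = 0.50` (trait
units), `c = 500` (currency per effort), trait bounds `[-2, 2]`, actions
`[0, 1]`.  Every solver output is cross-checked against
`fisheries_closed_forms()`, which was derived by hand before the numeric
build: `x* = K(u)(1 - H(u, m)/r)`,
`m_c = r\sigma_H^2/(\sigma_K^2 + \sigma_H^2) \approx 0.45249`,
`u_\pm = \pm\sigma_H\sqrt{\ln(m/m_c)}`, `m^*(0) = (r/2)(1 - c/K_{max})
= 0.475`.  Since `m^*(0) > m_c`, the Nash solution sits past the
bifurcation (`m_N \approx 0.643`, `u_N \approx \pm 0.296`) while the
Stackelberg solution harvests exactly at `m_c` with the trait at its
carrying-capacity optimum; raising the cost until `m^*(0) \le m_c` (e.g.
`c = 2000`) makes the two coincide, the no-trait-response case.

**Cancer** (`cancer_model()`): types (S, R) with `u_S = 0` frozen
(`sigma_S = 0`), resistance bounds `[0, 5]`, dose in `[0, 1]`.  Defaults:
`r_max = 0.45`, `g = 0.8`, `K = 10^4` cells, `d = 0.01`, `k = 2`,
`b = 10`, competition `alpha_SS = alpha_RR = 1`, `alpha_SR = 0.1`,
`alpha_RS = 0.9` (`alpha[i, j]` = effect of `j` on `i`; a rare mutant of
type R experiences the R row), progression threshold `delta = 0.7`,
objective weights `Q_max = 1`, `c1 = 0.54`, `c2 = 0.21`, `c3 = 0.25`.
The kill term is implemented as `m/(k + b v)`, the only reading under
which `k` acts as innate resistance present before drug exposure and `b`
as the benefit of evolved resistance; the resistance cost is the literal
exponential `r(v) = r_{max} e^{-g v}` with `v` constrained non-negative.
The burden entering the objective is the raw total `x_S + x_R` over the
nominal carrying capacity `K`, taken literally.

At these defaults the solver finds (all values computed by the test
suite): Stackelberg dose 0.660 with resistance 0.875 and burden 6999;
Nash dose 0.750 with resistance 0.891 and burden 6517 — the
evolutionarily enlightened physician doses less, induces less resistance
and achieves the higher quality of life; both stabilize the tumour
(burden below `delta K = 7000`).  Setting `c2 = 0` removes the trait from
the objective and the two doses coincide to below `1e-5`, which is exact
rather than approximate: at the resistant ESS the equilibrium burden is
stationary in the trait (the interior stationarity condition
`g d w^2 + g m w - m b = 0`, `w = k + b u`, is precisely the vanishing of
`dc_R/du`, hence of `dx^*/du` — the envelope property, which holds here
even with both types coexisting).  One caveat this machinery makes
explicit: the maximum tolerable dose (`m = 1`) drives the sensitive type
extinct and the resistant type to an equilibrium burden of about 5394,
i.e. 54% of `K`, which the threshold `delta = 0.7` classifies as
stabilization, not progression — at equilibrium, in this parameterization,
the aggressive dose is inferior in payoff but does not progress.  Claims
that maximum dosing ends in progression require either a transient
(pre-equilibrium) reading or a lower threshold; the package classifies
the computed equilibrium and leaves that interpretation to the user.

## Numerical defaults and problem sizes

Integration uses `lsoda` with `rtol = 1e-9`, `atol = 1e-10`; convergence
is declared when the sup-norm of the right-hand side is below `1e-8` at
the last two reported times (both built-in models have hyperbolic
equilibria at the default parameters, so this is unambiguous).  Negative
populations can only arise numerically and are clipped at zero with a
note.  Finite-difference defaults: gradient step `1e-6 max(1, |u|)`
(shrunk to stay inside the trait interval, one-sided with a warning at a
bound), curvature step `1e-4`, action-derivative step `1e-4`.  Branch
diagrams default to 201 grid actions over the leader bounds; the test
suite uses grids of 101 actions and integration horizons up to 1500 time
units, sizes chosen so the full suite solves both games from scratch in
about a minute on a single core.

## Limitations

Multi-trait (matrix-valued) evolution, polymorphic coalition dynamics
after branching, neighbourhood invasion stability, stochastic or
individual-based simulation, spatial structure, and time-varying leader
controls are out of scope.  The ESS search assumes a single evolving
scalar trait and at most a handful of singular points (multi-start over a
41-point grid); models with many closely spaced singular strategies would
need a denser `search_grid`.  Bifurcation detection keys on curvature
sign changes along continued branches, so bifurcations that do not change
the curvature sign at an existing branch (e.g. saddle-node pairs born far
from any tracked branch) are reported only indirectly through new
branches appearing.
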