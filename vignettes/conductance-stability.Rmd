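---
title: "Conductance-driven stability of the Hodgkin-Huxley neuron: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-driven stability of the Hodgkin-Huxley neuron: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the model, the numerical choices and the design
decisions behind `hhbif`.  Nothing here is a result the package cannot
recompute: every number quoted is produced by the test suite or by
`scripts/acceptance.R`.

## The model

The Hodgkin-Huxley membrane model is the four-dimensional autonomous
system

$$C_M \dot V = i_{ext} - \bar g_{Na} m^3 h (V - V_{Na})
              - \bar g_K n^4 (V - V_K) - \bar g_l (V - V_l),$$
$$\dot x = \alpha_x(V)(1 - x) - \beta_x(V)\,x, \qquad x \in \{m, h, n\},$$

with the classical squid-axon rate functions in the
depolarization-positive convention,

$$\alpha_m = \frac{0.1 (V-25)}{1 - e^{-(V-25)/10}},\quad
  \beta_m = 4 e^{-V/18},\quad
  \alpha_h = 0.07 e^{-V/20},$$
$$\beta_h = \frac{1}{1 + e^{-(V-30)/10}},\quad
  \alpha_n = \frac{0.01 (V-10)}{1 - e^{-(V-10)/10}},\quad
  \beta_n = 0.125 e^{-V/80}.$$

Units are fixed as mV, ms, mS/cm², µA/cm², µF/cm², so no conversion
factors appear anywhere; the state order is (V, m, h, n) throughout,
including the Jacobian layout.  The model is a point neuron: no cable
structure, no temperature scaling, no stochastic channel gating.  The
analysis throughout concerns the autonomous cell, $i_{ext} = 0$.

### Parameters and the leak reversal

| field  | default | unit    | meaning                      |
|--------|---------|---------|------------------------------|
| `g_Na` | 120     | mS/cm²  | maximal sodium conductance   |
| `g_K`  | 36      | mS/cm²  | maximal potassium conductance|
| `g_l`  | 0.3     | mS/cm²  | leak conductance             |
| `V_Na` | 115     | mV      | sodium reversal potential    |
| `V_K`  | −12     | mV      | potassium reversal potential |
| `V_l`  | 10.599  | mV      | leak reversal potential      |
| `C_M`  | 1.0     | µF/cm²  | membrane capacitance         |
| `i_ext`| 0       | µA/cm²  | injected current             |

The leak reversal deserves a note.  In this convention $V_l$ is the
free constant that pins the resting potential; the classical
literature quotes both 10.613 and nearby roundings.  We calibrated it
once, by requiring that the canonical resting equilibrium sit at
$V^* \approx 0$ and that the critical conductances be reproduced at
full printed precision, and fixed `V_l = 10.599` mV as the package
default.  The choice matters at the margins: moving to 10.613 shifts
the resting potential by ~0.01 mV and the sodium Hopf point by ~0.1
mS/cm².  All reversal potentials remain configurable fields of
`hh_params()`.

## Equilibria

At an equilibrium the three gate equations force
$x = x_\infty(V) = \alpha_x/(\alpha_x + \beta_x)$, so equilibria are
exactly the zeros of the scalar steady-state current balance
(`membrane_current_residual()`).  `find_equilibria()` scans it on a
uniform grid over $V \in [-50, 150]$ mV (2000 intervals by default —
comfortably containing every physiological equilibrium across the
conductance ranges scanned here), brackets each sign change, and
bisects to a bracket width of 1e−12 mV.  Bisection rather than a
derivative-based refiner is deliberate: it cannot overshoot, its error
is exactly controlled, and it makes the nine-plus printed digits of
the downstream critical conductances meaningful.  Duplicate roots
closer than 1e−8 mV are merged; all roots are reported.

When several equilibria coexist, downstream analysis follows the
branch continuously connected to the canonical resting state by
nearest-potential continuation (`tracked_equilibrium()`); across all
scans in the package's working ranges the root was in fact unique, but
the tracking rule is applied uniformly rather than assumed away.

### Removable singularities

$\alpha_m$ and $\alpha_n$ are ratios $0.1x/(1-e^{-x/10})$ (prefactor
0.01 for $\alpha_n$) with removable singularities at $x = 0$
($V = 25$ and $V = 10$ mV).  They are evaluated as
$x / (-\mathrm{expm1}(-x/10))$, which is accurate to machine precision
down to tiny $x$, with a second-order Taylor branch
$10 + x/2 + x^2/120$ engaged for $|x| < 10^{-7}$ so the limit value is
exact and there is no branch discontinuity.  The same treatment is
applied to the derivative, used in the Jacobian.

## Linearization and the stability verdict

The Jacobian has the arrow-like sparsity forced by the physics: each
gate relaxes independently at fixed $V$, so rows 2–4 are nonzero only
in column 1 and on the diagonal.  Its entries were derived by hand
from the model equations; because such derivations are error-prone,
the test suite checks the closed form entry-wise against a central
finite-difference Jacobian (step 1e−6) at the canonical equilibrium
and at 100 random conductance draws, at tolerance 1e−6.

The characteristic quartic
$\lambda^4 + a\lambda^3 + b\lambda^2 + c\lambda + d$ is expanded in
closed form from the sparsity pattern
(`characteristic_coefficients()`) and kept as an independent
representation of the spectrum: the Routh-Hurwitz criterion — stable
iff $a > 0$, $ab > c$, $d > 0$, $abc > c^2 + a^2 d$ — runs entirely
through these coefficients, while eigenvalues are computed separately
by a dense eigensolver (never the quartic formula).  The two routes
are cross-checked on thousands of random matrices with the same
sparsity.  Each Routh-Hurwitz quantity within 1e−10 of zero yields the
verdict `"boundary"` instead of a sign call; eigenvalue pairs whose
real part is below 1e−8 in magnitude are reported as 0-consistent
(such residuals are numerical zeros at a Hopf point).

## Hopf points by bisection

`find_hopf()` bisects one conductance on the *sign* of the stability
margin (largest eigenvalue real part) until the bracket is narrower
than 1e−9 mS/cm², reporting the midpoint; with margin slopes of order
1e−3 (1/ms)/(mS/cm²) this leaves the critical pair's real part at
~1e−12, far inside the 1e−8 zero band.  Bisection on the sign — rather
than eigenvalue-tracking continuation — is robust, derivative-free and
reproducible to the last digit.  The located points with canonical
companions are

* $\bar g_{Na}^* = 212.648720656$ (critical pair $\pm 0.37984\,i$),
* $\bar g_{K1}^* = 3.843499029$ ($\pm 1.13051\,i$),
* $\bar g_{K2}^* = 19.762260771$ ($\pm 0.34364\,i$),

each recomputed from scratch by `scripts/acceptance.R` and the test
suite.

## The two-parameter map and its upper boundary

`stability_map()` grids $(\bar g_{Na}, \bar g_K) \in [0,400] \times
[0,60]$ at 201 × 121 points (steps of 2 and 0.5 mS/cm²) and stores the
Routh-Hurwitz verdict per cell, sweeping each column upward in
$\bar g_K$ with continuation of the tracked equilibrium.  Every coarse
stable/unstable transition in a column is then refined by bisection to
1e−6 mS/cm².

The stable set has a nearly straight upper edge and an irregular lower
edge.  We define the **upper boundary** as, per column, the topmost
transition *that regains stability as $\bar g_K$ increases* — the
direction requirement matters, because for $\bar g_{Na} \gtrsim 352$
the upper Hopf branch leaves the $\bar g_K \le 60$ window and the
topmost in-window transition is actually the irregular lower edge;
tagging by position alone would contaminate the line fit with
lower-branch points and flatten the slope by half.  Columns whose
upper branch has left the window contribute no upper point.  The lower
branch is computed and stored but never fitted.

Ordinary least squares of $\bar g_K$ on $\bar g_{Na}$ over the refined
upper-branch points (171 of them at default resolution) gives

$$\bar g_K \approx 0.1746\,\bar g_{Na} - 1.278,$$

with an RMS residual of 0.13 mS/cm²: the boundary is straight to
within a slight, genuine concavity.  Because the refined transition
points are bisection-converged (unbiased to 1e−6), the fitted
intercept is resolution-robust; pixel-level boundary extraction on a
coarse grid (e.g. taking the last unstable cell per column) would bias
every point low by about half a grid step and shift the intercept down
by ~0.25–0.5 while barely moving the slope.  We deliberately fit the
unbiased points.

## Dynamics and attractor classification

`hh_simulate()` integrates with fixed-step classical RK4 at
`dt = 0.01` ms over `t_end = 500` ms by default (via `deSolve::rk4`):
deterministic, reproducible, and step-halving-converged to ~1e−4 mV at
desk scale.  Classification runs start from the tracked equilibrium
kicked by +1 mV in $V$ with gates at steady state — enough to reveal
instability without large-stimulus artifacts.

`classify_attractor()` discards the first half of the trace as
transient and measures the peak-to-trough amplitude of $V$ over the
remaining window (which must cover ≥ 100 ms).  Amplitude below 0.1 mV
is a `fixed_point`; at or above 1 mV with at least three inter-peak
intervals agreeing to a coefficient of variation under 5% it is a
`limit_cycle`; anything else — including the 0.1–1 mV band where slow
transients near a boundary linger — is `undetermined`, never silently
forced into a class.  Peaks are detected by slope-sign change with
plateau carry-through, so a crest sampled as two equal values still
counts once.

One dynamical subtlety: the Hopf bifurcations here are *hard* — just
past $\bar g_{Na}^*$ a 1 mV kick jumps straight onto the ~120 mV
relaxation-spike cycle, whose angular frequency (~0.30 rad/ms) is well
below the critical pair's 0.3798 rad/ms.  The small-amplitude limit is
therefore verified with a 0.01 mV kick: at $\bar g_{Na}^* + 0.5$ the
local growth rate is ~1.3e−3/ms, so the oscillation stays effectively
linear for hundreds of ms and its measured frequency matches the
critical eigenvalue frequency to ~0.1%.  (Whether the cycles branch
sub- or supercritically is not analysed here — no normal-form or
Lyapunov-coefficient computation is attempted.)

## Scenario generation

All inputs are parameter configurations, so the `scenarios` functions
generate everything the tests consume: the canonical set
(`canonical_parameters()`), the five single-override case studies with
their expected attractors (`reference_cases()`: g_Na = 198 and 250,
g_K = 2.8, 15 and 21), uniform conductance draws over the map
rectangle (`sample_parameters()`, default seed 20140703), and random
4×4 matrices with the gate-equation sparsity for linear-algebra
oracles (`random_structured_matrix()`).  The generator emulates
*parameter* variability only; it does not emulate voltage-clamp
recordings, measurement noise or channel stochasticity, so passing
tests say nothing about fitting such data — they validate the
deterministic analysis pipeline.

## Problem sizes and runtime

The default analysis sizes are the ones used throughout the tests and
the acceptance script: 2000-interval equilibrium scans, 1e−9
conductance bisection, the 201 × 121 refined map (~1 min on one CPU;
it dominates every other step), 500 ms / 0.01 ms classification runs,
1000-matrix and 100-equilibrium oracle batches, and a 50-point random
conductance sample for the linear-vs-nonlinear agreement property
(each checked point is kept only if its verdict is locally constant
within ±1 mS/cm² and its margin exceeds 0.005/ms, i.e. points well
clear of a bifurcation, where linear and nonlinear verdicts must
coincide).

## Known limitations

* The analysis is local: verdicts concern the tracked equilibrium.
  Coexisting attractors (e.g. the large cycle on the stable side of a
  hard Hopf point) are outside the linear verdict's scope, which is
  why the agreement property excludes near-boundary points.
* No fold-capable continuation: the scanned ranges have single-valued
  equilibrium curves, and `find_equilibria()` would report multiple
  roots if they arose, but no pseudo-arclength tracking around folds
  is attempted.
* The lower stability boundary is computed point-wise and stored; it
  is irregular and no model is fitted to it.
* Codimension-2 phenomena and Hopf criticality are out of scope.
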