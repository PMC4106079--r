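# hhbif

Local stability and bifurcation analysis of the Hodgkin–Huxley neuron
model as its maximal ion-channel conductances vary.

## The problem

The Hodgkin–Huxley (HH) model describes the membrane potential *V* of
an excitable cell together with three channel-gating fractions
*m*, *h* (sodium activation / inactivation) and *n* (potassium
activation):

```
C_M dV/dt = i_ext − g_Na m³h (V − V_Na) − g_K n⁴ (V − V_K) − g_l (V − V_l)
   dx/dt = α_x(V)(1 − x) − β_x(V) x          x ∈ {m, h, n}
```

in the depolarization-positive convention (rest near 0 mV), with units
mV, ms, mS/cm², µA/cm², µF/cm².  The maximal conductances g_Na and g_K
summarise how many functional channels the membrane carries; channel
loss or block (toxins, channelopathies, drugs) moves them.  This
package answers, quantitatively: *for which (g_Na, g_K) does the cell
sit at a stable resting state, and where does it switch to sustained
periodic firing?*

The machinery is classical dynamical-systems analysis, implemented
end-to-end:

* **Equilibria.**  With gates at steady state,
  x∞ = α_x/(α_x + β_x), every equilibrium is a root of a scalar
  current-balance in *V*; roots are bracketed on a grid and refined by
  bisection to 1e−12 mV (`find_equilibria()`).
* **Linearization.**  The 4×4 Jacobian at an equilibrium in closed
  form, its characteristic quartic λ⁴ + aλ³ + bλ² + cλ + d, its
  eigenvalues, and the Routh–Hurwitz criterion (stable iff a > 0,
  ab > c, d > 0, abc > c² + a²d) (`stability_report()`).
* **Hopf points.**  Bisection of one conductance on the sign of the
  stability margin (the largest eigenvalue real part) localises the
  Hopf bifurcations to nine digits (`find_hopf()`).  With all other
  parameters canonical there is a single critical sodium conductance
  g_Na\* ≈ 212.648720656, and two critical potassium conductances
  g_K\*₁ ≈ 3.843499029 and g_K\*₂ ≈ 19.762260771: the resting state is
  stable for g_K below the first or above the second, and the cell
  fires periodically in between.
* **Two-parameter map.**  A grid over (g_Na, g_K) ∈ [0,400] × [0,60]
  with per-column bisection refinement of the boundary; the upper edge
  of the stable region is close to a straight line, recovered by
  ordinary least squares as g_K ≈ 0.175·g_Na − 1.3
  (`stability_map()`, `fit_upper_boundary()`).
* **Simulation cross-check.**  Fixed-step RK4 integration and
  fixed-point vs limit-cycle classification of the long-run attractor
  confirm every linear verdict nonlinearly (`hh_simulate()`,
  `classify_attractor()`).

## Worked example

```r
library(hhbif)

p <- hh_params()          # canonical squid-axon parameters
stability_report(p)
#> <hh_stability>
#>   equilibrium: V* = 2.032999291e-05 mV
#>   char. coeffs: a = 5.20144, b = 2.69643, c = 1.12955, d = 0.10596
#>   eigenvalues (1/ms):
#>     -0.1206595291 +0i
#>     -0.2027177241 +0.3830621401i
#>     -0.2027177241 -0.3830621401i
#>     -4.675343295 +0i
#>   max real part: -0.12066;  Routh-Hurwitz: stable
```

The resting state sits at V\* ≈ 0 mV and every eigenvalue has negative
real part: the canonical cell returns to rest after perturbation.
Sweeping the potassium conductance finds where that changes:

```r
find_hopf(p, "g_K", bracket = c(10, 200))
#> <hh_hopf>  Hopf bifurcation point
#>   g_K* = 19.7622607715 mS/cm^2  (bracket width 6.91e-10)
#>   critical pair: -3.94e-12 +/- 0.3436440068i (1/ms)
```

At g_K\*₂ ≈ 19.762 a conjugate eigenvalue pair crosses the imaginary
axis at ±0.3436 i — the onset of oscillation at angular frequency
0.3436 rad/ms.  Below that, inside the unstable band, the nonlinear
model indeed fires:

```r
classify_attractor(hh_simulate(update(p, g_K = 15)))
#> <hh_attractor>  limit_cycle
#>   V amplitude 118.1 mV over [250, 500] ms;  period 18.14 ms (13 cycles, cv 1.38e-15)
```

i.e. full-height action potentials recurring every 18.1 ms.  A
`stability_map()` + `autoplot()` renders the whole (g_Na, g_K) plane;
see the methods vignette (`vignettes/conductance-stability.Rmd`) for
the modelling details and design choices.

There is also a small command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hhbif.R", package = "hhbif"))')" \
    hopf --param g_K --bracket 10 200 --out hopf.json
```

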