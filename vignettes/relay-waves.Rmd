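---
title: "Diffusive signaling relays: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusive signaling relays: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(relaywave)
```

## The model and its assumptions

A *diffusive relay* is the simplest collective-signaling motif: every cell
measures the local concentration `c` of one diffusible molecule and joins
in emitting it, at rate `a f(c)`, once activated. With cells treated as a
continuum of density `rho` confined to a plane (or line, or volume), the
concentration obeys a reaction-diffusion equation whose source lives on
the cell manifold. The package works with two activation families:
the Heaviside switch `f(c) = 1{c >= Cth}` and Hill functions
`f(c) = c^n/(c^n + Cth^n)`; the switch is the infinite-order Hill limit.

Assumptions built into everything below:

* cells are static, identical, and continuously distributed (validity
  requires `d v / 4D << 1` for cell spacing `d`);
* the cell layer is thin compared to `D/v` (`H v / D << 1`), so it enters
  as a surface source;
* emission is continuous (pulse duration `tau >> D/v^2`) and decay slow
  (`gamma << v^2/D`). Decay is supported as a numerical option in the PDE
  solver but the closed forms assume `gamma = 0`;
* fronts are axisymmetric; non-circular targets are idealized as disks.

`validity_report()` evaluates each of these ratios. The model states no
numeric cutoff for "much less than"; the package defaults (0.25 and 4) are
exposed as arguments, a package convention rather than a derived value.

## Dimensionality sets the physics

The asymptotic wave speed follows from dimensional analysis alone. In a
thin medium every concentration is proportional to `a rho / h`, leaving a
single time scale `h Cth / (a rho)` and hence `v ∝ sqrt(a rho D / (h Cth))`
(the classic square-root-of-`D` trigger-wave law). When diffusion has one
more dimension than the cells — planar cells under a deep medium — the only
combination with units of speed is `a rho / Cth`, so
`v = 2 a rho / (pi Cth)`: *independent of the diffusivity*. The exact
prefactors and the comoving concentration profiles (linear-inside /
exponential-outside for matched dimensions; square-root-inside /
damped-tail-outside for the half-space) are implemented in
`wave_speed()`, `profile_thin()` and `profile_thick()`.

`profile_thick()` is stated only in its two asymptotic limits; no closed
form exists for `|r - vt|` of order `D/v`. The function returns the limit
expressions there but flags them through the `reliable` attribute rather
than inventing an interpolation. While deriving the inner branch we found
that it crosses `Cth` at signed distance `-D/(pi v)` from the front; the
test suite pins that value.

## Natural units and the dimensionless core

All quadrature and simulation happens internally in natural units: lengths
in `D/v`, times in `D/v^2`, concentrations in `Cth`. In these units the
colony and front integrals become parameter-free, which gives a single
well-conditioned code path across twelve orders of magnitude of physical
parameters; dimensional conversion happens only at the API boundary. A
consequence worth knowing: two parameter sets that map to the same
dimensionless problem (e.g. the half-space geometry at different `D` with
fixed `Cth/(a rho)`) produce bitwise-identical dimensionless solutions, so
the D-independence of the mismatched-dimension wave is exact in the
implementation; the corresponding test validates the unit scaling layer.

The workhorse is the Gaussian *shell mass* `P_n(x, b, sigma)` — the mass,
inside cell-radius `b`, of an isotropic `n`-D Gaussian of per-axis variance
`2 sigma` centered at radius `x`. `P_1` and `P_3` have erf closed forms
(`P_3` switches to a ball-volume-times-density expansion when the Gaussian
is much wider than both radii, where the erf form cancels
catastrophically); `P_2` is a windowed 40-node Gauss-Legendre integral of
the exponentially scaled Bessel ring density, accurate to ~1e-9 and immune
to overflow (the scaled `I0` uses a Taylor series below `z = 4` and the
asymptotic series above `z = 50`). All three are tested against the
noncentral chi-square CDF, which is the same object in disguise.

Concentrations follow by a single time quadrature with the substitution
`u = sqrt(t - T)`, which removes the kernel's endpoint singularity exactly.
Colony concentrations use adaptive quadrature (absolute tolerance 1e-6 in
units of `Cth`, with a logarithmic tail panel for the very long times that
small-colony 2D initiation requires); front-history concentrations use
composite Gauss-Legendre panels — one per front step for the most recent 40
steps, geometrically coarsened panels for older history. Refining this
panel scheme (all steps resolved, 10 nodes, half the step) moves a
50-natural-time front by ~1e-4 relative, so the defaults are converged.

## The information-front propagator

With Heaviside activation the front `r_c(t)` is defined by self-consistency:
the concentration generated by every cell the front has passed (plus the
permanently emitting colony of radius `r_i`) equals `Cth` on the front
itself. The solver first computes the initiation time (`Cth` first reached
at the colony edge), then advances on a grid with step `dt = D/(10 v^2)` by
default. At each step the unknown radius appears twice — as the observer
point and as the endpoint of the source history. We give both roles the
same unknown and solve the resulting scalar equation directly with a
bracketed root-finder started from linear extrapolation; this computes the
same fixed point an iterate-and-resolve scheme would, in one solve. The
residual is monotone because concentration decays in the observer radius
much faster than the thin current-step source sliver contributes.
Convergence diagnostics: halving `dt` moves the final radius by well under
0.5%, and plugging the converged front back into
`concentration_from_front()` returns `Cth` to ~1e-3.

Finite fronts approach the asymptotic speed from below with a curvature
correction of order `(D/v)/r` — about 1% at `t = 100 D/v^2` for planar
cells, and twice that for cells in 3D (the front is a sphere, not a
cylinder). The test suite therefore measures the 3D front at
`t = 150 D/v^2`, where the correction has decayed into the 2% band; the
2D cases are measured at the conventional `t = 100 D/v^2`.

## Initiation

`initiation_time()` root-finds the colony-edge threshold crossing; in 3D
environments "never initiates" is decided from a dedicated steady-state
quadrature, not a finite horizon, to avoid false negatives from slow
saturation. The steady states have clean closed forms that the tests use
as oracles: a uniformly emitting ball reaches `a rho r_i^2 / 3D` at its
surface (critical radius `sqrt(3) D/v`), and a disk under a half-space
reaches `2 a rho r_i / (pi D)` at its rim (critical radius `D/v`).

The large-colony plateaus (`2 D/v^2` matched, `4 D/(pi v^2)` mismatched)
are exact limits: colonies with straight edges (cells in 1D) reach them
exponentially fast, but curved colony edges carry a `~(D/v)/r_i`
correction — at `r_i = 10 D/v` the half-space initiation time still sits
~7% above its plateau, decaying like `1/r_i` (0.4% at `160 D/v`). The
small-colony laws are asserted as exponents, not prefactors: the inverse
-square law in 1D (with its `pi/4` prefactor, which is sharp) and unit
slope of `log t_init` against `(2D/(v r_i))^2` in 2D, where the prefactor
is order-of-magnitude only.

## The PDE oracle

`simulate_thin()` and `simulate_thick()` integrate the reaction-diffusion
equation directly: conservative finite volumes, implicit (backward-Euler)
diffusion with the sparse Cholesky factor computed once, and the bounded
source treated explicitly with one corrector pass. The singular cell-layer
source is never discretized: in the half-space it becomes the flux
condition `-D dc/dz = a rho f(c)` at `z = 0`, i.e. a source in the bottom
cell row, with the cell-plane concentration obtained by linear
extrapolation of the first two rows (the bottom-row center sits half a cell
above the plane, inside the flux boundary layer). The vertical grid is
geometrically stretched. Mass balance holds to machine precision by
construction and is asserted to 0.5%.

Default problem sizes (chosen to resolve `D/v` while keeping a full run in
seconds to a couple of minutes on one CPU): thin solver `dr = D/(20v)`,
`dt = D/(20 v^2)`, domain `1.2 v t_end + 10 D/v`; half-space solver
`dr = dz0 = D/(10v)`, stretch ratio 1.15, `z`-extent `6 sqrt(D t_end)`.
The thin solver's measured speed converges fast (halving steps moves it
<1%; the 1D channel speed is exact to ~1e-3). The half-space Heaviside
level set sits on a square-root concentration profile, so its measured
speed converges only like a fractional power of `dr`; at default
resolution it is within ~7% of the Green's-function front, improving
monotonically under refinement. For quantitative Heaviside front work the
Green's-function propagator is the better tool (that is also why it is the
route used for the half-space speed checks); the PDE solver's unique value
is graded (Hill) activation and decay, where the front is smooth and the
discretization benign.

Two findings from cross-checking the routes are worth recording. First,
the explicit-source step carries a `+O(dt)` speed bias (~1% at
`dt = D/(20 v^2)`); at `dt -> 0` the PDE trajectory lands on the
Green's-function trajectory, which is the converged reference. Second,
graded activation is genuinely faster than the switch: in the clean 1D
channel the Hill order-2 wave runs ~9% above the Heaviside speed, order 4
~2%, order 8 ~1%, approaching the switch monotonically from above. For
planar cells under a half-space the measured order-2 prefactor
`alpha = v Cth/(a rho)` exceeds `2/pi` by ~5% (grid-refinement stable);
"the same speed for any steep activation" is an excellent approximation
but not exact at order 2, and the corresponding 5%-band check in the
acceptance suite sits knife-edge red at ~+5.2%. We report the honest
number rather than tuning the measurement window toward a pass.

## Neutrophil swarming application

The swarming chamber realizes the half-space geometry, where the model has
exactly two parameters: `Cth/(a rho)` (s/m) and `D`. `predict_front()`
propagates the information front for a permanently emitting disk target;
`fit_front()` estimates both parameters from observed `(t, r)` front
points by weighted least squares on radial residuals — a reproducible
stand-in for fitting by eye, with tolerances widened accordingly. The
residual surface has a curved, nearly degenerate valley (a slower wave
with a smaller diffusivity mimics a finite-window convex front), so the
fitter runs a coarse log-grid first, refines with Nelder-Mead from the two
best distinct basins, and restarts the simplex once or twice re-centered
(a degenerate simplex stalls long before the minimum in such valleys).
Self-fits recover noiseless parameters to optimizer tolerance; at 5% map
noise both parameters come back within a few percent.

`synth_front_map()` is the package's synthetic data generator. It emulates
the data product of a tracking experiment — the chemotactic index
`<cos theta>` binned in radius and time — as a step of height 0.9 inside
the true front plus Gaussian bin noise (default sd 0.05, i.e. "5% noise"),
on 25 µm x 50 s bins, and extracts front points by thresholding each time
bin at half the step height with linear interpolation. What it does *not*
emulate: single-cell trajectory statistics, inward migration of activated
cells (negligible here since cells move at ~0.3 µm/s, far below the wave
speed; the constant is documented but unused), oblong targets, receptor
saturation, or secondary mediators. Passing the recovery tests therefore
shows the *inference pipeline* is unbiased at realistic noise, not that
real swarms obey the one-molecule relay.

The parameter-recovery property is exercised over six seeded replicates
(about a minute of optimization each; the per-replicate behavior is
deterministic given the seed), and the model-discrimination property
checks that a relay fit cannot explain a simple-diffusion front as well as
the diffusion model itself.

`match_simple_diffusion_threshold()` exploits linearity: the no-relay
concentration is proportional to `a rho`, so the threshold that matches
the relay's signaling distance at `t` is just the colony concentration at
the relay front divided by `a rho`; the result is verified against the
diffusion front before being returned (equivalent to, but cheaper than,
bisection).

## Known limitations

* No asymptotic profiles for pulsed emission or decaying molecules; decay
  enters only as a numerical option (`gamma`) in the PDE solver.
* No discrete-cell (agent-based) or stochastic-emission dynamics beyond
  the `d v/4D` validity check.
* Cells in 1D with 3D diffusion is not among the supported geometry pairs.
* The half-space PDE solver should not be used for precision Heaviside
  speed measurements (see above); use `propagate_front()`.
* Fronts are strictly axisymmetric.
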