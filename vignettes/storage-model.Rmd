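---
title: "Modeling agitated platelet-concentrate storage: two-phase sloshing, wall shear and oxygen transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling agitated platelet-concentrate storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Platelet concentrates (PC) are stored at room temperature in gas-permeable
bags on flatbed agitators.  Agitation keeps oxygen supplied to the
suspension — but every bit of fluid motion also exposes platelets to wall
shear stress (WSS), a suspected contributor to the platelet storage
lesion.  `pcslosh` models the physics of this trade-off at desk scale: a
two-phase free-surface simulation of the agitated bag, with
post-processing for velocity, WSS, gas-liquid interfacial area, and a
surrogate model of oxygen transfer through the liquid film and the bag
wall.

## Model

### Geometry and the 2D reduction

The container is a rigid rectangular box of width `W1` along the agitation
direction, transverse depth `L1`, and interior height `H_total`, filled
with `fill_volume` of liquid (defaults: 0.12 m x 0.08 m x 0.03 m, 65 mL,
giving a liquid depth `H2` of about 6.8 mm).  Because the forcing acts
along a single horizontal axis, the solver operates on the vertical slice
`W1 x H_total`, with `L1` used as extrusion depth wherever an area or
volume is needed.  This 2D reduction is the main deliberate departure from
the field-scale 3D finite-volume model it emulates; transverse
recirculation and corner effects are absent, which is the dominant source
of quantitative disagreement at the strongest forcing.

The defaults for `W1`, `L1` and `H_total` are assumptions (chosen for a
neonatal-scale bag); every dimension is configuration-overridable and no
result is hard-wired to them.

### Governing equations

Both phases are incompressible and laminar; a single velocity field is
shared by liquid and gas (volume-of-fluid one-fluid formulation).  The
phase fraction `r(x, t)` (liquid = 1, gas = 0) is advected by the flow,
and mixture density/viscosity are phase-fraction weighted averages of
water (997 kg/m^3, 1 cP) and air (1.2 kg/m^3, 0.018 cP).  Momentum is
closed by

* pressure gradient and deviatoric viscous stress,
* gravity `g = 9.81 m/s^2`,
* the agitation body force `-a w^2 sin(w t)` along x — the container
  frame is non-inertial, which for a rigid container is mathematically
  equivalent to a moving mesh and far simpler,
* a continuum-surface-force (CSF) surface tension
  `F_s = sigma kappa grad(r)` with `sigma = 0.072 N/m` (clean water-air;
  not a measured PC property, config-overridable).

The laminar assumption is supported by Reynolds numbers computed with the
liquid depth `H2` as characteristic length: at the printed peak speed of
the strongest condition, `Re` stays below the 2300 transition threshold
for depths up to ~5 mm and only modestly above it at the default depth.
Platelets themselves are not resolved: their Stokes number
(`rho_p d_p^2 / (18 mu T)`, defaults 1060 kg/m^3 and 2 um) is of order
1e-7, so the suspension follows the carrier fluid and a particle-free
single liquid is adequate.

### Discretization

* Uniform staggered (MAC) grid, default 96 x 32 over the slice.
* VOF advection is geometric: Youngs-normal PLIC reconstruction with a
  conservative dimensionally-split flux scheme and a per-cell dilation
  correction.  Liquid volume is conserved to round-off per step for a
  discretely divergence-free velocity, and the fraction stays in [0, 1]
  for CFL <= 0.5 (default Courant target 0.3).  Sweep order alternates
  between steps.
* Momentum advection is limited second-order upwind; viscous stresses are
  explicit.  The explicit viscous stability limit is included in the
  timestep, and at these grids and fluid properties it is never the
  binding constraint, so an implicit viscous solve would buy nothing.
* Pressure-velocity coupling is PISO: explicit predictor, then at least
  two projection correctors; each projection solves a variable-density
  Poisson system (incomplete-Cholesky preconditioned conjugate gradients,
  relative tolerance 1e-8, warm-started from the previous step).  With
  face-averaged densities used consistently for gravity and the pressure
  gradient, a flat quiescent pool is an exact discrete equilibrium — the
  hydrostatic test holds to 1e-8 m/s.
* Interface curvature uses height functions (7-cell column sums of the
  fraction field in the dominant normal direction) with a
  smoothed-normal divergence fallback where columns do not bracket the
  interface; combined with the sharp `grad(r)` in the CSF term this gives
  a balanced-force discretization whose static-drop pressure jump is
  within a few percent of `sigma / R`.
* The timestep is the minimum of CFL, capillary
  (`sqrt(rho_mean h^3 / (2 pi sigma))`) and explicit-viscous limits,
  scaled by a 0.9 safety factor; with a quiescent field the forcing
  velocity scale `a w` bounds the CFL estimate so dt stays finite.
* Boundaries: no-slip bottom and side walls; the top is a fixed-pressure
  outlet (gauge 0) with zero tangential stress — the 2D image of the
  "pressure outlet at the top surface" of the 3D model.
* Start-up: liquid at rest, flat interface, discrete-hydrostatic
  pressure; no forcing ramp.  Cycle 1 carries the start-up transient and
  is excluded from all steady statistics (steady window = cycles 2-5).
* A zero-frequency protocol denotes unagitated storage and
  short-circuits to the static solution; the explicit integrator can be
  forced with `static_shortcut = FALSE` (used by the hydrostatic tests).

### Diagnostics

Per step the solver records the liquid-weighted volume-averaged speed
(gas-phase velocity is irrelevant to the stored suspension; a
whole-domain switch exists), the maximum local liquid-phase speed, wall
shear stress on wetted wall faces (one-sided `mu |u_t| / (h/2)`, exact
for a linear profile), and the gas-liquid interface extracted by marching
squares on the 0.5 level of the cell-centered fraction field.  The field
is padded to the walls with zero-gradient ghost nodes so a flat interface
measures exactly `W1`.  Interfacial area is `length x L1`, and
`V_interface` is the contour-length-weighted mean speed magnitude on the
contour (no tangential decomposition — the speed magnitude is the
renewal-relevant quantity and the source describes no decomposition).

"Volume-averaged WSS" is implemented as the wetted-wall area-weighted
average: a wall quantity has no volume average, and face-area weighting
is what a finite-volume wall report produces.  Whether dry
(gas-contacting) faces should enter the average is ambiguous; wetted-only
is assumed.  Peaks are maxima over wetted faces and the steady window.
Across-cycle variability is the sample variance (ddof = 1) of the four
steady per-cycle means.

### Mass transfer

Oxygen transfer from headspace to liquid uses Higbie penetration theory:
`K_L = 2 sqrt(D / (pi t_C))` with contact time `t_C = W1 / V_interface`
and `D = 2.42e-9 m^2/s` (the diffusivity is printed elsewhere with units
of m/s; that is treated as a typo for m^2/s, and the value is
config-overridable).  An unagitated interface has infinite contact time
and `K_L = 0` exactly — the nonzero fitted intercepts of the polynomial
fits are regression artifacts, not model values.

The storage bag itself is an oxygen resistance in series:
`1/K_total = 1/K_bag + 1/K_L`.  `K_bag` derives from a film's oxygen
transmission rate (OTR, cm^3 STP/m^2/24 h; polyolefin ~2000,
TOTM-plasticized PVC ~690) assuming the OTR is measured under a 1 atm
pure-oxygen partial-pressure difference, with saturation
`c_sat = 1.38 mol/m^3` (Henry's law, ~22 C).  Both constants are explicit
configuration; the ratio of `K_bag` between materials — which drives the
intercept-difference test — is independent of this convention.  At any
agitated frequency the bag resistance exceeds the liquid-film resistance
by a factor of order 100, which is the bag-limited regime behind the
central conclusion: less agitation need not cost oxygen availability.

### Regressions

The analysis fits follow the degrees of freedom of the published
statistics: mean speed and mean WSS against rpm are fitted through the
origin on the three agitated frequencies (df (1, 2); the published model
has no intercept term and R^2 uses uncorrected sums of squares, the
standard for no-intercept models); `K_total` fits use the four
frequencies 0/20/40/60 with intercept (df (1, 2)); the quadratic fits use
the same four points; the interfacial-area fit uses the three agitated
frequencies with intercept (df (1, 1)) — inconsistent with the K-fit
design but the only reading compatible with its printed df.  The
material-intercept comparison is a common-slope extra-sum-of-squares F
test, df (1, 5) for two groups over four shared frequencies.  p values
below 1e-15 are reported as "<1e-15".  All fits are computed with base
`lm()` behind the module interface and cross-checked in the test suite
against hand-rolled normal-equation oracles.

## Synthetic bead-track validation

The experimental validation of the original study — dye videos and
TrackMate bead tracking — cannot be reproduced without the physical
recordings, and its reported correlation (r = 0.818) depends on them.
What the package provides instead is the validation *pipeline* plus a
synthetic generator that emulates the experiment's design: >= 20 beads,
~600 frames, advected through a (simulated or analytic) velocity field by
explicit midpoint integration at the frame rate, with i.i.d. Gaussian
pixel noise on recorded positions standing in for LoG spot-localization
error (default sigma = 1 px; pixel calibration defaults to `W1` spanning
480 px).  Frame-to-frame displacements convert to cm/s; per-frame means
across beads carry 95% confidence intervals, and the comparison against
the simulated volume-averaged speed series is a Pearson correlation on a
common (linearly interpolated) time base, using frame means (how the
original per-frame speeds were aggregated is not stated; frame-mean is
assumed).

What passing these tests shows: the tracking pipeline is unbiased up to
the closed-form noise floor (the mean speed of pure noise is the folded
2D Gaussian expectation, checked in the suite), recovers known fields
within its confidence intervals, and correlates near-perfectly with the
series that generated it.  What it does not show: agreement with real
bead videos, real bag flexibility, or 3D flow structure.

## Mesh independence

`mesh_independence()` reruns a protocol over progressively refined grids
and tabulates steady-cycle bulk metrics with successive relative
differences, flagging convergence when the finest pair differs by < 5%
in cycle-mean volume-averaged speed.  The packaged study uses four grids
up to 96 x 32 at 40 rpm with a shortened (3-cycle) window; under those
conditions the finest pair agrees to ~0.5%.  At 20 rpm the picture is
different and worth knowing: the weak sub-resonant flow is governed by a
Stokes boundary layer of about `sqrt(2 nu / w)` ~ 1 mm, comparable to the
coarse-grid cell height, so cycle-mean speeds keep decreasing under
refinement and the 20 rpm bulk metrics on the default grid should be read
as upper estimates.

## Problem sizes and determinism

The canonical reproduction (and the acceptance script) runs 5 cycles at
0/20/40/60 rpm on the 96 x 32 default grid — a few minutes per sweep on
one core.  The standing-wave dispersion benchmark runs on 192 x 64 with
zero surface tension (the reference formula `sqrt(g k tanh(k H2))` is the
pure-gravity branch; capillarity would shift the frequency by < 0.3% but
cost a fivefold smaller timestep) over 2.5 s, with a deeper 15 mm fill so
bottom boundary-layer damping does not bury the oscillation.  The solver
contains no random number generation: identical configurations reproduce
bit-identical trajectories, and the bead generator is reproducible given
its seed.

## Known limitations

* The 2D slice cannot represent transverse sloshing or corner vortices;
  peak metrics at the strongest forcing are the least transferable.  The
  default geometry places the first sloshing mode near 64 rpm, so the
  60 rpm condition sits close to resonance and responds strongly; the
  published 3D container's modal structure is unknown (its dimensions are
  given only in a figure).
* Rigid walls: no fluid-structure interaction with the flexible bag film,
  no contact with the upper film surface.
* Oxygen is a surrogate model (Higbie + resistances in series), not a
  transported species; platelet oxygen consumption is out of scope.
* Laminar only; no turbulence closure at any frequency.
* First-order time integration; temporal accuracy is adequate for
  cycle-mean statistics but peak instantaneous values on coarse grids
  carry a few-percent timestep sensitivity.
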