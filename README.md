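# pcslosh

Desk-scale computational model of platelet-concentrate (PC) storage under
flatbed agitation, for transfusion-medicine and bioprocess researchers who
want to reason quantitatively about the trade-off at the heart of PC
storage protocols: agitation drives gas-liquid oxygen transfer, but the
same fluid motion exposes platelets to wall shear stress (WSS), a
suspected contributor to the platelet storage lesion.

## What it computes

A two-dimensional volume-of-fluid (VOF) free-surface solver simulates the
vertical slice of a rigid, partially filled storage container under
sinusoidal agitation. The phase fraction *r*(x, t) (liquid = 1, gas = 0)
obeys

    dr/dt + div(u r) = 0

with a single shared velocity field for both phases, mixture properties
`rho = r rho_l + (1-r) rho_g` (same form for viscosity), incompressible
laminar momentum with gravity, the container-frame agitation force

    acc_x(t) = -a w^2 sin(w t),      w = 2 pi f / 60,

and continuum-surface-force surface tension `F_s = sigma kappa grad(r)`.
Pressure and velocity couple through PISO (predictor plus multiple
projection correctors) on a staggered grid; the interface is kept sharp by
geometric PLIC advection that conserves liquid volume to round-off.

Post-processing produces the storage-relevant metrics per oscillation
cycle, discarding the start-up transient (cycle 1):

* liquid-volume-averaged speed and maximum local liquid speed,
* wetted-wall WSS (`tau = mu du_t/dn`, one-sided at the no-slip walls),
* gas-liquid interfacial area A from the 0.5 isocontour, and the
  interface-averaged speed V_interface,
* Higbie penetration-theory mass transfer
  `K_L = 2 sqrt(D / (pi t_C))`, contact time `t_C = W1 / V_interface`,
* container-limited total transfer by resistances in series,
  `1/K_total = 1/K_bag + 1/K_L`, with `K_bag` derived from a bag film's
  oxygen transmission rate (polyolefin ~2000, PVC-TOTM ~690
  cm^3/m^2/24 h),
* the frequency regressions: through-origin fits of mean speed and mean
  WSS vs rpm, quadratic fits of `K_L` and `K_L A` vs rpm, and the
  common-slope intercept-difference F test between bag materials.

A synthetic bead-tracking generator (20 beads, ~600 frames, Gaussian
pixel noise) emulates particle-tracking velocimetry for validating the
pipeline, and `mesh_independence()` runs the grid-refinement study.

## Worked example

```r
library(pcslosh)

cfg <- storage_config()        # 65 mL bag, +/-2 cm agitation, 96x32 grid
run <- run_simulation(cfg$geometry, cfg$phases,
                      agitation_protocol(0.02, 40, 5),
                      cfg$grid, cfg$numerics)
summarize_run(run)
```

    # A tibble: 1 x 12
        rpm mean_speed mean_wss peak_speed peak_wss mean_area mean_v_interface ...
      <dbl>      <dbl>    <dbl>      <dbl>    <dbl>     <dbl>            <dbl>
    1    40     0.0314   0.0547      0.198    0.217   0.00962           0.0415

At 40 rpm the liquid averages 3.1 cm/s with steady-cycle peaks of
0.20 m/s; wetted walls see a mean shear stress of 0.055 Pa
(0.55 dyne/cm^2) peaking at 0.22 Pa — below commonly cited platelet
activation thresholds (1.2–8 Pa) but not negligible over days of storage.
The interface area barely changes (0.0096 m^2, the flat-pool value), so
mass-transfer gains come from interface renewal, not area growth:

```r
runs <- simulate_sweep(cfg, c(0, 20, 40, 60))
analysis <- analyze_runs(runs, cfg)
subset(analysis$mass_transfer, material != "None" & rpm %in% c(0, 40))
```

    rpm  t_C      K_L        material  K_bag     K_total   ...
    0    Inf      0           PO       7.48e-07  0
    0    Inf      0           PVC-TOTM 2.58e-07  0
    40   2.89     3.26e-05    PO       7.48e-07  7.32e-07
    40   2.89     3.26e-05    PVC-TOTM 2.58e-07  2.56e-07

The liquid-side coefficient `K_L` (3.3e-5 m/s at 40 rpm) exceeds the
bag-side coefficient by a factor of ~50–100, so `K_total` is pinned at
the bag's permeability — once any agitation renews the interface, oxygen
supply is limited by the container material, not by how hard you shake
it. That is the practical conclusion the model supports: reducing
agitation frequency lowers shear exposure with essentially no oxygen
penalty, and material choice (polyolefin vs PVC-TOTM, a 2.9x difference
in `K_bag`) matters more than agitator speed.

The velocity-frequency relationship is linear through the origin:

```r
analysis$fits$speed_vs_rpm
#> <pc_fit origin-linear> B1 = 0.00162826
#>   R2 = 0.8306  F(1, 2) = 9.807  p = 0.08862
```

i.e. each additional rpm adds ~1.6 mm/s of mean fluid speed.

A command-line front end wraps the same pipeline:

```sh
inst/cli/pcslosh simulate --config inst/extdata/default_config.yaml --rpm 40 --out runs
inst/cli/pcslosh reproduce --out reproduction
```

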