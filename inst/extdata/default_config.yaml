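# Default storage-simulation configuration: 65 mL neonatal-scale bag,
# +/-2 cm flatbed agitation. Every key is optional; these are the defaults.
geometry:
  W1: 0.12            # m, along the agitation direction
  L1: 0.08            # m, transverse depth (extrusion depth of the slice)
  H_total: 0.03       # m, interior height
  fill_volume: 6.5e-5 # m^3 (65 mL)
fluids:
  liquid_density: 997     # kg/m^3
  liquid_viscosity: 1.0e-3 # Pa s
  gas_density: 1.2
  gas_viscosity: 1.8e-5
  surface_tension: 0.072  # N/m
agitation:
  amplitude: 0.02     # m, displacement half-range
  frequency: 20       # rpm
  n_cycles: 5
numerics:
  nx: 96
  ny: 32
  cfl: 0.3
  capillary_safety: 0.9
  n_correctors: 2
  poisson_tol: 1.0e-8
  max_poisson_iter: 5000
bag_materials:
  PO: 2000            # oxygen transmission rate, cm^3/m^2/24 h
  PVC-TOTM: 690
constants:
  gravity: 9.81       # m/s^2
  diffusivity: 2.42e-9 # m^2/s, O2 in water
  c_sat: 1.38         # mol/m^3, dissolved O2 at 1 atm O2
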