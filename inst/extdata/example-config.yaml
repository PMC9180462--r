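# Example photoheat configuration (values shown are the package defaults).
# Units: lengths mm, power mW, time s, temperatures degC.
domain:
  cylinder_radius: 15.0     # normal-tissue cylinder radius
  cylinder_depth: 20.0      # layer thicknesses must sum to this
  dx: 0.25
  dy: 0.25
  dz: 0.25
  tumor:
    shape: disc             # treatment geometry; "sphere" for validation
    radius: 5.0
    depth_extent: 2.0
    top_offset: 0.1         # depth of the tumor's upper face
nanoparticle:
  f_v: 1.0e-06              # gold-nanorod volume fraction
  r_eff_nm: 20.0            # effective particle radius
  aspect_ratio: 6.67
  Q_a: null                 # null -> calibrated from the reference optics
  Q_s: null
beam:
  profile: gaussian         # gaussian (1/e^2 radius) or top_hat
  phi_r: 1.0                # beam radius / tumor radius
  power: 100.0
solver:
  duration: 600.0
  snapshot_interval: 2.0
  safety: 0.9               # fraction of the explicit stability limit
  initial: 37.0
  boundary_value: 37.0      # Dirichlet wall/bottom temperature
transport:
  n_photons: 100000.0
  seed: 1
  w_min: 1.0e-04            # Russian-roulette threshold
  roulette_p: 0.1
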