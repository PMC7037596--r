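# Mitral-valve strip preset.
# Per-region ultimate stresses (MPa) follow the published microscopy-derived
# values for bisected MV pulls; geometry, composition and coupling parameters
# are the package's phantom conventions.
name: MV
region_bounds: [0.0, 8.0, 11.0, 19.0, 22.0, 30.0]
sigma_table:
  PM: 0.011
  PM-CT: 0.144
  CT: 1.491
  CT-LL: 0.024
  LL: 0.025
tear_force_N: 0.30
capacity_margin: 1.25
weak_region: PM-CT
eps_cap:
  PM: 0.40
  PM-CT: 0.25
  CT: 0.06
  CT-LL: 0.18
  LL: 0.22
drop_width: 0.6
residual: 0.5
muscle_fraction:
  pm_plateau: 0.85
  ct_plateau: 0.0
thickness_knots:
  x: [0.0, 8.0, 11.0, 19.0, 22.0, 30.0]
  t: [2.5, 2.5, 1.0, 1.0, 1.5, 1.5]
D0_nm: 67.0
d11_0_nm: 24.5
d11_gain: 0.3
strain_coupling:
  baseline: 0.02
  amp: 0.05
  sigma_mm: 1.2
orientation:
  sigma0_knots:
    x: [0.0, 8.0, 11.0, 19.0, 22.0, 30.0]
    sigma: [20.0, 18.0, 10.0, 12.0, 25.0, 25.0]
  align_gain: 2.0
  min_factor: 0.5
  cross_amp: 1.5
  cross_sigma_mm: 0.8
sensor_max_g: 455
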