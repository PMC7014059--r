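# Reference bone-implant scenario, fully spelled out. Every value below is
# also the package default, so an empty file plus `boundary: cais` would be
# equivalent; this copy documents the complete configuration surface.

layout:
  domain_height: 10.0       # mm
  domain_width: 1.5         # mm
  n_threads: 10
  thread_height: 1.0        # mm
  thread_depth: 0.5         # mm
  thread_profile: triangular   # or rectangular / trapezoidal

properties:
  rho_plasma: 1025          # kg/m^3, fibrinogen-free plasma
  rho_fibrinogen: 1400      # kg/m^3
  rho_rbc: 1125             # kg/m^3
  mu_rbc: 0.0050            # Pa.s
  sigma: 0.021              # N/m, plasma-RBC interfacial tension
  D_fib: 0.23e-10           # m^2/s, fibrinogen diffusivity

boundary:
  cais: 5                   # implant-plasma contact angle, degrees (required)
  inlet_speed: 0.01         # m/s at both velocity inlets
  inlet_hematocrit: 0.45    # RBC volume fraction at the inlets
  inlet_Y0: 0.0029          # fibrinogen mass fraction in inlet plasma

solver:
  dt: 1.0e-4                # s, reporting step (sub-stepped for stability)
  t_end: 3.0                # s
  inner_tolerance: 1.0e-9   # kg, per-step fibrinogen mass audit
  cfl_safety: 0.8
  sample_stride: 1          # record masses every outer step
  nsmooth: 2                # smoothing passes before curvature evaluation
  p_tol: 2.0e-3             # 1/s, rms divergence target of the pressure solve
  p_maxit: 3000
  c_compress: 0.5           # interface-compression coefficient

mesh:
  cell_size: 0.05           # mm; 0.05 = coarse preset, 0.025 = full preset

output:
  dir: .
  csv: true
  vtk: false
  png: false
  snapshot_times: [1, 3]    # s, displayed instants
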