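morphology:
  FRC: 3.0
  FRC_W: 3.5
  d_lim: 1.8
  r: 0.326
  eta: 2.97
  trachea_elongation: 0.0
  residual_allocation: equal
protocol:
  TV: 0.5
  T_B: 3.2
  waveform: sinusoidal
  n_breaths: 20
lobule:
  kappa: 0.85
  z_star: 6.0
  n1: 20.0
  n2: 2.0
  d_floor_mm: 0.3
numerics:
  dt: 0.005
  pipe_dx_max: 0.002
  pipe_min_cells: 6
  trumpet_cells: 60
  trumpet_stretch: 0.1
  advection_scheme: muscl
  theta_time: 1.0
  taylor_dispersion: yes
  duct_transport: yes
  newton_tol: 1.0e-10
  newton_maxit: 50
gas:
  mu: 1.8e-05
  rho: 1.2
  D: 2.2e-05
perturbations: []
p_TV: 1500.0
seed: 1
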