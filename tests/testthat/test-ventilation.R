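test_that("Womersley correction has the right limits and monotonicity", {
  expect_equal(womersley_factor(0), 1)
  expect_equal(womersley_factor(1e-3), 1, tolerance = 1e-6)
  w <- womersley_factor(seq(0, 20, by = 0.5))
  expect_true(all(diff(w) >= -1e-12))
  expect_true(all(w >= 1))
  # trachea-sized airway at tidal frequency is inertially corrected,
  # a 2 mm airway is not
  gas <- gas_config()
  om <- 2 * pi / 3.2
  Wo_tr <- 0.009 * sqrt(om * gas$rho / gas$mu)
  Wo_sm <- 0.001 * sqrt(om * gas$rho / gas$mu)
  expect_gt(womersley_factor(Wo_tr), 1.05)
  expect_lt(womersley_factor(Wo_sm), 1.01)
})

test_that("pipe resistance reduces to Poiseuille at low frequency", {
  gas <- gas_config()
  R_pois <- 128 * gas$mu * 0.01 / (pi * 0.002^4)
  expect_equal(pipe_resistance(0.002, 0.01, T_B = 1e6), R_pois,
               tolerance = 1e-6)
  expect_gt(pipe_resistance(0.018, 0.12, T_B = 3.2),
            128 * gas$mu * 0.12 / (pi * 0.018^4))
})

test_that("lobule resistance equals the lumped geometric series", {
  cfg <- lobule_config()
  gas <- gas_config()
  d_t <- 0.0015; l_t <- 0.005
  z_max <- floor(log(0.3e-3 / d_t) / log(cfg$kappa))
  # per generation: 2^z parallel tubes of diameter d kappa^z, length l kappa^z
  R_ref <- sum(vapply(1:z_max, function(z)
    128 * gas$mu * l_t * cfg$kappa^z / (pi * (d_t * cfg$kappa^z)^4) / 2^z,
    numeric(1)))
  expect_equal(lobule_resistance(d_t, l_t), R_ref, tolerance = 1e-12)
  # series ratio (kappa^-3 / 2) < 1 at kappa = 0.85, so the sum converges
  expect_lt(cfg$kappa^-3 / 2, 1)
  # geometric similarity (floor diameter scaled along): R scales as f^-3
  expect_equal(lobule_resistance(2 * d_t, 2 * l_t,
                                 lobule_config(d_floor_mm = 0.6)),
               R_ref / 8, tolerance = 1e-9)
})

test_that("elastic calibration pins the reference and quarter points", {
  V0 <- 9.6e-6; V_TV <- 1.645e-6; p_TV <- 1500
  for (phi in c(0.5, 1, 1.5)) {
    gam <- calibrate_gamma(phi, V_TV, p_TV)
    cal <- calibrate_beta(phi, gam, V0, V_TV, p_TV)
    # curve passes through (p_TV, V0 + phi V_TV)
    expect_equal(elastic_pressure(phi * V_TV, gam, cal$coef), p_TV,
                 tolerance = 1e-9 * p_TV)
    # quarter point (p_TV/4, V0 + 3/4 phi V_TV)
    expect_equal(elastic_pressure(0.75 * phi * V_TV, gam, cal$coef),
                 p_TV / 4, tolerance = 1e-8 * p_TV)
    # rest state
    expect_equal(elastic_pressure(0, gam, cal$coef), 0)
  }
  # gamma scales inversely with phi * V_TV (universal scaled root)
  g1 <- calibrate_gamma(1, V_TV)
  expect_equal(calibrate_gamma(0.5, V_TV), 2 * g1, tolerance = 1e-9)
  expect_equal(calibrate_gamma(1, 2 * V_TV), g1 / 2, tolerance = 1e-9)
  # the scaled ratio tends to 3/4 in the linear limit and to 0 when stiffening
  ratio <- function(g) expm1(0.75 * g) / expm1(g)
  expect_equal(ratio(1e-8), 0.75, tolerance = 1e-6)
  expect_lt(ratio(100), 1e-8)
  # beta is linear in p_TV at fixed gamma
  gam <- calibrate_gamma(1, V_TV)
  b1 <- calibrate_beta(1, gam, V0, V_TV, 1500)$beta
  b2 <- calibrate_beta(1, gam, V0, V_TV, 3000)$beta
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("ventilation distributes flow symmetrically on a symmetric tree", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  m <- mbw_model(tree, prot, numerics_config(trumpet_cells = 20))
  st <- run_steps(m, prot, 40)
  expect_equal(diff(range(st$dV_lb)), 0)            # identical lobule flows
  expect_equal(sum(st$dV_lb) / m$numerics$dt, prot$Q_in(40 * m$numerics$dt),
               tolerance = 1e-8)
  expect_lt(st$p_pl, 0)                              # inspiration
})

test_that("zero tracheal flow from rest leaves the state unchanged", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  m <- mbw_model(tree, prot)
  for (s in 1:5) step_ventilation(m, 0, 0.005)
  st <- model_state(m)
  expect_equal(st$p_pl, 0, tolerance = 1e-12)
  expect_equal(st$V_lb, tree$lobules$V0, tolerance = 1e-14)
})

test_that("carrier-gas volume is conserved over full breaths", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  m <- mbw_model(tree, prot, numerics_config(trumpet_cells = 20))
  st <- run_steps(m, prot, 640)       # one full sinusoidal breath
  expect_equal(sum(st$V_lb) - sum(tree$lobules$V0), 0,
               tolerance = 1e-8 * prot$TV * 1e-3)
})

test_that("halving dt changes peak-inspiration volumes below 1e-4 relative", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  # compare at peak inspiration (t = T_B/2), where volumes are furthest
  # from the rest state
  vols <- lapply(c(0.005, 0.0025), function(dt) {
    m <- mbw_model(tree, prot, numerics_config(dt = dt, trumpet_cells = 20))
    run_steps(m, prot, round(1.6 / dt), dt)$V_lb
  })
  expect_equal(vols[[1]], vols[[2]], tolerance = 1e-4)
})
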