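test_that("Taylor dispersion follows the local Peclet number", {
  expect_equal(effective_diffusivity(0, 0.01, 2.2e-5), 2.2e-5)
  # Pe = sqrt(192) doubles the diffusivity
  D <- 2.2e-5
  u <- sqrt(192) * D / 0.01
  expect_equal(effective_diffusivity(u, 0.01, D), 2 * D, tolerance = 1e-12)
  # direct evaluation
  Pe <- 0.1 * 0.01 / D
  expect_equal(effective_diffusivity(0.1, 0.01, D) / D, 1 + Pe^2 / 192,
               tolerance = 1e-12)
  expect_equal(1 + Pe^2 / 192, 11.76, tolerance = 1e-2)
  expect_error(effective_diffusivity(1, 0.01, -1), "invalid")
})

test_that("trumpet velocity satisfies carrier-gas conservation", {
  sh <- fit_trumpet_shape(1.8e-6, 0.005, 9e-6)
  Q <- 1.5e-6
  # inlet velocity
  expect_equal(trumpet_velocity(sh, Q, 0), Q / trumpet_section(sh, 0))
  # rigid trumpet: u = Q / S(x), decaying as the trumpet widens
  xs <- seq(0, sh$l_lb * 0.999, length.out = 30)
  expect_equal(trumpet_velocity(sh, Q, xs), Q / trumpet_section(sh, xs))
  expect_true(all(diff(trumpet_velocity(sh, Q, xs)) < 0))
  # closed distal end: wall uptake absorbs the whole inflow when the
  # p1 rate matches dV/dt = Q
  dp1 <- Q * (sh$n1 + 1) / sh$l_lb^(sh$n1 + 1)
  expect_equal(trumpet_velocity(sh, Q, sh$l_lb, dp1_dt = dp1), 0,
               tolerance = 1e-12 * Q / sh$S_t)
})

test_that("a concentration front advects at the carrier speed", {
  L <- 0.1; m <- 100; S <- 1e-4; u <- 0.5
  h <- rep(L / m, m)
  cf <- mbwsim:::pipe_transport_run(
    c0 = rep(1, m), h = h, vol = S * h, qf = rep(u * S, m + 1),
    gf = rep(0, m + 1), dt = 1e-3, nsteps = 100, theta = 1,
    bcL = 1L, cbcL = 0, bcR = 2L, cbcR = 0, scheme = 0L)
  xc <- (seq_len(m) - 0.5) * L / m
  pos <- stats::approx(cf, xc, xout = 0.5, ties = "ordered")$y
  expect_lt(abs(pos - u * 0.1), 2 * L / m)
  expect_true(all(cf >= -1e-12 & cf <= 1 + 1e-12))
})

test_that("free diffusion relaxes a step to the erf profile", {
  L <- 0.1; m <- 100; S <- 1e-4; D <- 1e-5
  h <- rep(L / m, m)
  xc <- (seq_len(m) - 0.5) * L / m
  tend <- L^2 / (16 * D) / 100      # boundaries stay far from the front
  cf <- mbwsim:::pipe_transport_run(
    c0 = as.numeric(xc > L / 2), h = h, vol = S * h,
    qf = rep(0, m + 1), gf = c(0, rep(S * D / (L / m), m - 1), 0),
    dt = tend / 2000, nsteps = 2000, theta = 0.5,
    bcL = 0L, cbcL = 0, bcR = 0L, cbcR = 0, scheme = 0L)
  exact <- 0.5 * (1 + pracma::erf((xc - L / 2) / sqrt(4 * D * tend)))
  expect_lt(sqrt(mean((cf - exact)^2)), 1e-3)
})

test_that("halving the grid spacing shrinks the diffusion error substantially", {
  err_for <- function(m) {
    L <- 0.1; S <- 1e-4; D <- 1e-5
    h <- rep(L / m, m)
    xc <- (seq_len(m) - 0.5) * L / m
    tend <- L^2 / (16 * D) / 100
    cf <- mbwsim:::pipe_transport_run(
      c0 = as.numeric(xc > L / 2), h = h, vol = S * h,
      qf = rep(0, m + 1), gf = c(0, rep(S * D / (L / m), m - 1), 0),
      dt = tend / 4000, nsteps = 4000, theta = 0.5,
      bcL = 0L, cbcL = 0, bcR = 0L, cbcR = 0, scheme = 0L)
    exact <- 0.5 * (1 + pracma::erf((xc - L / 2) / sqrt(4 * D * tend)))
    sqrt(mean((cf - exact)^2))
  }
  e1 <- err_for(50); e2 <- err_for(100)
  expect_gt(e1 / e2, 3)
})

test_that("zero flow and a uniform field are a transport equilibrium", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  m <- mbw_model(tree, prot, numerics_config(trumpet_cells = 20))
  set_concentration(m, 0.37)
  for (s in 1:10) { step_ventilation(m, 0, 0.005); advance_concentration(m, 0, 0.005) }
  st <- model_state(m)
  expect_equal(range(st$conc), c(0.37, 0.37), tolerance = 1e-13)
})

test_that("sibling subtrees of a symmetric lung carry identical fields", {
  tree <- toy_tree()
  prot <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 2)
  m <- mbw_model(tree, prot, numerics_config(trumpet_cells = 20))
  st <- run_steps(m, prot, 900)
  # lobule-mean concentrations identical across all 8 lobules
  expect_equal(diff(range(st$lobule_mean_conc)), 0)
  # left/right main-bronchus cells identical (pipes 2 and 3)
  nc <- m$spec$ncell
  off2 <- sum(nc[1]); off3 <- sum(nc[1:2])
  expect_identical(st$conc[(off2 + 1):(off2 + nc[2])],
                   st$conc[(off3 + 1):(off3 + nc[3])])
})

test_that("tracer mass changes only through the mouth flux", {
  res <- short_run()
  expect_lt(res$mass_audit$max_mass_err, 1e-6)
  expect_lt(max(abs(res$mass_audit$carrier_volume_rel)), 1e-8)
})

test_that("concentrations stay within physical bounds", {
  res <- short_run()
  expect_gt(min(res$trace$concentration), -1e-8)
  expect_lt(max(res$trace$concentration), 1 + 1e-8)
})

test_that("disabling Taylor dispersion changes slopes, not the mass budget", {
  cfg <- simulation_config(protocol = breathing_protocol(n_breaths = 6),
                           numerics = numerics_config(taylor_dispersion = FALSE))
  off <- simulate_washout(cfg)
  on <- short_run()
  # both runs account for every unit of expired tracer through the mouth
  expect_lt(off$mass_audit$max_mass_err, 1e-6)
  expect_lt(on$mass_audit$max_mass_err, 1e-6)
  # dispersion redistributes: the expirogram slopes differ
  expect_gt(mean(abs(off$breaths$s_III - on$breaths$s_III)), 1e-3)
})
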