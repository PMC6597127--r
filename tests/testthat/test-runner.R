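test_that("fixture generators honor their documented contracts", {
  # sine table: half-breath volumes +/- TV
  tab <- make_fixture("sinusoidal_flow", TV = 0.5, T_B = 3.2, n_breaths = 3)
  dt <- diff(tab$time_s)[1]
  half <- tab$flow_L_per_s[tab$time_s <= 1.6]
  expect_equal(sum(half) * dt, 0.5, tolerance = 1e-2)
  expect_equal(sum(tab$flow_L_per_s) * dt, 0, tolerance = 1e-6)
  # toy tree is symmetric with equal lobules
  tree <- make_fixture("toy_symmetric_tree")
  expect_identical(nrow(tree$lobules), 8L)
  expect_equal(diff(range(tree$lobules$V0)), 0)
  # synthetic envelope round-trips through the fitter
  env <- make_fixture("synthetic_envelope", A = 0.3, alpha1 = 0.015,
                      alpha2 = 0.06)
  f <- fit_envelope(env$time_s, env$concentration)
  expect_equal(c(f$A, f$alpha1, f$alpha2), c(0.3, 0.015, 0.06),
               tolerance = 1e-6)
})

test_that("short washouts satisfy global bookkeeping", {
  res <- short_run()
  b <- res$breaths
  expect_identical(nrow(b), 6L)
  expect_equal(b$inspired_volume, rep(0.5, 6), tolerance = 1e-3)
  expect_equal(b$expired_volume, rep(0.5, 6), tolerance = 1e-3)
  # end-expiratory concentration strictly decreasing for the uniform lung
  expect_true(all(diff(b$end_expiratory_concentration) < 0))
  # turnover strictly increasing
  expect_true(all(diff(b$turnover) > 0))
})

test_that("simulations are deterministic and reproducible", {
  cfg <- simulation_config(protocol = breathing_protocol(n_breaths = 2))
  r1 <- simulate_washout(cfg)
  r2 <- simulate_washout(cfg)
  expect_identical(r1$trace$concentration, r2$trace$concentration)
  expect_identical(r1$breaths$s_III, r2$breaths$s_III)
})

test_that("configurations round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- simulation_config(
    morphology = morphology_config(FRC = 2.8, d_lim = 1.6),
    protocol = breathing_protocol(TV = 0.4, n_breaths = 12),
    perturbations = list(
      list(mode = "regional", parameter = "phi", fraction = 0.25, value = 0.5)))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$morphology$FRC, 2.8)
  expect_equal(back$morphology$d_lim, 1.6)
  expect_equal(back$protocol$TV, 0.4)
  expect_identical(back$protocol$n_breaths, 12L)
  expect_equal(back$perturbations[[1]]$value, 0.5)
  unlink(f)
})

test_that("tabulated flow profiles drive the model like the sine they encode", {
  tab <- make_fixture("sinusoidal_flow", TV = 0.02, T_B = 3.2, n_breaths = 1,
                      dt = 0.001)
  f <- tempfile()
  utils::write.table(tab, f, row.names = FALSE, col.names = FALSE)
  prot_tab <- breathing_protocol(TV = 0.02, T_B = 3.2, waveform = "tabulated",
                                 flow_table = f)
  prot_sin <- breathing_protocol(TV = 0.02, T_B = 3.2, n_breaths = 1)
  tt <- seq(0.1, 3.1, by = 0.37)
  expect_equal(prot_tab$Q_in(tt), prot_sin$Q_in(tt), tolerance = 1e-6)
  unlink(f)
})

test_that("the experiment suite writes coherent outcome rows", {
  res <- run_experiment_suite("baseline",
    simulation_config(protocol = breathing_protocol(n_breaths = 8)))
  expect_identical(res$outcomes$name, "baseline")
  expect_true(res$outcomes$alpha1 > 0)
  expect_true(is.na(res$outcomes$LCI) || res$outcomes$LCI > 0)
  expect_error(run_experiment_suite("nonsense"), "arg")
})

test_that("the run manifest records the resolved perturbations", {
  cfg <- simulation_config(
    protocol = breathing_protocol(n_breaths = 2),
    perturbations = list(
      list(mode = "regional", parameter = "tau", fraction = 0.25, value = 8)))
  res <- simulate_washout(cfg)
  man <- res$manifest
  expect_identical(man$n_lobules, 304L)
  ids <- man$perturbations[[1]]$assignments[[1]]$lobule_ids
  expect_identical(length(ids), 76L)
  expect_identical(res$tree$lobules$tau[res$tree$lobules$id %in% ids],
                   rep(8, 76))
})
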