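test_that("breath segmentation integrates sinusoidal volumes exactly", {
  tab <- make_fixture("sinusoidal_flow", TV = 0.5, T_B = 3.2, n_breaths = 10)
  tab$concentration <- 0.5
  recs <- segment_breaths(tab)
  expect_identical(nrow(recs), 10L)
  expect_equal(recs$inspired_volume, rep(0.5, 10), tolerance = 1e-3)
  expect_equal(recs$expired_volume, rep(0.5, 10), tolerance = 1e-3)
  expect_true(all(diff(recs$cumulative_expired_volume) > 0))
})

test_that("segmentation rejects constant-sign flow", {
  tab <- data.frame(time_s = seq(0, 10, 0.01), flow_L_per_s = 0.3,
                    concentration = 0.5)
  expect_error(segment_breaths(tab), "segmentation error")
})

test_that("phase III slope has the closed form for a linear expirogram", {
  v <- seq(0, 0.5, length.out = 200)
  # constant concentration: zero slope
  expect_equal(phase_iii_slope(v, rep(0.3, 200)), 0, tolerance = 1e-12)
  # linear expirogram c = a + b v: s_III = b / mean(c in window)
  a <- 0.04; b <- 0.12
  cexp <- a + b * v
  sel <- v >= 0.25 & v <= 0.475
  expect_equal(phase_iii_slope(v, cexp), b / mean(cexp[sel]),
               tolerance = 1e-9)
  # invariant under concentration rescaling
  expect_equal(phase_iii_slope(v, 7 * cexp), phase_iii_slope(v, cexp),
               tolerance = 1e-12)
})

test_that("envelope fit recovers planted decay parameters to 1e-6", {
  t <- seq_len(50) * 3.2
  # single exponential
  f1 <- fit_envelope(t, exp(-0.031 * (t - t[1])))
  expect_equal(f1$A, 1)
  expect_equal(f1$alpha1, 0.031, tolerance = 1e-6)
  # bi-exponential, the documented example
  env <- make_fixture("synthetic_envelope", A = 0.44, alpha1 = 0.018,
                      alpha2 = 0.045)
  f2 <- fit_envelope(env$time_s, env$concentration)
  expect_equal(f2$A, 0.44, tolerance = 1e-6)
  expect_equal(f2$alpha1, 0.018, tolerance = 1e-6)
  expect_equal(f2$alpha2, 0.045, tolerance = 1e-6)
})

test_that("envelope recovery holds across a parameter grid", {
  t <- seq_len(50) * 3.2
  for (A in c(0.2, 0.5, 0.8)) {
    for (ratio in c(2, 3, 5)) {
      a1 <- 0.02; a2 <- a1 * ratio
      y <- A * exp(-a1 * (t - t[1])) + (1 - A) * exp(-a2 * (t - t[1]))
      f <- fit_envelope(t, y)
      expect_equal(f$A, A, tolerance = 1e-6)
      expect_equal(f$alpha1, a1, tolerance = 1e-6)
      expect_equal(f$alpha2, a2, tolerance = 1e-6)
    }
  }
})

test_that("LCI matches the single-compartment closed form", {
  FRC <- 3.0; TV <- 0.5
  tab <- make_fixture("single_compartment_trace", FRC = FRC, TV = TV,
                      n_breaths = 40)
  s <- analyze_washout(tab, FRC = FRC)
  ratio <- FRC / (FRC + TV)
  n_star <- ceiling(log(0.025) / log(ratio))
  expect_identical(s$n_breaths_lci, as.integer(n_star))
  expect_equal(s$lci, n_star * TV / FRC, tolerance = 1e-3)
})

test_that("LCI edge cases behave as documented", {
  recs <- data.frame(end_expiratory_concentration = c(0.5, 0.3),
                     cumulative_expired_volume = c(0.5, 1.0))
  expect_error(compute_lci(recs, FRC = 3), "not reached")
  expect_identical(compute_lci(recs, FRC = 3, start_concentration = 0),
                   list(lci = 0, n_breaths = 0L))
  # triplet rule needs three consecutive sub-threshold breaths
  recs2 <- data.frame(
    end_expiratory_concentration = c(0.1, 0.02, 0.03, 0.02, 0.01, 0.005),
    cumulative_expired_volume = (1:6) * 0.5)
  expect_identical(compute_lci(recs2, FRC = 3)$n_breaths, 2L)
  expect_identical(compute_lci(recs2, FRC = 3, consecutive = 3L)$n_breaths, 4L)
})

test_that("a perturbed flow table analyzes breath by breath", {
  tab <- make_fixture("perturbed_flow", TV = 0.5, T_B = 3.2, n_breaths = 8,
                      jitter = 0.1)
  tab$concentration <- 0.2
  recs <- segment_breaths(tab)
  expect_identical(nrow(recs), 8L)
  # jitter moves the per-breath volumes around the nominal TV
  expect_gt(diff(range(recs$expired_volume)), 0.01)
  expect_lt(max(abs(recs$expired_volume - 0.5)), 0.1)
})
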