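test_that("regional resolution builds contiguous traversal-order blocks", {
  tree <- default_lung()
  spec <- region_spec("regional", list(
    list(parameter = "phi", fraction = 0.25, value = 0.5),
    list(parameter = "phi", fraction = 0.25, value = 1.5)))
  spec <- resolve_regions(tree, spec)
  expect_identical(lengths(spec$resolved_sets), c(76L, 76L))
  ord <- mbwsim:::dfs_terminal_order(tree)
  expect_identical(spec$resolved_sets[[1]], ord[1:76])
  expect_identical(spec$resolved_sets[[2]], ord[77:152])
})

test_that("local resolution interleaves modifications over the lung", {
  tree <- default_lung()
  spec <- resolve_regions(tree, region_spec("local", list(
    list(parameter = "phi", fraction = 0.25, value = 0.5),
    list(parameter = "phi", fraction = 0.25, value = 1.5))))
  expect_identical(lengths(spec$resolved_sets), c(76L, 76L))
  ord <- mbwsim:::dfs_terminal_order(tree)
  pos1 <- match(spec$resolved_sets[[1]], ord)
  pos2 <- match(spec$resolved_sets[[2]], ord)
  # every other lobule is modified, alternating between the two values
  expect_identical(sort(c(pos1, pos2)), seq(2L, 304L, by = 2L))
  expect_true(all(abs(sort(pos1) - (sort(pos1))[1] -
                        4 * (seq_along(pos1) - 1)) <= 1))
})

test_that("empty fractions resolve to empty sets", {
  tree <- toy_tree()
  spec <- resolve_regions(tree, region_spec("regional", list(
    list(parameter = "tau", fraction = 0, value = 8))))
  expect_identical(lengths(spec$resolved_sets), 0L)
})

test_that("overlapping same-parameter assignments are rejected", {
  tree <- toy_tree()
  expect_error(resolve_regions(tree, region_spec("regional", list(
    list(parameter = "phi", fraction = 0.75, value = 0.5),
    list(parameter = "phi", fraction = 0.75, value = 1.5)))),
    "spec error")
})

test_that("volume modification preserves FRC exactly", {
  tree <- default_lung()
  ids <- tree$lobules$id[1:76]             # 25% of 304
  v_before <- sum(tree$lobules$V0)
  t2 <- apply_volume(tree, ids, 0.5)
  expect_equal(sum(t2$lobules$V0), v_before, tolerance = 1e-12)
  # equal-volume lobules: remaining 75% scale by (1 - 0.25*0.5)/0.75 = 7/6
  sel <- t2$lobules$id %in% ids
  expect_equal(t2$lobules$V0[sel], tree$lobules$V0[sel] * 0.5)
  expect_equal(t2$lobules$V0[!sel], tree$lobules$V0[!sel] * 7 / 6,
               tolerance = 1e-12)
  # shapes refitted to the new volumes
  k <- which(sel)[1]
  sh <- list(p1 = t2$lobules$p1[k], p2 = t2$lobules$p2[k],
             l_lb = t2$lobules$l_lb[k], S_t = t2$lobules$S_t[k],
             n1 = t2$lobules$n1[k], n2 = t2$lobules$n2[k])
  expect_equal(trumpet_volume(sh), t2$lobules$V0[k], tolerance = 1e-9)
  # theta = 1 is the identity
  t3 <- apply_volume(tree, ids, 1)
  expect_equal(t3$lobules$V0, tree$lobules$V0)
})

test_that("resistance modification is multiplicative and invertible", {
  tree <- toy_tree()
  ids <- tree$lobules$id[1:2]
  t2 <- apply_resistance(tree, ids, 8)
  sel <- t2$lobules$id %in% ids
  expect_equal(t2$lobules$tau[sel], rep(8, 2))
  expect_equal(t2$lobules$tau[!sel], rep(1, 6))
  t3 <- apply_resistance(tree, ids, 1)
  expect_identical(t3$lobules$tau, tree$lobules$tau)
  # tau = 8 corresponds to ~40% uniform diameter reduction under d^-4
  expect_equal(1 - 8^(-1 / 4), 0.405, tolerance = 2e-3)
  expect_equal(1 - 16^(-1 / 4), 0.5, tolerance = 1e-12)
})

test_that("compliance modification shifts the pressure-volume curve as specified", {
  tree <- toy_tree()
  tree <- apply_compliance(tree, tree$lobules$id[1], 0.5)
  tree <- apply_compliance(tree, tree$lobules$id[2], 1.5)
  tree <- calibrate_mechanics(tree, TV = 0.02)
  lb <- tree$lobules
  V_TV <- 0.02e-3 / nrow(lb)
  # at p_el = p_TV the lobules hold phi * V_TV above V0
  for (k in 1:3) {
    phi <- lb$phi[k]
    expect_equal(elastic_pressure(phi * V_TV, lb$gamma[k], lb$pel_coef[k]),
                 1500, tolerance = 1e-6 * 1500)
  }
})

test_that("unit factors reproduce the baseline simulation bit-for-bit", {
  cfg0 <- simulation_config(protocol = breathing_protocol(n_breaths = 2))
  cfg1 <- cfg0
  cfg1$perturbations <- list(
    list(mode = "regional", parameter = "phi", fraction = 0.25, value = 1),
    list(mode = "regional", parameter = "theta", fraction = 0.25, value = 1),
    list(mode = "regional", parameter = "tau", fraction = 0.25, value = 1))
  r0 <- simulate_washout(cfg0)
  r1 <- simulate_washout(cfg1)
  expect_identical(r1$trace$concentration, r0$trace$concentration)
})

test_that("the healthy-lung preset is a four-block composite", {
  tree <- healthy_lung_preset(default_lung())
  lb <- tree$lobules
  expect_identical(sum(lb$phi == 0.5), 38L)
  expect_identical(sum(lb$phi == 1.5), 38L)
  # 76 theta-reduced lobules; the rest absorbed the FRC-preserving rescale
  expect_identical(sum(abs(lb$theta - 0.5) < 1e-12), 76L)
  expect_identical(sum(lb$phi == 1 & abs(lb$theta - 0.5) > 1e-12), 152L)
  expect_equal(sum(lb$V0) + pipe_volume(tree), tree$FRC * 1e-3,
               tolerance = 1e-9)
})
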