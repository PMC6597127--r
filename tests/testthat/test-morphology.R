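test_that("trachea scaling follows the cube-root volume law", {
  expect_equal(scale_trachea(0.12, 3.5, 3.5), 0.12)
  expect_equal(scale_trachea(0.12, 8 * 3.5, 3.5), 0.24)
  expect_equal(scale_trachea(0.12, 3.0, 3.5), 0.12 * (3.0 / 3.5)^(1 / 3))
  expect_error(scale_trachea(0.12, -1, 3.5), "positive")
})

test_that("daughter scale factors satisfy the bifurcation identity", {
  ks <- daughter_scales(0.326, 2.97)
  expect_equal(unname(ks["kappa_major"]), (1 - 0.326)^(1 / 2.97))
  expect_equal(unname(ks["kappa_major"]), 0.8756, tolerance = 1e-3)
  expect_equal(unname(ks["kappa_minor"]), 0.6858, tolerance = 1e-3)
  # kappa_major^eta + kappa_minor^eta = 1 across parameter space
  for (r in c(0.1, 0.326, 0.5, 0.9)) {
    for (eta in c(1, 2.97, 5)) {
      ks <- daughter_scales(r, eta)
      expect_equal(ks[["kappa_major"]]^eta + ks[["kappa_minor"]]^eta, 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(daughter_scales(1.2, 3), "invalid")
  # symmetric limit
  ks <- daughter_scales(0.5, 3)
  expect_equal(ks[["kappa_major"]], ks[["kappa_minor"]])
})

test_that("default tree reproduces the documented lobule census", {
  tree <- default_lung()
  expect_identical(length(tree$terminal_pipe_ids), 304L)
  tg <- tree$pipes$generation[tree$pipes$is_terminal]
  expect_identical(range(tg), c(7L, 11L))
})

test_that("tree structure is dichotomous, connected and acyclic", {
  tree <- default_lung()
  p <- tree$pipes
  # exactly one root
  expect_identical(sum(is.na(p$parent)), 1L)
  # two children or none
  n_child <- (!is.na(p$major_child)) + (!is.na(p$minor_child))
  expect_true(all(n_child %in% c(0L, 2L)))
  expect_true(all(xor(p$is_terminal, n_child == 2L)))
  # every pipe reaches the root through strictly decreasing ids (acyclic)
  for (i in sample(p$id, 25)) {
    hops <- 0
    while (!is.na(p$parent[i])) {
      expect_lt(p$parent[i], i)
      i <- p$parent[i]
      hops <- hops + 1
      expect_lt(hops, 50)
    }
  }
  # positive dimensions
  expect_true(all(p$diameter > 0 & p$length > 0))
})

test_that("diameter identity d_maj^eta + d_min^eta = d_parent^eta holds past generation 4", {
  tree <- default_lung()
  p <- tree$pipes
  eta <- tree$config$eta
  parents <- p[!p$is_terminal & p$generation >= 4, ]
  lhs <- p$diameter[parents$major_child]^eta + p$diameter[parents$minor_child]^eta
  expect_equal(lhs, parents$diameter^eta, tolerance = 1e-12)
})

test_that("FRC rescaling scales lengths by f^(1/3) and volumes by f", {
  t1 <- build_tree(morphology_config(FRC = 3.0))
  f <- 1.3
  # d_lim must shrink with the same factor so the topology is identical
  t2 <- build_tree(morphology_config(FRC = 3.0 * f,
                                     d_lim = 1.8 * f^(1 / 3)))
  expect_identical(nrow(t2$pipes), nrow(t1$pipes))
  expect_equal(t2$pipes$length, t1$pipes$length * f^(1 / 3), tolerance = 1e-12)
  expect_equal(pipe_volume(t2), pipe_volume(t1) * f, tolerance = 1e-12)
})

test_that("d_lim sensitivity: nearby limit diameters build successfully", {
  for (dl in c(1.6, 1.8, 2.0)) {
    tree <- build_tree(morphology_config(d_lim = dl))
    expect_gt(length(tree$terminal_pipe_ids), 100)
  }
  counts <- vapply(c(1.6, 1.8, 2.0), function(dl)
    length(build_tree(morphology_config(d_lim = dl))$terminal_pipe_ids),
    numeric(1))
  expect_true(counts[1] > counts[2] && counts[2] > counts[3])
})

test_that("symmetric branching puts all terminals at one generation", {
  tree <- build_tree(morphology_config(r = 0.5))
  tg <- tree$pipes$generation[tree$pipes$is_terminal]
  expect_identical(length(unique(tg)), 1L)
})

test_that("oversized limit diameter raises a degenerate-tree error", {
  expect_error(build_tree(morphology_config(d_lim = 5)), "degenerate")
})

test_that("residual-volume allocation conserves FRC", {
  tree <- allocate_residual_volumes(build_tree(morphology_config()))
  expect_equal(sum(tree$lobules$V0) + pipe_volume(tree), tree$FRC * 1e-3,
               tolerance = 1e-9)
  # equal allocation (default): all V0 identical
  expect_equal(max(tree$lobules$V0), min(tree$lobules$V0))
  # cross-section-proportional alternative
  tcs <- allocate_residual_volumes(
    build_tree(morphology_config(residual_allocation = "cross_section")))
  expect_equal(sum(tcs$lobules$V0) + pipe_volume(tcs), tcs$FRC * 1e-3,
               tolerance = 1e-9)
  expect_equal(tcs$lobules$V0 / sum(tcs$lobules$V0),
               tcs$lobules$S_t / sum(tcs$lobules$S_t), tolerance = 1e-12)
  # symmetric tree: equal volumes under either rule
  tsym <- allocate_residual_volumes(build_tree(morphology_config(
    r = 0.5, residual_allocation = "cross_section")))
  expect_equal(max(tsym$lobules$V0), min(tsym$lobules$V0), tolerance = 1e-12)
  expect_error(allocate_residual_volumes(build_tree(morphology_config()),
                                         FRC = 0.01),
               "infeasible")
})

test_that("tree tables round-trip through the flat export", {
  tree <- default_lung()
  f <- tempfile(fileext = ".tsv")
  write_tree_table(tree, f)
  back <- read_tree_table(f, FRC = tree$FRC)
  expect_equal(back$pipes$diameter, tree$pipes$diameter)
  expect_equal(back$pipes$length, tree$pipes$length)
  expect_identical(back$pipes$parent, tree$pipes$parent)
  expect_identical(back$terminal_pipe_ids, tree$terminal_pipe_ids)
  unlink(f)
})
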