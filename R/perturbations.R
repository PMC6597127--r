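# Lobular perturbations: compliance (phi), residual volume (theta) and
# flow resistance (tau), applied to lobule subsets in regional
# (contiguous) or local (alternating) spatial patterns.

#' Specify a set of lobular modifications
#'
#' @param mode `"regional"` (contiguous blocks of lobules in depth-first
#'   traversal order of the tree, emulating spatially grouped regions) or
#'   `"local"` (assignments interleaved over every other lobule in
#'   traversal order).
#' @param assignments list of assignments, each a list/vector with fields
#'   `parameter` (one of `"phi"`, `"theta"`, `"tau"`), `fraction` (of all
#'   lobules) and `value`.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(mode = c("regional", "local"), assignments = list()) {
  mode <- match.arg(mode)
  for (a in assignments) {
    stopifnot(a$parameter %in% c("phi", "theta", "tau"),
              a$fraction >= 0, a$fraction <= 1, a$value > 0)
  }
  structure(list(mode = mode, assignments = assignments,
                 resolved_sets = NULL), class = "region_spec")
}

# depth-first (preorder, major-daughter first) ordering of terminal pipes
dfs_terminal_order <- function(tree) {
  p <- tree$pipes
  ord <- integer(0)
  stack <- p$id[is.na(p$parent)]
  while (length(stack) > 0) {
    i <- stack[1]; stack <- stack[-1]
    if (p$is_terminal[i]) ord <- c(ord, i)
    else stack <- c(p$major_child[i], p$minor_child[i], stack)
  }
  ord
}

#' Resolve a region spec into explicit lobule sets
#'
#' Regional mode assigns successive contiguous blocks of
#' `round(fraction * N_lb)` terminal pipes in depth-first traversal
#' order (block 1 starts at the first terminal pipe). Local mode
#' interleaves the assignments over the traversal order, lobule by
#' lobule, so modifications are regularly distributed through the lung.
#'
#' @param tree a `lung_tree`.
#' @param spec a [region_spec()].
#' @return The spec with `resolved_sets`: a list (one per assignment) of
#'   terminal-pipe ids.
#' @export
resolve_regions <- function(tree, spec) {
  stopifnot(inherits(spec, "region_spec"))
  ord <- dfs_terminal_order(tree)
  N <- length(ord)
  sizes <- vapply(spec$assignments, function(a) round(a$fraction * N), numeric(1))
  if (sum(sizes) > N) stop("spec error: assignments exceed the lobule count",
                           call. = FALSE)
  sets <- vector("list", length(spec$assignments))
  if (spec$mode == "regional") {
    start <- 1
    for (j in seq_along(sets)) {
      sets[[j]] <- if (sizes[j] > 0) ord[start:(start + sizes[j] - 1)] else integer(0)
      start <- start + sizes[j]
    }
  } else {
    # local mode: modified lobules are spread regularly over the whole
    # traversal order (e.g. every other lobule when half are modified),
    # with the assignments alternating proportionally among them
    n_tot <- sum(sizes)
    pos <- unique(floor((seq_len(n_tot) - 0.5) * N / n_tot) + 1L)
    count <- rep(0, length(sets))
    for (j in seq_along(sets)) sets[[j]] <- integer(0)
    for (p_i in pos) {
      j <- which.min(ifelse(sizes > 0, count / sizes, Inf))
      if (count[j] >= sizes[j]) next
      sets[[j]] <- c(sets[[j]], ord[p_i])
      count[j] <- count[j] + 1
    }
  }
  # overlapping assignments of the same parameter are a spec error
  pars <- vapply(spec$assignments, function(a) a$parameter, character(1))
  for (pp in unique(pars)) {
    ids <- unlist(sets[pars == pp])
    if (anyDuplicated(ids)) stop("spec error: overlapping assignments for ",
                                 pp, call. = FALSE)
  }
  spec$resolved_sets <- sets
  spec
}

#' Modify lobular compliance
#'
#' Sets the compliance factor `phi` for the given lobules; their elastic
#' shape parameters beta and gamma are recalibrated from phi when the
#' model is compiled (geometry is unchanged). `phi < 1` stiffens a
#' lobule (it reaches only `phi * V_TV` at the reference pressure),
#' `phi > 1` softens it.
#'
#' @param tree a `lung_tree`.
#' @param lobule_ids terminal-pipe ids.
#' @param phi compliance factor (> 0).
#' @return The modified tree.
#' @export
apply_compliance <- function(tree, lobule_ids, phi) {
  stopifnot(phi > 0)
  sel <- tree$lobules$id %in% lobule_ids
  tree$lobules$phi[sel] <- phi
  tree
}

#' Modify lobular residual volume, preserving FRC
#'
#' Scales the residual volume of the selected lobules by `theta` and
#' rescales all remaining lobules by a common factor so that the summed
#' residual volume (hence the model FRC) is unchanged. Trumpet shapes
#' are refitted to the new volumes; the mechanical calibration stays
#' referenced to the new V0.
#'
#' @param tree a `lung_tree` with fitted lobules.
#' @param lobule_ids terminal-pipe ids to modify.
#' @param theta volume factor (> 0).
#' @return The modified tree.
#' @export
apply_volume <- function(tree, lobule_ids, theta) {
  stopifnot(theta > 0)
  apply_volume_multi(tree, list(list(ids = lobule_ids, value = theta)))
}

# joint application of several theta assignments with a single
# FRC-preserving rescale of the complement
apply_volume_multi <- function(tree, assignments) {
  stopifnot(!is.null(tree$lobules$p1))
  lb <- tree$lobules
  all_sel <- rep(FALSE, nrow(lb))
  factor <- rep(1, nrow(lb))
  for (a in assignments) {
    sel <- lb$id %in% a$ids
    if (any(sel & all_sel))
      stop("spec error: overlapping theta assignments", call. = FALSE)
    all_sel <- all_sel | sel
    factor[sel] <- a$value
  }
  if (!any(all_sel)) return(tree)
  total <- sum(lb$V0)
  mod_total <- sum(lb$V0[all_sel] * factor[all_sel])
  rest <- sum(lb$V0[!all_sel])
  if (rest <= 0 && abs(mod_total - total) > 1e-15 * total)
    stop("infeasible rescale: no unmodified lobules to absorb the change",
         call. = FALSE)
  f_rest <- if (rest > 0) (total - mod_total) / rest else 1
  if (f_rest <= 0)
    stop("infeasible rescale: would require non-positive residual volumes",
         call. = FALSE)
  factor[!all_sel] <- f_rest
  lb$V0 <- lb$V0 * factor
  lb$theta <- lb$theta * factor
  tree$lobules <- lb
  # refit trumpet shapes to the new residual volumes
  fit_lobule_geometry(tree, tree$lobule_config)
}

#' Modify lobular flow resistance
#'
#' Multiplies the lumped lobule resistance by `tau` for the selected
#' lobules (`p_diss = tau R_lb Q_lb`). Under Poiseuille `d^-4` scaling,
#' `tau = 8` is equivalent to a uniform airway-diameter reduction of
#' `1 - 8^(-1/4)` (about 40%) inside those lobules.
#'
#' @param tree a `lung_tree`.
#' @param lobule_ids terminal-pipe ids.
#' @param tau resistance factor (> 0).
#' @return The modified tree.
#' @export
apply_resistance <- function(tree, lobule_ids, tau) {
  stopifnot(tau > 0)
  sel <- tree$lobules$id %in% lobule_ids
  tree$lobules$tau[sel] <- tree$lobules$tau[sel] * tau
  tree
}

#' Apply a resolved region spec to a tree
#'
#' @param tree a `lung_tree`.
#' @param spec a [region_spec()]; resolved against the tree if needed.
#' @return The modified tree, with the resolved spec attached as
#'   `tree$applied_perturbations` (appended).
#' @export
apply_perturbations <- function(tree, spec) {
  if (is.null(spec$resolved_sets)) spec <- resolve_regions(tree, spec)
  theta_assign <- list()
  for (j in seq_along(spec$assignments)) {
    a <- spec$assignments[[j]]
    ids <- spec$resolved_sets[[j]]
    if (a$parameter == "theta") {
      # collect; all theta blocks share one FRC-preserving rescale
      theta_assign <- c(theta_assign, list(list(ids = ids, value = a$value)))
    } else {
      tree <- switch(a$parameter,
                     phi = apply_compliance(tree, ids, a$value),
                     tau = apply_resistance(tree, ids, a$value))
    }
  }
  if (length(theta_assign) > 0) tree <- apply_volume_multi(tree, theta_assign)
  tree$applied_perturbations <- c(tree$applied_perturbations, list(spec))
  tree
}

#' Composite perturbation emulating a healthy lung
#'
#' Mild physiological ventilation inhomogeneity: four disjoint regional
#' blocks of 12.5% of the lobules each, carrying residual-volume
#' reduction (theta = 0.5 twice) and compliance modification (phi = 0.5
#' and phi = 1.5). Half the lobules remain unmodified; FRC is preserved
#' by the theta rescaling rule.
#'
#' @param tree a baseline `lung_tree`.
#' @return The modified tree.
#' @export
healthy_lung_preset <- function(tree) {
  spec <- region_spec("regional", list(
    list(parameter = "theta", fraction = 0.125, value = 0.5),
    list(parameter = "theta", fraction = 0.125, value = 0.5),
    list(parameter = "phi", fraction = 0.125, value = 0.5),
    list(parameter = "phi", fraction = 0.125, value = 1.5)))
  apply_perturbations(tree, spec)
}
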