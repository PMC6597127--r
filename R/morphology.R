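# Conducting-airway tree generation: Weibel dimensions for generations 0-4,
# asymmetric (major/minor) bifurcation beyond, FRC-based cube-root scaling.

#' Default Weibel dimensions for airway generations 0-4
#'
#' Classical symmetric-model airway dimensions (trachea = generation 0)
#' used for the first five generations of the conducting tree, in mm.
#' Deeper generations follow the asymmetric bifurcation rule instead.
#' The table can be overridden through [morphology_config()].
#'
#' @return A data.frame with columns `generation`, `diameter_mm`, `length_mm`.
#' @export
weibel_default_table <- function() {
  data.frame(
    generation  = 0:4,
    diameter_mm = c(18.0, 12.2, 8.3, 5.6, 4.5),
    length_mm   = c(120.0, 47.6, 19.0, 7.6, 12.7)
  )
}

#' Morphology configuration
#'
#' Parameters controlling generation of the conducting-airway tree.
#'
#' @param FRC functional residual capacity of the model (L); the whole
#'   airway network is scaled so that pipes plus lobule residual volumes
#'   total `FRC` at end-expiration.
#' @param FRC_W reference FRC (L) to which the reference airway dimensions
#'   correspond.
#' @param d_lim limit diameter (mm); a newly created pipe whose diameter
#'   falls below `d_lim` is kept, marked terminal, and not bifurcated.
#' @param r branching asymmetry parameter in (0, 1).
#' @param eta diameter reduction rate (exponent) of the bifurcation rule.
#' @param weibel_table data.frame as returned by [weibel_default_table()];
#'   absolute airway dimensions (mm) for generations 0-4 before FRC scaling.
#' @param trachea_elongation extra tracheal length (m, after scaling)
#'   representing upper-airway/equipment dead space; default 0.
#' @param residual_allocation how the lobular residual volume is split
#'   among lobules: `"cross_section"` (proportional to terminal-pipe
#'   cross-section) or `"equal"`.
#' @return A list of class `morphology_config`.
#' @export
morphology_config <- function(FRC = 3.0, FRC_W = 3.5, d_lim = 1.8,
                              r = 0.326, eta = 2.97,
                              weibel_table = weibel_default_table(),
                              trachea_elongation = 0,
                              residual_allocation = c("equal", "cross_section")) {
  residual_allocation <- match.arg(residual_allocation)
  if (!is.numeric(FRC) || length(FRC) != 1L || FRC <= 0)
    stop("invalid parameter: FRC must be a positive scalar (L)", call. = FALSE)
  if (FRC_W <= 0) stop("invalid parameter: FRC_W must be positive", call. = FALSE)
  if (d_lim <= 0) stop("invalid parameter: d_lim must be positive", call. = FALSE)
  if (r <= 0 || r >= 1) stop("invalid parameter: r must lie in (0, 1)", call. = FALSE)
  if (eta <= 0) stop("invalid parameter: eta must be positive", call. = FALSE)
  stopifnot(is.data.frame(weibel_table),
            all(c("generation", "diameter_mm", "length_mm") %in% names(weibel_table)))
  if (!identical(sort(weibel_table$generation), 0:4))
    stop("weibel_table must cover generations 0-4 exactly", call. = FALSE)
  if (trachea_elongation < 0)
    stop("invalid parameter: trachea_elongation must be >= 0", call. = FALSE)
  structure(list(FRC = FRC, FRC_W = FRC_W, d_lim = d_lim, r = r, eta = eta,
                 weibel_table = weibel_table[order(weibel_table$generation), ],
                 trachea_elongation = trachea_elongation,
                 residual_allocation = residual_allocation),
            class = "morphology_config")
}

#' Scale the trachea (and tree) to a target FRC
#'
#' Linear airway dimensions scale with the cube root of the lung volume
#' ratio, `l0 = l0_W * (FRC / FRC_W)^(1/3)`. The same factor applies to
#' every pipe diameter and length in the tree.
#'
#' @param l0_W reference tracheal length (m).
#' @param FRC target functional residual capacity (any volume unit).
#' @param FRC_W reference FRC in the same unit as `FRC`.
#' @return Scaled tracheal length (m).
#' @export
scale_trachea <- function(l0_W, FRC, FRC_W) {
  if (any(c(l0_W, FRC, FRC_W) <= 0))
    stop("invalid parameter: scale_trachea() requires positive inputs", call. = FALSE)
  l0_W * (FRC / FRC_W)^(1 / 3)
}

#' Daughter-airway scale factors of the asymmetric bifurcation rule
#'
#' Each parent pipe past generation 4 bifurcates into a major and a minor
#' daughter whose diameter and length are fractions
#' `kappa_major = (1 - r)^(1/eta)` and `kappa_minor = r^(1/eta)` of the
#' parent's. The factors satisfy `kappa_major^eta + kappa_minor^eta = 1`,
#' so the eta-th powers of daughter diameters partition the parent's.
#'
#' @param r asymmetry parameter in (0, 1).
#' @param eta reduction rate (> 0).
#' @return Named numeric vector `c(kappa_major, kappa_minor)`.
#' @export
daughter_scales <- function(r, eta) {
  if (r <= 0 || r >= 1) stop("invalid parameter: r must lie in (0, 1)", call. = FALSE)
  if (eta <= 0) stop("invalid parameter: eta must be positive", call. = FALSE)
  c(kappa_major = (1 - r)^(1 / eta), kappa_minor = r^(1 / eta))
}

#' Build the conducting-airway tree
#'
#' Generations 0-4 take the (symmetric) Weibel dimensions from the config
#' table; deeper pipes bifurcate asymmetrically with the major/minor scale
#' factors until a pipe's diameter falls below `d_lim`, at which point the
#' pipe is kept and marked terminal. All dimensions (including `d_lim`
#' screening) are applied after cube-root FRC scaling. The result is a
#' deterministic dichotomous tree; each terminal pipe later receives one
#' trumpet lobule.
#'
#' @param config a [morphology_config()].
#' @return An object of class `lung_tree`: a list with elements `pipes`
#'   (data.frame: `id`, `generation`, `parent`, `major_child`,
#'   `minor_child`, `diameter`, `length`, `is_terminal`, `proximal_node`,
#'   `distal_node`; lengths/diameters in m), `terminal_pipe_ids`, `FRC`
#'   (L), `scale` and `config`. Node 0 is the mouth end of the trachea;
#'   the distal node id of pipe `i` equals `i`.
#' @export
build_tree <- function(config = morphology_config()) {
  stopifnot(inherits(config, "morphology_config"))
  scale <- (config$FRC / config$FRC_W)^(1 / 3)
  wt <- config$weibel_table
  d_w <- wt$diameter_mm * 1e-3 * scale   # m, scaled
  l_w <- wt$length_mm * 1e-3 * scale
  d_lim <- config$d_lim * 1e-3           # m (screened against scaled dims)
  if (d_w[5] < d_lim)
    stop("degenerate tree: d_lim exceeds the scaled generation-4 diameter",
         call. = FALSE)
  ks <- daughter_scales(config$r, config$eta)

  # grow by recursion; preallocate generously and trim
  n_max <- 8192L
  gen <- integer(n_max); dia <- numeric(n_max); len <- numeric(n_max)
  par <- integer(n_max); maj <- integer(n_max); mino <- integer(n_max)
  n <- 0L
  new_pipe <- function(g, d, l, p) {
    n <<- n + 1L
    if (n > n_max) stop("tree larger than preallocated bound", call. = FALSE)
    gen[n] <<- g; dia[n] <<- d; len[n] <<- l; par[n] <<- p
    maj[n] <<- NA_integer_; mino[n] <<- NA_integer_
    n
  }
  # breadth-first queue so that parents always precede children
  l_trachea <- l_w[1] + config$trachea_elongation
  root <- new_pipe(0L, d_w[1], l_trachea, NA_integer_)
  queue <- root
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    g <- gen[i]
    if (g < 4L) {
      # symmetric Weibel levels: both daughters share the tabulated dims
      a <- new_pipe(g + 1L, d_w[g + 2L], l_w[g + 2L], i)
      b <- new_pipe(g + 1L, d_w[g + 2L], l_w[g + 2L], i)
      maj[i] <- a; mino[i] <- b
      queue <- c(queue, a, b)
    } else if (dia[i] >= d_lim) {
      a <- new_pipe(g + 1L, dia[i] * ks[["kappa_major"]],
                    len[i] * ks[["kappa_major"]], i)
      b <- new_pipe(g + 1L, dia[i] * ks[["kappa_minor"]],
                    len[i] * ks[["kappa_minor"]], i)
      maj[i] <- a; mino[i] <- b
      queue <- c(queue, a, b)
    }
    # else: diameter < d_lim -> kept as terminal, no children
  }
  idx <- seq_len(n)
  pipes <- data.frame(
    id = idx, generation = gen[idx], parent = par[idx],
    major_child = maj[idx], minor_child = mino[idx],
    diameter = dia[idx], length = len[idx],
    is_terminal = is.na(maj[idx]),
    proximal_node = ifelse(is.na(par[idx]), 0L, par[idx]),
    distal_node = idx
  )
  structure(list(pipes = pipes,
                 terminal_pipe_ids = pipes$id[pipes$is_terminal],
                 lobules = NULL, FRC = config$FRC, scale = scale,
                 config = config),
            class = "lung_tree")
}

#' Total airway-pipe volume of a tree
#'
#' Cylindrical volume `pi (d/2)^2 l` summed over all pipes.
#'
#' @param tree a `lung_tree`.
#' @return Volume in m^3.
#' @export
pipe_volume <- function(tree) {
  stopifnot(inherits(tree, "lung_tree"))
  sum(pi * (tree$pipes$diameter / 2)^2 * tree$pipes$length)
}

#' Allocate lobular residual volumes
#'
#' Distributes the volume `FRC - (total pipe volume)` among the trumpet
#' lobules so that the whole model holds exactly `FRC` at end-expiration.
#' The split is proportional to the terminal-pipe cross-section (default)
#' or equal, per the config's `residual_allocation`.
#'
#' @param tree a `lung_tree` from [build_tree()].
#' @param FRC target FRC (L); defaults to the tree's configured FRC.
#' @return The tree with a `lobules` data.frame holding `id` (terminal
#'   pipe id), `S_t` (m^2), `l_t`, `d_t` (m) and `V0` (m^3), plus unit
#'   modification factors `phi`, `theta`, `tau`.
#' @export
allocate_residual_volumes <- function(tree, FRC = tree$FRC) {
  stopifnot(inherits(tree, "lung_tree"))
  vp <- pipe_volume(tree)
  v_total <- FRC * 1e-3
  if (v_total <= vp)
    stop("infeasible FRC: smaller than the conducting-airway volume",
         call. = FALSE)
  term <- tree$pipes[tree$pipes$is_terminal, ]
  S_t <- pi * (term$diameter / 2)^2
  w <- switch(tree$config$residual_allocation,
              cross_section = S_t / sum(S_t),
              equal = rep(1 / nrow(term), nrow(term)))
  tree$lobules <- data.frame(
    id = term$id, S_t = S_t, l_t = term$length, d_t = term$diameter,
    V0 = (v_total - vp) * w,
    phi = 1, theta = 1, tau = 1
  )
  tree$FRC <- FRC
  tree
}

#' Build a complete lung model geometry
#'
#' Convenience wrapper: [build_tree()], [allocate_residual_volumes()] and
#' [fit_lobule_geometry()] in sequence.
#'
#' @param config a [morphology_config()].
#' @param lobule a [lobule_config()] with trumpet-lobule parameters.
#' @return A `lung_tree` with fitted trumpet lobules.
#' @export
build_lung <- function(config = morphology_config(), lobule = lobule_config()) {
  tree <- build_tree(config)
  tree <- allocate_residual_volumes(tree)
  fit_lobule_geometry(tree, lobule)
}

#' Export a tree as a flat table
#'
#' One row per pipe (id, generation, parent, diameter_m, length_m,
#' is_terminal), written as tab-separated text; round-trips through
#' [read_tree_table()] up to lobule geometry, which is refitted.
#'
#' @param tree a `lung_tree`.
#' @param file path to write to.
#' @export
write_tree_table <- function(tree, file) {
  stopifnot(inherits(tree, "lung_tree"))
  p <- tree$pipes
  out <- data.frame(id = p$id, generation = p$generation, parent = p$parent,
                    diameter_m = p$diameter, length_m = p$length,
                    is_terminal = p$is_terminal)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a tree table written by [write_tree_table()]
#'
#' Reconstructs the pipe network (children are identified from the parent
#' column; the lower child id is taken as the major daughter, matching the
#' creation order used by [build_tree()]).
#'
#' @param file path to a tree table.
#' @param FRC FRC (L) to attach to the reconstructed tree.
#' @param config optional [morphology_config()] to attach.
#' @return A `lung_tree` (without lobule volumes; pass through
#'   [allocate_residual_volumes()] to complete it).
#' @export
read_tree_table <- function(file, FRC = 3.0, config = morphology_config(FRC = FRC)) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  n <- nrow(tab)
  maj <- rep(NA_integer_, n); mino <- rep(NA_integer_, n)
  kids <- split(tab$id, tab$parent)
  for (pid in names(kids)) {
    ch <- sort(kids[[pid]])
    i <- as.integer(pid)
    maj[i] <- ch[1]; mino[i] <- ch[2]
  }
  pipes <- data.frame(id = tab$id, generation = tab$generation,
                      parent = tab$parent, major_child = maj,
                      minor_child = mino, diameter = tab$diameter_m,
                      length = tab$length_m, is_terminal = tab$is_terminal,
                      proximal_node = ifelse(is.na(tab$parent), 0L, tab$parent),
                      distal_node = tab$id)
  structure(list(pipes = pipes, terminal_pipe_ids = pipes$id[pipes$is_terminal],
                 lobules = NULL, FRC = FRC,
                 scale = (config$FRC / config$FRC_W)^(1 / 3), config = config),
            class = "lung_tree")
}

#' @export
print.lung_tree <- function(x, ...) {
  cat(sprintf("<lung_tree> %d pipes, %d terminal pipes/lobules, FRC %.3g L\n",
              nrow(x$pipes), length(x$terminal_pipe_ids), x$FRC))
  cat(sprintf("  terminal generations %d-%d; conducting volume %.1f mL\n",
              min(x$pipes$generation[x$pipes$is_terminal]),
              max(x$pipes$generation[x$pipes$is_terminal]),
              1e6 * pipe_volume(x)))
  if (!is.null(x$lobules))
    cat(sprintf("  lobule residual volume %.1f mL total\n", 1e6 * sum(x$lobules$V0)))
  invisible(x)
}
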