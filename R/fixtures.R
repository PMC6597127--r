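# Deterministic test-input generators: flow tables, a toy symmetric tree,
# synthetic washout envelopes and the single-compartment analytic trace.

#' Generate a deterministic test fixture
#'
#' @param kind one of `"sinusoidal_flow"`, `"perturbed_flow"`,
#'   `"toy_symmetric_tree"`, `"synthetic_envelope"`,
#'   `"single_compartment_trace"`.
#' @param ... kind-specific parameters, see Details.
#' @param file optional path; if given, tabular fixtures are also written
#'   there (tab-separated text).
#'
#' @details
#' * `sinusoidal_flow(TV, T_B, n_breaths, dt)`: two-column flow table
#'   (time_s, flow_L_per_s) of a sine profile; each half-breath
#'   integrates to +/- TV.
#' * `perturbed_flow(TV, T_B, n_breaths, dt, jitter)`: sine profile with
#'   deterministic breath-to-breath tidal-volume modulation of relative
#'   amplitude `jitter` (golden-angle phase stepping, so no two breaths
#'   repeat).
#' * `toy_symmetric_tree(n_gen, d0, l0, FRC, kappa_tree)`: a fully
#'   symmetric dichotomous tree with `n_gen` generations below the root
#'   pipe, all daughters scaled by `kappa_tree`; terminal pipes carry
#'   equal-volume lobules. Returns a fitted `lung_tree`.
#' * `synthetic_envelope(A, alpha1, alpha2, n_breaths, T_B)`: noise-free
#'   bi-exponential end-expiratory series (t, c).
#' * `single_compartment_trace(FRC, TV, T_B, n_breaths, dt)`: MBW trace
#'   of an ideal single mixing compartment without dead space: the
#'   end-expiratory concentration after breath n is
#'   `(FRC/(FRC+TV))^n`.
#' @return The fixture (data.frame or `lung_tree`).
#' @export
make_fixture <- function(kind = c("sinusoidal_flow", "perturbed_flow",
                                  "toy_symmetric_tree", "synthetic_envelope",
                                  "single_compartment_trace"),
                         ..., file = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
                sinusoidal_flow = fixture_sine_flow(...),
                perturbed_flow = fixture_perturbed_flow(...),
                toy_symmetric_tree = fixture_toy_tree(...),
                synthetic_envelope = fixture_envelope(...),
                single_compartment_trace = fixture_single_compartment(...))
  if (!is.null(file) && is.data.frame(out))
    utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

fixture_sine_flow <- function(TV = 0.5, T_B = 3.2, n_breaths = 50, dt = 0.005) {
  stopifnot(TV > 0, T_B > 0, n_breaths >= 1)
  t <- seq(0, n_breaths * T_B, by = dt)
  data.frame(time_s = t, flow_L_per_s = pi * TV / T_B * sin(2 * pi * t / T_B))
}

fixture_perturbed_flow <- function(TV = 0.5, T_B = 3.2, n_breaths = 50,
                                   dt = 0.005, jitter = 0.1) {
  stopifnot(jitter >= 0, jitter < 1)
  t <- seq(0, n_breaths * T_B, by = dt)
  breath <- pmin(floor(t / T_B), n_breaths - 1)
  golden <- 2 * pi * (sqrt(5) - 1) / 2
  tv_b <- TV * (1 + jitter * sin(golden * (breath + 1)))
  data.frame(time_s = t,
             flow_L_per_s = pi * tv_b / T_B * sin(2 * pi * t / T_B))
}

fixture_toy_tree <- function(n_gen = 3, d0 = 0.006, l0 = 0.03, FRC = 0.05,
                             kappa_tree = 0.8, lobule = lobule_config()) {
  stopifnot(n_gen >= 1)
  n_pipes <- 2^(n_gen + 1) - 1
  gen <- floor(log2(seq_len(n_pipes)))
  parent <- c(NA_integer_, seq_len(n_pipes)[-1] %/% 2)
  child1 <- ifelse(2 * seq_len(n_pipes) <= n_pipes, 2L * seq_len(n_pipes),
                   NA_integer_)
  child2 <- ifelse(2 * seq_len(n_pipes) + 1 <= n_pipes,
                   2L * seq_len(n_pipes) + 1L, NA_integer_)
  pipes <- data.frame(
    id = seq_len(n_pipes), generation = gen, parent = parent,
    major_child = child1, minor_child = child2,
    diameter = d0 * kappa_tree^gen, length = l0 * kappa_tree^gen,
    is_terminal = is.na(child1),
    proximal_node = ifelse(is.na(parent), 0L, parent),
    distal_node = seq_len(n_pipes))
  cfg <- morphology_config(FRC = FRC, residual_allocation = "equal")
  tree <- structure(list(pipes = pipes,
                         terminal_pipe_ids = pipes$id[pipes$is_terminal],
                         lobules = NULL, FRC = FRC, scale = 1, config = cfg),
                    class = "lung_tree")
  tree <- allocate_residual_volumes(tree)
  fit_lobule_geometry(tree, lobule)
}

fixture_envelope <- function(A = 0.44, alpha1 = 0.018, alpha2 = 0.045,
                             n_breaths = 50, T_B = 3.2) {
  stopifnot(A >= 0, A <= 1, alpha1 > 0, alpha2 >= alpha1)
  t <- seq_len(n_breaths) * T_B
  data.frame(time_s = t,
             concentration = A * exp(-alpha1 * (t - t[1])) +
               (1 - A) * exp(-alpha2 * (t - t[1])))
}

fixture_single_compartment <- function(FRC = 3.0, TV = 0.5, T_B = 3.2,
                                       n_breaths = 40, dt = 0.005) {
  tab <- fixture_sine_flow(TV, T_B, n_breaths, dt)
  breath <- pmin(floor(tab$time_s / T_B), n_breaths - 1) + 1
  ratio <- FRC / (FRC + TV)
  conc <- ifelse(tab$flow_L_per_s < 0, ratio^breath, 0)
  tab$concentration <- conc
  tab
}
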