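# Trumpet-lobule geometry: a power-law cross-section fitted to the
# exponential airway-lumping law, with volume changes carried by the
# high-order coefficient so that expansion concentrates peripherally.

#' Trumpet-lobule configuration
#'
#' @param kappa homothety ratio of successive airway generations lumped
#'   into the trumpet (daughter/parent linear scale).
#' @param z_star generation at which the power-law cross-section is pinned
#'   to the exponential lumping law.
#' @param n1,n2 power-law exponents; `n1` carries the time variation.
#' @param d_floor_mm smallest airway diameter (mm) included when summing
#'   the intra-lobule flow resistance.
#' @return A list of class `lobule_config`.
#' @export
lobule_config <- function(kappa = 0.85, z_star = 6, n1 = 20, n2 = 2,
                          d_floor_mm = 0.3) {
  if (kappa <= 0 || kappa >= 1)
    stop("invalid parameter: kappa must lie in (0, 1)", call. = FALSE)
  if (z_star <= 0) stop("invalid parameter: z_star must be positive", call. = FALSE)
  if (n1 <= n2 || n2 <= 0) stop("invalid parameter: need n1 > n2 > 0", call. = FALSE)
  structure(list(kappa = kappa, z_star = z_star, n1 = n1, n2 = n2,
                 d_floor_mm = d_floor_mm), class = "lobule_config")
}

#' Total trumpet length from the lumped geometric series
#'
#' Airway generation k inside the lobule has length `l_t * kappa^k`; the
#' cumulative length converges to `L = l_t * kappa / (1 - kappa)`.
#'
#' @param l_t terminal-pipe length (m).
#' @param kappa homothety ratio in (0, 1).
#' @return Trumpet length L (m).
#' @export
trumpet_length <- function(l_t, kappa) {
  if (kappa <= 0 || kappa >= 1)
    stop("invalid parameter: kappa must lie in (0, 1)", call. = FALSE)
  if (l_t <= 0) stop("invalid parameter: l_t must be positive", call. = FALSE)
  l_t * kappa / (1 - kappa)
}

#' Continuous airway generation at a position inside the trumpet
#'
#' Inverts the cumulative-length relation: `z(x)` is the (real-valued)
#' generation reached at distance `x` from the trumpet inlet, with
#' `z(0) = 0` and `z -> Inf` as `x -> L`.
#'
#' @param x distance from the trumpet inlet (m); must satisfy `0 <= x < L`.
#' @param l_t terminal-pipe length (m).
#' @param kappa homothety ratio in (0, 1).
#' @return Generation z(x) (dimensionless, real).
#' @export
generation_at <- function(x, l_t, kappa) {
  L <- trumpet_length(l_t, kappa)
  if (any(x < 0) || any(x >= L))
    stop("out of domain: generation_at() requires 0 <= x < L", call. = FALSE)
  log(x * (kappa - 1) / (kappa * l_t) + 1) / log(kappa)
}

# cumulative length at (real) generation z, inverse of generation_at()
cumlen_at <- function(z, l_t, kappa) l_t * kappa * (1 - kappa^z) / (1 - kappa)

#' Exponential lumped cross-section of the trumpet
#'
#' The cross-section obtained by counting `2^z` airways of diameter
#' `d_t * kappa^z` at generation `z(x)`: `S(x) = S_t * (2 kappa^2)^z(x)`.
#' This is the law the power-law model is fitted against.
#'
#' @param x position (m), `0 <= x < L`.
#' @param S_t terminal-pipe cross-section (m^2).
#' @param l_t terminal-pipe length (m).
#' @param kappa homothety ratio.
#' @return Cross-section (m^2).
#' @export
trumpet_reference_section <- function(x, S_t, l_t, kappa) {
  S_t * (2 * kappa^2)^generation_at(x, l_t, kappa)
}

#' Fit the power-law trumpet shape
#'
#' Determines `p1`, `p2` of `S_lb(x) = p1 x^n1 + p2 x^n2 + S_t` from two
#' linear conditions: (i) the section equals the exponential lumping law
#' `S_t * (2 kappa^2)^z_star` at the cumulative length `x*` of generation
#' `z_star`, and (ii) the integral over `[0, l_lb]` equals the prescribed
#' residual volume `V0`.
#'
#' @param S_t terminal-pipe cross-section (m^2).
#' @param l_t terminal-pipe length (m).
#' @param V0 residual (end-expiratory) lobule volume (m^3); must exceed
#'   `S_t * l_lb` so the trumpet widens.
#' @param config a [lobule_config()].
#' @return List with `p1`, `p2`, `l_lb`, `x_star`, `S_t`, plus the config
#'   exponents.
#' @export
fit_trumpet_shape <- function(S_t, l_t, V0, config = lobule_config()) {
  kappa <- config$kappa; n1 <- config$n1; n2 <- config$n2
  l_lb <- trumpet_length(l_t, kappa)
  if (V0 <= S_t * l_lb)
    stop("shape-fit error: V0 must exceed S_t * l_lb (trumpet must widen)",
         call. = FALSE)
  x_star <- cumlen_at(config$z_star, l_t, kappa)
  khat <- 2 * kappa^2
  # 2x2 linear system in (p1, p2); solved in the normalized coordinate
  # xi = x / l_lb to avoid underflow of x^n1 at millimetre scales
  xi <- x_star / l_lb
  A <- rbind(c(xi^n1, xi^n2),
             c(1 / (n1 + 1), 1 / (n2 + 1)))
  b <- c(S_t * (khat^config$z_star - 1), (V0 - S_t * l_lb) / l_lb)
  p <- tryCatch(solve(A, b), error = function(e)
    stop("shape-fit error: singular trumpet system", call. = FALSE))
  shape <- list(p1 = p[1] / l_lb^n1, p2 = p[2] / l_lb^n2, l_lb = l_lb,
                x_star = x_star, S_t = S_t, n1 = n1, n2 = n2)
  s <- trumpet_section(shape, seq(0, l_lb, length.out = 257))
  if (any(s <= 0) || any(diff(s) < -1e-12 * max(s)))
    stop("shape-fit error: fitted cross-section non-positive or decreasing",
         call. = FALSE)
  shape
}

#' Evaluate the power-law trumpet cross-section
#'
#' @param shape a shape list from [fit_trumpet_shape()] (or a one-row
#'   lobule record with `p1`, `p2`, `S_t`, `n1`, `n2`).
#' @param x positions (m) in `[0, l_lb]`.
#' @return Cross-sections (m^2).
#' @export
trumpet_section <- function(shape, x) {
  shape$p1 * x^shape$n1 + shape$p2 * x^shape$n2 + shape$S_t
}

#' Integrated trumpet volume up to position x
#'
#' @param shape a shape list from [fit_trumpet_shape()].
#' @param x upper integration limit(s) (m); defaults to the full length.
#' @return Volume(s) (m^3).
#' @export
trumpet_volume <- function(shape, x = shape$l_lb) {
  shape$p1 * x^(shape$n1 + 1) / (shape$n1 + 1) +
    shape$p2 * x^(shape$n2 + 1) / (shape$n2 + 1) + shape$S_t * x
}

#' Update the trumpet shape for a new instantaneous volume
#'
#' The time variation is carried by `p1` alone (`p2` keeps its initial
#' fit), so the sectional change `dS/dt = dp1/dt * x^n1` vanishes at the
#' inlet and is maximal at the distal end: the lobule expands peripherally.
#'
#' @param shape a shape list from [fit_trumpet_shape()].
#' @param V_new new total volume (m^3), must exceed `S_t * l_lb`.
#' @return The shape with updated `p1`.
#' @export
update_trumpet_volume <- function(shape, V_new) {
  if (V_new <= shape$S_t * shape$l_lb)
    stop("volume-range error: V_new must exceed S_t * l_lb", call. = FALSE)
  n1 <- shape$n1; n2 <- shape$n2; l <- shape$l_lb
  p1 <- (V_new - shape$p2 * l^(n2 + 1) / (n2 + 1) - shape$S_t * l) *
    (n1 + 1) / l^(n1 + 1)
  if (p1 < 0)
    stop("volume-range error: V_new yields a non-monotone cross-section",
         call. = FALSE)
  shape$p1 <- p1
  shape
}

#' Fit trumpet geometry for every lobule of a tree
#'
#' Adds the power-law shape coefficients, trumpet length and intra-lobule
#' flow resistance to the tree's lobule table.
#'
#' @param tree a `lung_tree` with allocated residual volumes.
#' @param config a [lobule_config()].
#' @param gas a [gas_config()] (viscosity used for the lobule resistance).
#' @return The tree with extended `lobules` and the lobule config stored
#'   as `tree$lobule_config`.
#' @export
fit_lobule_geometry <- function(tree, config = lobule_config(),
                                gas = gas_config()) {
  stopifnot(inherits(tree, "lung_tree"), !is.null(tree$lobules))
  lb <- tree$lobules
  n <- nrow(lb)
  p1 <- p2 <- l_lb <- x_star <- R_lb <- numeric(n)
  for (i in seq_len(n)) {
    sh <- fit_trumpet_shape(lb$S_t[i], lb$l_t[i], lb$V0[i], config)
    p1[i] <- sh$p1; p2[i] <- sh$p2; l_lb[i] <- sh$l_lb; x_star[i] <- sh$x_star
    R_lb[i] <- lobule_resistance(lb$d_t[i], lb$l_t[i], config, gas)
  }
  lb$p1 <- p1; lb$p2 <- p2; lb$l_lb <- l_lb; lb$x_star <- x_star
  lb$n1 <- config$n1; lb$n2 <- config$n2; lb$kappa <- config$kappa
  lb$z_star <- config$z_star
  lb$R_lb <- R_lb
  tree$lobules <- lb
  tree$lobule_config <- config
  tree
}

#' Write lobule geometry to a tabular file
#'
#' @param tree a `lung_tree` with fitted lobules.
#' @param file output path (tab-separated text).
#' @export
write_lobule_table <- function(tree, file) {
  stopifnot(!is.null(tree$lobules$p1))
  cols <- c("id", "S_t", "l_t", "l_lb", "V0", "p1", "p2", "z_star",
            "R_lb", "phi", "theta", "tau")
  utils::write.table(tree$lobules[, cols], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
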