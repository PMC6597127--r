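# 1D inert-gas transport: Taylor dispersion, trumpet velocity field, and
# the numerical grids on which the network transport equation is solved.

#' Effective axial diffusivity with Taylor dispersion
#'
#' `Dhat = D (1 + Pe^2 / 192)` with the Peclet number `Pe = |u| d / D`
#' built from the local mean velocity and local airway diameter. Radial
#' velocity gradients in laminar tube flow enhance axial mixing; the
#' quadratic Taylor form strictly applies to developed flow in straight
#' tubes and, if anything, underestimates mixing near bifurcations.
#'
#' @param u local mean velocity (m/s).
#' @param d local airway diameter (m).
#' @param D molecular diffusivity (m^2/s).
#' @return Effective diffusivity (m^2/s).
#' @export
effective_diffusivity <- function(u, d, D) {
  if (any(D <= 0)) stop("invalid parameter: D must be positive", call. = FALSE)
  Pe <- abs(u) * d / D
  D * (1 + Pe^2 / 192)
}

#' Gas velocity inside a trumpet lobule
#'
#' Carrier-gas mass conservation in a compartment with growing
#' cross-section: the flow entering at the throat is progressively
#' absorbed by wall motion, `u(x,t) = (Q_t - int_0^x dS/dt dx') / S_ad`.
#' With the volume change carried by the `p1` coefficient alone,
#' `int_0^x dS/dt dx' = dp1/dt * x^(n1+1) / (n1+1)`, so the velocity
#' decays from `Q_t / S_ad(0)` at the inlet to exactly zero at the closed
#' distal end whenever `Q_t = dV_lb/dt`.
#'
#' @param shape trumpet shape (see [fit_trumpet_shape()]).
#' @param Q_t flow into the trumpet inlet (m^3/s).
#' @param x position(s) (m).
#' @param dp1_dt rate of change of `p1` (0 for a rigid trumpet).
#' @param S_ad_frac fraction of the total cross-section carrying
#'   advection (default 1).
#' @return Velocity (m/s).
#' @export
trumpet_velocity <- function(shape, Q_t, x, dp1_dt = 0, S_ad_frac = 1) {
  S <- trumpet_section(shape, x)
  wall_uptake <- dp1_dt * x^(shape$n1 + 1) / (shape$n1 + 1)
  (Q_t - wall_uptake) / (S_ad_frac * S)
}

#' Numerics configuration
#'
#' @param dt time step (s) for the coupled ventilation + transport loop.
#' @param pipe_dx_max largest transport cell width in pipes (m).
#' @param pipe_min_cells minimum number of cells per pipe.
#' @param trumpet_cells number of transport cells per trumpet lobule.
#' @param trumpet_stretch ratio of distal-most to proximal-most trumpet
#'   cell width (< 1 clusters cells toward the distal end, where the
#'   power-law cross-section varies fastest).
#' @param advection_scheme `"muscl"` (default): explicit flux-limited
#'   (minmod) second-order advection, sub-stepped to keep every face
#'   Courant number below ~0.45, operator-split with implicit diffusion;
#'   strictly bounded and front-sharp at any breathing rate.
#'   `"implicit_upwind"`: one-step theta-implicit first-order upwind
#'   advection combined with the diffusion solve (more diffusive, no
#'   substeps).
#' @param theta_time time-weighting of the implicit (diffusion, or full
#'   transport for `"implicit_upwind"`) step: 0.5 is Crank-Nicolson, 1 is
#'   backward Euler (default; monotone at the stiff Taylor-dispersion
#'   numbers of the large airways).
#' @param taylor_dispersion logical; FALSE forces `Dhat = D`.
#' @param duct_transport logical; if TRUE (default) the axial transport
#'   cross-section inside trumpet lobules is restricted to the airway
#'   (duct) lumping law `S_t kappa_hat^z(x)`, capped by the total
#'   cross-section: the alveolar excess volume holds tracer but carries
#'   no axial flux. FALSE uses the full cross-section (`S_ad = S`).
#' @param newton_tol scaled residual tolerance of the ventilation Newton
#'   iteration.
#' @param newton_maxit maximum Newton iterations per time step.
#' @return A list of class `numerics_config`.
#' @export
numerics_config <- function(dt = 0.005, pipe_dx_max = 2e-3,
                            pipe_min_cells = 6L, trumpet_cells = 60L,
                            trumpet_stretch = 0.1,
                            advection_scheme = c("muscl", "implicit_upwind"),
                            theta_time = 1.0,
                            taylor_dispersion = TRUE, duct_transport = TRUE,
                            newton_tol = 1e-10, newton_maxit = 50L) {
  advection_scheme <- match.arg(advection_scheme)
  stopifnot(dt > 0, pipe_dx_max > 0, pipe_min_cells >= 2,
            trumpet_cells >= 4, trumpet_stretch > 0, trumpet_stretch <= 1,
            theta_time >= 0.5, theta_time <= 1)
  structure(list(dt = dt, pipe_dx_max = pipe_dx_max,
                 pipe_min_cells = as.integer(pipe_min_cells),
                 trumpet_cells = as.integer(trumpet_cells),
                 trumpet_stretch = trumpet_stretch,
                 advection_scheme = advection_scheme,
                 theta_time = theta_time,
                 taylor_dispersion = taylor_dispersion,
                 duct_transport = duct_transport,
                 newton_tol = newton_tol,
                 newton_maxit = as.integer(newton_maxit)),
            class = "numerics_config")
}

# face positions of the trumpet grid: geometrically shrinking cell widths
# toward the distal end (width ratio trumpet_stretch between last and first)
trumpet_faces <- function(l_lb, n_cells, stretch) {
  if (stretch == 1) return(seq(0, l_lb, length.out = n_cells + 1))
  q <- stretch^(1 / (n_cells - 1))
  w <- q^(0:(n_cells - 1))
  c(0, cumsum(w)) / sum(w) * l_lb
}

# face positions of a pipe grid: uniform, >= min_cells, dx <= dx_max
pipe_faces <- function(length, dx_max, min_cells) {
  m <- max(min_cells, ceiling(length / dx_max))
  seq(0, length, length.out = m + 1)
}
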