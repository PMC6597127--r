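# Compiled washout model: packs the fitted lung geometry, mechanics and
# numerics into the C++ stepping core and exposes step-level and run-level
# access from R.

#' Compile a lung model for simulation
#'
#' Builds the discrete representation used by the coupled ventilation +
#' transport solver: per-pipe resistances (Womersley-corrected at the
#' protocol's breathing frequency), transport grids, trumpet face tables
#' and the calibrated lobule mechanics.
#'
#' @param tree a `lung_tree` with fitted lobules (see [build_lung()]);
#'   mechanics are (re)calibrated here from the protocol's tidal volume.
#' @param protocol a [breathing_protocol()].
#' @param numerics a [numerics_config()].
#' @param gas a [gas_config()].
#' @param p_TV reference pleural pressure amplitude (Pa) for the
#'   compliance calibration.
#' @return An object of class `mbw_model` holding the external pointer to
#'   the solver state plus the R-side metadata. The initial state is the
#'   end-expiratory reference: `V_lb = V0`, zero flows, `p_pl = 0`,
#'   normalized tracer concentration 1 everywhere.
#' @export
mbw_model <- function(tree, protocol = breathing_protocol(),
                      numerics = numerics_config(), gas = gas_config(),
                      p_TV = 1500) {
  stopifnot(inherits(tree, "lung_tree"), !is.null(tree$lobules$p1))
  tree <- calibrate_mechanics(tree, TV = protocol$TV, p_TV = p_TV)
  p <- tree$pipes
  lb <- tree$lobules
  np <- nrow(p); nlb <- nrow(lb)
  # per-pipe resistance with Womersley correction at the breath frequency
  R_pipe <- vapply(seq_len(np), function(i)
    pipe_resistance(p$diameter[i], p$length[i], protocol$T_B, gas), numeric(1))
  ncells <- vapply(p$length, function(l)
    length(pipe_faces(l, numerics$pipe_dx_max, numerics$pipe_min_cells)) - 1L,
    numeric(1))
  term_lobule <- rep(-1L, np)
  term_lobule[lb$id] <- seq_len(nlb) - 1L
  # trumpet face tables
  nf <- numerics$trumpet_cells + 1L
  tf <- matrix(0, nf, nlb)
  dloc <- matrix(0, nf, nlb)
  sduct <- matrix(0, nf, nlb)
  for (k in seq_len(nlb)) {
    xf <- trumpet_faces(lb$l_lb[k], numerics$trumpet_cells,
                        numerics$trumpet_stretch)
    tf[, k] <- xf
    # homothety series => airway diameter tapers linearly with cumulative
    # length: d(x) = d_t (1 - x (1-kappa)/(kappa l_t)), and the lumped
    # airway (duct) cross-section follows S_t * (2 kappa^2)^z(x)
    a <- pmax(1e-12, 1 - xf * (1 - lb$kappa[k]) / (lb$kappa[k] * lb$l_t[k]))
    dloc[, k] <- lb$d_t[k] * a
    sduct[, k] <- lb$S_t[k] *
      a^(log(2 * lb$kappa[k]^2) / log(lb$kappa[k]))
  }
  spec <- list(
    parent = as.integer(ifelse(is.na(p$parent), -1L, p$parent - 1L)),
    term_lobule = term_lobule,
    ncell = as.integer(ncells),
    lob_pipe = as.integer(lb$id - 1L),
    R_pipe = R_pipe,
    S_pipe = pi * (p$diameter / 2)^2,
    d_pipe = p$diameter,
    len_pipe = p$length,
    V0 = lb$V0, gamma = lb$gamma, pel_coef = lb$pel_coef, R_eff = lb$R_eff,
    S_t = lb$S_t, l_lb = lb$l_lb, p2 = lb$p2, p1 = lb$p1,
    n1 = lb$n1[1], n2 = lb$n2[1],
    trumpet_faces = tf,
    trumpet_face_diam = as.numeric(dloc),
    trumpet_face_duct = as.numeric(sduct),
    duct_transport = numerics$duct_transport,
    advection_scheme = if (numerics$advection_scheme == "muscl") 0L else 1L,
    mu = gas$mu, rho = gas$rho, D = gas$D,
    taylor = numerics$taylor_dispersion,
    theta = numerics$theta_time,
    newton_tol = numerics$newton_tol,
    newton_maxit = numerics$newton_maxit,
    q_scale = max(pi * protocol$TV * 1e-3 / protocol$T_B, 1e-9)
  )
  structure(list(ptr = ml_create(spec), tree = tree, protocol = protocol,
                 numerics = numerics, gas = gas, spec = spec),
            class = "mbw_model")
}

#' Current state of a compiled model
#'
#' @param model an `mbw_model`.
#' @return List with time, pleural pressure, lobule volumes `V_lb` (m^3),
#'   per-step lobule volume increments `dV_lb`, pipe flows (m^3/s),
#'   concentration fields, the tracheal concentration `c_mouth`, the total
#'   tracer mass and the cumulative tracer flux through the mouth.
#' @export
model_state <- function(model) {
  stopifnot(inherits(model, "mbw_model"))
  ml_state(model$ptr)
}

#' Advance the ventilation model by one implicit time step
#'
#' Solves the lumped-parameter DAE for the new lobule volumes and the
#' pleural pressure such that the summed lobule inflow matches the
#' prescribed tracheal flow; node-wise flow balance holds by construction
#' of the tree assembly.
#'
#' @param model an `mbw_model`.
#' @param Q_in tracheal flow (m^3/s, positive = inspiration) at the end
#'   of the step.
#' @param dt time step (s); defaults to the model's configured dt.
#' @return The model (invisibly); the internal state is advanced. The
#'   Newton iteration count is attached as attribute `iterations`.
#' @export
step_ventilation <- function(model, Q_in, dt = model$numerics$dt) {
  it <- ml_vent_step(model$ptr, Q_in, dt)
  if (it < 0)
    stop("ventilation step failed to converge; try a smaller dt",
         call. = FALSE)
  structure(invisible(model), iterations = it)
}

#' Advance the tracer concentration field by one transport step
#'
#' Must follow a [step_ventilation()] call with the same `dt`: the face
#' flows of the transport step are derived from the discrete lobule
#' volume changes of that ventilation step, which makes the scheme
#' exactly conservative and constant-preserving.
#'
#' @param model an `mbw_model`.
#' @param Q_in the tracheal flow used for the matching ventilation step
#'   (sets the mouth boundary condition: fresh-gas Dirichlet during
#'   inspiration, advective outflow otherwise).
#' @param dt time step (s).
#' @return The model (invisibly).
#' @export
advance_concentration <- function(model, Q_in, dt = model$numerics$dt) {
  ml_transport_step(model$ptr, dt, Q_in)
  invisible(model)
}

#' Tracheal tracer concentration of a model state
#'
#' @param model an `mbw_model`.
#' @return Normalized concentration at the proximal end of the trachea.
#' @export
tracheal_concentration <- function(model) {
  ml_state(model$ptr)$c_mouth
}

#' Overwrite the tracer concentration field
#'
#' @param model an `mbw_model`.
#' @param value scalar (applied everywhere, junctions included) or a list
#'   with elements `conc` and `conc_junction` of matching lengths.
#' @export
set_concentration <- function(model, value) {
  st <- ml_state(model$ptr)
  if (is.numeric(value) && length(value) == 1) {
    ml_set_concentration(model$ptr, rep(value, length(st$conc)),
                         rep(value, length(st$conc_junction)))
  } else {
    ml_set_concentration(model$ptr, value$conc, value$conc_junction)
  }
  invisible(model)
}

#' @export
print.mbw_model <- function(x, ...) {
  st <- ml_state(x$ptr)
  cat(sprintf(
    "<mbw_model> %d pipes + %d lobules, %d transport cells, t = %.3f s\n",
    nrow(x$tree$pipes), nrow(x$tree$lobules), length(st$conc), st$t))
  invisible(x)
}
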