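# Lumped-parameter ventilation: Womersley-corrected pipe resistances,
# nonlinear lobule mechanics (exponential pressure-volume law) and the
# calibration of its shape parameters beta and gamma.

#' Gas properties
#'
#' @param mu dynamic viscosity of the carrier gas (Pa s).
#' @param rho density (kg/m^3).
#' @param D molecular diffusivity of the tracer in the carrier gas (m^2/s);
#'   default is N2 in O2.
#' @return A list of class `gas_config`.
#' @export
gas_config <- function(mu = 1.8e-5, rho = 1.2, D = 2.2e-5) {
  stopifnot(mu > 0, rho > 0, D > 0)
  structure(list(mu = mu, rho = rho, D = D), class = "gas_config")
}

#' Breathing protocol
#'
#' @param TV tidal volume (L).
#' @param T_B breath period (s).
#' @param waveform `"sinusoidal"` or `"tabulated"`.
#' @param n_breaths number of simulated breaths.
#' @param flow_table for `"tabulated"`: a two-column data.frame
#'   (time_s, flow_L_per_s, positive = inspiration) or a file path
#'   readable by [read_flow_table()].
#' @return A list of class `breathing_protocol` carrying `Q_in`, a
#'   function of time returning tracheal flow in m^3/s.
#' @export
breathing_protocol <- function(TV = 0.5, T_B = 3.2,
                               waveform = c("sinusoidal", "tabulated"),
                               n_breaths = 50L, flow_table = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(TV > 0, T_B > 0, n_breaths >= 1)
  if (waveform == "sinusoidal") {
    peak <- pi * TV / T_B * 1e-3           # m^3/s
    Q_in <- function(t) peak * sin(2 * pi * t / T_B)
    duration <- n_breaths * T_B
  } else {
    if (is.character(flow_table)) flow_table <- read_flow_table(flow_table)
    stopifnot(is.data.frame(flow_table), ncol(flow_table) >= 2)
    tt <- flow_table[[1]]; qq <- flow_table[[2]] * 1e-3
    Q_in <- function(t) stats::approx(tt, qq, xout = t, rule = 2)$y
    duration <- max(tt)
  }
  structure(list(TV = TV, T_B = T_B, waveform = waveform,
                 n_breaths = as.integer(n_breaths), Q_in = Q_in,
                 duration = duration, flow_table = flow_table),
            class = "breathing_protocol")
}

#' Read a tabulated tracheal flow profile
#'
#' Two-column whitespace- or comma-separated text (time_s, flow_L_per_s,
#' positive = inspiration). Lines starting with `#` are ignored.
#'
#' @param file path.
#' @return data.frame with columns `time_s`, `flow_L_per_s`.
#' @export
read_flow_table <- function(file) {
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           sep = "", fill = TRUE)
  if (ncol(tab) == 1)
    tab <- utils::read.table(file, header = FALSE, comment.char = "#", sep = ",")
  tab <- tab[, 1:2]
  names(tab) <- c("time_s", "flow_L_per_s")
  tab
}

# Kelvin functions ber, bei and derivatives by power series; the relevant
# Womersley numbers in tidal breathing stay below ~5, where the series is
# numerically benign.
kelvin_ber_bei <- function(x) {
  x2 <- (x / 2)^2
  ber <- 1; bei <- x2; berp <- 0; beip <- x / 2
  term_b <- 1; term_e <- x2
  for (k in 1:40) {
    # ber: sum (-1)^k (x/2)^{4k} / ((2k)!)^2
    term_b <- term_b * x2 * x2 / ((2 * k - 1)^2 * (2 * k)^2)
    ber <- ber + (-1)^k * term_b
    berp <- berp + (-1)^k * term_b * (4 * k) / x
    # bei: sum (-1)^k (x/2)^{4k+2} / ((2k+1)!)^2
    term_e <- term_e * x2 * x2 / ((2 * k)^2 * (2 * k + 1)^2)
    bei <- bei + (-1)^k * term_e
    beip <- beip + (-1)^k * term_e * (4 * k + 2) / x
  }
  list(ber = ber, bei = bei, berp = berp, beip = beip)
}

#' Womersley correction factor for oscillatory pipe flow resistance
#'
#' Ratio of the in-phase (resistive) part of the oscillatory flow
#' impedance of a rigid tube to its steady Poiseuille resistance,
#' evaluated at Womersley number `Wo = (d/2) sqrt(omega rho / mu)`.
#' Tends to 1 as `Wo -> 0` and grows monotonically; inertial effects
#' matter only in the first few airway generations during tidal breathing.
#'
#' @param Wo Womersley number(s), >= 0.
#' @return Correction factor(s) c(Wo) >= 1.
#' @export
womersley_factor <- function(Wo) {
  vapply(Wo, function(w) {
    if (w < 1e-4) return(1)
    k <- kelvin_ber_bei(w)
    J0 <- complex(real = k$ber, imaginary = k$bei)       # J0(i^{3/2} w)
    # J1(Lambda) = -J0'(Lambda) with dJ0/dw = J0'(Lambda) i^{3/2}
    i32 <- complex(real = -sqrt(0.5), imaginary = sqrt(0.5))  # i^{3/2}
    J1 <- -complex(real = k$berp, imaginary = k$beip) / i32
    Lam <- i32 * w
    Fw <- 2 * J1 / (Lam * J0)
    # per-length impedance: Z = i omega rho / (A (1 - F)); Poiseuille:
    # 8 mu / (pi r^4) = 8 mu / (A r^2); ratio uses w^2 = r^2 omega rho/mu
    z_norm <- complex(real = 0, imaginary = 1) * w^2 / (8 * (1 - Fw))
    max(1, Re(z_norm))
  }, numeric(1))
}

#' Hydrodynamic resistance of a conducting-airway pipe
#'
#' Poiseuille resistance `128 mu l / (pi d^4)` multiplied by the
#' Womersley correction at the breathing frequency `omega = 2 pi / T_B`.
#'
#' @param diameter pipe diameter (m).
#' @param length pipe length (m).
#' @param T_B breath period (s).
#' @param gas a [gas_config()].
#' @return Resistance (Pa s / m^3).
#' @export
pipe_resistance <- function(diameter, length, T_B = 3.2, gas = gas_config()) {
  stopifnot(diameter > 0, length > 0, T_B > 0)
  omega <- 2 * pi / T_B
  Wo <- (diameter / 2) * sqrt(omega * gas$rho / gas$mu)
  128 * gas$mu * length / (pi * diameter^4) * womersley_factor(Wo)
}

#' Lumped flow resistance of a trumpet lobule
#'
#' Series sum of per-generation Poiseuille resistances of the airways
#' lumped in the trumpet: generation z holds `2^z` parallel tubes of
#' diameter `d_t kappa^z` and length `l_t kappa^z`, summed from z = 1
#' down to the generation where diameters reach the floor diameter.
#'
#' @param d_t terminal-pipe diameter (m).
#' @param l_t terminal-pipe length (m).
#' @param config a [lobule_config()].
#' @param gas a [gas_config()].
#' @return Resistance (Pa s / m^3).
#' @export
lobule_resistance <- function(d_t, l_t, config = lobule_config(),
                              gas = gas_config()) {
  kappa <- config$kappa
  z_max <- max(1L, floor(log(config$d_floor_mm * 1e-3 / d_t) / log(kappa)))
  z <- seq_len(z_max)
  R0 <- 128 * gas$mu * l_t / (pi * d_t^4)
  sum(R0 * (kappa^(-3) / 2)^z)
}

#' Elastic recoil pressure of a lobule
#'
#' Exponential pressure-volume law `p_el = beta e^{gamma V0}
#' (e^{gamma Vtilde} - 1)` with `Vtilde = V - V0` the dynamic volume
#' above the end-expiratory reference. To avoid overflow the product
#' `beta e^{gamma V0}` is carried as a single coefficient.
#'
#' @param V_tilde dynamic volume(s) above V0 (m^3).
#' @param gamma nonlinearity parameter (1/m^3).
#' @param coef the combined coefficient `beta * exp(gamma V0)` (Pa); see
#'   [calibrate_beta()].
#' @return Elastic pressure (Pa).
#' @export
elastic_pressure <- function(V_tilde, gamma, coef) {
  coef * expm1(gamma * V_tilde)
}

#' Calibrate the pressure-scale parameter beta
#'
#' beta is fixed by requiring the elastic curve to pass through the
#' reference point: at the scaled tidal excursion `Vtilde = phi * V_TV`
#' the elastic pressure equals the reference pleural amplitude `p_TV`.
#' Worked in the log domain: the returned list carries both `beta` and
#' the overflow-safe combined coefficient `coef = beta e^{gamma V0}` used
#' by [elastic_pressure()].
#'
#' @param phi compliance modification factor (> 0); phi < 1 stiffens.
#' @param gamma nonlinearity (1/m^3), from [calibrate_gamma()].
#' @param V0 residual lobule volume (m^3).
#' @param V_TV nominal lobule tidal volume (m^3), `TV / N_lb`.
#' @param p_TV reference pressure amplitude (Pa).
#' @return List with `beta` (Pa) and `coef` (Pa).
#' @export
calibrate_beta <- function(phi, gamma, V0, V_TV, p_TV = 1500) {
  stopifnot(phi > 0, gamma > 0, V_TV > 0, p_TV > 0)
  coef <- p_TV / expm1(gamma * phi * V_TV)
  list(beta = exp(log(coef) - gamma * V0), coef = coef)
}

#' Calibrate the nonlinearity parameter gamma
#'
#' gamma is fixed by a quarter-point condition: the elastic curve passes
#' through `(p_TV / 4, V0 + 3/4 phi V_TV)`, i.e.
#' `(e^{3/4 g} - 1)/(e^{g} - 1) = 1/4` in the scaled variable
#' `g = gamma phi V_TV`. The ratio decreases monotonically from 3/4
#' (linear limit) to 0, so the root is unique; it is found by bisection
#' once in `g` and rescaled.
#'
#' @param phi compliance modification factor (> 0).
#' @param V_TV nominal lobule tidal volume (m^3).
#' @param p_TV reference pressure amplitude (Pa); enters only through the
#'   quarter-point construction and drops out of g.
#' @param tol bisection tolerance on the ratio condition.
#' @return gamma (1/m^3).
#' @export
calibrate_gamma <- function(phi, V_TV, p_TV = 1500, tol = 1e-12) {
  stopifnot(phi > 0, V_TV > 0)
  g <- gamma_quarter_root(tol)
  g / (phi * V_TV)
}

# universal root of (e^{3g/4}-1)/(e^g-1) = 1/4, cached per session
gamma_quarter_root <- local({
  cache <- NULL
  function(tol = 1e-12) {
    if (!is.null(cache)) return(cache)
    f <- function(g) expm1(0.75 * g) / expm1(g) - 0.25
    lo <- 1e-8; hi <- 50
    if (f(lo) < 0 || f(hi) > 0) stop("calibration error: bracket failed")
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    cache <<- (lo + hi) / 2
    cache
  }
})

#' Calibrate the mechanics of every lobule in a tree
#'
#' Computes per-lobule `gamma` and the elastic coefficient from each
#' lobule's compliance factor `phi` and the protocol's nominal lobule
#' tidal volume `V_TV = TV / N_lb`. Also applies the resistance factor
#' `tau` to the lumped lobule resistance.
#'
#' @param tree a `lung_tree` with fitted lobules.
#' @param TV tidal volume (L).
#' @param p_TV reference pressure amplitude (Pa).
#' @return The tree with `gamma`, `pel_coef` and `R_eff` lobule columns.
#' @export
calibrate_mechanics <- function(tree, TV = 0.5, p_TV = 1500) {
  stopifnot(inherits(tree, "lung_tree"), !is.null(tree$lobules$p1))
  lb <- tree$lobules
  V_TV <- TV * 1e-3 / nrow(lb)
  g_unit <- gamma_quarter_root()
  lb$gamma <- g_unit / (lb$phi * V_TV)
  lb$pel_coef <- p_TV / expm1(lb$gamma * lb$phi * V_TV)
  lb$R_eff <- lb$tau * lb$R_lb
  tree$lobules <- lb
  tree$mechanics <- list(TV = TV, p_TV = p_TV, V_TV = V_TV)
  tree
}
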