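# End-to-end orchestration: configuration, the simulate -> analyze
# pipeline, and the named experiment suite.

#' Full simulation configuration
#'
#' Defaults reproduce the baseline whole-lung setup: FRC 3.0 L, limit
#' diameter 1.8 mm, sinusoidal tracheal flow with TV 0.5 L and breath
#' period 3.2 s, 50 breaths.
#'
#' @param morphology a [morphology_config()].
#' @param protocol a [breathing_protocol()].
#' @param lobule a [lobule_config()].
#' @param numerics a [numerics_config()].
#' @param gas a [gas_config()].
#' @param perturbations list of perturbation entries, each a list with
#'   `mode` ("regional"/"local"), `parameter` ("phi"/"theta"/"tau"),
#'   `fraction` and `value`; entries sharing a mode are resolved together
#'   (regional entries become successive contiguous blocks, local entries
#'   interleave).
#' @param p_TV reference pleural pressure amplitude (Pa).
#' @param seed integer, reserved for protocols with random components
#'   (the pipeline itself is deterministic).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(morphology = morphology_config(),
                              protocol = breathing_protocol(),
                              lobule = lobule_config(),
                              numerics = numerics_config(),
                              gas = gas_config(),
                              perturbations = list(),
                              p_TV = 1500, seed = 1L) {
  structure(list(morphology = morphology, protocol = protocol,
                 lobule = lobule, numerics = numerics, gas = gas,
                 perturbations = perturbations, p_TV = p_TV,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# group flat perturbation entries into region_spec objects (one per mode)
perturbation_specs <- function(entries) {
  if (length(entries) == 0) return(list())
  modes <- vapply(entries, function(e) e$mode, character(1))
  lapply(unique(modes), function(m) {
    region_spec(m, lapply(entries[modes == m], function(e)
      list(parameter = e$parameter, fraction = e$fraction, value = e$value)))
  })
}

#' Simulate a complete nitrogen washout
#'
#' Builds the lung, applies the configured perturbations, initializes the
#' normalized tracer concentration to 1 everywhere (washout of a resident
#' gas; no washin phase) and advances the coupled ventilation + transport
#' model over the configured breaths. The simulation is deterministic for
#' a fixed configuration.
#'
#' @param config a [simulation_config()].
#' @param tree optionally a pre-built (possibly hand-modified)
#'   `lung_tree`; by default built from the config.
#' @param verbose print per-breath progress.
#' @return List of class `mbw_result`: `trace` (data.frame `time_s`,
#'   `flow_L_per_s`, `concentration`), `summary` ([analyze_washout()]
#'   output), `breaths`, `mass_audit` (per-breath relative tracer-mass
#'   balance error and carrier-volume closure), `lobule_conc_breath` /
#'   `lobule_vol_breath` (per-breath lobule means), and `manifest`.
#' @export
simulate_washout <- function(config = simulation_config(), tree = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(tree)) {
    tree <- build_lung(config$morphology, config$lobule)
    for (spec in perturbation_specs(config$perturbations))
      tree <- apply_perturbations(tree, spec)
  }
  model <- mbw_model(tree, config$protocol, config$numerics, config$gas,
                     p_TV = config$p_TV)
  dt <- config$numerics$dt
  nsteps <- round(config$protocol$duration / dt)
  tgrid <- seq_len(nsteps) * dt
  Qin <- config$protocol$Q_in(tgrid)
  # breath-end step indices (last step before the next inspiratory onset)
  pos <- Qin > 0
  starts <- which(pos[-1] & !pos[-nsteps]) + 1L
  if (pos[1]) starts <- c(1L, starts)
  breath_end <- unique(c(starts[-1] - 1L, nsteps))
  res <- ml_run(model$ptr, Qin, dt, as.integer(breath_end))
  trace <- data.frame(time_s = res$t, flow_L_per_s = Qin * 1e3,
                      concentration = res$c_mouth)
  summary <- analyze_washout(trace, FRC = tree$FRC)
  # audits: initial tracer mass equals the FRC gas volume (c = 1)
  V_frc <- tree$FRC * 1e-3
  mass_err <- (res$tracer_mass - (V_frc + res$cum_mouth_flux)) / V_frc
  nb <- length(breath_end)
  vol_closure <- numeric(nb)
  for (b in seq_len(nb)) {
    s <- breath_end[b]
    expected <- V_frc + sum(Qin[seq_len(s)]) * dt -
      sum(pi * (tree$pipes$diameter / 2)^2 * tree$pipes$length)
    vol_closure[b] <- (sum(res$lobule_vol_breath[b, ]) - expected) /
      (config$protocol$TV * 1e-3)
  }
  audit <- list(mass_balance_rel = mass_err[breath_end],
                carrier_volume_rel = vol_closure,
                max_mass_err = max(abs(mass_err)))
  manifest <- list(
    FRC_L = tree$FRC, TV_L = config$protocol$TV, T_B = config$protocol$T_B,
    n_breaths = config$protocol$n_breaths, dt = dt,
    n_lobules = nrow(tree$lobules), n_pipes = nrow(tree$pipes),
    perturbations = lapply(tree$applied_perturbations, function(s)
      list(mode = s$mode,
           assignments = lapply(seq_along(s$assignments), function(j)
             c(s$assignments[[j]], list(lobule_ids = s$resolved_sets[[j]]))))),
    package_version = as.character(utils::packageVersion("mbwsim")))
  if (verbose)
    message(sprintf("washout: %d breaths, final cet = %.4g, A = %.3f",
                    nb, summary$breaths$end_expiratory_concentration[nb],
                    summary$envelope$A))
  structure(list(trace = trace, summary = summary, breaths = summary$breaths,
                 mass_audit = audit,
                 lobule_conc_breath = res$lobule_conc_breath,
                 lobule_vol_breath = res$lobule_vol_breath,
                 newton_iters = res$newton_iters,
                 manifest = manifest, tree = tree, config = config),
            class = "mbw_result")
}

#' @export
print.mbw_result <- function(x, ...) {
  cat("MBW simulation result\n")
  print(x$summary)
  cat(sprintf("  max |tracer mass balance error| = %.2e (rel. FRC)\n",
              x$mass_audit$max_mass_err))
  invisible(x)
}

#' Run one of the named washout experiments
#'
#' The experiment suite reproduces the canonical perturbation studies:
#' `baseline` (uniform lobules), `regional_compliance` (phi = 0.5 and
#' 1.5 in two contiguous 25% blocks), `regional_volume` (theta = 0.5 on
#' a 25% block, FRC-preserving), `regional_resistance` (tau = 8 on a
#' 25% block), `local_compliance` (phi = 0.5/1.5 alternating over every
#' other lobule) and `healthy_preset` (see [healthy_lung_preset()]).
#'
#' @param name experiment name.
#' @param config base [simulation_config()] (its perturbation block is
#'   replaced by the experiment's).
#' @param verbose print progress.
#' @return The [simulate_washout()] result, with an additional
#'   `outcomes` element: a one-row data.frame (name, A, alpha1, alpha2,
#'   LCI, s_III_first, s_III_last).
#' @export
run_experiment_suite <- function(name = c("baseline", "regional_compliance",
                                          "regional_volume",
                                          "regional_resistance",
                                          "local_compliance",
                                          "healthy_preset"),
                                 config = simulation_config(),
                                 verbose = FALSE) {
  name <- match.arg(name)
  config$perturbations <- switch(
    name,
    baseline = list(),
    regional_compliance = list(
      list(mode = "regional", parameter = "phi", fraction = 0.25, value = 0.5),
      list(mode = "regional", parameter = "phi", fraction = 0.25, value = 1.5)),
    regional_volume = list(
      list(mode = "regional", parameter = "theta", fraction = 0.25, value = 0.5)),
    regional_resistance = list(
      list(mode = "regional", parameter = "tau", fraction = 0.25, value = 8)),
    local_compliance = list(
      list(mode = "local", parameter = "phi", fraction = 0.25, value = 0.5),
      list(mode = "local", parameter = "phi", fraction = 0.25, value = 1.5)),
    healthy_preset = list(
      list(mode = "regional", parameter = "theta", fraction = 0.125, value = 0.5),
      list(mode = "regional", parameter = "theta", fraction = 0.125, value = 0.5),
      list(mode = "regional", parameter = "phi", fraction = 0.125, value = 0.5),
      list(mode = "regional", parameter = "phi", fraction = 0.125, value = 1.5)))
  res <- simulate_washout(config, verbose = verbose)
  e <- res$summary$envelope
  s <- res$breaths$s_III
  res$outcomes <- data.frame(name = name, A = e$A, alpha1 = e$alpha1,
                             alpha2 = e$alpha2, LCI = res$summary$lci,
                             s_III_first = s[1], s_III_last = s[length(s)])
  res
}

#' Write a simulation configuration to a YAML file
#'
#' @param config a [simulation_config()].
#' @param file output path.
#' @export
write_config <- function(config, file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  x <- list(
    morphology = config$morphology[c("FRC", "FRC_W", "d_lim", "r", "eta",
                                     "trachea_elongation",
                                     "residual_allocation")],
    protocol = config$protocol[c("TV", "T_B", "waveform", "n_breaths")],
    lobule = unclass(config$lobule),
    numerics = unclass(config$numerics),
    gas = unclass(config$gas),
    perturbations = config$perturbations,
    p_TV = config$p_TV, seed = config$seed)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a simulation configuration from a YAML file
#'
#' @param file path written by [write_config()] (or hand-edited).
#' @return A [simulation_config()].
#' @export
read_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  x <- yaml::read_yaml(file)
  simulation_config(
    morphology = do.call(morphology_config, x$morphology),
    protocol = do.call(breathing_protocol, x$protocol),
    lobule = do.call(lobule_config, x$lobule),
    numerics = do.call(numerics_config, x$numerics),
    gas = do.call(gas_config, x$gas),
    perturbations = if (is.null(x$perturbations)) list() else x$perturbations,
    p_TV = if (is.null(x$p_TV)) 1500 else x$p_TV,
    seed = if (is.null(x$seed)) 1L else x$seed)
}

#' Write the run manifest of a result
#'
#' @param result an `mbw_result`.
#' @param file output path (YAML).
#' @export
write_manifest <- function(result, file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for manifests", call. = FALSE)
  yaml::write_yaml(result$manifest, file)
  invisible(file)
}

#' Write the simulated MBW trace
#'
#' @param result an `mbw_result`.
#' @param file output path (tab-separated: time_s, flow_L_per_s,
#'   concentration).
#' @export
write_trace <- function(result, file) {
  utils::write.table(result$trace, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
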