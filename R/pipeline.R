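# End-to-end pipeline: parameters -> unit-cell upscaling -> chamber fluid
# solve -> drug transport -> cell-kill dynamics, with a JSON-configurable
# entry point and serialisable summary.

# tiny FNV-1a hash for provenance stamping (no cryptographic intent)
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

.default_config <- function() {
  list(
    parameters = list(),
    geometry = list(),
    mesh = list(n_theta = 48, n_inner = 8, n_outer = 12),
    region1_network = "hexagonal",
    network_radius_factor = 0.1,
    P_region1 = NULL,
    sweep = list(log10_min = -16, log10_max = -10.5, n = 15),
    run_sweep = TRUE,
    run_treatment = TRUE,
    treatment = list(K_values = c(1 / 29, 1 / 31, 1 / 33), t_end_h = 712),
    seed = 1L
  )
}

#' Load and validate a pipeline run configuration
#'
#' @param config A list, or path to a JSON file. Unknown keys are rejected;
#'   omitted keys take defaults. The parameter block is validated through
#'   [model_parameters()] (so e.g. a configuration with d >= s is rejected
#'   at load).
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(def, config)
  # validate parameter overrides now (fail at load, not mid-run)
  do.call(model_parameters, cfg$parameters)
  structure(cfg, class = "run_config")
}

#' Run the full chamber pipeline
#'
#' Executes the model end to end: dimensionless bookkeeping, unit-cell
#' permeability upscaling for the region-1 capillary network, the coupled
#' chamber pressure solve and interface fluxes (optionally a P sweep), the
#' plasma pharmacokinetic fit, drug transport under both dosing regimes,
#' and the interstitial volume-fraction outcome with second-dose timing.
#' Deterministic given the configuration.
#'
#' @param config A list or JSON path accepted by [load_config()].
#' @param out_dir Optional output directory: writes `summary.json`,
#'   `sweep.csv`, `phi_av.csv` and `concentrations.csv`.
#' @return Object of class `pipeline_result`; its `summary` element is a
#'   plain list serialisable to JSON.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_config(config)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  params <- stage("parameters", do.call(model_parameters, cfg$parameters))
  groups <- dimensionless_groups(params)
  cell <- stage("unitcell", make_fixture_network(
    cfg$region1_network, d = params$d,
    radius = cfg$network_radius_factor * params$d))
  K1 <- stage("unitcell", network_permeability(cell, params$mu))
  k1 <- mean(diag(unclass(K1)))
  P1 <- if (is.null(cfg$P_region1)) compose_P(k1, params$d, params$L, params$s) else cfg$P_region1
  geo <- stage("geometry", do.call(build_geometry, c(list(params = params), cfg$geometry)))
  mesh <- stage("mesh", do.call(mesh_chamber, c(list(geometry = geo), cfg$mesh)))
  fluid <- stage("fluid", solve_pressures(mesh, params, P_region1 = P1))
  fluxes <- interface_fluxes(fluid)
  sweep <- NULL
  if (isTRUE(cfg$run_sweep)) {
    Ps <- 10^seq(cfg$sweep$log10_min, cfg$sweep$log10_max, length.out = cfg$sweep$n)
    sweep <- stage("sweep", sweep_P(mesh, params, Ps))
  }
  pk <- stage("pk", pk_fit())
  comparison <- NULL
  phi_inj <- NULL
  dose2 <- NULL
  if (isTRUE(cfg$run_treatment)) {
    comparison <- stage("treatment", compare_treatments(
      fluid, K_values = cfg$treatment$K_values, t_end_h = cfg$treatment$t_end_h))
    nt1 <- n_t_from_ratio(volume_ratio(cell)$Vt_over_Vc)
    phi_inj <- evolve_phi(comparison$injection_state,
                          kill_parameters(K = 1 / 31), phi0 = nt1)
    dose2 <- second_dose_time(phi_inj)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("tumourperf")),
    config_hash = .config_hash(unclass(cfg)),
    dimensionless = list(nu = groups$nu, eta = groups$eta, Re = groups$Re,
                         kappa = groups$kappa, R = groups$R,
                         Vstar = groups$Vstar, Peclet = groups$Peclet),
    P = list(region1 = P1, region2 = fluid$P_region2,
             region1_network = cfg$region1_network,
             k_region1_m2 = k1),
    fluxes = list(Q_c_um2_s = fluxes$Q_c * 1e12, Q_t_um2_s = fluxes$Q_t * 1e12,
                  Qt_over_Qc = fluxes$ratio),
    sweep = if (!is.null(sweep)) list(P_opt = sweep$P_opt,
                                      Q_c_opt_um2_s = sweep$Q_c_opt * 1e12,
                                      P_signchange = sweep$P_signchange),
    pk = list(amplitudes = as.list(coef(pk)), rates_per_min = pk$rates,
              dose_nM = pk$dose),
    treatment = if (!is.null(comparison)) list(
      table = comparison$summary,
      second_dose = dose2)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(sweep)) {
      utils::write.csv(sweep$curve, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
    }
    if (!is.null(comparison)) {
      utils::write.csv(comparison$summary, file.path(out_dir, "treatment.csv"),
                       row.names = FALSE)
      pv <- data.frame(t_h = phi_inj$times_h, phi_av_injection = phi_inj$phi_av)
      utils::write.csv(pv, file.path(out_dir, "phi_av.csv"), row.names = FALSE)
      conc <- data.frame(
        t_h = comparison$injection_state$times_h,
        c_a = average_concentration(comparison$injection_state, "region1", "c_a"),
        c_v = average_concentration(comparison$injection_state, "region1", "c_v"),
        c_c = average_concentration(comparison$injection_state, "region1", "c_c"))
      utils::write.csv(conc, file.path(out_dir, "concentrations.csv"),
                       row.names = FALSE)
    }
  }
  res <- list(summary = summary, params = params, fluid = fluid,
              sweep = sweep, pk = pk, comparison = comparison,
              phi_injection = phi_inj,
              elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("tumourperf pipeline result (config", s$config_hash, ")\n")
  cat(sprintf("  nu=%.3g eta=%.3g Re=%.3g V*=%.3g Pe=%.3g\n",
              s$dimensionless$nu, s$dimensionless$eta, s$dimensionless$Re,
              s$dimensionless$Vstar, s$dimensionless$Peclet))
  cat(sprintf("  P1 = %.3g m2 (%s network), P2 = %.3g m2\n",
              s$P$region1, s$P$region1_network, s$P$region2))
  cat(sprintf("  Q_c = %.4g um2/s, Q_t = %.4g um2/s\n",
              s$fluxes$Q_c_um2_s, s$fluxes$Q_t_um2_s))
  if (!is.null(s$sweep)) {
    cat(sprintf("  sweep: Q_c max %.4g um2/s at P ~ %.3g m2\n",
                s$sweep$Q_c_opt_um2_s, s$sweep$P_opt))
  }
  cat(sprintf("  PK amplitudes (nM): %s\n",
              paste(sprintf("%.0f", unlist(s$pk$amplitudes)), collapse = ", ")))
  if (!is.null(s$treatment)) {
    tb <- s$treatment$table
    cat(sprintf("  treatment winner(s): %s; second-dose minimum %s\n",
                paste(unique(tb$winner), collapse = "/"),
                if (s$treatment$second_dose$interior)
                  sprintf("at %.3g days", s$treatment$second_dose$t_min_h / 24)
                else "on the boundary (monotone phi_av)"))
  }
  cat(sprintf("  elapsed %.1f s\n", x$elapsed_s))
  invisible(x)
}
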