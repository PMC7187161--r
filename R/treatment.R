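# Cell-kill dynamics and treatment comparison.
#
# Drug exposure is converted to cell kill through a saturating
# (Michaelis-Menten) kill-rate law M(c) = rho1 * c / (rho2 + c). The
# interstitial volume fraction phi evolves pointwise by net proliferation
# minus kill,
#   d phi / dt = (K - M(c_c(x, t))) * phi,
# an exponential-form linear ODE integrated exactly per stored-output
# interval with c interpolated linearly in time (the integral of M along a
# linear segment has a closed form). The treatment outcome metric is the
# area-averaged phi over the tumour region.

#' Parameters of the kill-rate law and proliferation
#'
#' @param rho1 Maximal kill rate (h^-1). Default 1/24.
#' @param rho2 Half-maximal concentration (nM). Default 2.
#' @param K Net cell proliferation rate (h^-1). Default 1/31.
#' @return List of class `kill_parameters`.
#' @export
kill_parameters <- function(rho1 = 1 / 24, rho2 = 2, K = 1 / 31) {
  .check_positive(rho1, rho2, K)
  structure(list(rho1 = rho1, rho2 = rho2, K = K), class = "kill_parameters")
}

#' Saturating cell-kill rate
#'
#' M(c) = rho1 * c / (rho2 + c): proportional to concentration at low dose,
#' saturating at the maximal rate rho1; the half-maximal rate is reached at
#' c = rho2.
#'
#' @param c Drug concentration (nM), >= 0.
#' @param kill_params A [kill_parameters()] object.
#' @return Kill rate (h^-1).
#' @export
kill_rate <- function(c, kill_params = kill_parameters()) {
  if (any(c < 0)) stop("negative concentration", call. = FALSE)
  kill_params$rho1 * c / (kill_params$rho2 + c)
}

# exact integral of M(c(t)) over [0, dt] with c linear from c0 to c1
.int_kill <- function(c0, c1, dt, rho1, rho2) {
  slope <- (c1 - c0) / dt
  flat <- abs(c1 - c0) <= 1e-12 * pmax(c0, c1, 1e-300)
  out <- numeric(length(c0))
  cm <- (c0 + c1) / 2
  out[flat] <- rho1 * cm[flat] / (rho2 + cm[flat]) * dt
  i <- !flat
  out[i] <- rho1 * (dt - (rho2 / slope[i]) * log((rho2 + c1[i]) / (rho2 + c0[i])))
  out
}

#' Evolve the interstitial volume fraction under drug exposure
#'
#' Integrates d phi/dt = (K - M(c_c)) phi pointwise on the mesh nodes of a
#' drug state, with phi(x, 0) = phi0 (a scalar - typically the interstitial
#' volume fraction n_t of the region-1 unit-cell network - or a nodal
#' field), and accumulates the region-1 area average phi_av(t).
#'
#' @param drug_state A `drug_state` from [solve_drug()], or a list with
#'   `times_h` and a `c_c` matrix for prescribed exposure.
#' @param kill_params A [kill_parameters()] object.
#' @param phi0 Initial interstitial volume fraction (scalar or nodal
#'   vector). Default 0.8.
#' @param mesh Optional mesh when `drug_state` is a bare exposure list.
#' @return Object of class `volume_fraction`: `times_h`, `phi_av`, and the
#'   final nodal field `phi_final`.
#' @export
evolve_phi <- function(drug_state, kill_params = kill_parameters(), phi0 = 0.8,
                       mesh = NULL) {
  if (inherits(drug_state, "drug_state")) mesh <- drug_state$mesh
  if (is.null(mesh)) stop("mesh required when drug_state is a bare exposure", call. = FALSE)
  times <- drug_state$times_h
  cc <- drug_state$c_c
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1)
  nt <- length(times)
  if (nt < 2 || ncol(cc) != nt) stop("time grid mismatch between exposure and times",
                                     call. = FALSE)
  nn <- nrow(cc)
  phi <- rep_len(if (length(phi0) == 1) phi0 else phi0, nn)
  if (length(phi0) != 1 && length(phi0) != nn) {
    stop("phi0 must be scalar or one value per node", call. = FALSE)
  }
  w <- mesh$lump_region1
  if (nn == nrow(mesh$nodes)) wts <- w / sum(w) else wts <- rep(1 / nn, nn)
  phi_av <- numeric(nt)
  phi_av[1] <- sum(wts * phi)
  K <- kill_params$K
  for (k in 2:nt) {
    dt <- times[k] - times[k - 1]
    intM <- .int_kill(cc[, k - 1], cc[, k], dt, kill_params$rho1, kill_params$rho2)
    phi <- phi * exp(K * dt - intM)
    phi_av[k] <- sum(wts * phi)
  }
  structure(list(times_h = times, phi_av = phi_av, phi_final = phi,
                 kill_params = kill_params, phi0 = phi0),
            class = "volume_fraction")
}

#' @export
print.volume_fraction <- function(x, ...) {
  m <- second_dose_time(x)
  cat(sprintf("Interstitial volume fraction: phi_av %.4g -> %.4g over %.3g h\n",
              x$phi_av[1], x$phi_av[length(x$phi_av)], max(x$times_h)))
  if (m$interior) {
    cat(sprintf("  interior minimum %.4g at t = %.4g h (%.2f days)\n",
                m$phi_min, m$t_min_h, m$t_min_h / 24))
  } else {
    cat(sprintf("  no interior minimum (boundary minimum at t = %.4g h)\n", m$t_min_h))
  }
  invisible(x)
}

#' @export
plot.volume_fraction <- function(x, ...) {
  graphics::plot(x$times_h / 24, x$phi_av, type = "l", xlab = "time (days)",
                 ylab = expression(phi^av), ...)
  invisible(x)
}

#' Optimal second-dose time from the phi_av series
#'
#' The candidate time for a second dose is the global minimum of phi_av
#' (ties resolve to the earliest time). A minimum attained at either end of
#' the series is flagged as a boundary minimum ("no interior minimum").
#'
#' @param phi A `volume_fraction` object, or a list with `times_h` and
#'   `phi_av`.
#' @return List: `t_min_h`, `phi_min`, `interior` (logical).
#' @export
second_dose_time <- function(phi) {
  t <- phi$times_h; v <- phi$phi_av
  if (!length(v)) stop("empty series", call. = FALSE)
  i <- which(v == min(v))[1]
  list(t_min_h = t[i], phi_min = v[i],
       interior = i > 1 && i < length(v))
}

#' Compare injection and constant-perfusion treatment
#'
#' Runs the drug transport problem under both dosing regimes on the same
#' frozen fluid solution, evolves the interstitial volume fraction for each
#' proliferation rate and each supplied initial condition, and reports the
#' final phi_av values and the more effective regime (smaller final
#' phi_av).
#'
#' @param fluid A `chamber_fluid` solution.
#' @param K_values Proliferation rates (h^-1). Default 1/29, 1/31, 1/33.
#' @param n_t Named vector of initial interstitial volume fractions (one
#'   run per value). Default derives from the tabulated network volume
#'   ratios via [n_t_from_ratio()].
#' @param t_end_h Horizon (h), shared by both regimes. Default 712.
#' @param injection A `pk_model`. Default [pk_fit()].
#' @param perfusion A `perfusion_schedule`. Default 8 nM for 120 h.
#' @param drug_params Optional [drug_parameters()].
#' @return Object of class `treatment_comparison`: data frame `summary`
#'   (K, n_t, final phi_av per regime, winner) and the two drug states.
#' @export
compare_treatments <- function(fluid, K_values = c(1 / 29, 1 / 31, 1 / 33),
                               n_t = n_t_from_ratio(table2_volume_ratios()),
                               t_end_h = 712,
                               injection = pk_fit(),
                               perfusion = perfusion_schedule(),
                               drug_params = NULL) {
  stopifnot(inherits(fluid, "chamber_fluid"))
  ds_inj <- solve_drug(fluid, injection, drug_params, t_end_h = t_end_h)
  ds_per <- solve_drug(fluid, perfusion, drug_params, t_end_h = t_end_h)
  rows <- list()
  for (K in K_values) {
    kp <- kill_parameters(K = K)
    for (nm in names(n_t)) {
      fi <- evolve_phi(ds_inj, kp, phi0 = n_t[[nm]])
      fp <- evolve_phi(ds_per, kp, phi0 = n_t[[nm]])
      vi <- fi$phi_av[length(fi$phi_av)]
      vp <- fp$phi_av[length(fp$phi_av)]
      rows[[length(rows) + 1L]] <- data.frame(
        K_per_h = K, network = nm, n_t = n_t[[nm]],
        phi_final_injection = vi, phi_final_perfusion = vp,
        winner = if (vi < vp) "injection" else if (vp < vi) "perfusion" else "tie")
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 injection_state = ds_inj, perfusion_state = ds_per),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  s <- x$summary
  cat("Treatment comparison (final phi_av, smaller is better)\n")
  for (K in unique(s$K_per_h)) {
    sk <- s[s$K_per_h == K, ]
    cat(sprintf("  K = 1/%.0f h^-1: injection [%.4g, %.4g], perfusion [%.4g, %.4g], winner: %s\n",
                1 / K, min(sk$phi_final_injection), max(sk$phi_final_injection),
                min(sk$phi_final_perfusion), max(sk$phi_final_perfusion),
                paste(unique(sk$winner), collapse = "/")))
  }
  invisible(x)
}
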