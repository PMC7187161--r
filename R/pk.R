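# Vinblastine plasma pharmacokinetics.
#
# After an intravenous bolus the plasma concentration decays in four phases
# (rapid whole-body distribution followed by three progressively slower
# redistribution/metabolism phases), modelled as a sum of four exponentials
#   sigma(t) = A e^{-k1 t} + B e^{-k2 t} + C e^{-k3 t} + D e^{-k4 t}.
# The amplitudes are determined from the initial dose and three later-time
# concentration conditions by solving the 4x4 linear system exactly.
# Constant perfusion is a piecewise-constant schedule.

#' Phase rate constants from half-lives
#'
#' k = ln(2) / t_half, returned in min^-1.
#'
#' @param halflives Numeric vector of half-lives.
#' @param units Units of `halflives`: `"min"` (default) or `"s"`.
#' @return Rates in min^-1, sorted decreasing if the input half-lives are
#'   sorted increasing.
#' @examples
#' rates_from_halflives(c(1/60, 4, 53, 1173))  # ~ (41.6, 0.17, 0.013, 5.9e-4)
#' @export
rates_from_halflives <- function(halflives, units = c("min", "s")) {
  units <- match.arg(units)
  if (any(halflives <= 0)) stop("half-lives must be positive", call. = FALSE)
  t_min <- if (units == "s") halflives / 60 else halflives
  log(2) / t_min
}

#' Printed four-phase decay rates (min^-1)
#'
#' The reported rate constants of the four metabolism phases. These are
#' consistent with half-lives of 1 s, 4 min, 53 min and 1173 min
#' (`rates_from_halflives(c(1/60, 4, 53, 1173))` reproduces them to the
#' printed precision).
#' @return Numeric vector (k1, k2, k3, k4) in min^-1.
#' @export
vinblastine_rates <- function() c(41.6, 0.17, 1.3e-2, 5.9e-4)

#' Fit the four-exponential amplitudes
#'
#' Solves the linear system sigma(0) = dose, sigma(t_i) = c_i for the three
#' conditions, in the amplitudes (A, B, C, D). The first equation forces
#' A + B + C + D = dose exactly.
#'
#' @param dose Initial dose (nM).
#' @param conditions Two-column matrix or data frame `(time_min, conc_nM)`
#'   with exactly `length(rates) - 1` rows.
#' @param rates Phase rates (min^-1), strictly decreasing and distinct.
#' @return Named numeric vector of amplitudes (nM) with attributes
#'   `residual` (solution residual norm) and `condition_number`.
#' @export
fit_amplitudes <- function(dose = 2700,
                           conditions = cbind(c(4, 53, 1173), c(700, 150, 10)),
                           rates = vinblastine_rates()) {
  .check_positive(dose, .names = "dose")
  conditions <- as.matrix(conditions)
  if (nrow(conditions) != length(rates) - 1) {
    stop("need exactly ", length(rates) - 1, " conditions for ", length(rates),
         " rates (plus the initial dose)", call. = FALSE)
  }
  if (any(diff(rates) >= 0)) stop("rates must be strictly decreasing", call. = FALSE)
  t <- c(0, conditions[, 1]); rhs <- c(dose, conditions[, 2])
  M <- exp(-outer(t, rates))
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    stop("ill-conditioned amplitude system (condition number ", format(cn), ")",
         call. = FALSE)
  }
  amp <- solve(M, rhs)
  names(amp) <- if (length(amp) == 4) c("A", "B", "C", "D") else
    paste0("A", seq_along(amp))
  attr(amp, "residual") <- max(abs(M %*% amp - rhs))
  attr(amp, "condition_number") <- cn
  amp
}

#' Fit an injection pharmacokinetic model
#'
#' Fitting-function interface around [fit_amplitudes()]: returns a classed
#' model object with `coef`, `predict`, `residuals` and `print` methods.
#'
#' @param dose Initial dose (nM). Default 2700.
#' @param conditions Conditions matrix as in [fit_amplitudes()].
#' @param rates Phase rates (min^-1); either the printed values (default)
#'   or recomputed ones from [rates_from_halflives()].
#' @return Object of class `pk_model`.
#' @examples
#' fit <- pk_fit()
#' coef(fit)
#' predict(fit, t_min = c(0, 4, 53))
#' @export
pk_fit <- function(dose = 2700,
                   conditions = cbind(c(4, 53, 1173), c(700, 150, 10)),
                   rates = vinblastine_rates()) {
  amp <- fit_amplitudes(dose, conditions, rates)
  obj <- list(amplitudes = c(unclass(amp)), rates = rates, dose = dose,
              conditions = as.matrix(conditions),
              residual = attr(amp, "residual"))
  names(obj$amplitudes) <- names(amp)
  class(obj) <- "pk_model"
  obj
}

#' @export
coef.pk_model <- function(object, ...) object$amplitudes

#' @export
print.pk_model <- function(x, ...) {
  cat("Four-exponential plasma decay model\n")
  cat(sprintf("  dose %.4g nM; rates (min^-1): %s\n", x$dose,
              paste(format(x$rates, digits = 3), collapse = ", ")))
  cat(sprintf("  amplitudes (nM): %s\n",
              paste(sprintf("%s = %.4g", names(x$amplitudes), x$amplitudes),
                    collapse = ", ")))
  cat(sprintf("  fit residual %.3g nM\n", x$residual))
  invisible(x)
}

#' @export
predict.pk_model <- function(object, t_min, ...) {
  stopifnot(all(t_min >= 0))
  as.numeric(exp(-outer(t_min, object$rates)) %*% object$amplitudes)
}

#' @export
residuals.pk_model <- function(object, ...) {
  predict(object, object$conditions[, 1]) - object$conditions[, 2]
}

#' Constant-perfusion schedule
#'
#' @param level Concentration held in the plasma (nM). Default 8.
#' @param duration_h Duration of the perfusion (h). Default 120.
#' @return Object of class `perfusion_schedule`.
#' @export
perfusion_schedule <- function(level = 8, duration_h = 120) {
  stopifnot(level >= 0)
  .check_positive(duration_h)
  structure(list(level = level, duration_h = duration_h),
            class = "perfusion_schedule")
}

#' @export
print.perfusion_schedule <- function(x, ...) {
  cat(sprintf("Constant perfusion: %.3g nM for %.3g h, then 0\n",
              x$level, x$duration_h))
  invisible(x)
}

#' Evaluate a treatment schedule sigma(t)
#'
#' For a `pk_model` (single injection) evaluates the fitted exponential sum;
#' for a `perfusion_schedule` returns the level while t <= duration (the
#' cut-off is right-continuous: sigma(duration) is still the level, any
#' t > duration gives 0).
#'
#' @param t_min Times (minutes, >= 0).
#' @param schedule A `pk_model` or `perfusion_schedule`.
#' @return Concentrations (nM).
#' @export
sigma_schedule <- function(t_min, schedule) {
  if (any(t_min < 0)) stop("negative time", call. = FALSE)
  if (inherits(schedule, "pk_model")) {
    predict(schedule, t_min)
  } else if (inherits(schedule, "perfusion_schedule")) {
    ifelse(t_min <= schedule$duration_h * 60, schedule$level, 0)
  } else {
    stop("unknown schedule type", call. = FALSE)
  }
}
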