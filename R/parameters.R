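# Model parameters for the four-compartment chamber model.
#
# The model distinguishes three length scales: the intercapillary separation
# d (~50 um), the interarteriole/intervenule separation s (~10^3 um) and the
# chamber scale L (~1 cm). Their ratios nu = d/s and eta = s/L must both be
# small for the scale-separated (homogenised) description to be valid; the
# constructor enforces this.

#' Construct the fixed parameter set of the chamber model
#'
#' Creates a validated `model_parameters` object holding every dimensional
#' constant of the model in SI units, together with the composite literals
#' (`n`, `r_literal`, `C`) that the source experiments report directly.
#' Defaults reproduce the dorsal skinfold chamber case study.
#'
#' Unit conventions at this boundary: lengths `d_um`, `s_um` in micrometres,
#' `L_cm` in centimetres, permeabilities `k_int_m2`, `h_um2`, `k2_um2` in the
#' units their suffix states, pressures `p_artery_mmHg` / `p_vein_mmHg` in
#' mmHg. Everything is stored in SI (m, m2, Pa, kg, s).
#'
#' @param d_um Intercapillary separation (um). Default 50.
#' @param s_um Interarteriole/intervenule separation (um). Default 1000.
#'   (A representative mean separation; note some tabulations quote 100 um,
#'   which does not reproduce the reported dimensionless groups.)
#' @param L_cm Chamber side length (cm). Default 1.
#' @param mu Blood (plasma) viscosity (kg m-1 s-1). Default 4e-3.
#' @param rho Blood density (kg m-3). Default 1040.
#' @param U Typical capillary blood velocity (m s-1). Default 25e-6.
#' @param k_int_m2 Interstitial permeability (m2). Default 4e-18 (lower end
#'   of the experimentally derived range `k_int_range_m2`; the tabulated
#'   literal 0.4 um2 is kept in `k_int_table_m2`).
#' @param L_p Vascular hydraulic permeability of the capillary walls
#'   (m2 s kg-1). Default 1e-10 (= 1e-6 cm2 s kg-1).
#' @param h_um2 Isotropic permeability of the arteriole and venule networks
#'   (um2). Default 37.4.
#' @param k2_um2 Permeability of the surrounding (region 2) capillary
#'   network (um2). Default 37.4.
#' @param Ra,Rv Dimensionless leakiness of the arteriole/venule walls.
#'   Default 1e-2.
#' @param Sa_over_Va,Sv_over_Vv Arteriole (venule) surface-to-own-volume
#'   ratio (m-1). Default 647 (= 6.47e-4 um-1).
#' @param Sa_over_Vp,Sv_over_Vp Arteriole (venule) surface to porous-tissue
#'   volume ratio (m-1). Default 98.6 (= 9.86e-5 um-1).
#' @param n Arteriole (venule) to porous-tissue volume ratio Va/Vp
#'   (dimensionless literal). Default 0.152.
#' @param r_literal Reported composite coupling ratio (dimensionless
#'   literal, not reproducible from its defining formula; see `r_formula`
#'   on the returned object for the recomputed value Ra*s*Sa/Vp).
#'   Default 0.986.
#' @param C_m2 Interstitial composite permeability C (m2, reported literal).
#'   Default 4e-9. The formula value k_int_table*L^2/s^2 is exposed as
#'   `C_formula_m2`.
#' @param p_artery_mmHg,p_vein_mmHg Artery / vein boundary pressures (mmHg).
#'   Defaults 50 and 10.
#' @param D_c Vinblastine diffusivity in the capillaries (m2 s-1).
#'   Default 3.3e-10 (= 3.3e-6 cm2 s-1).
#' @param ra_drug,rv_drug Vessel-wall drug transfer coefficients. Default
#'   23.1e-12 interpreted according to `drug_transfer_units`.
#' @param drug_transfer_units Either `"velocity"` (m s-1; the reading under
#'   which the exchange terms are dimensionally closed, default) or
#'   `"rate"` (s-1, the units printed alongside the value; under this
#'   reading the surface-to-volume factor is treated as already folded in).
#' @return An object of class `model_parameters`.
#' @seealso [dimensionless_groups()], [compose_P()], [read_parameters()]
#' @export
model_parameters <- function(d_um = 50, s_um = 1000, L_cm = 1,
                             mu = 4e-3, rho = 1040, U = 25e-6,
                             k_int_m2 = 4e-18, L_p = 1e-10,
                             h_um2 = 37.4, k2_um2 = 37.4,
                             Ra = 1e-2, Rv = 1e-2,
                             Sa_over_Va = 647, Sv_over_Vv = 647,
                             Sa_over_Vp = 98.6, Sv_over_Vp = 98.6,
                             n = 0.152, r_literal = 0.986, C_m2 = 4e-9,
                             p_artery_mmHg = 50, p_vein_mmHg = 10,
                             D_c = 3.3e-10,
                             ra_drug = 23.1e-12, rv_drug = 23.1e-12,
                             drug_transfer_units = c("velocity", "rate")) {
  drug_transfer_units <- match.arg(drug_transfer_units)
  .check_positive(d_um, s_um, L_cm, mu, rho, U, k_int_m2, L_p, h_um2, k2_um2,
                  Ra, Rv, Sa_over_Va, Sv_over_Vv, Sa_over_Vp, Sv_over_Vp,
                  n, r_literal, C_m2, D_c, ra_drug, rv_drug)
  d <- um_to_m(d_um); s <- um_to_m(s_um); L <- cm_to_m(L_cm)
  if (!(d / s < 1)) stop("invalid parameter: homogenisation requires nu = d/s < 1", call. = FALSE)
  if (!(s / L < 1)) stop("invalid parameter: homogenisation requires eta = s/L < 1", call. = FALSE)
  if (!(p_artery_mmHg > p_vein_mmHg)) {
    stop("invalid parameter: p_artery must exceed p_vein", call. = FALSE)
  }
  p <- list(
    d = d, s = s, L = L, mu = mu, rho = rho, U = U,
    k_int = k_int_m2,
    k_int_table = um2_to_m2(0.4),
    k_int_range = c(4e-18, 4e-15),
    L_p = L_p,
    h = um2_to_m2(h_um2), k2 = um2_to_m2(k2_um2),
    Ra = Ra, Rv = Rv,
    Sa_over_Va = Sa_over_Va, Sv_over_Vv = Sv_over_Vv,
    Sa_over_Vp = Sa_over_Vp, Sv_over_Vp = Sv_over_Vp,
    n = n,
    r_literal = r_literal,
    r_formula = Ra * s * Sa_over_Vp,
    C = C_m2,
    C_formula = um2_to_m2(0.4) * L^2 / s^2,
    p_artery = mmhg_to_pa(p_artery_mmHg),
    p_vein = mmhg_to_pa(p_vein_mmHg),
    D_c = D_c,
    ra_drug = ra_drug, rv_drug = rv_drug,
    drug_transfer_units = drug_transfer_units
  )
  class(p) <- "model_parameters"
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  g <- dimensionless_groups(x)
  cat("Four-compartment chamber model parameters (SI)\n")
  cat(sprintf("  length scales    d = %.3g m, s = %.3g m, L = %.3g m\n", x$d, x$s, x$L))
  cat(sprintf("  fluid            mu = %.3g Pa s, rho = %.4g kg/m3, U = %.3g m/s\n",
              x$mu, x$rho, x$U))
  cat(sprintf("  permeabilities   k_int = %.3g m2, h = %.3g m2, k2 = %.3g m2\n",
              x$k_int, x$h, x$k2))
  cat(sprintf("  composites       n = %.3g, r (literal) = %.3g, r (formula) = %.3g, C = %.3g m2\n",
              x$n, x$r_literal, x$r_formula, x$C))
  cat(sprintf("  boundary         p_artery = %.4g Pa, p_vein = %.4g Pa\n",
              x$p_artery, x$p_vein))
  cat(sprintf("  dimensionless    nu = %.3g, eta = %.3g, Re = %.3g, R = %.3g, V* = %.3g\n",
              g$nu, g$eta, g$Re, g$R, g$Vstar))
  invisible(x)
}

#' Reynolds number in the capillaries
#'
#' Re = rho * U * d / mu, the ratio of inertial to viscous forces at the
#' capillary scale. For tumour microvasculature this is ~1e-4, justifying
#' Stokes (creeping) flow in the unit-cell problems.
#'
#' @param rho Fluid density (kg m-3).
#' @param U Velocity scale (m s-1).
#' @param d Length scale (m).
#' @param mu Dynamic viscosity (kg m-1 s-1).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(1040, 25e-6, 50e-6, 4e-3)  # ~3.3e-4
#' @export
reynolds_number <- function(rho, U, d, mu) {
  .check_positive(rho, U, d, mu)
  rho * U * d / mu
}

#' Dimensionless groups of the fluid transport problem
#'
#' Computes the scale ratios and dimensionless parameters that organise the
#' homogenisation: nu = d/s, eta = s/L, the capillary Reynolds number,
#' the relative interstitial permeability kappa = k_int * s / d^3, the
#' capillary-wall leakiness R = mu * L_p * s^3 / d^4, the velocity-scale
#' ratio V* = s^4 / (d^2 L^2) = eta^2/nu^2, the capillary Peclet number
#' U*d/D_c, and the region-2 composite permeability P2 (see [compose_P()]).
#' `kappa_range` gives kappa over the experimentally derived range of
#' interstitial permeabilities stored on the parameter object.
#'
#' @param params A [model_parameters()] object.
#' @return A list of class `dimensionless_groups`.
#' @export
dimensionless_groups <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  g <- list(
    nu = params$d / params$s,
    eta = params$s / params$L,
    Re = reynolds_number(params$rho, params$U, params$d, params$mu),
    kappa = params$k_int * params$s / params$d^3,
    kappa_range = params$k_int_range * params$s / params$d^3,
    R = params$mu * params$L_p * params$s^3 / params$d^4,
    Vstar = params$s^4 / (params$d^2 * params$L^2),
    Peclet = params$U * params$d / params$D_c,
    P2 = compose_P(params$k2, params$d, params$L, params$s),
    C = params$C
  )
  class(g) <- "dimensionless_groups"
  g
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups\n")
  cat(sprintf("  nu = %.3g  eta = %.3g  Re = %.3g  R = %.3g  V* = %.3g  Pe = %.3g\n",
              x$nu, x$eta, x$Re, x$R, x$Vstar, x$Peclet))
  cat(sprintf("  kappa = %.3g  (range %.3g .. %.3g)\n",
              x$kappa, x$kappa_range[1], x$kappa_range[2]))
  cat(sprintf("  P2 = %.3g m2   C = %.3g m2\n", x$P2, x$C))
  invisible(x)
}

#' Composite capillary perfusion parameter P
#'
#' P = k * L^2 * d^2 / s^4 = k * nu^2 / eta^2 (m2) combines the capillary
#' network permeability k with the capillary density (through d) and the
#' intermediate scale s. It is the single knob through which capillary
#' architecture enters the chamber-scale flow problem.
#'
#' @param k Capillary network permeability (m2).
#' @param d Intercapillary separation (m).
#' @param L Chamber length (m).
#' @param s Interarteriole separation (m).
#' @return P in m2.
#' @examples
#' compose_P(37.4e-12, 50e-6, 1e-2, 1e-3)  # region 2 default, ~9.36e-12 m2
#' @export
compose_P <- function(k, d, L, s) {
  .check_positive(k, d, L, s)
  k * L^2 * d^2 / s^4
}

#' Read model parameters from a JSON file
#'
#' The file must contain a flat JSON object whose keys are arguments of
#' [model_parameters()] (unit-suffixed, e.g. `"d_um"`, `"L_cm"`,
#' `"p_artery_mmHg"`). Unknown keys are rejected rather than ignored.
#'
#' @param path Path to a JSON file.
#' @return A [model_parameters()] object.
#' @export
read_parameters <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(model_parameters))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(model_parameters, cfg)
}

#' Write a parameter configuration to JSON
#'
#' Serialises the configuration-boundary representation (unit-suffixed keys)
#' of a parameter object, such that [read_parameters()] round-trips it.
#'
#' @param params A [model_parameters()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  cfg <- list(
    d_um = params$d * 1e6, s_um = params$s * 1e6, L_cm = params$L * 1e2,
    mu = params$mu, rho = params$rho, U = params$U,
    k_int_m2 = params$k_int, L_p = params$L_p,
    h_um2 = params$h * 1e12, k2_um2 = params$k2 * 1e12,
    Ra = params$Ra, Rv = params$Rv,
    Sa_over_Va = params$Sa_over_Va, Sv_over_Vv = params$Sv_over_Vv,
    Sa_over_Vp = params$Sa_over_Vp, Sv_over_Vp = params$Sv_over_Vp,
    n = params$n, r_literal = params$r_literal, C_m2 = params$C,
    p_artery_mmHg = pa_to_mmhg(params$p_artery),
    p_vein_mmHg = pa_to_mmhg(params$p_vein),
    D_c = params$D_c,
    ra_drug = params$ra_drug, rv_drug = params$rv_drug,
    drug_transfer_units = params$drug_transfer_units
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
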