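# Chamber-scale vinblastine transport.
#
# Three coupled concentration fields (arterioles c_a, venules c_v,
# capillaries c_c; the interstitial concentration equals c_c at this order)
# are advected by the frozen fluid velocities and exchanged across the
# vessel walls:
#
#   dc_a/dt + u_a . grad c_a = -lambda_aa (c_a - c_c)
#   dc_v/dt + u_v . grad c_v = -lambda_vv (c_v - c_c)
#   dc_c/dt + u_c . grad c_c =  lambda_pa (c_a - c_c) + lambda_pv (c_v - c_c)
#
# plus a small isotropic stabilising diffusion (the formally neglected
# next-order term of the homogenised model). The advection operator is the
# concentration (non-conservative) form: the homogenised velocity fields
# are not divergence-free - fluid leaks between compartments - and a parcel
# losing fluid at its own concentration keeps its concentration, so the
# drug equations advect c rather than transport the product c*u. This form
# preserves spatially uniform states exactly, which the constant-perfusion
# equilibrium (everything at the perfusion level) relies on.
#
# Discretisation: P1 Galerkin convection with algebraic (low-order) upwind
# stabilisation - the discrete operator annihilates constants and has the
# sign pattern of an M-matrix - lumped-mass exchange, implicit Euler time
# stepping (unconditionally positive for the advection-exchange part),
# Dirichlet c_a = sigma(t) on the artery arc, natural no-flux conditions
# elsewhere.

#' Drug transport parameters
#'
#' Derives the wall-transfer exchange rates and the stabilising diffusion
#' from the model parameters. With `drug_transfer_units = "velocity"`
#' (default) the membrane permeability is a velocity and the exchange rates
#' are (S/V) * T with T = r_drug / eta^2; with `"rate"` the printed value is
#' taken as the full exchange rate T itself (surface-to-volume factor
#' already folded in).
#'
#' @param params A [model_parameters()] object.
#' @param D_num Stabilising diffusion (m2 s-1). Default eta^2 * U * L.
#' @return List of class `drug_parameters` with exchange rates (s^-1) and
#'   `D_num`.
#' @export
drug_parameters <- function(params, D_num = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  eta <- params$s / params$L
  Ta <- params$ra_drug / eta^2
  Tv <- params$rv_drug / eta^2
  if (params$drug_transfer_units == "velocity") {
    lam <- list(aa = params$Sa_over_Va * Ta, vv = params$Sv_over_Vv * Tv,
                pa = params$Sa_over_Vp * Ta, pv = params$Sv_over_Vp * Tv)
  } else {
    lam <- list(aa = Ta, vv = Tv, pa = Ta, pv = Tv)
  }
  if (is.null(D_num)) D_num <- eta^2 * params$U * params$L
  .check_positive(D_num, .names = "D_num")
  structure(c(lam, list(D_num = D_num)), class = "drug_parameters")
}

# low-order upwind advection operator: returns sparse A with
# (A c)_i ~ integral phi_i (u . grad c) after discrete upwinding;
# rows sum to zero, off-diagonals <= 0 after the sign flip used below.
.upwind_advection <- function(mesh, u_elem, grad) {
  tri <- mesh$tri
  nn <- nrow(mesh$nodes)
  # Galerkin convection triplets: c_ij = u_T . grad(phi_j) * A_T / 3
  ii <- jj <- vv <- vector("list", 9)
  idx <- 1
  for (i in 1:3) for (j in 1:3) {
    ii[[idx]] <- tri[, i]; jj[[idx]] <- tri[, j]
    vv[[idx]] <- (u_elem[, 1] * grad$b[, j] + u_elem[, 2] * grad$c[, j]) / 6
    idx <- idx + 1
  }
  C <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(nn, nn))
  # algebraic upwinding: d_ij = max(0, c_ij, c_ji) off-diagonal (applied to
  # K = -C), diagonal balances rows
  s <- Matrix::summary(C)
  off <- s$i != s$j
  si <- s$i[off]; sj <- s$j[off]; sx <- s$x[off]
  key <- paste(pmin(si, sj), pmax(si, sj), sep = "_")
  dpair <- tapply(sx, key, function(v) max(0, v))
  ij <- do.call(rbind, strsplit(names(dpair), "_", fixed = TRUE))
  pi_ <- as.integer(ij[, 1]); pj_ <- as.integer(ij[, 2])
  d <- as.numeric(dpair)
  nz <- d > 0
  Dm <- Matrix::sparseMatrix(i = c(pi_[nz], pj_[nz]), j = c(pj_[nz], pi_[nz]),
                             x = c(d[nz], d[nz]), dims = c(nn, nn))
  diagD <- Matrix::Diagonal(nn, as.numeric(Matrix::rowSums(Dm)))
  # advection operator in the form M dc/dt = -A c
  C + (diagD - Dm)
}

#' Solve the chamber drug transport problem
#'
#' Time-integrates the three coupled advection-exchange equations on a
#' frozen fluid solution with sigma(t) imposed on the artery arc, zero
#' initial concentrations, and stores the nodal fields at `output_times`.
#'
#' @param fluid A `chamber_fluid` solution (carries mesh and velocities).
#' @param schedule A `pk_model` or `perfusion_schedule`.
#' @param drug_params A [drug_parameters()] object (default derived from the
#'   fluid solution's parameters).
#' @param t_end_h Simulation horizon (hours). Default 712.
#' @param output_times_h Times (hours) at which fields are stored; default a
#'   log-graded grid resolving the injection transient.
#' @param dt_blocks Optional data frame `(t_end_h, dt_s)` defining
#'   piecewise-constant time-step blocks.
#' @return Object of class `drug_state`: output times (h), matrices `c_a`,
#'   `c_v`, `c_c` (nodes x times, nM), `c_t = c_c`, and a weighted
#'   mass-balance series.
#' @export
solve_drug <- function(fluid, schedule, drug_params = NULL,
                       t_end_h = 712, output_times_h = NULL,
                       dt_blocks = NULL) {
  stopifnot(inherits(fluid, "chamber_fluid"))
  .check_positive(t_end_h)
  mesh <- fluid$mesh
  params <- fluid$params
  if (is.null(drug_params)) drug_params <- drug_parameters(params)
  if (is.null(output_times_h)) {
    output_times_h <- unique(sort(c(0,
      10^seq(log10(1 / 60), log10(t_end_h), length.out = 80), t_end_h)))
    output_times_h <- output_times_h[output_times_h <= t_end_h]
  }
  if (is.null(dt_blocks)) {
    dt_blocks <- data.frame(
      t_end_h = c(0.05, 0.5, 4, 24, 120, Inf),
      dt_s = c(10, 60, 300, 1800, 7200, 14400))
  }
  nn <- nrow(mesh$nodes)
  grad <- .p1_gradients(mesh)
  A_a <- .upwind_advection(mesh, fluid$u_a, grad)
  A_v <- .upwind_advection(mesh, fluid$u_v, grad)
  A_c <- .upwind_advection(mesh, fluid$u_c, grad)
  S1 <- .stiffness(mesh, rep(drug_params$D_num, nrow(mesh$tri)), grad)
  Ml <- mesh$lump
  lam <- drug_params
  trip <- function(S) { s <- Matrix::summary(S); list(i = s$i, j = s$j, x = s$x) }
  ta <- trip(A_a + S1); tv <- trip(A_v + S1); tc <- trip(A_c + S1)
  sq <- seq_len(nn)
  I <- c(ta$i, sq, sq,
         nn + tv$i, nn + sq, nn + sq,
         2 * nn + tc$i, 2 * nn + sq, 2 * nn + sq, 2 * nn + sq)
  J <- c(ta$j, sq, 2 * nn + sq,
         nn + tv$j, nn + sq, 2 * nn + sq,
         2 * nn + tc$j, 2 * nn + sq, sq, nn + sq)
  X <- c(ta$x, lam$aa * Ml, -lam$aa * Ml,
         tv$x, lam$vv * Ml, -lam$vv * Ml,
         tc$x, (lam$pa + lam$pv) * Ml, -lam$pa * Ml, -lam$pv * Ml)
  dir_rows <- mesh$artery_nodes
  keep <- !(I %in% dir_rows)
  A_op <- Matrix::sparseMatrix(i = I[keep], j = J[keep], x = X[keep],
                               dims = c(3 * nn, 3 * nn))
  Mvec <- rep(Ml, 3)
  out_t <- output_times_h * 3600
  n_out <- length(out_t)
  Ca <- matrix(0, nn, n_out); Cv <- matrix(0, nn, n_out); Cc <- matrix(0, nn, n_out)
  mass <- numeric(n_out)
  wa <- if (lam$aa > 0) lam$pa / lam$aa else 0  # Va/Vp volume weighting
  wv <- if (lam$vv > 0) lam$pv / lam$vv else 0
  record <- function(k, cvec) {
    Ca[, k] <<- cvec[sq]; Cv[, k] <<- cvec[nn + sq]; Cc[, k] <<- cvec[2 * nn + sq]
    mass[k] <<- sum(Ml * (wa * cvec[sq] + wv * cvec[nn + sq] + cvec[2 * nn + sq]))
  }
  cvec <- numeric(3 * nn)
  t_now <- 0
  k_out <- 1
  if (out_t[1] <= 0) { record(1, cvec); k_out <- 2 }
  t_end_s <- t_end_h * 3600
  blocks <- dt_blocks
  blocks$t_end_h <- pmin(blocks$t_end_h, t_end_h)
  prev_end <- 0
  for (bl in seq_len(nrow(blocks))) {
    b_end <- blocks$t_end_h[bl] * 3600
    if (b_end <= prev_end) next
    dt <- blocks$dt_s[bl]
    Asys <- Matrix::Diagonal(3 * nn, Mvec / dt) + A_op
    # Dirichlet rows for c_a on the artery arc
    Asys <- as(Asys, "CsparseMatrix")
    sA <- Matrix::summary(Asys)
    keep2 <- !(sA$i %in% dir_rows)
    Asys <- Matrix::sparseMatrix(i = c(sA$i[keep2], dir_rows),
                                 j = c(sA$j[keep2], dir_rows),
                                 x = c(sA$x[keep2], rep(1, length(dir_rows))),
                                 dims = c(3 * nn, 3 * nn))
    lu <- Matrix::lu(Asys)
    nstep <- ceiling((b_end - prev_end) / dt - 1e-9)
    for (st in seq_len(nstep)) {
      t_next <- min(t_now + dt, b_end)
      dt_eff <- t_next - t_now
      if (abs(dt_eff - dt) > 1e-9 * dt) {
        # short final step of the block: refactor once
        Ash <- Matrix::Diagonal(3 * nn, Mvec / dt_eff) + A_op
        Ash <- as(Ash, "CsparseMatrix")
        sA <- Matrix::summary(Ash)
        keep3 <- !(sA$i %in% dir_rows)
        Ash <- Matrix::sparseMatrix(i = c(sA$i[keep3], dir_rows),
                                    j = c(sA$j[keep3], dir_rows),
                                    x = c(sA$x[keep3], rep(1, length(dir_rows))),
                                    dims = c(3 * nn, 3 * nn))
        lu_use <- Matrix::lu(Ash)
      } else lu_use <- lu
      rhs <- (Mvec / dt_eff) * cvec
      rhs[dir_rows] <- sigma_schedule(t_next / 60, schedule)
      cvec <- as.numeric(Matrix::solve(lu_use, rhs))
      t_now <- t_next
      while (k_out <= n_out && out_t[k_out] <= t_now + 1e-6) {
        record(k_out, cvec)
        k_out <- k_out + 1
      }
      if (t_now >= t_end_s) break
    }
    prev_end <- b_end
    if (t_now >= t_end_s) break
  }
  while (k_out <= n_out) { record(k_out, cvec); k_out <- k_out + 1 }
  st <- list(mesh = mesh, times_h = output_times_h,
             c_a = Ca, c_v = Cv, c_c = Cc, c_t = Cc,
             schedule = schedule, drug_params = drug_params,
             mass_weighted = mass,
             mass_weights = c(arteriole = wa, venule = wv, capillary = 1))
  class(st) <- "drug_state"
  st
}

#' Steady state of the drug transport operator under constant plasma level
#'
#' Solves the time-independent advection-exchange system with a constant
#' sigma on the artery arc. With any strictly positive exchange rates the
#' unique steady state is spatially uniform at the plasma level in every
#' compartment; this accessor exposes it for verification.
#'
#' @param fluid A `chamber_fluid` solution.
#' @param level Constant plasma concentration (nM).
#' @param drug_params Optional [drug_parameters()].
#' @return List of nodal fields `c_a`, `c_v`, `c_c` (nM).
#' @export
solve_drug_steady <- function(fluid, level = 8, drug_params = NULL) {
  stopifnot(inherits(fluid, "chamber_fluid"))
  mesh <- fluid$mesh
  if (is.null(drug_params)) drug_params <- drug_parameters(fluid$params)
  nn <- nrow(mesh$nodes)
  grad <- .p1_gradients(mesh)
  S1 <- .stiffness(mesh, rep(drug_params$D_num, nrow(mesh$tri)), grad)
  A_a <- .upwind_advection(mesh, fluid$u_a, grad) + S1
  A_v <- .upwind_advection(mesh, fluid$u_v, grad) + S1
  A_c <- .upwind_advection(mesh, fluid$u_c, grad) + S1
  Ml <- mesh$lump; lam <- drug_params
  trip <- function(S) { s <- Matrix::summary(S); list(i = s$i, j = s$j, x = s$x) }
  ta <- trip(A_a); tv <- trip(A_v); tc <- trip(A_c)
  sq <- seq_len(nn)
  I <- c(ta$i, sq, sq,
         nn + tv$i, nn + sq, nn + sq,
         2 * nn + tc$i, 2 * nn + sq, 2 * nn + sq, 2 * nn + sq)
  J <- c(ta$j, sq, 2 * nn + sq,
         nn + tv$j, nn + sq, 2 * nn + sq,
         2 * nn + tc$j, 2 * nn + sq, sq, nn + sq)
  X <- c(ta$x, lam$aa * Ml, -lam$aa * Ml,
         tv$x, lam$vv * Ml, -lam$vv * Ml,
         tc$x, (lam$pa + lam$pv) * Ml, -lam$pa * Ml, -lam$pv * Ml)
  dir_rows <- mesh$artery_nodes
  keep <- !(I %in% dir_rows)
  A <- Matrix::sparseMatrix(i = c(I[keep], dir_rows), j = c(J[keep], dir_rows),
                            x = c(X[keep], rep(1, length(dir_rows))),
                            dims = c(3 * nn, 3 * nn))
  b <- numeric(3 * nn); b[dir_rows] <- level
  sol <- as.numeric(Matrix::solve(A, b))
  list(c_a = sol[sq], c_v = sol[nn + sq], c_c = sol[2 * nn + sq])
}

#' @export
print.drug_state <- function(x, ...) {
  av <- function(f) average_concentration(x, "region1", f)
  cc <- av("c_c")
  cat(sprintf("Drug transport state: %d stored times over %.3g h\n",
              length(x$times_h), max(x$times_h)))
  cat(sprintf("  region-1 capillary mean: peak %.4g nM at t = %.3g h, final %.4g nM\n",
              max(cc), x$times_h[which.max(cc)], cc[length(cc)]))
  invisible(x)
}

#' Area-weighted average concentration time series
#'
#' @param state A `drug_state`.
#' @param region `"region1"` or `"chamber"`.
#' @param compartment One of `"c_a"`, `"c_v"`, `"c_c"`, `"c_t"`.
#' @return Numeric vector (nM) along `state$times_h`.
#' @export
average_concentration <- function(state, region = c("region1", "chamber"),
                                  compartment = c("c_c", "c_a", "c_v", "c_t")) {
  stopifnot(inherits(state, "drug_state"))
  region <- match.arg(region)
  compartment <- match.arg(compartment)
  w <- if (region == "region1") state$mesh$lump_region1 else state$mesh$lump
  if (sum(w) <= 0) stop("empty region", call. = FALSE)
  as.numeric(crossprod(state[[compartment]], w) / sum(w))
}

#' @export
plot.drug_state <- function(x, region = "region1", ...) {
  t <- x$times_h
  ca <- average_concentration(x, region, "c_a")
  cv <- average_concentration(x, region, "c_v")
  cc <- average_concentration(x, region, "c_c")
  graphics::matplot(t, cbind(ca, cv, cc), type = "l", lty = 1, col = c(2, 4, 1),
                    xlab = "time (h)", ylab = "concentration (nM)", log = "x", ...)
  graphics::legend("topright", c("arterioles", "venules", "capillaries/interstitium"),
                   col = c(2, 4, 1), lty = 1)
  invisible(x)
}
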