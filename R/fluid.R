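# Coupled four-compartment pressure solve on the chamber.
#
# The chamber-scale model consists of three coupled elliptic equations for
# the arteriole, venule and capillary pressures (the interstitial pressure
# equals the capillary pressure at this order):
#
#   div( h grad p_a ) = gamma_a (p_a - p_c)
#   div( h grad p_v ) = gamma_v (p_v - p_c)
#   div( P grad p_c ) = beta (2 p_c - p_a - p_v)
#
# with Dirichlet data on the artery/vein arcs (p_a and p_v respectively),
# homogeneous Neumann conditions elsewhere, and continuity of pressure and
# normal flux across the region interface Gamma (the P jump is handled by
# per-element coefficients in the weak form). The dimensionless exchange
# coefficients are computed in chamber units: the network permeabilities
# live on their natural s^2 scale and lengths on the chamber scale L, giving
#
#   gamma = eta * r * s^2 / (n * L^2),   beta = r * s^2 / L^2,
#
# with r the recomputed arteriole/venule coupling ratio Ra * s * Sa/Vp.
# This scaling reproduces the physical regimes of the model (arteriole
# pressure variation over millimetres; capillary boundary layers that
# shrink as the region-1 composite parameter P decreases). A literal
# reading with coefficients eta*r/(h*n) and r/P per square metre is
# available via `coupling_mode = "literal"`; it places every exchange
# boundary layer on the micron scale.

#' Exchange coupling coefficients for the chamber pressure system
#'
#' @param params A [model_parameters()] object.
#' @param coupling_mode `"chamber"` (default; see the package vignette) or
#'   `"literal"`.
#' @return List with `gamma_a`, `gamma_v`, `beta` (dimensionless weights on
#'   the pressure differences in the conservation-form equations).
#' @export
coupling_coefficients <- function(params, coupling_mode = c("chamber", "literal")) {
  coupling_mode <- match.arg(coupling_mode)
  if (coupling_mode == "chamber") {
    r <- params$r_formula
    g <- params$s^2 * (params$s / params$L) * r / (params$n * params$L^2)
    b <- r * params$s^2 / params$L^2
  } else {
    r <- params$r_literal
    g <- (params$s / params$L) * r / params$n
    b <- r
  }
  list(gamma_a = g, gamma_v = g, beta = b)
}

#' Solve the coupled chamber pressure system
#'
#' Assembles and solves the three coupled elliptic equations in one sparse
#' linear system (P1 finite elements, lumped-mass exchange terms). Dirichlet
#' p_a on the artery arc and p_v on the vein arc; homogeneous Neumann for
#' every field on the outer boundary and for p_c on the artery/vein arcs.
#'
#' @param mesh A [mesh_chamber()] triangulation.
#' @param params A [model_parameters()] object.
#' @param P_region1 Composite capillary parameter P in region 1 (m2).
#' @param P_region2 P in region 2 (m2); default `compose_P(k2, d, L, s)`.
#' @param coupling Optional list overriding the exchange coefficients
#'   (`gamma_a`, `gamma_v`, `beta`), e.g. from [coupling_coefficients()].
#' @param coupling_mode Passed to [coupling_coefficients()] when `coupling`
#'   is not supplied.
#' @return An object of class `chamber_fluid` holding the nodal pressures
#'   (`p_a`, `p_v`, `p_c`, and `p_t = p_c`) in Pa, element velocities (m/s),
#'   and bookkeeping for flux evaluation.
#' @export
solve_pressures <- function(mesh, params, P_region1, P_region2 = NULL,
                            coupling = NULL,
                            coupling_mode = c("chamber", "literal")) {
  stopifnot(inherits(mesh, "chamber_mesh"), inherits(params, "model_parameters"))
  .check_positive(P_region1)
  if (is.null(P_region2)) {
    P_region2 <- compose_P(params$k2, params$d, params$L, params$s)
  }
  if (is.null(coupling)) {
    coupling <- coupling_coefficients(params, match.arg(coupling_mode))
  }
  ga <- coupling$gamma_a; gv <- coupling$gamma_v; be <- coupling$beta
  stopifnot(is.finite(ga), is.finite(gv), is.finite(be),
            ga >= 0, gv >= 0, be >= 0)
  if (be == 0) {
    stop("singular system: p_c has neither Dirichlet data nor exchange coupling ",
         "(beta = 0); its null space contains the constants", call. = FALSE)
  }
  nn <- nrow(mesh$nodes)
  grad <- .p1_gradients(mesh)
  P_elem <- ifelse(mesh$region == 1L, P_region1, P_region2)
  trip <- function(S) {
    s <- Matrix::summary(S)
    list(i = s$i, j = s$j, x = s$x)
  }
  t_h <- trip(.stiffness(mesh, rep(params$h, nrow(mesh$tri)), grad))
  t_P <- trip(.stiffness(mesh, P_elem, grad))
  Ml <- mesh$lump
  sq <- seq_len(nn)
  # block triplets, ordering (a, v, c); lumped-mass exchange terms
  I <- c(t_h$i,      sq,       sq,
         nn + t_h$i, nn + sq,  nn + sq,
         2 * nn + t_P$i, 2 * nn + sq, 2 * nn + sq, 2 * nn + sq)
  J <- c(t_h$j,      sq,       2 * nn + sq,
         nn + t_h$j, nn + sq,  2 * nn + sq,
         2 * nn + t_P$j, 2 * nn + sq, sq, nn + sq)
  X <- c(t_h$x,      ga * Ml,  -ga * Ml,
         t_h$x,      gv * Ml,  -gv * Ml,
         t_P$x,      2 * be * Ml, -be * Ml, -be * Ml)
  # Dirichlet rows: p_a on the artery arc, p_v on the vein arc
  rows_a <- mesh$artery_nodes
  rows_v <- nn + mesh$vein_nodes
  dirichlet <- c(rows_a, rows_v)
  keep <- !(I %in% dirichlet)
  I <- c(I[keep], dirichlet); J <- c(J[keep], dirichlet)
  X <- c(X[keep], rep(1, length(dirichlet)))
  b <- numeric(3 * nn)
  b[rows_a] <- params$p_artery
  b[rows_v] <- params$p_vein
  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(3 * nn, 3 * nn))
  sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e) stop("singular pressure system: ", conditionMessage(e),
                                           call. = FALSE))
  p_a <- sol[1:nn]; p_v <- sol[nn + 1:nn]; p_c <- sol[2 * nn + 1:nn]
  eta <- params$s / params$L
  u_a <- -(params$h / params$mu) * .elem_grad(mesh, p_a, grad)
  u_v <- -(params$h / params$mu) * .elem_grad(mesh, p_v, grad)
  gc_ <- .elem_grad(mesh, p_c, grad)
  u_c <- -(eta * P_elem / params$mu) * gc_
  u_t <- -(eta^2 * params$C / params$mu) * gc_
  out <- list(mesh = mesh, params = params,
              P_region1 = P_region1, P_region2 = P_region2,
              coupling = coupling,
              p_a = p_a, p_v = p_v, p_c = p_c, p_t = p_c,
              u_a = u_a, u_v = u_v, u_c = u_c, u_t = u_t,
              grad_p_c = gc_)
  class(out) <- "chamber_fluid"
  out
}

#' @export
print.chamber_fluid <- function(x, ...) {
  rng <- function(v) sprintf("[%.3f, %.3f] mmHg", min(v) / 133.322, max(v) / 133.322)
  cat("Chamber fluid solution\n")
  cat(sprintf("  P1 = %.3g m2, P2 = %.3g m2\n", x$P_region1, x$P_region2))
  cat(sprintf("  p_a %s  p_v %s  p_c %s\n", rng(x$p_a), rng(x$p_v), rng(x$p_c)))
  fl <- interface_fluxes(x)
  cat(sprintf("  Q_c = %.4g um2/s, Q_t = %.4g um2/s (region 1 -> region 2)\n",
              fl$Q_c * 1e12, fl$Q_t * 1e12))
  invisible(x)
}

#' Element-wise Darcy velocities of a fluid solution
#'
#' Returns the velocity fields already carried by the solution object;
#' provided as an explicit accessor mirroring the velocity laws
#' u_a = -(h/mu) grad p_a, u_v = -(h/mu) grad p_v,
#' u_c = -(eta P/mu) grad p_c, u_t = -(eta^2 C/mu) grad p_t.
#'
#' @param solution A `chamber_fluid` object.
#' @return List of element-wise velocity matrices (m/s).
#' @export
velocities <- function(solution) {
  stopifnot(inherits(solution, "chamber_fluid"))
  solution[c("u_a", "u_v", "u_c", "u_t")]
}

#' Fluid fluxes across the region interface
#'
#' Q_c and Q_t are the net capillary and interstitial fluid fluxes from
#' region 1 into region 2 through Gamma (2D fluxes, m2/s). They are
#' evaluated in conservative (residual) form: the Gamma boundary integral of
#' P grad p_c . n equals the integral of the capillary exchange source over
#' region 1 (the artery/vein arcs carry no p_c flux), which converges at the
#' scheme's full order. Q_t = (eta C / P) Q_c holds exactly because both
#' use the same discrete gradient integral. A direct edge-quadrature value
#' `Q_c_edge` is also reported for cross-checking.
#'
#' @param solution A `chamber_fluid` object.
#' @return An object of class `flux_result` with `Q_c`, `Q_t` (m2/s),
#'   `Q_c_edge`, and the `P` used in region 1.
#' @export
interface_fluxes <- function(solution) {
  stopifnot(inherits(solution, "chamber_fluid"))
  mesh <- solution$mesh; params <- solution$params
  eta <- params$s / params$L
  be <- solution$coupling$beta
  # discrete conservation identity: summing the capillary equations over the
  # nodes strictly inside Gamma equates the Gamma flux of P grad p_c to the
  # exchange source over region 1 (the arcs carry no p_c flux)
  idx <- mesh$region1_interior_nodes
  src <- sum(mesh$lump[idx] *
               (be * (2 * solution$p_c - solution$p_a - solution$p_v))[idx])
  G <- src / solution$P_region1          # = integral over Gamma of grad p_c . n
  Q_c <- -(eta * solution$P_region1 / params$mu) * G
  Q_t <- -(eta^2 * params$C / params$mu) * G
  # direct edge quadrature using the region-1 elements adjacent to Gamma
  Q_c_edge <- .gamma_edge_flux(solution) * (-(eta / params$mu))
  out <- list(Q_c = Q_c, Q_t = Q_t, Q_c_edge = Q_c_edge,
              P = solution$P_region1, ratio = eta * params$C / solution$P_region1)
  class(out) <- "flux_result"
  out
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("Interface fluxes: Q_c = %.4g um2/s, Q_t = %.4g um2/s (Q_t/Q_c = %.4g)\n",
              x$Q_c * 1e12, x$Q_t * 1e12, x$ratio))
  invisible(x)
}

# integral over Gamma of P grad p_c . n via edge quadrature on the
# region-1 side (outward normal from region 1)
.gamma_edge_flux <- function(solution) {
  mesh <- solution$mesh
  ge <- mesh$gamma_edges
  centre <- mesh$geometry$vessel_center
  # for each Gamma edge find the region-1 triangle containing both endpoints
  tri <- mesh$tri; region <- mesh$region
  # build lookup: edges of region-1 triangles
  tot <- 0
  gset <- rep(FALSE, nrow(mesh$nodes)); gset[mesh$gamma_nodes] <- TRUE
  cand <- which(region == 1L &
                  (gset[tri[, 1]] + gset[tri[, 2]] + gset[tri[, 3]]) >= 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_of <- new.env(hash = TRUE)
  for (t in cand) {
    vs <- tri[t, ]
    on <- vs[gset[vs]]
    if (length(on) == 2) assign(key(on[1], on[2]), t, envir = edge_of)
  }
  g <- .p1_gradients(mesh)
  for (r in seq_len(nrow(ge))) {
    a <- ge[r, 1]; b <- ge[r, 2]
    t <- get0(key(a, b), envir = edge_of)
    if (is.null(t)) next
    pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
    ev <- pb - pa; len <- sqrt(sum(ev^2))
    nrm <- c(ev[2], -ev[1]) / len
    mid <- (pa + pb) / 2
    if (sum((mid - centre) * nrm) < 0) nrm <- -nrm   # outward from region 1
    gp <- solution$grad_p_c[t, ]
    tot <- tot + solution$P_region1 * sum(gp * nrm) * len
  }
  tot
}

#' Net boundary fluxes through the artery and vein arcs
#'
#' Reaction-force (residual) evaluation of the arteriole inflow through the
#' artery arc and the venule outflow through the vein arc; used for the
#' global conservation check (with equal arteriole/venule coupling the two
#' match up to discretisation error).
#'
#' @param solution A `chamber_fluid` object.
#' @return List with `artery_in` and `vein_out` (m2/s, positive numbers for
#'   the default pressure drop).
#' @export
boundary_fluxes <- function(solution) {
  stopifnot(inherits(solution, "chamber_fluid"))
  mesh <- solution$mesh; params <- solution$params
  grad <- .p1_gradients(mesh)
  S_h <- .stiffness(mesh, rep(params$h, nrow(mesh$tri)), grad)
  Ml <- mesh$lump
  ga <- solution$coupling$gamma_a; gv <- solution$coupling$gamma_v
  res_a <- as.numeric(S_h %*% solution$p_a) + ga * Ml * (solution$p_a - solution$p_c)
  res_v <- as.numeric(S_h %*% solution$p_v) + gv * Ml * (solution$p_v - solution$p_c)
  # residual at a Dirichlet node equals the outward boundary flux integral
  # of h grad p . n weighted by the hat function (outward from the tissue,
  # i.e. into the vessel lumen)
  artery_in <- sum(res_a[mesh$artery_nodes]) / params$mu
  vein_out <- -sum(res_v[mesh$vein_nodes]) / params$mu
  list(artery_in = artery_in, vein_out = vein_out)
}

#' Sweep the region-1 perfusion parameter P
#'
#' Solves the pressure system for each P in `P_values` (region 2 held at its
#' default), records Q_c and Q_t, refines the location of the Q_c maximum by
#' golden-section search between the bracketing samples (in log10 P), and
#' reports the sign-change value of Q_c if the curve crosses zero. Ties in
#' the sampled maximum resolve to the smaller P before refinement.
#'
#' @param mesh A [mesh_chamber()] object.
#' @param params A [model_parameters()] object.
#' @param P_values Positive, sorted vector of P samples (m2).
#' @param refine Golden-section refinement of the maximum (default TRUE).
#' @param ... Passed to [solve_pressures()] (e.g. `coupling`).
#' @return An object of class `P_sweep`: data frame `curve` (P, Q_c, Q_t),
#'   `P_opt`, `Q_c_opt`, and `P_signchange` (NA when Q_c does not cross 0).
#' @export
sweep_P <- function(mesh, params, P_values, refine = TRUE, ...) {
  stopifnot(all(P_values > 0), !is.unsorted(P_values))
  qc <- function(P) {
    s <- tryCatch(solve_pressures(mesh, params, P_region1 = P, ...),
                  error = function(e) stop("solver failed at P = ", format(P), ": ",
                                           conditionMessage(e), call. = FALSE))
    fl <- interface_fluxes(s)
    c(fl$Q_c, fl$Q_t)
  }
  res <- vapply(P_values, qc, numeric(2))
  curve <- data.frame(P = P_values, Q_c = res[1, ], Q_t = res[2, ])
  i_best <- which(curve$Q_c == max(curve$Q_c))[1]   # ties -> smaller P
  P_opt <- curve$P[i_best]; Q_opt <- curve$Q_c[i_best]
  if (refine && i_best > 1 && i_best < nrow(curve)) {
    f <- function(lp) qc(10^lp)[1]
    o <- stats::optimize(f, lower = log10(curve$P[i_best - 1]),
                         upper = log10(curve$P[i_best + 1]),
                         maximum = TRUE, tol = 0.02)
    if (o$objective > Q_opt) {
      P_opt <- 10^o$maximum; Q_opt <- o$objective
    }
  }
  sgn <- sign(curve$Q_c)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  P_signchange <- NA_real_
  if (length(flip)) {
    k <- flip[1]
    f <- function(lp) qc(10^lp)[1]
    P_signchange <- 10^stats::uniroot(f, lower = log10(curve$P[k]),
                                      upper = log10(curve$P[k + 1]),
                                      tol = 0.01)$root
  }
  out <- list(curve = curve, P_opt = P_opt, Q_c_opt = Q_opt,
              P_signchange = P_signchange)
  class(out) <- "P_sweep"
  out
}

#' @export
print.P_sweep <- function(x, ...) {
  cat(sprintf("P sweep over [%.3g, %.3g] m2 (%d samples)\n",
              min(x$curve$P), max(x$curve$P), nrow(x$curve)))
  cat(sprintf("  Q_c maximum %.4g um2/s at P ~ %.3g m2\n",
              x$Q_c_opt * 1e12, x$P_opt))
  if (is.finite(x$P_signchange)) {
    cat(sprintf("  Q_c changes sign at P ~ %.3g m2\n", x$P_signchange))
  } else {
    cat("  Q_c does not change sign over the sweep\n")
  }
  invisible(x)
}

#' @export
plot.P_sweep <- function(x, ...) {
  graphics::plot(x$curve$P, x$curve$Q_c * 1e12, log = "x", type = "b",
                 xlab = "P (m2)", ylab = "flux (um2/s)", ...)
  graphics::lines(x$curve$P, x$curve$Q_t * 1e12, type = "b", col = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("Q_c", "Q_t"), col = 1:2, lty = 1)
  invisible(x)
}

#' @export
plot.chamber_fluid <- function(x, field = c("p_c", "p_a", "p_v"), ...) {
  field <- match.arg(field)
  v <- pa_to_mmhg(x[[field]])
  mesh <- x$mesh
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$tri, 1], ncol = 3)),
                rowMeans(matrix(mesh$nodes[mesh$tri, 2], ncol = 3)))
  vc <- rowMeans(matrix(v[mesh$tri], ncol = 3))
  cols <- grDevices::hcl.colors(64, "viridis")
  ci <- cut(vc, 64, labels = FALSE)
  graphics::plot(cent, col = cols[ci], pch = 15, cex = 0.4, asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("%s (mmHg), range [%.1f, %.1f]",
                                field, min(v), max(v)), ...)
  invisible(x)
}
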