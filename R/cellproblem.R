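# Periodic elliptic cell problems on a regular grid.
#
# The interstitial tensor E comes from a Laplace problem on the interstitium
# with an inhomogeneous Neumann condition on the capillary walls; the
# porous-matrix tensor F comes from the analogous Darcy problem with
# coefficient K and flux conditions on the arteriole/venule boundaries. Both
# reduce to the same discrete operation: solve
#   div( K (grad w + e_j) ) = 0   on the unmasked cells, periodic wrap,
#   zero total normal flux on masked-cell faces,
# and average the flux field v = K (grad w + e_j). The auxiliary potential
# of the continuous formulation is P = -w; the boundary-integral form of the
# tensor is algebraically identical to the flux average used here.
#
# Discretisation: cell-centred two-point finite volumes with harmonic face
# coefficients and periodic wrap; masked cells are removed from the system.
# The scheme's nominal order on smooth inclusions is one (the staircase
# boundary representation dominates the error).

# face lists for an n x m periodic grid restricted to fluid cells
.periodic_cell_solve <- function(coef, mask) {
  mask <- as.matrix(mask)
  n <- nrow(mask); m <- ncol(mask)
  if (all(mask)) stop("vessel mask fills the whole cell: no interstitium left", call. = FALSE)
  hx <- 1 / n; hy <- 1 / m
  id <- matrix(seq_len(n * m), n, m)
  fluid <- !mask
  fid <- matrix(NA_integer_, n, m)
  fid[fluid] <- seq_len(sum(fluid))
  nf <- sum(fluid)
  # coefficient per cell (scalar field)
  if (length(coef) == 1) coef <- matrix(coef, n, m)
  coef <- as.matrix(coef)
  if (any(coef[fluid] <= 0) || any(!is.finite(coef[fluid]))) {
    stop("singular or non-positive coefficient field", call. = FALSE)
  }
  ip1 <- c(2:n, 1); jp1 <- c(2:m, 1)
  # x-faces: between (i,j) and (i+1 mod n, j)
  fc <- function(a, b) 2 * a * b / (a + b)
  faces <- list()
  for (axis in 1:2) {
    if (axis == 1) {
      ca <- id; cb <- id[ip1, , drop = FALSE]
      la <- hy; dist <- hx
    } else {
      ca <- id; cb <- id[, jp1, drop = FALSE]
      la <- hx; dist <- hy
    }
    ok <- fluid & matrix(fluid[cb], n, m)
    a <- ca[ok]; b <- cb[ok]
    kf <- fc(coef[a], coef[b])
    faces[[axis]] <- list(from = fid[a], to = fid[b], t = kf * la / dist,
                          kf = kf, area = la, axis = axis)
  }
  from <- c(faces[[1]]$from, faces[[2]]$from)
  to <- c(faces[[1]]$to, faces[[2]]$to)
  tr <- c(faces[[1]]$t, faces[[2]]$t)
  i <- c(from, to, from, to); j <- c(from, to, to, from)
  v <- c(tr, tr, -tr, -tr)
  A <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nf, nf))
  comp <- .components(nf, from, to)
  ground <- match(unique(comp), comp)
  A <- A + Matrix::sparseMatrix(i = ground, j = ground,
                                x = rep(max(tr) * 4, length(ground)),
                                dims = c(nf, nf))
  V <- 1
  V_t <- sum(fluid) * hx * hy
  tensor <- matrix(0, 2, 2)
  for (dirn in 1:2) {
    rhs <- numeric(nf)
    intg <- c(0, 0)
    for (axis in 1:2) {
      f <- faces[[axis]]
      if (axis == dirn) {
        # driving flux K_f * (e_j . n) through each fluid-fluid face
        drive <- f$kf * f$area
        rhs <- rhs + tapply_add(f$from, drive, nf) - tapply_add(f$to, drive, nf)
      }
    }
    w <- as.numeric(Matrix::solve(A, rhs))
    for (axis in 1:2) {
      f <- faces[[axis]]
      vface <- f$kf * ((w[f$to] - w[f$from]) / (if (axis == 1) hx else hy) +
                         as.numeric(axis == dirn))
      # integral of v_axis over the cell: face value times face-slab volume
      intg[axis] <- sum(vface) * hx * hy
    }
    tensor[, dirn] <- intg / V
  }
  list(bulk = (tensor + t(tensor)) / 2, V_t = V_t, V = V)
}

#' Effective interstitial permeability tensor E from a periodic cell problem
#'
#' Solves the periodic Laplace cell problem on the interstitial subdomain of
#' a unit cell (the vessel cross-sections act as impermeable inclusions with
#' an inhomogeneous Neumann wall condition) and assembles the dimensionless
#' tensor E. Under intrinsic normalisation (default) the flux average is
#' taken over the interstitial volume, matching the 1/V_t definition of the
#' continuum model; under bulk normalisation it is taken over the whole
#' cell, which is the quantity classical effective-medium formulas (e.g.
#' the 2D Maxwell dilute limit (1-phi)/(1+phi) for insulating disks)
#' describe.
#'
#' @param vessel_mask Logical matrix: `TRUE` marks vessel cross-section
#'   cells on a regular periodic grid over the unit cell. The matrix
#'   resolution is the discretisation.
#' @param normalisation `"intrinsic"` (default) or `"bulk"`.
#' @return A `permeability_tensor` (dimensionless), symmetric with
#'   eigenvalues in (0, 1] for a percolating interstitium.
#' @export
interstitial_tensor <- function(vessel_mask,
                                normalisation = c("intrinsic", "bulk")) {
  normalisation <- match.arg(normalisation)
  vessel_mask <- as.matrix(vessel_mask)
  stopifnot(is.logical(vessel_mask))
  sol <- .periodic_cell_solve(1, vessel_mask)
  M <- if (normalisation == "intrinsic") sol$bulk * sol$V / sol$V_t else sol$bulk
  permeability_tensor(M, normalisation = normalisation,
                      label = "interstitial E", units = "dimensionless")
}

#' Effective porous-matrix permeability tensor F
#'
#' Solves the periodic Darcy cell problem on the porous tissue matrix of the
#' arteriole/venule-scale unit cell: coefficient field K (the upscaled
#' capillary permeability), impermeable arteriole/venule inclusions with the
#' corresponding flux wall condition, periodicity and a zero-mean potential
#' constraint (the tensor is invariant to the constant, which is projected
#' out). With K equal to the identity the problem reduces to the
#' interstitial one, so F equals E on the same mask.
#'
#' @param K Capillary permeability on the matrix subdomain (m2): a scalar or
#'   a matrix field with one value per grid cell (isotropic per cell; the
#'   two-point scheme does not support full anisotropy).
#' @param vessel_mask Logical matrix marking arteriole/venule
#'   cross-sections.
#' @param normalisation `"intrinsic"` (default, 1/V_p) or `"bulk"`.
#' @return A `permeability_tensor` in m2.
#' @export
porous_matrix_tensor <- function(K, vessel_mask,
                                 normalisation = c("intrinsic", "bulk")) {
  normalisation <- match.arg(normalisation)
  vessel_mask <- as.matrix(vessel_mask)
  stopifnot(is.logical(vessel_mask))
  sol <- .periodic_cell_solve(K, vessel_mask)
  M <- if (normalisation == "intrinsic") sol$bulk * sol$V / sol$V_t else sol$bulk
  permeability_tensor(M, normalisation = normalisation,
                      label = "porous-matrix F", units = "m2")
}

#' Build a periodic disk-array vessel mask
#'
#' Square array of circular inclusions centred in the cell; the standard
#' benchmark for dilute-limit checks of the cell-problem solver.
#'
#' @param n Grid resolution (n x n).
#' @param area_fraction Target inclusion area fraction.
#' @return Logical n x n matrix.
#' @export
disk_mask <- function(n, area_fraction) {
  stopifnot(n >= 8, area_fraction > 0, area_fraction < 1)
  r <- sqrt(area_fraction / pi)
  xc <- (seq_len(n) - 0.5) / n
  dx <- outer(xc - 0.5, rep(1, n))
  dy <- t(dx)
  dx^2 + dy^2 < r^2
}
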