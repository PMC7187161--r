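# Periodic vessel-network unit cells and Poiseuille-network permeability
# upscaling.
#
# A unit cell is a rectangular box with vessel segments (cylindrical tubes)
# forming a graph that closes periodically on the torus. The effective
# capillary permeability tensor K is obtained by imposing a unit macroscopic
# pressure gradient in each coordinate direction, solving nodal mass balance
# with Poiseuille segment conductances under the periodic jump conditions,
# and averaging the resulting segment fluxes over the cell. This is the
# discrete (network) counterpart of the Stokes unit-cell problem: each
# segment carries fully developed Poiseuille flow, which is the exact Stokes
# solution in a long circular tube.

#' Construct a periodic unit-cell vessel network
#'
#' @param box Numeric length-2: cell dimensions (m). Unit out-of-plane depth
#'   is assumed; segment volume is pi * r^2 * length.
#' @param nodes Numeric matrix (n x 2) of node positions inside the box (m).
#' @param segments Data frame with columns `from`, `to` (node indices),
#'   `radius` (m) and optionally `wrap_x`, `wrap_y` (integer periodic image
#'   shifts applied to the `to` node, so a segment may close across the
#'   cell boundary).
#' @param periodic_pairs Optional 2-column matrix identifying boundary nodes
#'   across opposite faces (each row `(i, j)` merges node `j` onto node `i`
#'   on the torus). Paired nodes must lie on opposite faces with matching
#'   transverse coordinates.
#' @param label Topology name.
#' @return An object of class `unit_cell_network`.
#' @export
unit_cell_network <- function(box, nodes, segments, periodic_pairs = NULL,
                              label = "custom") {
  stopifnot(length(box) == 2, all(box > 0))
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 2)
  segments <- as.data.frame(segments)
  if (is.null(segments$wrap_x)) segments$wrap_x <- 0L
  if (is.null(segments$wrap_y)) segments$wrap_y <- 0L
  stopifnot(all(c("from", "to", "radius") %in% names(segments)))
  nseg <- nrow(segments)
  if (nseg == 0) stop("network must contain at least one segment", call. = FALSE)
  stopifnot(all(segments$from >= 1), all(segments$to >= 1),
            all(segments$from <= nrow(nodes)), all(segments$to <= nrow(nodes)))
  dx <- nodes[segments$to, 1] + segments$wrap_x * box[1] - nodes[segments$from, 1]
  dy <- nodes[segments$to, 2] + segments$wrap_y * box[2] - nodes[segments$from, 2]
  segments$length <- sqrt(dx^2 + dy^2)
  if (any(segments$length <= 0)) stop("every segment must have positive length", call. = FALSE)
  if (any(segments$radius <= 0)) stop("every segment radius must be positive", call. = FALSE)
  if (any(segments$radius >= segments$length)) {
    stop("segment radius must be smaller than its length", call. = FALSE)
  }
  if (!is.null(periodic_pairs)) {
    periodic_pairs <- as.matrix(periodic_pairs)
    stopifnot(ncol(periodic_pairs) == 2)
    tol <- 1e-9 * max(box)
    for (k in seq_len(nrow(periodic_pairs))) {
      i <- periodic_pairs[k, 1]; j <- periodic_pairs[k, 2]
      dif <- abs(nodes[i, ] - nodes[j, ])
      on_x <- abs(dif[1] - box[1]) < tol && dif[2] < tol
      on_y <- abs(dif[2] - box[2]) < tol && dif[1] < tol
      if (!on_x && !on_y) {
        stop("periodic pair (", i, ", ", j,
             ") does not lie on opposite faces with matching transverse coordinates",
             call. = FALSE)
      }
    }
    ids <- c(periodic_pairs)
    if (anyDuplicated(ids)) stop("periodic pairing must be an involution", call. = FALSE)
  }
  net <- list(box = box, nodes = nodes, segments = segments,
              periodic_pairs = periodic_pairs, label = label)
  class(net) <- "unit_cell_network"
  net
}

#' @export
print.unit_cell_network <- function(x, ...) {
  cat(sprintf("Periodic unit-cell network '%s': %d nodes, %d segments, box %.3g x %.3g m\n",
              x$label, nrow(x$nodes), nrow(x$segments), x$box[1], x$box[2]))
  vr <- tryCatch(volume_ratio(x), error = function(e) NULL)
  if (!is.null(vr)) {
    cat(sprintf("  vessel volume fraction %.4f (V_t/V_c = %.4f)\n",
                1 - vr$n_t, vr$Vt_over_Vc))
  }
  invisible(x)
}

#' Poiseuille volumetric conductance of a cylindrical segment
#'
#' q = g * (delta p) with g = pi r^4 / (8 mu l): the exact Stokes-flow
#' conductance of a circular tube.
#'
#' @param radius Tube radius (m).
#' @param length Tube length (m).
#' @param mu Viscosity (kg m-1 s-1).
#' @return Conductance (m3 Pa-1 s-1).
#' @export
poiseuille_conductance <- function(radius, length, mu) {
  .check_positive(radius, length, mu)
  pi * radius^4 / (8 * mu * length)
}

# Merge periodic pairs into torus node identifications and express every
# segment against representative nodes with an explicit geometric offset.
.torus_graph <- function(cell) {
  nodes <- cell$nodes
  seg <- cell$segments
  box <- cell$box
  rep_of <- seq_len(nrow(nodes))
  if (!is.null(cell$periodic_pairs)) {
    for (k in seq_len(nrow(cell$periodic_pairs))) {
      i <- cell$periodic_pairs[k, 1]; j <- cell$periodic_pairs[k, 2]
      rep_of[rep_of == rep_of[j]] <- rep_of[i]
    }
  }
  from <- rep_of[seg$from]
  to <- rep_of[seg$to]
  # geometric segment vector uses the ORIGINAL endpoint coordinates
  dx <- nodes[seg$to, 1] + seg$wrap_x * box[1] - nodes[seg$from, 1]
  dy <- nodes[seg$to, 2] + seg$wrap_y * box[2] - nodes[seg$from, 2]
  keep <- sort(unique(c(from, to)))
  idx <- match(from, keep); jdx <- match(to, keep)
  periodic <- any(seg$wrap_x != 0 | seg$wrap_y != 0) || !is.null(cell$periodic_pairs)
  # integer winding of each edge on the torus (accounts for pair merges)
  wind_x <- round((nodes[seg$to, 1] + seg$wrap_x * box[1] - nodes[to, 1]) / box[1] -
                  (nodes[seg$from, 1] - nodes[from, 1]) / box[1])
  wind_y <- round((nodes[seg$to, 2] + seg$wrap_y * box[2] - nodes[to, 2]) / box[2] -
                  (nodes[seg$from, 2] - nodes[from, 2]) / box[2])
  list(nnode = length(keep), from = idx, to = jdx, dx = dx, dy = dy,
       radius = seg$radius, length = seg$length, periodic = periodic,
       wind = cbind(wind_x, wind_y))
}

.components <- function(nnode, from, to) {
  comp <- seq_len(nnode)
  repeat {
    m <- pmin(comp[from], comp[to])
    agg <- tapply(c(m, m), c(from, to), min)
    new <- comp
    idx <- as.integer(names(agg))
    new[idx] <- pmin(new[idx], agg)
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

#' Effective permeability tensor of a periodic vessel network
#'
#' For each unit macroscopic pressure gradient e_j (1 Pa/m), solves nodal
#' mass balance with Poiseuille conductances under the periodic jump
#' condition, then averages segment fluxes to the Darcy tensor
#' K[i, j] = -mu * <u_i> under gradient e_j. Intrinsic normalisation divides
#' the flux average by the vessel volume V_c (the tensor of the unit-cell
#' average over the capillary domain); bulk normalisation divides by the
#' full cell volume.
#'
#' @param cell A [unit_cell_network()].
#' @param mu Viscosity (kg m-1 s-1). The result is independent of `mu`
#'   (it cancels between conductance and Darcy law) but is accepted for
#'   interface symmetry.
#' @param normalisation `"intrinsic"` (default) or `"bulk"`.
#' @return A `permeability_tensor`: a 2x2 symmetric matrix (m2) with
#'   attributes `normalisation` and `label`. A direction with no percolating
#'   path yields a zero column, with a warning.
#' @export
network_permeability <- function(cell, mu = 4e-3,
                                 normalisation = c("intrinsic", "bulk")) {
  stopifnot(inherits(cell, "unit_cell_network"))
  normalisation <- match.arg(normalisation)
  .check_positive(mu)
  tg <- .torus_graph(cell)
  if (!tg$periodic) {
    stop("network is not periodic: no wrapped segments or periodic pairs", call. = FALSE)
  }
  g <- pi * tg$radius^4 / (8 * mu * tg$length)
  nn <- tg$nnode
  comp <- .components(nn, tg$from, tg$to)
  # graph Laplacian with one grounded node per connected component
  i <- c(tg$from, tg$to, tg$from, tg$to)
  j <- c(tg$from, tg$to, tg$to, tg$from)
  v <- c(g, g, -g, -g)
  L <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nn, nn))
  ground <- match(unique(comp), comp)
  diag_fix <- Matrix::sparseMatrix(i = ground, j = ground,
                                   x = rep(max(g) * nn, length(ground)),
                                   dims = c(nn, nn))
  A <- L + diag_fix
  V_c <- sum(pi * tg$radius^2 * tg$length)
  V_norm <- if (normalisation == "intrinsic") V_c else prod(cell$box)
  K <- matrix(0, 2, 2)
  D <- cbind(tg$dx, tg$dy)
  for (dir in 1:2) {
    rhs <- numeric(nn)
    drive <- g * D[, dir]           # G . dx per segment, G = e_dir
    # sum at `from` of +drive, at `to` of -drive (from L p = rhs)
    rhs <- rhs + tapply_add(tg$from, drive, nn) - tapply_add(tg$to, drive, nn)
    p <- as.numeric(Matrix::solve(A, rhs))
    q <- g * (p[tg$from] - p[tg$to] - D[, dir])   # flow from->to under total pressure
    flux <- colSums(q * D)                         # integral of u over vessels
    K[, dir] <- -mu * flux / V_norm
  }
  K <- (K + t(K)) / 2
  scale_ref <- max(abs(K), max(tg$radius)^2)
  for (dir in 1:2) {
    if (max(abs(K[, dir])) < 1e-12 * scale_ref) {
      K[, dir] <- 0; K[dir, ] <- 0
      warning("no percolating path in direction ", dir, "; zero column returned",
              call. = FALSE)
    }
  }
  permeability_tensor(K, normalisation = normalisation, label = cell$label)
}

tapply_add <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Construct a permeability tensor object
#'
#' @param matrix A symmetric 2x2 (or 3x3) matrix; symmetrised on input.
#' @param normalisation `"intrinsic"` or `"bulk"`.
#' @param label Descriptive label.
#' @param units Units string (default `"m2"`; the interstitial tensor E is
#'   dimensionless).
#' @return A `permeability_tensor` object.
#' @export
permeability_tensor <- function(matrix, normalisation = "intrinsic",
                                label = "", units = "m2") {
  m <- (matrix + t(matrix)) / 2
  structure(m, class = c("permeability_tensor", "matrix"),
            normalisation = normalisation, label = label, units = units)
}

#' @export
print.permeability_tensor <- function(x, ...) {
  cat(sprintf("Permeability tensor (%s, %s normalisation)%s\n",
              attr(x, "units"), attr(x, "normalisation"),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else ""))
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Interstitial-to-vessel volume ratio of a unit cell
#'
#' @param cell A [unit_cell_network()].
#' @return List with `Vt_over_Vc` (interstitial over vessel volume) and
#'   `n_t = V_t / (V_t + V_c)`, the interstitial volume fraction used as the
#'   initial condition of the cell-kill dynamics.
#' @export
volume_ratio <- function(cell) {
  stopifnot(inherits(cell, "unit_cell_network"))
  V <- prod(cell$box)
  V_c <- sum(pi * cell$segments$radius^2 * cell$segments$length)
  if (V_c <= 0) stop("zero vessel volume", call. = FALSE)
  if (V_c >= V) stop("vessel volume exceeds cell volume", call. = FALSE)
  V_t <- V - V_c
  list(Vt_over_Vc = V_t / V_c, n_t = V_t / (V_t + V_c))
}

#' Interstitial volume fraction from a tabulated V_t/V_c ratio
#'
#' @param Vt_over_Vc Interstitial-to-vessel volume ratio.
#' @return n_t = x / (1 + x).
#' @export
n_t_from_ratio <- function(Vt_over_Vc) {
  stopifnot(all(Vt_over_Vc > 0))
  Vt_over_Vc / (1 + Vt_over_Vc)
}

#' Reported interstitial-to-vessel volume ratios of the explicit networks
#'
#' Named vector of V_t/V_c for the eight explicit unit-cell topologies of
#' the case study, as reported with the original chamber simulations. Used
#' as initial-condition inputs for the treatment comparison.
#' @return Named numeric vector.
#' @export
table2_volume_ratios <- function() {
  c(grid1 = 1.6933, grid2 = 2.4458, grid3 = 3.6812, grid = 4.2632,
    irregular2 = 4.4358, irregular1 = 6.0295, grid4 = 6.0571,
    hexagonal = 6.5651)
}

# ---- fixture topologies -----------------------------------------------------

# Square-lattice cell: m x m interior nodes, full horizontal and vertical
# links closing periodically by wrap. Pruned variants grid1..grid4 remove
# links progressively in the documented order below (chosen to keep both
# directions percolating through row 3 / column 3).
.grid_removals <- list(
  grid1 = list(c("H", 2, 2)),
  grid2 = list(c("H", 2, 2), c("V", 2, 2)),
  grid3 = list(c("H", 2, 2), c("V", 2, 2), c("H", 1, 1)),
  grid4 = list(c("H", 2, 2), c("V", 2, 2), c("H", 1, 1), c("V", 1, 1))
)

.make_grid_cell <- function(d, radius, m = 3L, removals = NULL, label = "grid",
                            jitter = NULL, extra = NULL) {
  box <- c(m * d, m * d)
  idx <- function(i, j) (j - 1L) * m + i
  nodes <- matrix(0, m * m, 2)
  for (j in seq_len(m)) for (i in seq_len(m)) {
    nodes[idx(i, j), ] <- c((i - 0.5) * d, (j - 0.5) * d)
  }
  if (!is.null(jitter)) nodes <- nodes + jitter
  segs <- list()
  key <- function(type, i, j) paste(type, i, j)
  removed <- vapply(removals, function(r) key(r[1], as.integer(r[2]), as.integer(r[3])), "")
  for (j in seq_len(m)) for (i in seq_len(m)) {
    # horizontal link (i,j) -> (i+1,j)
    if (!(key("H", i, j) %in% removed)) {
      ii <- if (i == m) 1L else i + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        from = idx(i, j), to = idx(ii, j), radius = radius,
        wrap_x = if (i == m) 1L else 0L, wrap_y = 0L)
    }
    if (!(key("V", i, j) %in% removed)) {
      jj <- if (j == m) 1L else j + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        from = idx(i, j), to = idx(i, jj), radius = radius,
        wrap_x = 0L, wrap_y = if (j == m) 1L else 0L)
    }
  }
  segments <- do.call(rbind, c(segs, extra))
  unit_cell_network(box, nodes, segments, label = label)
}

.make_hexagonal_cell <- function(d, radius) {
  a <- d / sqrt(3)   # edge length so the horizontal lattice period equals d
  box <- c(sqrt(3) * a, 3 * a)
  off <- c(sqrt(3) * a / 4, a / 4)
  A1 <- off
  B1 <- A1 + c(0, a)
  A2 <- A1 + c(sqrt(3) * a / 2, 3 * a / 2)
  B2 <- A2 + c(0, a)
  nodes <- rbind(A1, B1, A2, B2)
  segments <- data.frame(
    from   = c(1, 2, 2, 3, 4, 4),
    to     = c(2, 3, 3, 4, 1, 1),
    radius = radius,
    wrap_x = c(0L, 0L, -1L, 0L, 0L, 1L),
    wrap_y = c(0L, 0L, 0L, 0L, 1L, 1L))
  unit_cell_network(box, nodes, segments, label = "hexagonal")
}

#' Construct one of the explicit unit-cell network fixtures
#'
#' Deterministic generators for the eight benchmark topologies: a square
#' `grid` (3x3 lattice), a `hexagonal` honeycomb, two irregular variants and
#' the pruned grids `grid1`..`grid4` formed by progressively removing one
#' link each (removal order fixed in the fixture metadata; inlets/outlets
#' are identical to the grid). Vessel radii are not part of the published
#' geometries, so `radius` is a parameter with a documented default of
#' one tenth of the spacing.
#'
#' @param name One of `"grid"`, `"hexagonal"`, `"irregular1"`,
#'   `"irregular2"`, `"grid1"`, `"grid2"`, `"grid3"`, `"grid4"`.
#' @param d Characteristic vessel spacing (m). Default 50e-6.
#' @param radius Vessel radius (m). Default `d / 10`.
#' @return A [unit_cell_network()], with pruned grids carrying a
#'   `removed_links` attribute documenting the removal order.
#' @export
make_fixture_network <- function(name, d = 50e-6, radius = d / 10) {
  .check_positive(d, radius)
  name <- match.arg(name, c("grid", "hexagonal", "irregular1", "irregular2",
                            "grid1", "grid2", "grid3", "grid4"))
  cell <- switch(name,
    grid = .make_grid_cell(d, radius),
    hexagonal = .make_hexagonal_cell(d, radius),
    grid1 = ,
    grid2 = ,
    grid3 = ,
    grid4 = .make_grid_cell(d, radius, removals = .grid_removals[[name]], label = name),
    irregular1 = {
      extra <- list(
        data.frame(from = 1L, to = 5L, radius = radius, wrap_x = 0L, wrap_y = 0L),
        data.frame(from = 5L, to = 9L, radius = radius, wrap_x = 0L, wrap_y = 0L))
      .make_grid_cell(d, radius,
                      removals = list(c("H", 2, 2), c("V", 2, 2)),
                      label = "irregular1", extra = extra)
    },
    irregular2 = {
      # fixed documented jitter (fractions of d), deterministic
      jit <- d * 0.12 * matrix(c(
         1, -1,  0,  1, -1,  0,  1,  0, -1,
        -1,  0,  1, -1,  1,  0,  0,  1, -1), ncol = 2)
      .make_grid_cell(d, radius, jitter = jit, label = "irregular2")
    })
  if (name %in% names(.grid_removals)) {
    attr(cell, "removed_links") <- vapply(.grid_removals[[name]],
                                          paste, character(1), collapse = "-")
  }
  cell
}

#' Check percolation of a unit cell in each coordinate direction
#'
#' A direction percolates when the torus graph contains a cycle with
#' non-zero winding number in that direction. Connectivity is reported, not
#' assumed, for pruned networks.
#'
#' @param cell A [unit_cell_network()].
#' @return Logical length-2 vector (x, y).
#' @export
percolates <- function(cell) {
  tg <- .torus_graph(cell)
  out <- c(x = FALSE, y = FALSE)
  # BFS from each node tracking cumulative winding
  nn <- tg$nnode
  adj <- vector("list", nn)
  wq <- tg$wind
  for (k in seq_along(tg$from)) {
    adj[[tg$from[k]]] <- rbind(adj[[tg$from[k]]], c(tg$to[k], wq[k, ]))
    adj[[tg$to[k]]] <- rbind(adj[[tg$to[k]]], c(tg$from[k], -wq[k, ]))
  }
  for (dir in 1:2) {
    seen <- rep(NA_real_, nn)
    found <- FALSE
    for (start in seq_len(nn)) {
      if (!is.na(seen[start])) next
      seen[start] <- 0
      queue <- list(start)
      while (length(queue) && !found) {
        u <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[u]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
          v <- nb[r, 1]; w <- seen[u] + nb[r, 1 + dir]
          if (is.na(seen[v])) {
            seen[v] <- w
            queue[[length(queue) + 1L]] <- v
          } else if (abs(seen[v] - w) > 0.5) {
            found <- TRUE; break
          }
        }
      }
      if (found) break
    }
    out[dir] <- found
  }
  out
}

#' Serialise a unit cell to JSON
#' @param cell A [unit_cell_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_cell <- function(cell, path) {
  stopifnot(inherits(cell, "unit_cell_network"))
  obj <- list(box = cell$box,
              nodes = unname(as.matrix(cell$nodes)),
              segments = cell$segments[, c("from", "to", "radius", "wrap_x", "wrap_y")],
              periodic_pairs = if (is.null(cell$periodic_pairs)) NULL else
                unname(as.matrix(cell$periodic_pairs)),
              label = cell$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a unit cell from JSON
#' @param path Path written by [write_unit_cell()].
#' @return A [unit_cell_network()].
#' @export
read_unit_cell <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- obj$periodic_pairs
  if (is.null(pairs) || length(pairs) == 0) pairs <- NULL
  unit_cell_network(box = obj$box, nodes = obj$nodes,
                    segments = obj$segments,
                    periodic_pairs = pairs,
                    label = obj$label)
}

# rotate a cell by 90 degrees counter-clockwise (testing utility)
.rotate_cell_90 <- function(cell) {
  nodes <- cbind(cell$box[2] - cell$nodes[, 2], cell$nodes[, 1])
  seg <- cell$segments
  seg2 <- data.frame(from = seg$from, to = seg$to, radius = seg$radius,
                     wrap_x = -seg$wrap_y, wrap_y = seg$wrap_x)
  unit_cell_network(rev(cell$box), nodes, seg2, label = paste0(cell$label, "-rot90"))
}
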