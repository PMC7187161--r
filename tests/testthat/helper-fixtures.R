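# Shared fixtures, built once per run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

default_params <- function() {
  if (is.null(.fix$params)) .fix$params <- model_parameters()
  .fix$params
}

coarse_mesh <- function() {
  if (is.null(.fix$mesh)) {
    .fix$mesh <- mesh_chamber(build_geometry(default_params()),
                              n_theta = 48, n_inner = 8, n_outer = 12)
  }
  .fix$mesh
}

coarse_fluid <- function(P1 = 1e-12) {
  key <- paste0("fluid_", format(P1))
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- solve_pressures(coarse_mesh(), default_params(), P_region1 = P1)
  }
  .fix[[key]]
}

# a deliberately asymmetric random periodic network on the torus
random_network <- function(seed, n_nodes = 6) {
  set.seed(seed)
  repeat {
    box <- c(1, 1) * 1e-4
    nodes <- cbind(runif(n_nodes, 0.1, 0.9) * box[1],
                   runif(n_nodes, 0.1, 0.9) * box[2])
    from <- sample(n_nodes, n_nodes + 2, replace = TRUE)
    to <- sample(n_nodes, n_nodes + 2, replace = TRUE)
    keep <- from != to
    segs <- data.frame(from = from[keep], to = to[keep], radius = 2e-6,
                       wrap_x = sample(-1:1, sum(keep), replace = TRUE),
                       wrap_y = sample(-1:1, sum(keep), replace = TRUE))
    # ensure periodic closure in both directions
    segs <- rbind(segs,
                  data.frame(from = 1, to = 1, radius = 2e-6, wrap_x = 1L, wrap_y = 0L),
                  data.frame(from = 2, to = 2, radius = 2e-6, wrap_x = 0L, wrap_y = 1L))
    cell <- tryCatch(unit_cell_network(box, nodes, segs, label = paste0("rand", seed)),
                     error = function(e) NULL)
    if (!is.null(cell)) return(cell)
  }
}

expect_psd <- function(M, tol = 1e-10) {
  M <- array(as.numeric(M), dim = dim(M))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev >= -tol * max(abs(ev), 1e-300)))
}

# strip class and descriptive attributes for numeric comparison
plain <- function(M) array(as.numeric(M), dim = dim(M))
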