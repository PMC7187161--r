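test_that("Poiseuille conductance follows the quartic tube law", {
  g <- poiseuille_conductance(5e-6, 50e-6, 4e-3)
  expect_equal(g, pi * (5e-6)^4 / (8 * 4e-3 * 50e-6), tolerance = 1e-14)
  expect_equal(g, 1.227e-15, tolerance = 1e-3)
  expect_equal(poiseuille_conductance(10e-6, 50e-6, 4e-3), 16 * g)
  expect_equal(poiseuille_conductance(5e-6, 100e-6, 4e-3), g / 2)
  expect_error(poiseuille_conductance(-1e-6, 50e-6, 4e-3), "invalid parameter")
})

test_that("a single spanning tube reproduces the analytic intrinsic permeability", {
  d <- 50e-6; r <- 5e-6
  tube <- unit_cell_network(c(d, d),
                            rbind(c(0, d / 2), c(d, d / 2)),
                            data.frame(from = 1, to = 2, radius = r),
                            periodic_pairs = rbind(c(1, 2)), label = "tube")
  K <- suppressWarnings(network_permeability(tube))
  expect_equal(K[1, 1], r^2 / 8, tolerance = 1e-12)
  expect_equal(K[2, 2], 0)
  expect_equal(K[1, 2], 0)
  # result independent of viscosity
  K2 <- suppressWarnings(network_permeability(tube, mu = 1e-2))
  expect_equal(plain(K2), plain(K), tolerance = 1e-12)
})

test_that("hexagonal cell gives an isotropic diagonal tensor", {
  K <- network_permeability(make_fixture_network("hexagonal"))
  expect_equal(K[1, 2], 0, tolerance = 1e-15 * K[1, 1])
  expect_equal(K[1, 1], K[2, 2], tolerance = 1e-10)
  expect_psd(K)
})

test_that("all fixture networks yield symmetric PSD tensors and percolate", {
  for (nm in c("grid", "hexagonal", "irregular1", "irregular2",
               "grid1", "grid2", "grid3", "grid4")) {
    cell <- make_fixture_network(nm)
    K <- suppressWarnings(network_permeability(cell))
    expect_equal(plain(K), t(plain(K)), info = nm)
    expect_psd(K)
    expect_true(all(percolates(cell)), info = nm)
  }
})

test_that("pruned grids lose exactly one link per level and conductance is monotone", {
  nseg <- function(nm) nrow(make_fixture_network(nm)$segments)
  expect_equal(nseg("grid1"), nseg("grid") - 1)
  expect_equal(nseg("grid2"), nseg("grid") - 2)
  expect_equal(nseg("grid3"), nseg("grid") - 3)
  expect_equal(nseg("grid4"), nseg("grid") - 4)
  expect_false(is.null(attr(make_fixture_network("grid3"), "removed_links")))
  # removing links never increases BULK-normalised permeability
  tr <- function(nm) sum(diag(plain(
    suppressWarnings(network_permeability(make_fixture_network(nm),
                                          normalisation = "bulk")))))
  vals <- vapply(c("grid", "grid1", "grid2", "grid3", "grid4"), tr, 0)
  expect_true(all(diff(vals) <= 1e-25))
})

test_that("network tensors transform equivariantly under 90-degree rotation", {
  R <- matrix(c(0, 1, -1, 0), 2)
  for (seed in 1:5) {
    cell <- random_network(seed)
    K1 <- suppressWarnings(network_permeability(cell))
    K2 <- suppressWarnings(network_permeability(tumourperf:::.rotate_cell_90(cell)))
    expect_equal(plain(K2), R %*% plain(K1) %*% t(R),
                 tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("non-periodic networks are rejected; dead directions give zero columns", {
  d <- 50e-6
  open_net <- unit_cell_network(c(d, d),
                                rbind(c(0.2 * d, d / 2), c(0.8 * d, d / 2)),
                                data.frame(from = 1, to = 2, radius = 2e-6))
  expect_error(network_permeability(open_net), "not periodic")
  tube <- unit_cell_network(c(d, d), rbind(c(0, d / 2), c(d, d / 2)),
                            data.frame(from = 1, to = 2, radius = 5e-6),
                            periodic_pairs = rbind(c(1, 2)))
  expect_warning(K <- network_permeability(tube), "no percolating path")
  expect_equal(K[2, 2], 0)
})

test_that("volume ratios and n_t behave as x/(1+x)", {
  expect_equal(n_t_from_ratio(1), 0.5)
  expect_equal(n_t_from_ratio(6.5651), 0.8678, tolerance = 1e-4)
  expect_equal(n_t_from_ratio(1.6933), 0.6287, tolerance = 1e-4)
  d <- 50e-6; r <- 5e-6
  tube <- unit_cell_network(c(d, d), rbind(c(0, d / 2), c(d, d / 2)),
                            data.frame(from = 1, to = 2, radius = r),
                            periodic_pairs = rbind(c(1, 2)))
  vr <- volume_ratio(tube)
  V <- d * d; Vc <- pi * r^2 * d
  expect_equal(vr$Vt_over_Vc, (V - Vc) / Vc, tolerance = 1e-12)
  expect_equal(vr$n_t, (V - Vc) / V, tolerance = 1e-12)
  tab <- table2_volume_ratios()
  expect_length(tab, 8)
  expect_true(all(diff(unname(tab)) > 0))
})

test_that("unit cells serialise to JSON and round-trip", {
  cell <- make_fixture_network("grid2")
  f <- withr::local_tempfile(fileext = ".json")
  write_unit_cell(cell, f)
  back <- read_unit_cell(f)
  expect_equal(back$nodes, cell$nodes, ignore_attr = TRUE)
  expect_equal(back$segments$length, cell$segments$length)
  K1 <- suppressWarnings(network_permeability(cell))
  K2 <- suppressWarnings(network_permeability(back))
  expect_equal(plain(K1), plain(K2), tolerance = 1e-14)
})

test_that("degenerate segment geometry is rejected", {
  d <- 50e-6
  expect_error(unit_cell_network(c(d, d), rbind(c(0, 0), c(0, 0)),
                                 data.frame(from = 1, to = 2, radius = 1e-6)),
               "positive length")
  expect_error(unit_cell_network(c(d, d), rbind(c(0, 0), c(2e-6, 0)),
                                 data.frame(from = 1, to = 2, radius = 5e-6)),
               "radius must be smaller")
})
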