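test_that("default geometry reproduces the tumour-region area and validates overrides", {
  p <- default_params()
  geo <- build_geometry(p)
  expect_equal(pi * geo$region1_radius^2, 0.4948e-4, tolerance = 1e-10)
  expect_error(build_geometry(p, region1_radius = p$L / 2), "strictly inside")
  expect_error(build_geometry(p, vessel_offset = c(3.5e-3, 0)), "inside region 1")
  expect_error(build_geometry(p, vessel_radius = -1), "invalid parameter")
})

test_that("mesh tags cover the domain and refine as expected", {
  p <- default_params()
  geo <- build_geometry(p)
  msh <- coarse_mesh()
  target <- p$L^2 - pi * geo$vessel_radius^2
  expect_lt(abs(sum(msh$area) - target) / target, 0.005)
  a1 <- sum(msh$area[msh$region == 1L])
  a1_target <- pi * (geo$region1_radius^2 - geo$vessel_radius^2)
  expect_lt(abs(a1 - a1_target) / a1_target, 0.005)
  # halving h (doubling every resolution parameter) roughly quadruples elements
  msh2 <- mesh_chamber(geo, n_theta = 96, n_inner = 16, n_outer = 24)
  expect_equal(nrow(msh2$tri) / nrow(msh$tri), 4, tolerance = 0.01)
  # every Gamma edge separates a region-1 element from a region-2 element
  tri <- msh$tri; region <- msh$region
  gset <- rep(FALSE, nrow(msh$nodes)); gset[msh$gamma_nodes] <- TRUE
  for (r in seq_len(nrow(msh$gamma_edges))) {
    a <- msh$gamma_edges[r, 1]; b <- msh$gamma_edges[r, 2]
    touch <- which((tri[, 1] == a | tri[, 2] == a | tri[, 3] == a) &
                     (tri[, 1] == b | tri[, 2] == b | tri[, 3] == b))
    expect_setequal(region[touch], c(1L, 2L))
  }
})

test_that("pressure fields obey the maximum principle and the Dirichlet data", {
  p <- default_params()
  for (P1 in c(1e-14, 1e-12, 1e-10)) {
    sol <- coarse_fluid(P1)
    lo <- p$p_vein - 1e-6; hi <- p$p_artery + 1e-6
    for (f in list(sol$p_a, sol$p_v, sol$p_c)) {
      expect_gte(min(f), lo)
      expect_lte(max(f), hi)
    }
    expect_equal(sol$p_a[sol$mesh$artery_nodes], rep(p$p_artery, 24), tolerance = 1e-12)
    expect_equal(sol$p_v[sol$mesh$vein_nodes], rep(p$p_vein, 24), tolerance = 1e-12)
    expect_identical(sol$p_t, sol$p_c)
  }
})

test_that("capillary pressure relaxes to the inter-vessel background away from the arcs", {
  sol <- coarse_fluid(1e-14)
  # strong-coupling background: midway between artery and vein pressures
  bg <- pa_to_mmhg(stats::median(sol$p_c))
  expect_gt(bg, 29); expect_lt(bg, 31.5)
})

test_that("global flux balance: artery inflow matches vein outflow", {
  bf <- boundary_fluxes(coarse_fluid(1e-12))
  expect_gt(bf$artery_in, 0)
  expect_gt(bf$vein_out, 0)
  expect_lt(abs(bf$artery_in - bf$vein_out) / bf$artery_in, 0.01)
})

test_that("Q_t equals (eta C / P) Q_c to machine precision and matches edge quadrature", {
  p <- default_params()
  for (P1 in c(1e-13, 9.36e-12)) {
    fl <- interface_fluxes(coarse_fluid(P1))
    eta <- p$s / p$L
    expect_equal(fl$Q_t, (eta * p$C / P1) * fl$Q_c, tolerance = 1e-14)
    # discrete divergence identity vs direct edge quadrature
    expect_equal(fl$Q_c_edge, fl$Q_c, tolerance = 0.2)
  }
})

test_that("uniform pressure implies zero velocity; velocity prefactors are honoured", {
  p <- default_params()
  sol <- coarse_fluid(1e-12)
  v <- velocities(sol)
  eta <- p$s / p$L
  # u_t / u_c = eta C / P elementwise wherever the gradient is nonzero
  P_elem <- ifelse(sol$mesh$region == 1L, sol$P_region1, sol$P_region2)
  expect_equal(v$u_t, v$u_c * (eta * p$C / P_elem), tolerance = 1e-10)
  big <- which.max(abs(v$u_c[, 1]))
  expect_equal(v$u_t[big, 1] / v$u_c[big, 1], eta * p$C / P_elem[big],
               tolerance = 1e-10)
  # uniform field -> zero gradient
  gz <- tumourperf:::.elem_grad(sol$mesh, rep(3, nrow(sol$mesh$nodes)))
  expect_lt(max(abs(gz)), 1e-9)
})

test_that("zero exchange coupling is rejected with the capillary null space named", {
  expect_error(
    solve_pressures(coarse_mesh(), default_params(), P_region1 = 1e-12,
                    coupling = list(gamma_a = 0, gamma_v = 0, beta = 0)),
    "null space")
})

test_that("reflection through the vessel axis swaps artery and vein solutions", {
  p <- default_params()
  geo <- build_geometry(p, vessel_offset = c(0, 0))
  msh <- mesh_chamber(geo, n_theta = 48, n_inner = 8, n_outer = 12)
  sol <- solve_pressures(msh, p, P_region1 = 1e-12)
  nod <- msh$nodes
  refl <- cbind(nod[, 1], p$L - nod[, 2])
  key <- function(m) paste(round(m[, 1], 12), round(m[, 2], 12))
  idx <- match(key(refl), key(nod))
  expect_false(anyNA(idx))
  tot <- p$p_artery + p$p_vein
  expect_equal(sol$p_a[idx], tot - sol$p_v, tolerance = 1e-8 * tot)
  expect_equal(sol$p_c[idx], tot - sol$p_c, tolerance = 1e-8 * tot)
})

test_that("interface flux converges at second order under mesh refinement", {
  # run at the region-2 P value, where the capillary boundary layers are
  # thick enough to be resolved on every mesh of the refinement triple
  p <- default_params()
  geo <- build_geometry(p)
  qc <- sapply(list(c(48, 8, 12), c(96, 16, 24), c(192, 32, 48)), function(r) {
    m <- mesh_chamber(geo, n_theta = r[1], n_inner = r[2], n_outer = r[3])
    interface_fluxes(solve_pressures(m, p, P_region1 = 9.36e-12))$Q_c
  })
  e1 <- abs(qc[1] - qc[3]); e2 <- abs(qc[2] - qc[3])
  order_obs <- log2(e1 / e2)
  expect_gt(order_obs, 1.5)
})

test_that("the P sweep is unimodal with an interior maximum and a sign change", {
  p <- default_params()
  sw <- sweep_P(coarse_mesh(), p, 10^seq(-16, -10.5, length.out = 15),
                refine = TRUE)
  qc <- sw$curve$Q_c
  i <- which.max(qc)
  expect_gt(i, 1); expect_lt(i, length(qc))
  # single sign change of the first differences (unimodal)
  d <- diff(qc)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  expect_gt(qc[1], 0)                      # small positive at smallest P
  expect_lt(qc[length(qc)], 0)             # negative at large P
  expect_true(is.finite(sw$P_signchange))
  expect_gt(sw$P_opt, min(sw$curve$P)); expect_lt(sw$P_opt, max(sw$curve$P))
  expect_gte(sw$Q_c_opt, max(qc))
})

test_that("sweep argmax is invariant under rescaling all boundary pressures", {
  p <- default_params()
  p2 <- model_parameters(p_artery_mmHg = 100, p_vein_mmHg = 20)
  Ps <- 10^seq(-14, -11, length.out = 7)
  s1 <- sweep_P(coarse_mesh(), p, Ps, refine = FALSE)
  s2 <- sweep_P(coarse_mesh(), p2, Ps, refine = FALSE)
  expect_equal(which.max(s1$curve$Q_c), which.max(s2$curve$Q_c))
  expect_equal(s2$curve$Q_c / s1$curve$Q_c, rep(2, 7), tolerance = 1e-10)
})
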