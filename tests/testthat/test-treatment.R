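test_that("the kill-rate law is saturating with the documented half-maximum", {
  kp <- kill_parameters()
  expect_equal(kill_rate(2, kp), (1 / 24) / 2)
  expect_equal(kill_rate(0, kp), 0)
  expect_equal(kill_rate(1e9, kp), 1 / 24, tolerance = 1e-8)
  expect_true(all(diff(kill_rate(seq(0, 50, by = 0.5), kp)) > 0))
  expect_error(kill_rate(-1, kp), "negative")
  expect_error(kill_parameters(rho1 = 0), "invalid parameter")
})

test_that("phi follows the closed form for zero and constant exposure", {
  msh <- coarse_mesh()
  nn <- nrow(msh$nodes)
  times <- seq(0, 200, length.out = 41)
  kp <- kill_parameters(K = 1 / 31)
  # zero drug: pure exponential growth at rate K
  exposure0 <- list(times_h = times, c_c = matrix(0, nn, length(times)))
  phi0 <- evolve_phi(exposure0, kp, phi0 = 0.7, mesh = msh)
  expect_equal(phi0$phi_av, 0.7 * exp(kp$K * times), tolerance = 1e-10)
  # constant c: growth at K - M(c)
  cc <- 5
  exposure1 <- list(times_h = times, c_c = matrix(cc, nn, length(times)))
  phi1 <- evolve_phi(exposure1, kp, phi0 = 0.7, mesh = msh)
  rate <- kp$K - kill_rate(cc, kp)
  expect_equal(phi1$phi_av, 0.7 * exp(rate * times), tolerance = 1e-6)
})

test_that("time-varying uniform exposure matches quadrature of the growth integral", {
  msh <- coarse_mesh()
  nn <- nrow(msh$nodes)
  times <- seq(0, 100, length.out = 801)
  ct <- 6 * exp(-times / 25)           # decaying uniform exposure
  kp <- kill_parameters(K = 1 / 29)
  exposure <- list(times_h = times,
                   c_c = matrix(rep(ct, each = nn), nn, length(times)))
  phi <- evolve_phi(exposure, kp, phi0 = 0.8, mesh = msh)
  intM <- sapply(times, function(tt) {
    stats::integrate(function(u) kill_rate(6 * exp(-u / 25), kp),
                     0, tt, rel.tol = 1e-10)$value
  })
  oracle <- 0.8 * exp(kp$K * times - intM)
  expect_equal(phi$phi_av, oracle, tolerance = 1e-5)
})

test_that("under uniform exposure phi_av scales exactly with the initial condition", {
  msh <- coarse_mesh()
  nn <- nrow(msh$nodes)
  times <- seq(0, 712, length.out = 60)
  ct <- pmax(0, 4 * exp(-times / 80))
  exposure <- list(times_h = times,
                   c_c = matrix(rep(ct, each = nn), nn, length(times)))
  kp <- kill_parameters(K = 1 / 29)
  nts <- n_t_from_ratio(table2_volume_ratios()[c("hexagonal", "grid1")])
  f1 <- evolve_phi(exposure, kp, phi0 = nts[["hexagonal"]], mesh = msh)
  f2 <- evolve_phi(exposure, kp, phi0 = nts[["grid1"]], mesh = msh)
  ratio <- f1$phi_av / f2$phi_av
  expect_equal(ratio, rep(nts[["hexagonal"]] / nts[["grid1"]], length(times)),
               tolerance = 1e-12)
})

test_that("larger exposure never yields larger final phi_av", {
  msh <- coarse_mesh()
  nn <- nrow(msh$nodes)
  times <- seq(0, 300, length.out = 30)
  kp <- kill_parameters()
  finals <- sapply(c(0, 1, 3, 9), function(level) {
    ex <- list(times_h = times, c_c = matrix(level, nn, length(times)))
    f <- evolve_phi(ex, kp, phi0 = 0.8, mesh = msh)
    f$phi_av[length(times)]
  })
  expect_true(all(diff(finals) < 0))
})

test_that("second_dose_time distinguishes interior and boundary minima with early ties", {
  v <- list(times_h = 0:10, phi_av = c(5, 4, 3, 2, 3, 4, 5, 6, 7, 8, 9))
  m <- second_dose_time(v)
  expect_true(m$interior)
  expect_equal(m$t_min_h, 3)
  mono <- list(times_h = 0:5, phi_av = 6:1)
  m2 <- second_dose_time(mono)
  expect_false(m2$interior)
  expect_equal(m2$t_min_h, 5)
  tie <- list(times_h = 0:4, phi_av = c(3, 1, 2, 1, 3))
  expect_equal(second_dose_time(tie)$t_min_h, 1)
  expect_error(second_dose_time(list(times_h = numeric(0), phi_av = numeric(0))),
               "empty")
})

test_that("evolve_phi validates its inputs", {
  msh <- coarse_mesh()
  bad <- list(times_h = 1:3, c_c = matrix(0, 4, 2))
  expect_error(evolve_phi(bad, mesh = msh), "mismatch")
  ok <- list(times_h = c(0, 1), c_c = matrix(0, 2, 2))
  expect_error(evolve_phi(ok, phi0 = c(1, 2, 3), mesh = msh), "scalar or one value")
})

test_that("identical exposures tie and zero-dose schedules reduce to pure growth", {
  fl <- coarse_fluid(1e-12)
  zero1 <- perfusion_schedule(level = 0, duration_h = 10)
  cmp <- compare_treatments(fl, K_values = 1 / 29,
                            n_t = c(hexagonal = 0.8678),
                            t_end_h = 24,
                            injection = zero1,
                            perfusion = perfusion_schedule(level = 0))
  s <- cmp$summary
  expect_equal(s$winner, "tie")
  expect_equal(s$phi_final_injection, 0.8678 * exp(24 / 29), tolerance = 1e-8)
})
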