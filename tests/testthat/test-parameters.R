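test_that("Reynolds number reproduces the capillary-scale estimate and scales linearly", {
  expect_equal(reynolds_number(1040, 25e-6, 50e-6, 4e-3), 3.3e-4, tolerance = 0.02)
  expect_equal(reynolds_number(1000, 1, 1, 1), 1000)
  expect_equal(reynolds_number(1040, 50e-6, 50e-6, 4e-3),
               2 * reynolds_number(1040, 25e-6, 50e-6, 4e-3))
  expect_error(reynolds_number(1040, 0, 50e-6, 4e-3), "invalid parameter")
})

test_that("dimensionless groups reproduce the reported values on the defaults", {
  g <- dimensionless_groups(default_params())
  expect_equal(g$nu, 0.05)
  expect_equal(g$eta, 0.1)
  expect_equal(g$Re, 3.3e-4, tolerance = 0.02)
  expect_equal(g$R, 6.4e-5, tolerance = 0.02)
  expect_equal(g$Vstar, 4, tolerance = 1e-12)
  expect_equal(g$Peclet, 3.8, tolerance = 0.02)
  expect_equal(g$kappa_range, c(3.2e-8, 3.2e-5), tolerance = 0.02)
  expect_gte(g$kappa, g$kappa_range[1] * 0.99)
  expect_lte(g$kappa, g$kappa_range[2] * 1.01)
  expect_equal(g$P2, 9.36e-12, tolerance = 0.02)
})

test_that("compose_P matches its two algebraically identical forms", {
  expect_equal(compose_P(37.4e-12, 50e-6, 1e-2, 1e-3), 9.36e-12, tolerance = 0.02)
  expect_equal(compose_P(1, 1, 1, 1), 1)
  # doubling d quadruples P
  expect_equal(compose_P(1e-12, 2 * 50e-6, 1e-2, 1e-3),
               4 * compose_P(1e-12, 50e-6, 1e-2, 1e-3))
  expect_error(compose_P(0, 50e-6, 1e-2, 1e-3), "invalid parameter")
  set.seed(42)
  for (i in 1:20) {
    k <- 10^runif(1, -14, -10); d <- 10^runif(1, -5, -4)
    L <- 10^runif(1, -2.5, -1.5); s <- 10^runif(1, -3.5, -2.5)
    nu <- d / s; eta <- s / L
    expect_equal(compose_P(k, d, L, s), k * nu^2 / eta^2, tolerance = 1e-12)
  }
})

test_that("mmHg conversion is exact and invertible", {
  expect_equal(mmhg_to_pa(0), 0)
  expect_equal(mmhg_to_pa(50), 6666.1)
  expect_equal(mmhg_to_pa(10), 1333.22)
  expect_equal(pa_to_mmhg(mmhg_to_pa(37.3)), 37.3)
})

test_that("constructor enforces homogenisation validity and positivity", {
  expect_error(model_parameters(d_um = 2000, s_um = 1000), "nu = d/s < 1")
  expect_error(model_parameters(s_um = 20000, L_cm = 1), "eta = s/L < 1")
  expect_error(model_parameters(p_artery_mmHg = 5, p_vein_mmHg = 10), "exceed")
  expect_error(model_parameters(mu = -1), "invalid parameter")
  p <- default_params()
  expect_true(p$p_artery > p$p_vein)
  expect_equal(p$n, 0.152)
  expect_equal(p$r_literal, 0.986)
  expect_equal(p$C, 4e-9)
  expect_equal(p$r_formula, p$Ra * p$s * p$Sa_over_Vp)
})

test_that("JSON parameter files round-trip and reject unknown keys", {
  p <- model_parameters(d_um = 40, p_artery_mmHg = 45)
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(q$d, p$d)
  expect_equal(q$p_artery, p$p_artery, tolerance = 1e-12)
  expect_equal(q$C, p$C)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"d_um": 50, "bogus_key": 1}', bad)
  expect_error(read_parameters(bad), "unknown parameter key")
})
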