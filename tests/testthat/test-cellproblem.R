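test_that("empty vessel mask gives the identity interstitial tensor", {
  E <- interstitial_tensor(matrix(FALSE, 16, 16))
  expect_equal(plain(E), diag(2), tolerance = 1e-12)
  Eb <- interstitial_tensor(matrix(FALSE, 16, 16), normalisation = "bulk")
  expect_equal(plain(Eb), diag(2), tolerance = 1e-12)
})

test_that("disk arrays reproduce the 2D Maxwell dilute limit (bulk) and 1/(1+phi) (intrinsic)", {
  m <- disk_mask(128, 0.05)
  phi <- mean(m)
  Eb <- interstitial_tensor(m, normalisation = "bulk")
  expect_equal(Eb[1, 1], (1 - phi) / (1 + phi), tolerance = 0.03)
  expect_equal(Eb[1, 2], 0, tolerance = 1e-12)
  expect_equal(Eb[1, 1], Eb[2, 2], tolerance = 1e-10)
  Ei <- interstitial_tensor(m)
  expect_equal(Ei[1, 1], 1 / (1 + phi), tolerance = 0.03)
  # intrinsic and bulk differ exactly by the interstitial volume fraction
  expect_equal(Eb[1, 1] / Ei[1, 1], 1 - phi, tolerance = 1e-12)
})

test_that("interstitial eigenvalues lie in (0, 1] and decrease with inclusion fraction", {
  fracs <- c(0.03, 0.08, 0.15, 0.25)
  evs <- sapply(fracs, function(f) {
    E <- interstitial_tensor(disk_mask(64, f), normalisation = "bulk")
    eigen(plain(E), symmetric = TRUE, only.values = TRUE)$values
  })
  expect_true(all(evs > 0 & evs <= 1 + 1e-12))
  expect_true(all(diff(evs[1, ]) < 0))
  expect_true(all(diff(evs[2, ]) < 0))
})

test_that("interstitial tensor converges under grid refinement on the disk benchmark", {
  # compare each resolution against the dilute-limit value at its own
  # realised inclusion fraction (the staircase mask area varies with n)
  errs <- sapply(c(40, 80, 160), function(n) {
    m <- disk_mask(n, 0.05)
    phi <- mean(m)
    abs(interstitial_tensor(m, normalisation = "bulk")[1, 1] -
          (1 - phi) / (1 + phi))
  })
  # staircase-wall scheme: nominal first order
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("interstitial tensor is equivariant under quarter-turn mask rotation", {
  m <- matrix(FALSE, 48, 48)
  m[5:15, 8:30] <- TRUE; m[30:40, 35:44] <- TRUE
  mr <- t(m)[rev(seq_len(ncol(m))), ]
  R <- matrix(c(0, 1, -1, 0), 2)
  Ea <- plain(interstitial_tensor(m, normalisation = "bulk"))
  Er <- plain(interstitial_tensor(mr, normalisation = "bulk"))
  expect_equal(Er, R %*% Ea %*% t(R), tolerance = 1e-10)
})

test_that("porous-matrix tensor reduces correctly in its two limit cases", {
  # uniform isotropic K, no inclusions -> F = k I
  k <- 3.74e-11
  Fu <- porous_matrix_tensor(k, matrix(FALSE, 24, 24))
  expect_equal(plain(Fu), k * diag(2), tolerance = 1e-12)
  # K = I reduces the Darcy cell problem to the Laplace one: F == E
  m <- disk_mask(64, 0.12)
  Fm <- porous_matrix_tensor(1, m, normalisation = "bulk")
  Eb <- interstitial_tensor(m, normalisation = "bulk")
  expect_equal(plain(Fm), plain(Eb), tolerance = 1e-12)
  # symmetric inclusions with isotropic K -> diagonal F
  expect_equal(Fm[1, 2], 0, tolerance = 1e-12)
  expect_psd(Fm)
})

test_that("porous-matrix solver accepts coefficient fields and rejects singular K", {
  m <- disk_mask(32, 0.1)
  Kfield <- matrix(2e-11, 32, 32)
  Kfield[1:16, ] <- 4e-11
  Fm <- porous_matrix_tensor(Kfield, m)
  expect_psd(Fm)
  expect_error(porous_matrix_tensor(0, m), "singular")
  Kbad <- Kfield; Kbad[2, 2] <- -1
  expect_error(porous_matrix_tensor(Kbad, m), "singular")
})

test_that("a mask with no interstitium is rejected", {
  expect_error(interstitial_tensor(matrix(TRUE, 8, 8)), "no interstitium")
})
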