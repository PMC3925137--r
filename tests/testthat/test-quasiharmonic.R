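make_gaussian_traj <- function(n_atoms, n_frames, sds, seed = 1) {
  # frames drawn about a fixed random base structure with independent
  # per-coordinate Gaussian displacements of known standard deviation
  set.seed(seed)
  base <- matrix(rnorm(n_atoms * 3, sd = 20), n_atoms, 3)
  co <- array(0, dim = c(n_atoms, 3, n_frames))
  for (i in seq_len(n_frames))
    co[, , i] <- base + matrix(rnorm(3 * n_atoms, sd = sds), n_atoms, 3, byrow = FALSE)
  atoms <- data.frame(element = "C", atom_name = "CA",
                      residue_index = seq_len(n_atoms), strand_index = 1L,
                      layer_index = NA_integer_, mass = 12.011)
  fibril_trajectory(co, atoms)
}

test_that("fluctuation matrix: degenerate cases and a known-covariance oracle", {
  tr0 <- sample_beam_trajectory(small_beam_spec(temperature = 0), 3, seed = 1)
  Q0 <- fluctuation_matrix(tr0, align = FALSE)
  expect_equal(max(abs(Q0)), 0)
  expect_error(fluctuation_matrix(window_frames(tr0, 0, 3)), "2 frames")

  # two frames at +/- d about the mean: Q = d d^T
  at <- data.frame(element = "C", atom_name = "CA", residue_index = 1:3,
                   strand_index = 1L, layer_index = NA_integer_, mass = 12)
  base <- matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0), 3, 3, byrow = TRUE)
  d <- rnorm(9, sd = 0.1)
  co <- array(0, dim = c(3, 3, 2))
  co[, , 1] <- base + matrix(d, 3, 3, byrow = TRUE)
  co[, , 2] <- base - matrix(d, 3, 3, byrow = TRUE)
  Q2 <- fluctuation_matrix(fibril_trajectory(co, at), align = FALSE)
  expect_equal(unclass(Q2), outer(d, d), tolerance = 1e-12,
               ignore_attr = TRUE)

  # sampled Gaussian displacements recover the prescribed variances
  tr <- make_gaussian_traj(8, 10000, sds = 0.5, seed = 42)
  Q <- fluctuation_matrix(tr, align = FALSE)
  expect_equal(mean(diag(Q)), 0.25, tolerance = 0.05)
  expect_lt(max(abs(Q - diag(diag(Q)))), 0.05 * 0.25 * 10)
})

test_that("alignment: fixed-reference invariance and eigenvalue invariance", {
  tr <- sample_beam_trajectory(small_beam_spec(), 120, seed = 9)
  Q1 <- fluctuation_matrix(tr, align = TRUE)
  ref <- attr(Q1, "mean_structure")
  moved <- transform_trajectory(tr)
  Qa <- fluctuation_matrix(tr, align = TRUE, ref = ref)
  Qb <- fluctuation_matrix(moved, align = TRUE, ref = ref)
  expect_lt(max(abs(Qa - Qb)), 1e-8)
  # with self-mean alignment the matrix lives in rotated axes, but the
  # spectrum is invariant
  Q2 <- fluctuation_matrix(moved, align = TRUE)
  e1 <- eigen(unclass(Q1), symmetric = TRUE, only.values = TRUE)$values
  e2 <- eigen(unclass(Q2), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("spectral decomposition: diagonal, rank-one, reconstruction identity", {
  D <- diag(c(3, 2, 1, 0.5, 0.1, 0.05))
  sp <- spectral_decompose(D)
  expect_equal(sp$values, c(3, 2, 1, 0.5, 0.1, 0.05))
  expect_equal(abs(sp$vectors), diag(6), tolerance = 1e-12)

  d <- c(1, -2, 3, 0.5, -1, 2)
  sp1 <- spectral_decompose(outer(d, d))
  expect_equal(sp1$values[1], sum(d^2), tolerance = 1e-12)
  expect_equal(abs(sp1$vectors[, 1]), abs(d) / sqrt(sum(d^2)), tolerance = 1e-12)
  expect_lt(max(abs(sp1$values[-1])), 1e-12)

  set.seed(3)
  M <- matrix(rnorm(900), 30, 30); M <- M + t(M)
  spM <- spectral_decompose(M)
  rec <- spM$vectors %*% (t(spM$vectors) * spM$values)
  expect_lt(max(abs(rec - M)), 1e-10)
  expect_lt(max(abs(crossprod(spM$vectors) - diag(30))), 1e-10)
  Mbad <- M; Mbad[1, 2] <- Mbad[1, 2] + 1
  expect_error(spectral_decompose(Mbad), "symmetric")
})

test_that("stiffness matrix is kB T times the retained-subspace pseudo-inverse", {
  set.seed(11)
  C <- matrix(rnorm(12 * 8), 12, 8)
  Q <- tcrossprod(C)   # 12 x 12 PSD of rank 8
  sp <- spectral_decompose(Q, temperature = 300)
  K <- stiffness_matrix(sp, n_rigid = 4)
  # pseudo-inverse oracle over the retained modes
  pinv <- sp$vectors[, 1:8] %*% (t(sp$vectors[, 1:8]) / sp$values[1:8])
  expect_equal(K, kBT(300) * pinv, tolerance = 1e-8, ignore_attr = TRUE)
  # K Q = kB T x identity on the retained subspace
  P <- tcrossprod(sp$vectors[, 1:8])
  expect_equal(K %*% Q %*% P, kBT(300) * P, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(stiffness_matrix(sp, n_rigid = 12), "retained")
})

test_that("quasi-harmonic frequencies carry the right units and scalings", {
  # hand unit-conversion oracle
  xi <- 0.25; M <- 12.011; T <- 300
  omega_oracle <- sqrt(1.380649e-23 * T / (M * 1.66053906660e-27 * xi * 1e-20))
  sp <- spectral_decompose(diag(c(0.25, 0.25, 0.25)), temperature = T,
                           calpha_mass = M)
  f <- natural_frequencies(sp, n_rigid = 0)
  expect_equal(f$omega_rad_s, rep(omega_oracle, 3), tolerance = 1e-9)
  expect_equal(f$nu_THz, f$omega_rad_s / (2 * pi) / 1e12)
  # unit construction: xi = kB T / M (consistent units) gives omega = 1
  xi_unit <- 1.380649e-23 * T / (M * 1.66053906660e-27) / 1e-20
  sp1 <- spectral_decompose(diag(rep(xi_unit, 3)), temperature = T, calpha_mass = M)
  expect_equal(natural_frequencies(sp1, 0)$omega_rad_s, rep(1, 3),
               tolerance = 1e-12)
  # doubling T scales every omega by sqrt(2)
  sp2 <- spectral_decompose(diag(c(0.25, 0.25, 0.25)), temperature = 2 * T,
                            calpha_mass = M)
  expect_equal(natural_frequencies(sp2, 0)$omega_rad_s,
               sqrt(2) * f$omega_rad_s, tolerance = 1e-12)
})

test_that("mode contributions: normalization, equal spectra, (4,3,2,1) ratios", {
  sp <- spectral_decompose(diag(c(4, 3, 2, 1, 1e-12, 1e-12)))
  mc <- mode_contributions(sp, n_rigid = 2)
  expect_equal(mc$modes$alpha, c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-10)
  expect_equal(sum(mc$modes$alpha), 1, tolerance = 1e-8)
  # trace conservation: N RMSF^2 = sum of retained eigenvalues
  expect_equal(sp$n_atoms * mc$rmsf_total^2, sum(sp$values[1:4]),
               tolerance = 1e-12)
  spe <- spectral_decompose(diag(rep(2, 5)))
  expect_equal(mode_contributions(spe, 0)$modes$alpha, rep(0.2, 5))
})
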