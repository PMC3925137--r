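test_that("free-free roots satisfy the characteristic equation to 1e-10", {
  lam <- free_free_roots(1:8)
  # the product form is well-conditioned only for low orders (cosh amplifies
  # round-off by e^lambda); higher orders are checked in the sech form
  expect_lt(max(abs(cos(lam[1:3]) * cosh(lam[1:3]) - 1)), 1e-10)
  # high orders via sech form (cosh overflows but cos -> sech root remains)
  expect_lt(max(abs(cos(lam) - 1 / cosh(lam))), 1e-10)
  # independent bisection oracle for the first root
  g <- function(l) cos(l) - 1 / cosh(l)
  oracle <- uniroot(g, c(4, 5), tol = 1e-14)$root
  expect_equal(lam[1], oracle, tolerance = 1e-10)
  expect_true(all(diff(lam) > 0))
})

test_that("free-free bending shapes are orthogonal and carry no rigid content", {
  x <- seq(0, 1, length.out = 200)
  p1 <- beam_mode_shape(1, x); p2 <- beam_mode_shape(2, x)
  expect_lt(abs(sum(p1 * p2)), 1e-4)
  # no net translation or rotation (zero mean and zero first moment,
  # trapezoid quadrature)
  w <- c(0.5, rep(1, 198), 0.5) / 199
  for (n in 1:3) {
    p <- beam_mode_shape(n, x, normalize = FALSE)
    expect_lt(abs(sum(w * p)) / max(abs(p)), 1e-4)
    expect_lt(abs(sum(w * p * (x - 0.5))) / max(abs(p)), 1e-4)
  }
  expect_equal(sum(beam_mode_shape(2, x)^2), 1, tolerance = 1e-12)
})

test_that("analytic frequencies: scalings, root ratios, finite-difference oracle", {
  geom <- beam_geometry(L = 1.2e-8, mu = 6.1e-15)
  w1 <- analytic_frequencies(geom, "soft-bend", 1, 1e-28)
  expect_equal(analytic_frequencies(geom, "soft-bend", 1, 2e-28), sqrt(2) * w1)
  lam <- free_free_roots(1:2)
  expect_equal(analytic_frequencies(geom, "soft-bend", 2, 1e-28) / w1,
               (lam[2] / lam[1])^2, tolerance = 1e-12)
  expect_equal((lam[2] / lam[1])^2, 2.7565, tolerance = 1e-4)

  # independent oracle: lumped finite-difference free-free beam, 64 nodes
  nb <- 64; EI <- 1e-28; L <- geom$L; mu <- geom$mu; dx <- L / (nb - 1)
  A2 <- matrix(0, nb - 2, nb)
  for (i in 1:(nb - 2)) A2[i, i:(i + 2)] <- c(1, -2, 1)
  K <- EI / dx^3 * crossprod(A2)
  mvec <- rep(mu * dx, nb); mvec[c(1, nb)] <- mu * dx / 2
  Ms <- diag(1 / sqrt(mvec))
  w2 <- sort(eigen(Ms %*% K %*% Ms, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(length(which(w2 < 1e-6 * max(w2))), 2)  # 2 planar rigid modes
  w_fd <- sqrt(w2[3])
  expect_equal(w_fd, w1, tolerance = 0.01)

  # torsion / axial rod relations
  gA <- beam_geometry(L = 1e-8, mu = 5e-15, A = 4e-18, I_y = 2e-37, I_z = 1e-37)
  wt <- analytic_frequencies(gA, "torsion", 2, 2e-28)
  expect_equal(wt, (2 * pi / 1e-8) * sqrt(2e-28 / gA$inertia_per_length))
  wa <- analytic_frequencies(gA, "axial", 3, 2e-9)
  expect_equal(wa, (3 * pi / 1e-8) * sqrt(2e-9 / 5e-15))
})

test_that("frequency inversion is the exact algebraic inverse for every family", {
  geom <- beam_geometry(L = 1.2e-8, mu = 6.1e-15, A = 4e-18,
                        I_y = 2e-37, I_z = 1e-37)
  for (n in 1:3) {
    w <- analytic_frequencies(geom, "soft-bend", n, 1.7e-28)
    inv <- invert_bending(w, geom, n, "soft")
    expect_equal(inv$rigidity, 1.7e-28, tolerance = 1e-12)
    expect_equal(inv$modulus, 1.7e-28 / 1e-37, tolerance = 1e-12)
    wt <- analytic_frequencies(geom, "torsion", n, 3e-28)
    expect_equal(invert_torsion(wt, geom, n)$rigidity, 3e-28, tolerance = 1e-12)
    wa <- analytic_frequencies(geom, "axial", n, 2.4e-9)
    expect_equal(invert_axial(wa, geom, n)$rigidity, 2.4e-9, tolerance = 1e-12)
  }
  # omega scaled by 2 -> bending rigidity scaled by 4
  w <- analytic_frequencies(geom, "stiff-bend", 1, 2e-28)
  expect_equal(invert_bending(2 * w, geom, 1, "stiff")$rigidity, 8e-28,
               tolerance = 1e-12)
  # G_T from the homogeneous-section relation: J cancels
  rho <- geom$rho
  wt <- analytic_frequencies(geom, "torsion", 1, 3e-28)
  GT_direct <- rho * (wt * geom$L / pi)^2
  expect_equal(invert_torsion(wt, geom, 1)$modulus, GT_direct, tolerance = 1e-10)
})

test_that("persistence length follows l_p = EI / kB T", {
  expect_equal(persistence_length(2e-28, 300),
               2e-28 / (1.380649e-23 * 300), tolerance = 1e-12)
  expect_equal(persistence_length(2e-28, 300), 4.83e-8, tolerance = 0.01)
  # increases with rigidity, decreases with temperature
  expect_gt(persistence_length(3e-28, 300), persistence_length(2e-28, 300))
  expect_lt(persistence_length(2e-28, 350), persistence_length(2e-28, 300))
})

test_that("cross-section estimation: fixed model, cylinder envelope, scaling", {
  sp <- small_beam_spec()
  gt <- beam_ground_truth(sp)
  st <- fibril_structure(gt$reference$atoms, gt$reference$coords)
  gf <- estimate_cross_section(st, "fixed", A = 4e-18, I_y = 2e-37, I_z = 1e-37)
  expect_equal(gf$A, 4e-18); expect_equal(gf$I_y, 2e-37)
  expect_equal(gf$J, 3e-37)
  expect_equal(gf$L, sp$L_nm * 1e-9, tolerance = 1e-12)
  expect_equal(gf$mu, gt$geom$mu, tolerance = 1e-12)
  expect_equal(gf$inertia_per_length, gt$geom$inertia_per_length,
               tolerance = 1e-12)

  # cylinder sampled densely on a grid: A within 5% of pi r^2, I within 10%
  # of pi r^4 / 4
  r <- 15; h <- 0.6
  g <- expand.grid(x = seq(-r, r, by = h), y = seq(-r, r, by = h))
  g <- g[g$x^2 + g$y^2 <= r^2, ]
  zs <- seq(0, 100, length.out = 6)
  cc <- do.call(rbind, lapply(zs, function(z) cbind(z, g$x, g$y)))
  at <- data.frame(element = "C", atom_name = "CA",
                   residue_index = seq_len(nrow(cc)), strand_index = 1L,
                   layer_index = rep(1:6, each = nrow(g)), mass = 12)
  cyl <- fibril_structure(at, cc)
  ge <- estimate_cross_section(cyl, "envelope", r_eff = 0.3)
  r_m <- r * 1e-10
  expect_equal(ge$A, pi * r_m^2, tolerance = 0.05)
  expect_equal(ge$I_y, pi * r_m^4 / 4, tolerance = 0.10)
  expect_equal(ge$I_z, pi * r_m^4 / 4, tolerance = 0.10)

  # doubling all coordinates (and r_eff) scales A by 4 and I by 16
  cyl2 <- fibril_structure(at, cc * 2)
  ge2 <- estimate_cross_section(cyl2, "envelope", r_eff = 0.6)
  expect_equal(ge2$A / ge$A, 4, tolerance = 1e-9)
  expect_equal(ge2$I_y / ge$I_y, 16, tolerance = 1e-9)
})
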