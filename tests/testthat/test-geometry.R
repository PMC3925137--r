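test_that("superposition recovers rigid transforms and matches the quaternion oracle", {
  set.seed(101)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(A, A)$rotation, diag(3), tolerance = 1e-9)

  shifted <- sweep(A, 2, c(4, -1, 2), `+`)
  s <- superpose(A, shifted)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  expect_equal(s$translation, c(4, -1, 2), tolerance = 1e-9)

  # rotated + noised targets: residual equals Horn's quaternion solution
  for (k in 1:5) {
    set.seed(200 + k)
    P <- matrix(rnorm(15), 5, 3)
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    Qc <- P %*% R + matrix(rnorm(15, sd = 0.3), 5, 3) + 1.5
    expect_equal(superpose(P, Qc)$rmsd, quaternion_superpose_rmsd(P, Qc),
                 tolerance = 1e-9)
    expect_equal(det(superpose(P, Qc)$rotation), 1, tolerance = 1e-9)
  }
  expect_error(superpose(A[1:2, ], A[1:2, ]), "3 atoms")
})

test_that("rmsd series vanishes for constant and rigidly moved trajectories", {
  tr <- sample_beam_trajectory(small_beam_spec(temperature = 0), 4, seed = 1)
  expect_equal(rmsd_series(tr), rep(0, 4), tolerance = 1e-10)
  tr2 <- sample_beam_trajectory(small_beam_spec(), 6, seed = 5)
  moved <- transform_trajectory(tr2)
  # superposed RMSD is invariant under a rigid transform of every frame
  expect_equal(rmsd_series(moved), rmsd_series(tr2), tolerance = 1e-8)
  # and equals a direct per-frame recomputation
  ref <- frame_coords(tr2, 1)
  direct <- vapply(1:6, function(i)
    superpose(frame_coords(tr2, i), ref)$rmsd, numeric(1))
  expect_equal(rmsd_series(tr2), direct)
})

test_that("layer dihedrals read back the built-in twist exactly", {
  for (tw in c(0, 10, 25)) {
    f <- build_zipper_fibril("aa-pho",
      fibril_build_params(n_layers = 5, twist_per_layer = tw))
    d <- layer_dihedral(f$coords, f$atoms$layer_index)
    expect_equal(d, rep(tw, 4), tolerance = 1e-6)
  }
})

test_that("bending angle: straight, right angle, and single-mode beam geometry", {
  f0 <- build_zipper_fibril("co-pho",
    fibril_build_params(n_layers = 7, twist_per_layer = 4))
  expect_equal(bending_angle(f0$coords, f0$atoms$layer_index), 0,
               tolerance = 1e-7)
  # centroids forming a right angle at the mid layer
  cents <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  cc <- cents[rep(1:3, each = 2), ] +
    rbind(c(0, .1, 0), c(0, -.1, 0), c(0, .1, 0), c(0, -.1, 0),
          c(.1, 0, 0), c(-.1, 0, 0))
  expect_equal(bending_angle(cc, rep(1:3, each = 2)), 90, tolerance = 1e-8)
  expect_error(bending_angle(cc[1:4, ], rep(1:2, each = 2)), "layer")

  # beam bent by its first free-free mode: compare to the analytic shape
  sp <- beam_spec(n_beads = 21, local_noise_A = 0)
  gt <- beam_ground_truth(sp)
  q <- 8  # amplitude, A
  co <- gt$reference$coords + q * matrix(gt$D[, 1], ncol = 3, byrow = TRUE)
  got <- bending_angle(co, gt$reference$atoms$layer_index)
  x <- gt$reference$xs
  phi <- q * beam_mode_shape(1, (x - min(x)) / diff(range(x)))
  mid <- (length(x) + 1) %/% 2
  v1 <- c(x[1] - x[mid], phi[1] - phi[mid])
  v2 <- c(x[21] - x[mid], phi[21] - phi[mid])
  want <- 180 - acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("order parameter is a circular variance with the documented properties", {
  expect_equal(order_parameter(c(12, 12, 12, 12)), 0)
  a <- 0.3  # radians
  expect_equal(order_parameter(c(a, -a) * 180 / pi), a^2, tolerance = 1e-12)
  set.seed(7)
  th <- rnorm(40, mean = 10, sd = 8)           # degrees, no wraparound
  rad <- th * pi / 180
  oracle <- mean((rad - mean(rad))^2)          # two-pass population variance
  expect_equal(order_parameter(th), oracle, tolerance = 1e-12)
  expect_gte(order_parameter(th), 0)
  expect_equal(order_parameter(th, "circular_sd"), sqrt(oracle), tolerance = 1e-12)
  expect_error(order_parameter(5), ">= 2")
  expect_true(is_disordered(0.08))
  expect_false(is_disordered(0.04))
})

test_that("strands per helical pitch", {
  expect_equal(strands_per_pitch(10, 2), 72L)
  expect_equal(strands_per_pitch(360, 2), 2L)
  expect_equal(strands_per_pitch(12.857, 2), 56L)
  expect_error(strands_per_pitch(0, 2), "positive")
})
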