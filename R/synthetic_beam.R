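# Synthetic thermal trajectories of a discretized free-free elastic beam with
# known ground-truth mechanics. Each axial station carries two tracer beads
# offset +/- r0 perpendicular to the axis (mirroring the two strands of a
# cross-beta layer) so that twist is observable from coordinates alone.
# Frames superpose analytic free-free normal modes with amplitudes drawn by
# equipartition, q_n ~ N(0, kB T / (m_n omega_n^2)), m_n the discrete modal
# mass, plus a small isotropic thermal jitter that plays the role of the
# unresolved local disorder of a real MD trajectory (it makes the fluctuation
# spectrum full-rank, as observed covariances are).

#' Specification of a synthetic elastic beam
#'
#' Defaults describe a ~12 nm amyloid-fibril-like filament: 20 layers of two
#' ~1.1 kDa strands, soft/stiff bending rigidities of order 1e-28 N m^2
#' (the scale reported for short amyloid fibrils), and torsional/axial
#' stiffness giving shear and axial moduli of a few tenths of GPa for a
#' nm-scale cross-section.
#'
#' @param L_nm Beam length, nm.
#' @param n_beads Number of axial stations (>= 8); each station carries two
#'   tracer beads, so the structure has `2 * n_beads` atoms.
#' @param mass_per_bead_Da Mass of one tracer bead, Da.
#' @param bending_rigidity_soft,bending_rigidity_stiff `E_B I` about the two
#'   principal transverse axes, N m^2 (`soft <= stiff`).
#' @param torsional_rigidity `G_T J`, N m^2.
#' @param axial_stiffness `E_X A`, N.
#' @param temperature Temperature, K.
#' @param n_modes_per_family Analytic modes excited per deformation family.
#' @param tracer_offset_A Tracer offset from the centerline, A.
#' @param local_noise_A RMS per-coordinate thermal jitter at 300 K, A
#'   (scaled by sqrt(T / 300)).
#' @param time_per_frame_ps Sampling interval metadata, ps.
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(L_nm = 12, n_beads = 20, mass_per_bead_Da = 1100,
                      bending_rigidity_soft = 1e-28,
                      bending_rigidity_stiff = 2e-28,
                      torsional_rigidity = 2e-28,
                      axial_stiffness = 2e-9,
                      temperature = 300,
                      n_modes_per_family = 3,
                      tracer_offset_A = 5,
                      local_noise_A = 0.1,
                      time_per_frame_ps = 6) {
  stopifnot(L_nm > 0, n_beads >= 8, mass_per_bead_Da > 0,
            bending_rigidity_soft > 0, bending_rigidity_stiff > 0,
            torsional_rigidity > 0, axial_stiffness > 0,
            temperature >= 0, n_modes_per_family >= 1,
            tracer_offset_A > 0, local_noise_A >= 0)
  if (bending_rigidity_soft > bending_rigidity_stiff)
    stop("bending_rigidity_soft must be <= bending_rigidity_stiff")
  structure(as.list(environment()), class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("Beam spec: L = %g nm, %d stations x 2 tracers, T = %g K\n",
              x$L_nm, x$n_beads, x$temperature))
  cat(sprintf("  EI (soft/stiff) = %.3g / %.3g N m^2, GJ = %.3g N m^2, EA = %.3g N\n",
              x$bending_rigidity_soft, x$bending_rigidity_stiff,
              x$torsional_rigidity, x$axial_stiffness))
  invisible(x)
}

# reference geometry: stations along global x, tracers at +/- r0 in y
.beam_reference <- function(spec) {
  L_A <- spec$L_nm * 10
  xs <- seq(0, L_A, length.out = spec$n_beads)
  coords <- cbind(rep(xs, each = 2),
                  rep(c(spec$tracer_offset_A, -spec$tracer_offset_A),
                      spec$n_beads),
                  0)
  atoms <- data.frame(
    element = "C", atom_name = "CA",
    residue_index = rep(seq_len(spec$n_beads), each = 2),
    strand_index = rep(1:2, spec$n_beads),
    layer_index = rep(seq_len(spec$n_beads), each = 2),
    mass = spec$mass_per_bead_Da, stringsAsFactors = FALSE)
  list(coords = coords, atoms = atoms, xs = xs, L_A = L_A)
}

# 3N x 6 rigid-body displacement basis (translations + rotations about the
# centroid axes) at the reference geometry, orthonormalized
.rigid_basis <- function(coords) {
  n <- nrow(coords)
  cen <- colMeans(coords)
  P <- sweep(coords, 2, cen)
  B <- matrix(0, 3 * n, 6)
  for (ax in 1:3) B[seq(ax, 3 * n, by = 3), ax] <- 1
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    rot <- t(apply(P, 1, function(p) c(e[2] * p[3] - e[3] * p[2],
                                       e[3] * p[1] - e[1] * p[3],
                                       e[1] * p[2] - e[2] * p[1])))
    B[, 3 + ax] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

#' Ground-truth mode table of a beam specification
#'
#' The analytic free-free frequencies and discrete modal data the generator
#' samples from. Displacement patterns are Gram-Schmidt orthogonalized
#' against the exact discrete rigid-body space so that sampled trajectories
#' carry no spurious rigid content.
#'
#' @param spec A [beam_spec()].
#' @return List with `modes` (data.frame: family, order, omega_rad_s,
#'   sigma_A, modal_mass_kg), `D` (3N x n_modes displacement matrix, A per
#'   unit amplitude), `reference` (list from the internal builder), `geom`
#'   (the exact [beam_geometry()] of the discrete model).
#' @export
beam_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "beam_spec"))
  ref <- .beam_reference(spec)
  n <- spec$n_beads
  t01 <- (ref$xs - min(ref$xs)) / (max(ref$xs) - min(ref$xs))
  m_kg <- spec$mass_per_bead_Da * fm_constants$Da
  L_m <- spec$L_nm * 1e-9
  mu <- 2 * n * m_kg / L_m
  r0_m <- spec$tracer_offset_A * fm_constants$A
  iota <- 2 * n * m_kg * r0_m^2 / L_m   # rotary inertia per unit length
  geom <- beam_geometry(L = L_m, mu = mu, inertia_per_length = iota)

  fam <- character(0); ord <- integer(0); omega <- numeric(0)
  cols <- list()
  add_mode <- function(family, k, w, disp) {
    fam <<- c(fam, family); ord <<- c(ord, k); omega <<- c(omega, w)
    cols[[length(cols) + 1L]] <<- disp
  }
  for (k in seq_len(spec$n_modes_per_family)) {
    phi <- beam_mode_shape(k, t01)               # unit norm over stations
    psi <- rod_mode_shape(k, t01)
    # soft bending: both tracers displace along z
    dz <- rbind(0, 0, rep(phi, each = 2))
    add_mode("soft-bend", k,
             analytic_frequencies(geom, "soft-bend", k, spec$bending_rigidity_soft),
             as.numeric(dz))
    # stiff bending: both tracers displace along y
    dy <- rbind(0, rep(phi, each = 2), 0)
    add_mode("stiff-bend", k,
             analytic_frequencies(geom, "stiff-bend", k, spec$bending_rigidity_stiff),
             as.numeric(dy))
    # torsion: tracers at +/- r0 y move -/+ along z (rotation about +x),
    # scaled by r0 so a unit amplitude is a displacement in A
    tz <- rbind(0, 0, rep(psi, each = 2) * rep(c(1, -1), n) * spec$tracer_offset_A)
    add_mode("torsion", k,
             analytic_frequencies(geom, "torsion", k, spec$torsional_rigidity),
             as.numeric(tz))
    # axial: both tracers displace along x
    dx <- rbind(rep(psi, each = 2), 0, 0)
    add_mode("axial", k,
             analytic_frequencies(geom, "axial", k, spec$axial_stiffness),
             as.numeric(dx))
  }
  if (any(omega <= 0)) stop("non-positive analytic frequency")
  D <- do.call(cbind, cols)
  R <- .rigid_basis(ref$coords)
  D <- D - R %*% crossprod(R, D)                 # project out rigid space
  # The continuum shapes evaluated at a finite set of stations are only
  # approximately orthogonal; the normal modes of the discrete system are
  # exactly orthogonal, so restore that structure by Gram-Schmidt in order
  # of ascending frequency (low modes keep their analytic shape, higher
  # modes absorb the small discretization corrections).
  gs_order <- order(omega)
  for (a in seq_along(gs_order)) {
    ia <- gs_order[a]
    if (a > 1) for (b in seq_len(a - 1)) {
      ib <- gs_order[b]
      D[, ia] <- D[, ia] - sum(D[, ia] * D[, ib]) / sum(D[, ib]^2) * D[, ib]
    }
  }
  # discrete modal mass m_n = m * |D_n|^2 (equal bead masses, D in A)
  modal_mass <- m_kg * colSums(D^2)
  sigma2_m2 <- kBT(max(spec$temperature, 1e-300)) / (modal_mass * omega^2)
  sigma_A <- if (spec$temperature > 0) sqrt(sigma2_m2) / fm_constants$A else rep(0, length(omega))
  list(modes = data.frame(family = fam, order = ord, omega_rad_s = omega,
                          sigma_A = sigma_A, modal_mass_kg = modal_mass,
                          stringsAsFactors = FALSE),
       D = D, reference = ref, geom = geom)
}

#' Sample a thermally fluctuating beam trajectory
#'
#' Draws, per frame, one Gaussian amplitude per analytic mode (variance
#' `kB T / (m_n omega_n^2)`; modes in the order of the ground-truth table,
#' frames outermost), adds the per-atom thermal jitter, and (optionally)
#' rigid-body translation/rotation noise. Deterministic for a fixed seed.
#'
#' @param spec A [beam_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer RNG seed.
#' @param include_rigid_motion Add per-frame rigid translation (sd 2 A per
#'   axis) and small rotations (sd 0.02 rad per axis).
#' @return A `fibril_trajectory` with attribute `ground_truth` (see
#'   [beam_ground_truth()]).
#' @export
sample_beam_trajectory <- function(spec, n_frames, seed = 1,
                                   include_rigid_motion = FALSE) {
  stopifnot(n_frames >= 1)
  gt <- beam_ground_truth(spec)
  ref <- gt$reference
  nat <- nrow(ref$coords)
  set.seed(seed)
  M <- nrow(gt$modes)
  amps <- matrix(stats::rnorm(M * n_frames), M, n_frames) * gt$modes$sigma_A
  X <- as.numeric(t(ref$coords)) + gt$D %*% amps
  noise_sd <- spec$local_noise_A * sqrt(spec$temperature / 300)
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(3 * nat * n_frames, sd = noise_sd),
                                    3 * nat, n_frames)
  coords <- array(0, dim = c(nat, 3, n_frames))
  for (i in seq_len(n_frames)) coords[, , i] <- matrix(X[, i], ncol = 3, byrow = TRUE)
  if (include_rigid_motion) {
    for (i in seq_len(n_frames)) {
      ang <- stats::rnorm(3, sd = 0.02)
      Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3, 3)
      Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0, cos(ang[2])), 3, 3)
      Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
      shift <- stats::rnorm(3, sd = 2)
      cen <- colMeans(coords[, , i])
      coords[, , i] <- sweep(sweep(coords[, , i], 2, cen) %*% (Rx %*% Ry %*% Rz),
                             2, cen + shift, `+`)
    }
  }
  traj <- fibril_trajectory(coords, ref$atoms, spec$time_per_frame_ps,
                            metadata = list(kind = "synthetic_beam"))
  attr(traj, "ground_truth") <- gt
  traj
}
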