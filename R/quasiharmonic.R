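# Quasi-harmonic analysis: the C-alpha fluctuation (covariance) matrix, its
# spectral decomposition, the statistical-mechanics stiffness matrix, the
# quasi-harmonic natural frequencies, and per-mode fluctuation contributions.
#
# Treating the observed covariance Q = <(r - <r>) (x) (r - <r>)> as arising
# from an effective harmonic potential gives a stiffness K = kB T Q^-1 on the
# internal subspace and per-mode frequencies omega_j = sqrt(kB T / (M xi_j)).

# trajectory as n_frames x 3N matrix (row-major per atom: x1 y1 z1 x2 ...)
.traj_matrix <- function(traj) {
  nf <- n_frames(traj); na <- nrow(traj$atoms)
  X <- matrix(0, nf, 3 * na)
  for (i in seq_len(nf)) X[i, ] <- as.numeric(t(traj$coords[, , i]))
  X
}

.row_to_coords <- function(row) matrix(row, ncol = 3, byrow = TRUE)

#' Fluctuation (covariance) matrix of a C-alpha trajectory
#'
#' `Q = <(r - <r>) (x) (r - <r>)>` over frames, a symmetric positive
#' semi-definite 3N x 3N matrix in A^2. With `align = TRUE` every frame is
#' first least-squares superposed onto the running mean structure, iterating
#' the mean until convergence, so rigid diffusion does not swamp the internal
#' modes.
#'
#' @param traj A `fibril_trajectory` (C-alpha / bead level; n_frames >= 2).
#' @param align Iteratively superpose frames onto the mean structure.
#' @param max_iter,tol Alignment iteration controls (mean-structure RMS
#'   change below `tol` A stops the iteration).
#' @param ref Optional fixed n x 3 reference: frames are superposed onto it
#'   once instead of onto the iterated mean, which pins the output to the
#'   reference axes (rigid pre-transforms of the trajectory then leave `Q`
#'   strictly unchanged).
#' @return 3N x 3N matrix (A^2) with attributes `n_atoms`, `n_frames`,
#'   `mean_structure` (the converged mean, n x 3).
#' @export
fluctuation_matrix <- function(traj, align = TRUE, max_iter = 50, tol = 1e-6,
                               ref = NULL) {
  if (n_frames(traj) < 2) stop("fluctuation matrix needs at least 2 frames")
  X <- .traj_matrix(traj)
  if (align && !is.null(ref)) {
    ref <- as.matrix(ref)
    for (i in seq_len(nrow(X))) {
      f <- .row_to_coords(X[i, ])
      X[i, ] <- as.numeric(t(apply_transform(f, superpose(f, ref))))
    }
  } else if (align) {
    ref <- .row_to_coords(colMeans(X))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (i in seq_len(nrow(X))) {
        f <- .row_to_coords(X[i, ])
        X[i, ] <- as.numeric(t(apply_transform(f, superpose(f, ref))))
      }
      newref <- .row_to_coords(colMeans(X))
      delta <- sqrt(mean((newref - ref)^2))
      ref <- newref
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) stop("alignment did not converge in ", max_iter, " iterations")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Q <- crossprod(Xc) / nrow(Xc)
  attr(Q, "n_atoms") <- nrow(traj$atoms)
  attr(Q, "n_frames") <- n_frames(traj)
  attr(Q, "mean_structure") <- .row_to_coords(mu)
  Q
}

#' Spectral decomposition of the fluctuation matrix
#'
#' Dense symmetric eigendecomposition; eigenvalues descending, eigenvectors
#' orthonormal columns with a deterministic sign convention (the largest-
#' magnitude component of each vector is positive).
#'
#' @param Q Symmetric fluctuation matrix (A^2).
#' @param temperature Temperature the trajectory was sampled at, K.
#' @param calpha_mass Mass assigned to each C-alpha / bead site, Da. The
#'   convention of quasi-harmonic analysis on C-alpha coordinates uses the
#'   carbon mass 12.011 Da; for coarse bead models supply the bead mass.
#' @param sym_tol Maximum allowed relative asymmetry of `Q`.
#' @return Object of class `eigen_spectrum`: list with `values` (xi_j, A^2,
#'   descending), `vectors` (3N x 3N), `n_atoms`, `temperature`,
#'   `calpha_mass`, `mean_structure` (if present on `Q`).
#' @export
spectral_decompose <- function(Q, temperature = 300, calpha_mass = 12.011,
                               sym_tol = 1e-8) {
  Q <- unclass(Q)
  asym <- max(abs(Q - t(Q)))
  scale <- max(abs(Q), 1e-300)
  if (asym > sym_tol * scale) stop("matrix is not symmetric")
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(values = e$values, vectors = V,
                 n_atoms = nrow(Q) / 3L,
                 temperature = temperature, calpha_mass = calpha_mass,
                 mean_structure = attr(Q, "mean_structure")),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("Quasi-harmonic spectrum: %d modes over %d atoms (T = %g K)\n",
              length(x$values), x$n_atoms, x$temperature))
  cat("  leading eigenvalues (A^2):",
      paste(format(utils::head(x$values, 5), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Effective stiffness matrix from the fluctuation spectrum
#'
#' `K = kB T * sum_j xi_j^-1 v_j v_j^T` over the retained (internal) modes,
#' excluding the `n_rigid` smallest-eigenvalue modes that span the rigid-body
#' space. K and Q are mutual pseudo-inverses (scaled by kB T) on the retained
#' subspace.
#'
#' @param spec An `eigen_spectrum`.
#' @param n_rigid Number of rigid-body modes to exclude (default 6).
#' @return 3N x 3N stiffness matrix in J/A^2 (attribute `units`).
#' @export
stiffness_matrix <- function(spec, n_rigid = 6) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  m <- length(spec$values)
  if (n_rigid >= m) stop("n_rigid leaves no retained modes")
  keep <- seq_len(m - n_rigid)
  xi <- spec$values[keep]
  if (any(xi <= 0)) stop("retained eigenvalues must be positive")
  V <- spec$vectors[, keep, drop = FALSE]
  K <- V %*% (t(V) * (kBT(spec$temperature) / xi))
  attr(K, "units") <- "J/A^2"
  K
}

#' Quasi-harmonic natural frequencies
#'
#' `omega_j = sqrt(kB T / (M xi_j))`: each principal mode is treated as a
#' harmonic oscillator of mass M (the C-alpha site mass) whose positional
#' variance is the eigenvalue xi_j. Units: Da and A^2 in, rad/s (and THz as
#' nu = omega / 2 pi) out.
#'
#' @param spec An `eigen_spectrum`.
#' @param n_rigid Number of trailing (smallest-xi) rigid modes reported as NA.
#' @return data.frame with `mode`, `xi_A2`, `omega_rad_s`, `nu_THz`;
#'   frequencies ascend as xi descends.
#' @export
natural_frequencies <- function(spec, n_rigid = 6) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  m <- length(spec$values)
  keep <- seq_len(max(m - n_rigid, 0))
  xi <- spec$values
  if (any(xi[keep] <= 0)) stop("retained eigenvalues must be positive")
  M_kg <- spec$calpha_mass * fm_constants$Da
  omega <- rep(NA_real_, m)
  omega[keep] <- sqrt(kBT(spec$temperature) / (M_kg * xi[keep] * fm_constants$A^2))
  data.frame(mode = seq_len(m), xi_A2 = xi, omega_rad_s = omega,
             nu_THz = omega / (2 * pi) / 1e12)
}

#' Per-mode contributions to the thermal fluctuation
#'
#' RMSF over the retained modes, the per-mode RMSF(k), and the dimensionless
#' contribution `alpha_k = RMSF(k)^2 / RMSF^2 = xi_k / sum(xi)`, which sums
#' to 1 over the retained spectrum.
#'
#' @param spec An `eigen_spectrum`.
#' @param n_rigid Number of trailing rigid modes excluded.
#' @return List with `rmsf_total` (A), and a data.frame `modes` holding
#'   `mode`, `xi_A2`, `rmsf_A`, `alpha`.
#' @export
mode_contributions <- function(spec, n_rigid = 6) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  m <- length(spec$values)
  if (n_rigid >= m) stop("n_rigid leaves no retained modes")
  keep <- seq_len(m - n_rigid)
  xi <- spec$values[keep]
  if (any(xi < 0)) xi[xi < 0] <- 0
  N <- spec$n_atoms
  rmsf_total <- sqrt(sum(xi) / N)
  modes <- data.frame(mode = keep, xi_A2 = xi,
                      rmsf_A = sqrt(xi / N),
                      alpha = xi / sum(xi))
  list(rmsf_total = rmsf_total, modes = modes)
}
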