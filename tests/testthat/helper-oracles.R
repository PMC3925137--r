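# Independent oracles used to cross-check the package implementations.

# Horn's quaternion method for optimal rigid superposition: independent of
# the SVD (Kabsch) route used by superpose().
quaternion_superpose_rmsd <- function(mobile, ref) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(X, Y)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(X^2) + sum(Y^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(X))
}

# exhaustive O(n^2) hydrogen-bond enumeration over all N (donor) / O
# (acceptor) pairs with the same geometric criterion
brute_force_hbonds <- function(coords, atoms, dist_cutoff = 3.5,
                               angle_cutoff = 150) {
  don <- which(atoms$atom_name == "N")
  acc <- which(atoms$atom_name == "O")
  hyd <- which(atoms$atom_name == "H")
  count <- 0L
  for (d in don) {
    h <- hyd[atoms$strand_index[hyd] == atoms$strand_index[d] &
               atoms$residue_index[hyd] == atoms$residue_index[d]]
    if (length(h) != 1) next
    for (a in acc) {
      if (atoms$strand_index[a] == atoms$strand_index[d] &&
          atoms$residue_index[a] == atoms$residue_index[d]) next
      if (sqrt(sum((coords[a, ] - coords[d, ])^2)) > dist_cutoff) next
      v1 <- coords[d, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff) count <- count + 1L
    }
  }
  count
}

# small fast beam spec for tests that only need structure, not statistics
small_beam_spec <- function(...) {
  beam_spec(n_beads = 10, n_modes_per_family = 2, ...)
}

# rigidly transform every frame of a trajectory
transform_trajectory <- function(traj, angle = 0.5, shift = c(3, -2, 5)) {
  R <- matrix(c(cos(angle), sin(angle), 0, -sin(angle), cos(angle), 0, 0, 0, 1), 3, 3)
  co <- traj$coords
  for (i in seq_len(dim(co)[3]))
    co[, , i] <- sweep(co[, , i] %*% R, 2, shift, `+`)
  fibril_trajectory(co, traj$atoms, traj$time_per_frame)
}
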