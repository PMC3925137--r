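# Geometric backbone hydrogen-bond detection. Donors are backbone amide
# N-H groups, acceptors are carbonyl O atoms; the criterion is the common
# geometric convention D...A <= 3.5 A and D-H...A angle >= 150 deg, with a
# distance-only N...O <= 3.2 A fallback when no hydrogens are present.

#' Detect backbone hydrogen bonds in one frame
#'
#' @param coords n x 3 coordinate matrix, angstrom.
#' @param atoms Topology table with `atom_name`, `residue_index`,
#'   `strand_index` columns.
#' @param dist_cutoff Donor-acceptor distance cutoff, angstrom.
#' @param angle_cutoff Minimum D-H...A angle, degrees (angle at H between the
#'   H->D and H->A directions; 180 = linear).
#' @param fallback_dist N...O cutoff used when the structure carries no amide
#'   hydrogens (a warning is issued).
#' @return data.frame with one row per bond: `donor`, `hydrogen`, `acceptor`
#'   atom indices, `distance` (A), `angle` (deg, NA in fallback mode).
#' @export
detect_hbonds <- function(coords, atoms, dist_cutoff = 3.5, angle_cutoff = 150,
                          fallback_dist = 3.2) {
  don <- which(atoms$atom_name == "N")
  acc <- which(atoms$atom_name == "O")
  if (!length(don) || !length(acc)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  hyd <- which(atoms$atom_name == "H")
  # pair each donor N with the H of the same residue on the same strand
  hmatch <- rep(NA_integer_, length(don))
  if (length(hyd)) {
    key_h <- paste(atoms$strand_index[hyd], atoms$residue_index[hyd])
    key_d <- paste(atoms$strand_index[don], atoms$residue_index[don])
    hmatch <- hyd[match(key_d, key_h)]
  }
  use_angle <- any(!is.na(hmatch))
  if (!use_angle) {
    warning("no amide hydrogens found; using N...O distance-only criterion (",
            fallback_dist, " A)")
    dist_cutoff <- fallback_dist
  }
  out <- list(); k <- 0L
  for (i in seq_along(don)) {
    d <- don[i]
    dv <- sweep(coords[acc, , drop = FALSE], 2, coords[d, ])
    dist <- sqrt(rowSums(dv^2))
    same_res <- atoms$strand_index[acc] == atoms$strand_index[d] &
      atoms$residue_index[acc] == atoms$residue_index[d]
    cand <- which(dist <= dist_cutoff & !same_res)
    for (j in cand) {
      a <- acc[j]; ang <- NA_real_
      if (use_angle) {
        h <- hmatch[i]
        if (is.na(h)) next
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < angle_cutoff) next
      }
      k <- k + 1L
      out[[k]] <- data.frame(donor = d, hydrogen = if (use_angle) hmatch[i] else NA_integer_,
                             acceptor = a, distance = dist[j], angle = ang)
    }
  }
  if (!k) return(data.frame(donor = integer(0), hydrogen = integer(0),
                            acceptor = integer(0), distance = numeric(0),
                            angle = numeric(0)))
  do.call(rbind, out)
}

#' Hydrogen bonds per residue over a trajectory
#'
#' Per-frame bond count divided by the number of residues (distinct
#' strand/residue pairs), with the ensemble mean and fluctuation magnitude.
#'
#' @param traj A `fibril_trajectory` carrying backbone atoms.
#' @param ... Passed to [detect_hbonds()].
#' @return List with `series` (per-frame bonds per residue), `mean`, and `sd`.
#' @export
hbonds_per_residue <- function(traj, ...) {
  n_res <- nrow(unique(traj$atoms[, c("strand_index", "residue_index")]))
  series <- vapply(seq_len(n_frames(traj)), function(i) {
    nrow(detect_hbonds(frame_coords(traj, i), traj$atoms, ...)) / n_res
  }, numeric(1))
  list(series = series, mean = mean(series), sd = stats::sd(series))
}
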