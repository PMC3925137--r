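# Core containers: a fibril structure (topology + one coordinate set) and a
# trajectory (shared topology + ordered frames).

#' Construct a fibril structure
#'
#' @param atoms data.frame with columns `element`, `atom_name`,
#'   `residue_index`, `strand_index`, `layer_index`, `mass` (Da). Extra
#'   columns are preserved.
#' @param coords Numeric matrix, n_atoms x 3, angstrom.
#' @param metadata Optional list (zipper class label, builder parameters, ...).
#' @return Object of class `fibril_structure`.
#' @export
fibril_structure <- function(atoms, coords, metadata = list()) {
  coords <- as.matrix(coords)
  stopifnot(is.data.frame(atoms), ncol(coords) == 3,
            nrow(atoms) == nrow(coords))
  if (!all(is.finite(coords))) stop("non-finite coordinates in structure")
  needed <- c("element", "atom_name", "residue_index", "strand_index",
              "layer_index", "mass")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stop("atoms table lacks columns: ",
                            paste(missing, collapse = ", "))
  # residue_index must be non-decreasing within each strand
  for (s in split(atoms$residue_index, atoms$strand_index)) {
    if (is.unsorted(s[!is.na(s)])) stop("residue_index decreases within a strand")
  }
  structure(list(atoms = atoms, coords = coords, metadata = metadata),
            class = "fibril_structure")
}

#' @export
print.fibril_structure <- function(x, ...) {
  nl <- length(unique(stats::na.omit(x$atoms$layer_index)))
  ns <- length(unique(stats::na.omit(x$atoms$strand_index)))
  cat(sprintf("Fibril structure: %d atoms, %d strands, %d layers\n",
              nrow(x$atoms), ns, nl))
  if (!is.null(x$metadata$class_label))
    cat("  zipper class:", x$metadata$class_label, "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param coords 3-D array `n_atoms x 3 x n_frames` (angstrom) or a list of
#'   n_atoms x 3 matrices.
#' @param atoms Shared topology table (see [fibril_structure()]).
#' @param time_per_frame Sampling interval, ps.
#' @param metadata Optional list.
#' @return Object of class `fibril_trajectory`.
#' @export
fibril_trajectory <- function(coords, atoms, time_per_frame = 1,
                              metadata = list()) {
  if (is.list(coords) && !is.array(coords)) {
    n <- unique(vapply(coords, nrow, integer(1)))
    if (length(n) != 1) stop("frames differ in atom count")
    coords <- array(unlist(coords), dim = c(n, 3, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms)) stop("atom table / coordinate mismatch")
  if (dim(coords)[3] < 1) stop("trajectory needs at least one frame")
  if (time_per_frame <= 0) stop("time_per_frame must be positive")
  structure(list(coords = coords, atoms = atoms,
                 time_per_frame = time_per_frame, metadata = metadata),
            class = "fibril_trajectory")
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ps\n",
              n_frames(x), nrow(x$atoms), x$time_per_frame))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `fibril_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param traj A `fibril_trajectory`.
#' @param i Frame index.
#' @return n_atoms x 3 matrix (angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Mean structure of a trajectory
#' @param traj A `fibril_trajectory`.
#' @return A [fibril_structure()] at the frame-averaged coordinates.
#' @export
mean_structure <- function(traj) {
  m <- apply(traj$coords, c(1, 2), mean)
  fibril_structure(traj$atoms, m, traj$metadata)
}

#' Restrict a trajectory to C-alpha (or bead) atoms
#'
#' Keeps atoms named `CA` in order. Synthetic bead trajectories name their
#' beads `CA` so this is the identity selection there.
#'
#' @param traj A `fibril_trajectory`.
#' @return Sub-trajectory over the selected atoms.
#' @export
select_calpha <- function(traj) {
  keep <- which(traj$atoms$atom_name == "CA")
  if (!length(keep)) stop("no C-alpha atoms in trajectory")
  fibril_trajectory(traj$coords[keep, , , drop = FALSE],
                    traj$atoms[keep, , drop = FALSE],
                    traj$time_per_frame, traj$metadata)
}

#' Discard an equilibration window and subsample frames
#'
#' Drops the leading `discard_fraction` of frames, then keeps every
#' `stride`-th remaining frame; the effective sampling interval is recorded.
#'
#' @param traj A `fibril_trajectory`.
#' @param discard_fraction Fraction in \[0, 1) of leading frames to drop.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @return Windowed `fibril_trajectory`.
#' @export
window_frames <- function(traj, discard_fraction = 0, stride = 1) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1, stride >= 1)
  nf <- n_frames(traj)
  first <- ceiling(discard_fraction * nf) + 1
  if (first > nf) stop("windowing left no frames")
  keep <- seq(first, nf, by = stride)
  fibril_trajectory(traj$coords[, , keep, drop = FALSE], traj$atoms,
                    traj$time_per_frame * stride, traj$metadata)
}
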