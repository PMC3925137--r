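# Rigid-body least-squares superposition (Kabsch) and RMSD time series.

#' Optimal rigid superposition of two coordinate sets
#'
#' Kabsch algorithm: the proper rotation (det = +1) and translation
#' minimizing the least-squares deviation of `mobile` from `ref`. A
#' reflection-only optimum is corrected by flipping the sign of the smallest
#' singular direction.
#'
#' @param mobile,ref n x 3 coordinate matrices (same n >= 3), angstrom.
#' @return List with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` best matches `ref`, and the residual
#'   `rmsd` (angstrom).
#' @export
superpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref)) stop("coordinate sets differ in atom count")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  if (max(abs(X)) == 0 && max(abs(Y)) == 0) {
    R <- diag(3)
  } else {
    H <- crossprod(X, Y)                       # 3x3 covariance
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$u %*% D %*% t(sv$v)
  }
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

#' Apply a rigid transform returned by [superpose()]
#'
#' @param coords n x 3 matrix.
#' @param tf List with `rotation` and `translation`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% tf$rotation, 2, tf$translation, `+`)
}

#' RMSD of every frame against a reference frame
#'
#' Each frame is rigidly superposed onto the reference before the deviation
#' is measured, so the series reflects conformational change only.
#'
#' @param traj A `fibril_trajectory`.
#' @param ref_frame_index Index of the reference frame (default 1).
#' @param fit Superpose each frame first (default TRUE).
#' @return Numeric vector of per-frame RMSD values, angstrom.
#' @export
rmsd_series <- function(traj, ref_frame_index = 1, fit = TRUE) {
  ref <- frame_coords(traj, ref_frame_index)
  vapply(seq_len(n_frames(traj)), function(i) {
    f <- frame_coords(traj, i)
    if (fit) superpose(f, ref)$rmsd else sqrt(mean(rowSums((f - ref)^2)))
  }, numeric(1))
}
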