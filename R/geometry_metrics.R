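# Conformational metrics on layered fibril structures: per-layer frames,
# inter-layer dihedral (twist), bending angle, twist-disorder order
# parameter, and the strands-per-helical-pitch count.

#' Per-layer centroids and in-plane axes
#'
#' For every layer: the centroid, the leading principal axis of the layer's
#' atoms (the strand direction in a cross-beta layer) with its sign fixed by
#' continuity against the previous layer, and the layer normal.
#'
#' @param coords n x 3 coordinate matrix for one frame, angstrom.
#' @param layer_index Integer layer label per atom.
#' @return List with `centroid` (n_layers x 3), `axis` (n_layers x 3 unit
#'   rows), `layers` (sorted labels).
#' @export
layer_frames <- function(coords, layer_index) {
  layers <- sort(unique(layer_index[!is.na(layer_index)]))
  if (length(layers) < 2) stop("need at least 2 layers")
  cent <- matrix(NA_real_, length(layers), 3)
  axis <- matrix(NA_real_, length(layers), 3)
  for (i in seq_along(layers)) {
    P <- coords[layer_index == layers[i], , drop = FALSE]
    if (nrow(P) < 2) stop("layer ", layers[i], " has fewer than 2 atoms")
    cent[i, ] <- colMeans(P)
    C <- sweep(P, 2, cent[i, ])
    a <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 1]
    if (sum(a^2) < 1e-16) stop("degenerate layer axis in layer ", layers[i])
    if (i > 1 && sum(a * axis[i - 1, ]) < 0) a <- -a
    axis[i, ] <- a / sqrt(sum(a^2))
  }
  list(centroid = cent, axis = axis, layers = layers)
}

.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Inter-layer dihedral (twist) angles
#'
#' For each adjacent layer pair (j, j+1) the IUPAC right-handed dihedral of
#' the four points: tip of layer-j axis, centroid j, centroid j+1, tip of
#' layer-(j+1) axis. For an ideal twisted stack this equals the built-in
#' twist per layer; reported in (-180, 180] degrees.
#'
#' @inheritParams layer_frames
#' @return Numeric vector of n_layers - 1 dihedral angles, degrees.
#' @export
layer_dihedral <- function(coords, layer_index) {
  lf <- layer_frames(coords, layer_index)
  n <- nrow(lf$centroid)
  vapply(seq_len(n - 1), function(j) {
    .dihedral4(lf$centroid[j, ] + lf$axis[j, ], lf$centroid[j, ],
               lf$centroid[j + 1, ], lf$centroid[j + 1, ] + lf$axis[j + 1, ])
  }, numeric(1))
}

#' Bending angle of a fibril frame
#'
#' Splits the layer centroids into two contiguous halves at `split`, and
#' measures the angle at the split-point centroid between the two end
#' centroids, reported as the deviation from straight (0 = straight fibril).
#'
#' @inheritParams layer_frames
#' @param split Layer position of the hinge (default: middle layer). The
#'   hinge point is the centroid of layer `split`.
#' @return Bending angle in degrees (0 = straight).
#' @export
bending_angle <- function(coords, layer_index, split = NULL) {
  lf <- layer_frames(coords, layer_index)
  n <- nrow(lf$centroid)
  if (n < 3) stop("bending angle needs at least 3 layer centroids")
  if (is.null(split)) split <- (n + 1) %/% 2
  stopifnot(split > 1, split < n)
  mid <- lf$centroid[split, ]
  v1 <- lf$centroid[1, ] - mid
  v2 <- lf$centroid[n, ] - mid
  ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  180 - acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' Twist-disorder order parameter
#'
#' Scalar disorder measure of the inter-layer dihedral set: the population
#' variance (rad^2) of the dihedrals about their circular mean (default), or
#' the circular standard deviation. A fibril whose order parameter exceeds
#' 0.07 is conventionally flagged as unstable/disordered.
#'
#' @param dihedrals_deg Dihedral angles per layer pair, degrees (n >= 2).
#' @param variant "variance" (rad^2, default) or "circular_sd" (rad).
#' @return Non-negative scalar; 0 iff all dihedrals are equal.
#' @export
order_parameter <- function(dihedrals_deg, variant = c("variance", "circular_sd")) {
  variant <- match.arg(variant)
  if (length(dihedrals_deg) < 2) stop("order parameter needs >= 2 dihedrals")
  th <- dihedrals_deg * pi / 180
  # unwrap onto a continuous branch about the circular mean direction, then
  # take the plain two-pass population variance (equals the ordinary
  # variance whenever the angles do not straddle the +/-180 cut)
  mu <- atan2(mean(sin(th)), mean(cos(th)))
  x <- mu + atan2(sin(th - mu), cos(th - mu))
  v <- mean((x - mean(x))^2)
  if (variant == "variance") v else sqrt(v)
}

#' Flag a disordered fibril from its order parameter
#'
#' @param op Order parameter value (rad^2 variance scale).
#' @param threshold Disorder threshold (default 0.07).
#' @return TRUE when the structure is classified unstable/disordered.
#' @export
is_disordered <- function(op, threshold = 0.07) op > threshold

#' Beta strands per helical pitch
#'
#' Number of strands completing one full 360-degree turn of the fibril helix
#' given the mean inter-layer dihedral: `strands_per_layer * round(360 / d)`.
#'
#' @param mean_dihedral Mean inter-layer dihedral, degrees in (0, 180].
#' @param strands_per_layer Strands per layer (default 2).
#' @return Integer strand count per pitch.
#' @export
strands_per_pitch <- function(mean_dihedral, strands_per_layer = 2) {
  if (mean_dihedral <= 0) stop("mean dihedral must be positive")
  stopifnot(mean_dihedral <= 360)
  as.integer(strands_per_layer * round(360 / mean_dihedral))
}
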