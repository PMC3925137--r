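# Classification of quasi-harmonic modes into continuum deformation families
# (soft/stiff bending, torsion, axial, rigid, mixed) by overlap with the
# analytic free-free mode-shape bases, and inversion of the matched
# frequencies into mechanical properties.

# stations along the fibril axis: prefer the topology's layer_index, fall
# back to 1-D gap clustering of the axial coordinate
.assign_stations <- function(coords, atoms, axis, center) {
  if (!is.null(atoms$layer_index) && !anyNA(atoms$layer_index)) {
    return(as.integer(factor(atoms$layer_index,
                             levels = sort(unique(atoms$layer_index)))))
  }
  s <- as.numeric(sweep(coords, 2, center) %*% axis)
  o <- order(s)
  gaps <- diff(s[o])
  thr <- 0.2 * max(gaps)
  station <- integer(length(s))
  station[o] <- cumsum(c(1, as.integer(gaps > thr)))
  station
}

# principal frame of the mean structure: axis = leading principal direction,
# e1/e2 = principal transverse directions of the perpendicular scatter
.structure_frame <- function(coords) {
  cen <- colMeans(coords)
  P <- sweep(coords, 2, cen)
  ev <- eigen(crossprod(P) / nrow(P), symmetric = TRUE)
  if (ev$values[1] < 3 * ev$values[2])
    stop("degenerate fibril axis: mass distribution is not filament-like")
  axis <- ev$vectors[, 1]
  perp <- P - outer(as.numeric(P %*% axis), axis)
  ev2 <- eigen(crossprod(perp) / nrow(perp), symmetric = TRUE)
  list(center = cen, axis = axis, e1 = ev2$vectors[, 1], e2 = ev2$vectors[, 2])
}

#' Classify quasi-harmonic modes into beam deformation families
#'
#' Each eigenvector is decomposed per axial station into collective
#' transverse (two principal planes), axial, and twist channels; the squared
#' overlap of each channel profile with the corresponding analytic free-free
#' shape basis (bending shapes, torsional/axial cosines) assigns the family.
#' The bending plane whose order-1 mode carries the larger fluctuation
#' eigenvalue (lower frequency) is labelled `soft-bend`, the other
#' `stiff-bend`. Modes whose eigenvalue is below `rigid_tol * xi_1`, or whose
#' best overlap is with the rigid-body basis, are labelled `rigid`; best
#' overlaps below `mixed_threshold` give `mixed`.
#'
#' @param spec An `eigen_spectrum` (with a mean structure, or supply one).
#' @param structure A `fibril_structure` giving topology and, by default, the
#'   mean geometry (overridden by the spectrum's stored mean structure).
#' @param n_orders Analytic shape orders per family in the overlap basis.
#' @param mixed_threshold Minimum overlap for a family assignment.
#' @param rigid_tol Relative eigenvalue threshold for rigid modes.
#' @param max_modes Classify only the leading `max_modes` modes (default all).
#' @return data.frame (`mode_assignment`): `mode`, `family`, `order`,
#'   `overlap`, `xi_A2`; attributes `frame` (axes) and `stations`.
#' @export
classify_modes <- function(spec, structure, n_orders = 4,
                           mixed_threshold = 0.5, rigid_tol = 1e-6,
                           max_modes = NULL) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  coords <- if (!is.null(spec$mean_structure)) spec$mean_structure else structure$coords
  atoms <- structure$atoms
  stopifnot(nrow(coords) == nrow(atoms), nrow(coords) == spec$n_atoms)
  fr <- .structure_frame(coords)
  station <- .assign_stations(coords, atoms, fr$axis, fr$center)
  ns <- max(station)
  if (ns < 4) stop("need at least 4 axial stations to classify modes")
  s_axial <- as.numeric(sweep(coords, 2, fr$center) %*% fr$axis)
  xs <- tapply(s_axial, station, mean)
  t01 <- (xs - min(xs)) / (max(xs) - min(xs))
  ord_s <- order(xs)  # stations sorted along the axis

  # orthonormal analytic bases evaluated at the stations; the internal-mode
  # bases are projected into the complement of the rigid station basis, since
  # the discretely sampled continuum shapes carry a little rigid content
  gs <- function(M) qr.Q(qr(M))
  B_rigid_t <- gs(cbind(rep(1, ns), t01[ord_s] - mean(t01[ord_s])))  # translation + tilt
  B_rigid_c <- matrix(rep(1, ns) / sqrt(ns), ncol = 1)               # translation/spin
  deflate <- function(M, R) M - R %*% crossprod(R, M)
  B_bend <- gs(deflate(vapply(seq_len(n_orders),
                              function(k) beam_mode_shape(k, t01[ord_s]),
                              numeric(ns)), B_rigid_t))
  B_rod <- gs(deflate(vapply(seq_len(n_orders),
                             function(k) rod_mode_shape(k, t01[ord_s]),
                             numeric(ns)), B_rigid_c))

  # per-atom offsets from station centroids, for the twist channel
  d_perp <- matrix(0, nrow(coords), 3)
  r_eff <- numeric(ns)
  for (st in seq_len(ns)) {
    idx <- which(station == st)
    d <- sweep(coords[idx, , drop = FALSE], 2, colMeans(coords[idx, , drop = FALSE]))
    d <- d - outer(as.numeric(d %*% fr$axis), fr$axis)
    d_perp[idx, ] <- d
    r_eff[st] <- sqrt(mean(rowSums(d^2)))
  }

  m_total <- length(spec$values)
  n_classify <- if (is.null(max_modes)) m_total else min(max_modes, m_total)
  xi1 <- max(spec$values[1], .Machine$double.eps)
  res <- data.frame(mode = seq_len(n_classify), family = NA_character_,
                    order = NA_integer_, overlap = NA_real_,
                    xi_A2 = spec$values[seq_len(n_classify)])
  for (j in seq_len(n_classify)) {
    V <- matrix(spec$vectors[, j], ncol = 3, byrow = TRUE)
    c1 <- c2 <- cx <- ct <- numeric(ns)
    for (st in seq_len(ns)) {
      idx <- which(station == st)
      u <- colMeans(V[idx, , drop = FALSE])
      c1[st] <- sum(u * fr$e1); c2[st] <- sum(u * fr$e2); cx[st] <- sum(u * fr$axis)
      dp <- d_perp[idx, , drop = FALSE]
      denom <- sum(rowSums(dp^2))
      if (denom > 1e-12) {
        # least-squares twist angle about the axis, scaled to displacement units
        cr <- dp[, c(2, 3, 1), drop = FALSE] * V[idx, c(3, 1, 2), drop = FALSE] -
          dp[, c(3, 1, 2), drop = FALSE] * V[idx, c(2, 3, 1), drop = FALSE]
        ct[st] <- (as.numeric(cr %*% fr$axis) |> sum()) / denom * r_eff[st]
      }
    }
    c1 <- c1[ord_s]; c2 <- c2[ord_s]; cx <- cx[ord_s]; ct <- ct[ord_s]
    Etot <- sum(c1^2) + sum(c2^2) + sum(cx^2) + sum(ct^2)
    if (Etot < 1e-14 || spec$values[j] < rigid_tol * xi1) {
      res$family[j] <- "rigid"; res$overlap[j] <- NA_real_
      next
    }
    proj <- function(v, B) colSums((t(B) %*% v)^2)
    ov <- c(`bend-1` = sum(proj(c1, B_bend)),
            `bend-2` = sum(proj(c2, B_bend)),
            axial = sum(proj(cx, B_rod)),
            torsion = sum(proj(ct, B_rod)),
            rigid = sum(proj(c1, B_rigid_t)) + sum(proj(c2, B_rigid_t)) +
              sum(proj(cx, B_rigid_c)) + sum(proj(ct, B_rigid_c))) / Etot
    best <- names(ov)[which.max(ov)]
    res$overlap[j] <- max(ov)
    if (max(ov) < mixed_threshold) {
      res$family[j] <- "mixed"
    } else if (best == "rigid") {
      res$family[j] <- "rigid"
    } else {
      res$family[j] <- best
      B <- if (best %in% c("bend-1", "bend-2")) B_bend else B_rod
      v <- switch(best, `bend-1` = c1, `bend-2` = c2, axial = cx, torsion = ct)
      res$order[j] <- which.max(as.numeric(t(B) %*% v)^2)
    }
  }
  # soft/stiff labelling: the bending plane with the larger order-1 eigenvalue
  # fluctuates more, i.e. is the softer plane
  xi_first <- function(fam) {
    hit <- res$family == fam & res$order == 1
    if (any(hit, na.rm = TRUE)) max(res$xi_A2[which(hit)]) else NA_real_
  }
  x1 <- xi_first("bend-1"); x2 <- xi_first("bend-2")
  soft <- if (is.na(x2) || (!is.na(x1) && x1 >= x2)) "bend-1" else "bend-2"
  stiff <- setdiff(c("bend-1", "bend-2"), soft)
  res$family[res$family == soft] <- "soft-bend"
  res$family[res$family == stiff] <- "stiff-bend"
  attr(res, "frame") <- fr
  attr(res, "stations") <- station
  class(res) <- c("mode_assignment", "data.frame")
  res
}

# Section properties (area and centroidal second moments) of one station's
# atom-center convex hull inflated outward by r_eff (miter offset along the
# vertex normals; corner rounding neglected). Exact shoelace integrals on the
# offset polygon. Degenerate sections (< 3 non-collinear points) fall back to
# a rectangle of width 2 r_eff along the point spread.
.section_properties <- function(x, y, r_eff) {
  pts <- unique(cbind(x, y))
  degenerate <- nrow(pts) < 3
  if (!degenerate) {
    h <- grDevices::chull(pts)
    P <- pts[h, , drop = FALSE]
    cross2 <- sum(P[, 1] * P[c(2:nrow(P), 1), 2] - P[c(2:nrow(P), 1), 1] * P[, 2])
    degenerate <- nrow(P) < 3 || abs(cross2) < 1e-9 * max(1, max(abs(pts))^2)
  }
  if (degenerate) {
    cen <- colMeans(pts)
    d <- sweep(pts, 2, cen)
    ev <- eigen(crossprod(d) / max(nrow(d), 1), symmetric = TRUE)
    len <- if (nrow(pts) > 1) 2 * sqrt(max(ev$values[1], 0)) * sqrt(3) else 0
    a <- len + 2 * r_eff; b <- 2 * r_eff
    dirm <- if (nrow(pts) > 1) ev$vectors[, 1] else c(1, 0)
    # rectangle a x b with long side along dirm, moments rotated to (u, v)
    I_long <- a * b^3 / 12; I_short <- b * a^3 / 12
    c2 <- dirm[1]^2; s2 <- dirm[2]^2
    return(list(A = a * b,
                Iu = I_short * c2 + I_long * s2,
                Iv = I_short * s2 + I_long * c2))
  }
  if (cross2 < 0) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]  # force CCW
  if (r_eff > 0) {
    n <- nrow(P)
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    en <- function(i, j) {                      # outward edge normal i -> j
      e <- P[j, ] - P[i, ]
      c(e[2], -e[1]) / sqrt(sum(e^2))
    }
    Q <- P
    for (i in seq_len(n)) {
      n1 <- en(prv[i], i); n2 <- en(i, nxt[i])
      m <- n1 + n2; m <- m / sqrt(sum(m^2))
      cosh2 <- sqrt((1 + sum(n1 * n2)) / 2)     # cos of half exterior angle
      Q[i, ] <- P[i, ] + m * r_eff / max(cosh2, 0.1)
    }
    P <- Q
  }
  xs <- P[, 1]; ys <- P[, 2]
  xn <- xs[c(2:length(xs), 1)]; yn <- ys[c(2:length(ys), 1)]
  cr <- xs * yn - xn * ys
  A <- sum(cr) / 2
  cx <- sum((xs + xn) * cr) / (6 * A)
  cy <- sum((ys + yn) * cr) / (6 * A)
  xs <- xs - cx; ys <- ys - cy
  xn <- xs[c(2:length(xs), 1)]; yn <- ys[c(2:length(ys), 1)]
  cr <- xs * yn - xn * ys
  Iu <- sum((xs^2 + xs * xn + xn^2) * cr) / 12  # second moment of the u-coordinate
  Iv <- sum((ys^2 + ys * yn + yn^2) * cr) / 12
  list(A = A, Iu = Iu, Iv = Iv)
}

#' Estimate beam geometry from a mean structure
#'
#' `model = "envelope"`: length is the extent along the principal axis, mass
#' per length the total mass over that length; the cross-section area and
#' second moments are the per-station averages of the atom-center convex
#' hull inflated outward by an effective atomic radius `r_eff` (exact polygon
#' integrals); the rotary inertia per length comes directly from the mass
#' distribution. `model = "fixed"`: the caller supplies `A`, `I_y`, `I_z`
#' (and optionally `J`), and only `L`, `mu` and the rotary inertia are
#' measured.
#'
#' @param structure A `fibril_structure` with masses (Da).
#' @param model "envelope" or "fixed".
#' @param A,I_y,I_z,J Section values (SI) for `model = "fixed"`.
#' @param r_eff Effective atomic radius for the envelope, angstrom.
#' @return A [beam_geometry()].
#' @export
estimate_cross_section <- function(structure, model = c("envelope", "fixed"),
                                   A = NULL, I_y = NULL, I_z = NULL, J = NULL,
                                   r_eff = 3) {
  model <- match.arg(model)
  coords <- structure$coords
  atoms <- structure$atoms
  fr <- .structure_frame(coords)
  s <- as.numeric(sweep(coords, 2, fr$center) %*% fr$axis)
  L_m <- (max(s) - min(s)) * fm_constants$A
  if (L_m <= 0) stop("structure has no axial extent")
  mass_kg <- sum(atoms$mass) * fm_constants$Da
  mu <- mass_kg / L_m
  # rotary inertia per unit length about the fibril axis (mass-based)
  P <- sweep(coords, 2, fr$center)
  perp2 <- rowSums((P - outer(as.numeric(P %*% fr$axis), fr$axis))^2)
  iota <- sum(atoms$mass * fm_constants$Da * perp2 * fm_constants$A^2) / L_m
  if (model == "fixed") {
    stopifnot(!is.null(A), !is.null(I_y), !is.null(I_z))
    return(beam_geometry(L = L_m, mu = mu, A = A, I_y = I_y, I_z = I_z, J = J,
                         inertia_per_length = iota))
  }
  station <- .assign_stations(coords, atoms, fr$axis, fr$center)
  if (max(station) < 4) stop("envelope model needs at least 4 stations")
  u <- as.numeric(P %*% fr$e1); v <- as.numeric(P %*% fr$e2)
  areas <- c(); i22 <- c(); i11 <- c()
  for (st in seq_len(max(station))) {
    idx <- which(station == st)
    sec <- .section_properties(u[idx], v[idx], r_eff)
    areas <- c(areas, sec$A); i11 <- c(i11, sec$Iu); i22 <- c(i22, sec$Iv)
  }
  A_m2 <- mean(areas) * fm_constants$A^2
  Ia <- mean(i11) * fm_constants$A^4   # bending displacement along e1
  Ib <- mean(i22) * fm_constants$A^4   # along e2
  beam_geometry(L = L_m, mu = mu, A = A_m2,
                I_y = max(Ia, Ib), I_z = min(Ia, Ib),
                inertia_per_length = iota)
}

#' Mechanical properties from a classified spectrum
#'
#' Pairs each deformation family's lowest-order classified mode with its
#' quasi-harmonic frequency and inverts the free-free beam relations into
#' rigidities (always) and moduli (when the geometry carries a section).
#'
#' @param spec An `eigen_spectrum`.
#' @param assignment Result of [classify_modes()].
#' @param geom A [beam_geometry()], e.g. from [estimate_cross_section()].
#' @param n_rigid Rigid-mode count for the frequency table.
#' @return Object of class `mechanical_properties`: data.frame with one row
#'   per family (`family`, `mode`, `order`, `nu_THz`, `rigidity`, `modulus`,
#'   `persistence_length_m`), plus attribute `temperature`.
#' @export
fibril_mechanics <- function(spec, assignment, geom, n_rigid = 6) {
  # under-sampled trajectories can leave more than n_rigid numerically zero
  # eigenvalues; frequencies are only defined on the positive part
  floor_xi <- 1e-12 * max(spec$values[1], .Machine$double.eps)
  n_zero <- sum(spec$values <= floor_xi)
  freqs <- natural_frequencies(spec, n_rigid = max(n_rigid, n_zero))
  rows <- list()
  for (fam in c("soft-bend", "stiff-bend", "torsion", "axial")) {
    sel <- which(assignment$family == fam & !is.na(assignment$order))
    if (!length(sel)) next
    j <- sel[which.min(assignment$order[sel])]
    n <- assignment$order[j]
    omega <- freqs$omega_rad_s[assignment$mode[j]]
    if (is.na(omega)) next
    inv <- switch(fam,
                  "soft-bend" = invert_bending(omega, geom, n, "soft", spec$temperature),
                  "stiff-bend" = invert_bending(omega, geom, n, "stiff", spec$temperature),
                  "torsion" = invert_torsion(omega, geom, n),
                  "axial" = invert_axial(omega, geom, n))
    rows[[fam]] <- data.frame(
      family = fam, mode = assignment$mode[j], order = n,
      nu_THz = freqs$nu_THz[assignment$mode[j]],
      rigidity = inv$rigidity, modulus = inv$modulus,
      persistence_length_m = if (fam == "soft-bend") inv$persistence_length else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "temperature") <- spec$temperature
  class(out) <- c("mechanical_properties", "data.frame")
  out
}
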