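# Shrake-Rupley solvent-accessible surface area and the SASA-proportional
# nonpolar solvation energy.

#' Bondi van der Waals radii for common elements
#'
#' @param elements Character vector of element symbols.
#' @return Numeric radii, angstrom.
#' @export
vdw_radii <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- tab[toupper(elements)]
  if (anyNA(r)) stop("no van der Waals radius for element(s): ",
                     paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere is expanded by the probe radius and covered with a
#' deterministic quasi-uniform point mesh; the accessible fraction is the
#' share of mesh points not buried inside any neighbor's expanded sphere,
#' times the expanded-sphere area `4 pi (r + probe)^2`.
#'
#' @param coords n x 3 coordinate matrix, angstrom.
#' @param radii Per-atom van der Waals radii, angstrom (all > 0).
#' @param probe Probe radius, angstrom (default 1.4, a water probe).
#' @param n_sphere_points Mesh points per atom (>= 16; default 960).
#' @return List with `total` (A^2) and `per_atom` (numeric vector, A^2).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_sphere_points = 960) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(radii), all(radii > 0), probe >= 0)
  if (n_sphere_points < 16) stop("n_sphere_points must be at least 16")
  pts <- .sphere_points(n_sphere_points)
  n <- nrow(coords)
  rexp <- radii + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    test <- sweep(pts * rexp[i], 2, coords[i, ], `+`)
    dv <- sweep(coords, 2, coords[i, ])
    nb <- which(rowSums(dv^2) < (rexp + rexp[i])^2 & seq_len(n) != i)
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dd <- sweep(test, 2, coords[j, ])
      accessible <- accessible & (rowSums(dd^2) > rexp[j]^2)
      if (!any(accessible)) break
    }
    per_atom[i] <- mean(accessible) * 4 * pi * rexp[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation energy from SASA
#'
#' The SASA-proportional nonpolar term of an MM-PBSA decomposition:
#' `dG_np = gamma * SASA + beta`, with the conventional surface-tension
#' coefficient gamma = 0.00542 kcal/(mol A^2) and intercept
#' beta = 0.92 kcal/mol.
#'
#' @param sasa_value Solvent-accessible surface area, A^2 (>= 0).
#' @param gamma Surface tension coefficient, kcal/(mol A^2).
#' @param beta_const Intercept, kcal/mol.
#' @return Nonpolar solvation energy, kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_value, gamma = 0.00542, beta_const = 0.92) {
  stopifnot(all(sasa_value >= 0))
  gamma * sasa_value + beta_const
}
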