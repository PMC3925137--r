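# Continuum Euler-Bernoulli layer: free-free mode shapes, the analytic
# frequency relations for bending / torsion / axial families, and their
# algebraic inversion into rigidities and moduli.

#' Roots of the free-free bending characteristic equation
#'
#' Bending eigenvalues of an unconstrained (free-free) Euler-Bernoulli beam
#' satisfy `cos(lambda) * cosh(lambda) = 1`. The first roots are tabulated to
#' full double precision and higher orders are obtained by Newton refinement
#' of the asymptotic guess `lambda_n ~ (2n + 1) * pi / 2`.
#'
#' @param n Mode orders (positive integers), vectorized.
#' @return Numeric vector of roots `lambda_n = beta_n * L`.
#' @export
free_free_roots <- function(n) {
  stopifnot(all(n >= 1), all(n == round(n)))
  tabulated <- c(4.730040744862704, 7.853204624095838, 10.995607838001671,
                 14.137165491257464, 17.278759657399480)
  vapply(as.integer(n), function(k) {
    lam <- if (k <= length(tabulated)) tabulated[k] else (2 * k + 1) * pi / 2
    # Newton on f = cos(l)cosh(l) - 1; cosh overflows are avoided by working
    # with g = cos(l) - sech(l), which has the same roots.
    for (i in 1:50) {
      g  <- cos(lam) - 1 / cosh(lam)
      dg <- -sin(lam) + tanh(lam) / cosh(lam)
      step <- g / dg
      lam <- lam - step
      if (abs(step) < 1e-14) break
    }
    lam
  }, numeric(1))
}

#' Free-free bending mode shape
#'
#' Evaluates the order-`n` transverse mode shape of a free-free beam,
#' `phi_n(x) = (cosh(b x) + cos(b x)) - sigma_n (sinh(b x) + sin(b x))`
#' with `b = lambda_n / L` and
#' `sigma_n = (cosh(lambda_n) - cos(lambda_n)) / (sinh(lambda_n) - sin(lambda_n))`,
#' normalized to unit discrete norm over the supplied stations.
#'
#' @param n Mode order (>= 1).
#' @param x_over_L Positions along the beam as fractions in \[0, 1\].
#' @param normalize Normalize to unit Euclidean norm over the stations
#'   (default TRUE).
#' @return Numeric vector of shape values at `x_over_L`.
#' @export
beam_mode_shape <- function(n, x_over_L, normalize = TRUE) {
  stopifnot(length(n) == 1, n >= 1, all(x_over_L >= -1e-12), all(x_over_L <= 1 + 1e-12))
  lam <- free_free_roots(n)
  sig <- (cosh(lam) - cos(lam)) / (sinh(lam) - sin(lam))
  z <- lam * x_over_L
  phi <- (cosh(z) + cos(z)) - sig * (sinh(z) + sin(z))
  if (normalize) phi <- phi / sqrt(sum(phi^2))
  phi
}

#' Free-free torsional / axial mode shape
#'
#' Torsion and axial vibration of a free-free uniform beam share the shape
#' family `cos(n pi x / L)` (the n = 0 member is the rigid-body mode and is
#' excluded).
#'
#' @inheritParams beam_mode_shape
#' @return Numeric vector of shape values at `x_over_L`.
#' @export
rod_mode_shape <- function(n, x_over_L, normalize = TRUE) {
  stopifnot(length(n) == 1, n >= 1)
  psi <- cos(n * pi * x_over_L)
  if (normalize) psi <- psi / sqrt(sum(psi^2))
  psi
}

#' Beam cross-section and inertia description
#'
#' Bundles the geometric quantities entering the frequency relations. Only
#' `L` and `mu` are required for the assumption-free rigidity outputs;
#' `A`, `I_y`, `I_z`, `J` enable conversion of rigidities to moduli (Pa) and
#' `inertia_per_length` (rotary inertia per unit length, kg m) enters the
#' torsional relation. By convention `I_z <= I_y`: z is the soft bending axis.
#'
#' @param L Beam length, m.
#' @param mu Mass per unit length, kg/m.
#' @param A Cross-section area, m^2 (optional).
#' @param I_y,I_z Principal second moments of area, m^4 (optional).
#' @param J Polar second moment, m^4; defaults to `I_y + I_z` when both given.
#' @param inertia_per_length Rotary inertia per unit length about the beam
#'   axis, kg m; defaults to `rho * J` when `A` and `J` are available.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(L, mu, A = NULL, I_y = NULL, I_z = NULL, J = NULL,
                          inertia_per_length = NULL) {
  stopifnot(L > 0, mu > 0)
  if (!is.null(I_y) && !is.null(I_z)) {
    stopifnot(I_y > 0, I_z > 0)
    if (I_z > I_y) stop("convention violated: I_z (soft axis) must be <= I_y")
    if (is.null(J)) J <- I_y + I_z
  }
  rho <- if (!is.null(A)) mu / A else NULL
  if (is.null(inertia_per_length) && !is.null(rho) && !is.null(J)) {
    inertia_per_length <- rho * J
  }
  structure(list(L = L, mu = mu, A = A, I_y = I_y, I_z = I_z, J = J,
                 rho = rho, inertia_per_length = inertia_per_length),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("Beam geometry: L =", format(x$L, digits = 4), "m, mu =",
      format(x$mu, digits = 4), "kg/m\n")
  if (!is.null(x$A)) cat("  A =", format(x$A, digits = 4), "m^2, rho =",
                         format(x$rho, digits = 4), "kg/m^3\n")
  if (!is.null(x$I_y)) cat("  I_y =", format(x$I_y, digits = 4),
                           " I_z =", format(x$I_z, digits = 4),
                           " J =", format(x$J, digits = 4), "m^4\n")
  invisible(x)
}

#' Analytic free-free natural frequencies
#'
#' Frequency relations of the uniform free-free beam:
#' bending `omega_n = lambda_n^2 sqrt(EI / (mu L^4))`,
#' torsion `omega_n = (n pi / L) sqrt(GJ / iota)` with `iota` the rotary
#' inertia per unit length (equal to `rho J` for a homogeneous section), and
#' axial `omega_n = (n pi / L) sqrt(EA / mu)`.
#'
#' @param geom A [beam_geometry()].
#' @param family One of "soft-bend", "stiff-bend", "torsion", "axial".
#' @param n Mode order(s), >= 1.
#' @param rigidity The family's rigidity: `E_B I` (N m^2) for bending,
#'   `G_T J` (N m^2) for torsion, `E_X A` (N) for axial.
#' @return Angular frequencies, rad/s.
#' @export
analytic_frequencies <- function(geom, family, n, rigidity) {
  stopifnot(inherits(geom, "beam_geometry"), all(n >= 1), rigidity > 0)
  family <- match.arg(family, c("soft-bend", "stiff-bend", "torsion", "axial"))
  if (family %in% c("soft-bend", "stiff-bend")) {
    lam <- free_free_roots(n)
    lam^2 * sqrt(rigidity / (geom$mu * geom$L^4))
  } else if (family == "torsion") {
    if (is.null(geom$inertia_per_length))
      stop("torsional frequency needs inertia_per_length (or A and J) in geometry")
    (n * pi / geom$L) * sqrt(rigidity / geom$inertia_per_length)
  } else {
    (n * pi / geom$L) * sqrt(rigidity / geom$mu)
  }
}

#' Invert a bending frequency into rigidity, modulus and persistence length
#'
#' Algebraic inverse of the bending relation:
#' `E_B I = omega^2 mu L^4 / lambda_n^4`. The bending modulus `E_B = EI / I`
#' is reported when the geometry carries the matching principal moment, and
#' the persistence length is `l_p = EI / (kB T)`.
#'
#' @param omega Angular frequency, rad/s.
#' @param geom A [beam_geometry()].
#' @param n Bending mode order the frequency belongs to.
#' @param plane "soft" (I_z) or "stiff" (I_y); selects the principal moment
#'   for the modulus conversion.
#' @param temperature Temperature in K for the persistence length.
#' @return List with `rigidity` (N m^2), `modulus` (Pa or NA), and
#'   `persistence_length` (m).
#' @export
invert_bending <- function(omega, geom, n = 1, plane = c("soft", "stiff"),
                           temperature = 300) {
  stopifnot(omega > 0, inherits(geom, "beam_geometry"))
  plane <- match.arg(plane)
  lam <- free_free_roots(n)
  EI <- omega^2 * geom$mu * geom$L^4 / lam^4
  I <- if (plane == "soft") geom$I_z else geom$I_y
  list(rigidity = EI,
       modulus = if (is.null(I)) NA_real_ else EI / I,
       persistence_length = persistence_length(EI, temperature))
}

#' Persistence length of a filament
#'
#' `l_p = E_B I / (kB T)`: the ratio of bending rigidity to thermal energy.
#'
#' @param rigidity Bending rigidity `E_B I`, N m^2.
#' @param temperature Temperature, K.
#' @return Persistence length in m.
#' @export
persistence_length <- function(rigidity, temperature = 300) {
  stopifnot(all(rigidity > 0))
  rigidity / kBT(temperature)
}

#' Invert a torsional frequency
#'
#' `G_T J = iota (omega L / (n pi))^2`; with a homogeneous section
#' (`iota = rho J`) this reduces to the textbook `G_T = rho (omega L / n pi)^2`
#' and the polar moment J cancels from the modulus.
#'
#' @inheritParams invert_bending
#' @return List with `rigidity` (`G_T J`, N m^2) and `modulus` (`G_T`, Pa, NA
#'   when the geometry lacks a density).
#' @export
invert_torsion <- function(omega, geom, n = 1) {
  stopifnot(omega > 0, n >= 1, inherits(geom, "beam_geometry"))
  if (is.null(geom$inertia_per_length))
    stop("torsional inversion needs inertia_per_length (or A and J) in geometry")
  GJ <- geom$inertia_per_length * (omega * geom$L / (n * pi))^2
  modulus <- if (!is.null(geom$rho)) (omega * geom$L / (n * pi))^2 * geom$rho else NA_real_
  if (!is.null(geom$J)) modulus <- GJ / geom$J
  list(rigidity = GJ, modulus = modulus)
}

#' Invert an axial frequency
#'
#' `E_X A = mu (omega L / (n pi))^2`, i.e. `E_X = rho (omega L / n pi)^2`.
#'
#' @inheritParams invert_bending
#' @return List with `rigidity` (`E_X A`, N) and `modulus` (`E_X`, Pa, NA
#'   without a cross-section area).
#' @export
invert_axial <- function(omega, geom, n = 1) {
  stopifnot(omega > 0, n >= 1, inherits(geom, "beam_geometry"))
  EA <- geom$mu * (omega * geom$L / (n * pi))^2
  list(rigidity = EA,
       modulus = if (is.null(geom$A)) NA_real_ else EA / geom$A)
}
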