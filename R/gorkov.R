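# Gor'kov potential and acoustic radiation force on a Rayleigh-regime sphere.
#
# The potential is implemented in the modified form
#   U = 2 K1 |p|^2 - 2 K2 (|px|^2 + |py|^2 + |pz|^2)
# with
#   K1 = (V/4) (1/(c0^2 rho0) - 1/(c1^2 rho1))
#   K2 = (3V/4) (rho0 - rho1) / (omega^2 rho0 (rho0 + 2 rho1)).
# These prefactors differ from the textbook Gor'kov convention (roughly a
# factor two on the monopole term and an opposite sign on the dipole term);
# a "classic" variant is available for cross-checks. The force is F = -grad U.

#' Gor'kov coefficients
#'
#' Material-contrast coefficients of the radiation-force potential. Both are
#' linear in the particle volume, so the force scales exactly with the cube
#' of the particle diameter. For a particle acoustically matched to the
#' medium both vanish.
#'
#' @param medium An [medium()] object (density `rho0`, sound speed `c0`).
#' @param particle A [particle_spec()] (density `rho1`, sound speed `c1`,
#'   volume `V`).
#' @param omega Angular frequency of the drive (rad/s).
#' @param variant `"modified"` (default) uses the prefactors above;
#'   `"classic"` returns coefficients that make
#'   `U = 2 K1 |p|^2 - 2 K2 |grad p|^2` equal the textbook Gor'kov
#'   potential with monopole/dipole factors
#'   `f1 = 1 - rho0 c0^2 / (rho1 c1^2)` and
#'   `f2 = 2 (rho1 - rho0) / (2 rho1 + rho0)`.
#' @return An object of class `acoustonav_gorkov` with fields `K1`, `K2`,
#'   `omega`, `variant`.
#' @examples
#' co <- gorkov_coefficients(medium(), particle_spec(), 2 * pi * 1e6)
#' co$K1  # ~7.04e-27 for 10 um polystyrene in water
#' @export
gorkov_coefficients <- function(medium, particle, omega,
                                variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  stopifnot(omega > 0)
  rho0 <- medium$density; c0 <- medium$sound_speed
  rho1 <- particle$density; c1 <- particle$sound_speed
  V <- particle$volume
  lambda <- 2 * pi * c0 / omega
  if (particle$diameter > lambda / 10)
    warning("particle diameter exceeds lambda/10: Rayleigh-regime potential is questionable")
  if (variant == "modified") {
    K1 <- (V / 4) * (1 / (c0^2 * rho0) - 1 / (c1^2 * rho1))
    K2 <- (3 * V / 4) * (rho0 - rho1) / (omega^2 * rho0 * (rho0 + 2 * rho1))
  } else {
    f1 <- 1 - rho0 * c0^2 / (rho1 * c1^2)
    f2 <- 2 * (rho1 - rho0) / (2 * rho1 + rho0)
    K1 <- V * f1 / (8 * rho0 * c0^2)
    K2 <- (3 * V / 16) * f2 / (omega^2 * rho0)
  }
  structure(list(K1 = K1, K2 = K2, omega = omega, variant = variant),
            class = "acoustonav_gorkov")
}

#' Gor'kov potential from a field sample
#'
#' `U = 2 K1 |p|^2 - 2 K2 (|px|^2 + |py|^2 + |pz|^2)` (J), vectorised over
#' samples.
#'
#' @param field An `acoustonav_field` (from [field_with_derivatives()]) or
#'   any list with complex components `p, px, py, pz`.
#' @param coeffs [gorkov_coefficients()] output.
#' @return Numeric vector of potential values (J).
#' @export
gorkov_potential <- function(field, coeffs) {
  2 * coeffs$K1 * Mod(field$p)^2 -
    2 * coeffs$K2 * (Mod(field$px)^2 + Mod(field$py)^2 + Mod(field$pz)^2)
}

#' Acoustic radiation force
#'
#' `F = -grad U` evaluated by central differences of the Gor'kov potential
#' with step `step_h` (default one two-hundredth of a wavelength). The
#' potential is quadratic in the pressure amplitude, so the force scales
#' with the square of the peak pressure and with the cube of the particle
#' diameter.
#'
#' @param array An `acoustonav_array`.
#' @param points A 3-vector or n x 3 matrix (m).
#' @param medium An [medium()] object.
#' @param particle A [particle_spec()].
#' @param step_h Finite-difference step (m).
#' @return An n x 3 matrix of forces (N).
#' @export
radiation_force <- function(array, points, medium, particle, step_h = NULL) {
  P <- .as_points(points)
  k <- wavenumber(medium, array$frequency)
  lambda <- 2 * pi / k
  h <- step_h %||% (lambda / 200)
  co <- gorkov_coefficients(medium, particle, 2 * pi * array$frequency)
  n <- nrow(P)
  F <- matrix(0, n, 3L)
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- h
    Up <- gorkov_potential(
      field_with_derivatives(array, P + matrix(e, n, 3L, byrow = TRUE),
                             medium, step_h = h), co)
    Um <- gorkov_potential(
      field_with_derivatives(array, P - matrix(e, n, 3L, byrow = TRUE),
                             medium, step_h = h), co)
    F[, a] <- -(Up - Um) / (2 * h)
  }
  F
}

#' Radiation force and potential over a set of grid nodes
#'
#' Convenience wrapper evaluating [radiation_force()] and the potential at
#' each node, returned as a long table suitable for CSV/VTK export.
#'
#' @param array An `acoustonav_array`.
#' @param grid_points n x 3 matrix of node coordinates (m).
#' @param medium An [medium()] object.
#' @param particle A [particle_spec()].
#' @param step_h Finite-difference step (m).
#' @return Data frame `x, y, z, Fx, Fy, Fz, U`.
#' @export
force_map <- function(array, grid_points, medium, particle, step_h = NULL) {
  P <- .as_points(grid_points)
  co <- gorkov_coefficients(medium, particle, 2 * pi * array$frequency)
  U <- gorkov_potential(field_with_derivatives(array, P, medium, step_h), co)
  F <- radiation_force(array, P, medium, particle, step_h)
  data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
             Fx = F[, 1], Fy = F[, 2], Fz = F[, 3], U = U)
}
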