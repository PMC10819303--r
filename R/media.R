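#' Acoustic propagation medium
#'
#' Bundles the fluid properties that enter the piston-source field model,
#' the Gor'kov coefficients and the Stokes drag: mass density, speed of
#' sound and dynamic viscosity. All quantities are SI.
#'
#' @param density Fluid density (kg/m^3).
#' @param sound_speed Speed of sound in the fluid (m/s).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return An object of class `acoustonav_medium`.
#' @seealso [medium_preset()] for the bundled water and simulation-table
#'   parameter sets, [wavenumber()].
#' @examples
#' water <- medium(997, 1450, 1e-3)
#' wavenumber(water, 1e6)
#' @export
medium <- function(density = 997, sound_speed = 1450, viscosity = 1e-3) {
  stopifnot(is.numeric(density), density > 0,
            is.numeric(sound_speed), sound_speed > 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(density = density, sound_speed = sound_speed,
                 viscosity = viscosity),
            class = "acoustonav_medium")
}

#' Bundled medium parameter sets
#'
#' `"water"` is plain water (997 kg/m^3, 1450 m/s, 1e-3 Pa s), the default
#' carrier fluid. `"blood_like"` keeps the water density and sound speed but
#' raises the viscosity to 5e-3 Pa s, representative of whole blood; it
#' mainly rescales the Stokes drag.
#'
#' @param name Preset name.
#' @return An `acoustonav_medium`.
#' @export
medium_preset <- function(name = c("water", "blood_like")) {
  name <- match.arg(name)
  switch(name,
         water  = medium(997, 1450, 1e-3),
         blood_like = medium(997, 1450, 5e-3))
}

#' @export
print.acoustonav_medium <- function(x, ...) {
  cat(sprintf("<medium> rho0 = %g kg/m^3, c0 = %g m/s, eta = %g Pa s\n",
              x$density, x$sound_speed, x$viscosity))
  invisible(x)
}

#' Spherical particle specification
#'
#' Material and size of the transported microsphere. The volume
#' `V = pi d^3 / 6` is derived and stored; it sets the scale of both Gor'kov
#' coefficients, so the radiation force is exactly proportional to the cube
#' of the diameter while Stokes drag is linear in it.
#'
#' @param diameter Particle diameter (m).
#' @param density Particle density (kg/m^3).
#' @param sound_speed Longitudinal sound speed in the particle material (m/s).
#' @return An object of class `acoustonav_particle`.
#' @seealso [particle_preset()], [gorkov_coefficients()],
#'   [particle_response_time()].
#' @export
particle_spec <- function(diameter = 10e-6, density = 1050,
                          sound_speed = 1500) {
  stopifnot(diameter > 0, density > 0, sound_speed > 0)
  structure(list(diameter = diameter, density = density,
                 sound_speed = sound_speed,
                 volume = pi * diameter^3 / 6),
            class = "acoustonav_particle")
}

#' Bundled particle parameter sets
#'
#' `"polystyrene"`: 10 um polystyrene bead (1050 kg/m^3, 1500 m/s), the
#' default. `"polystyrene_light"`: the same bead with the slightly lighter
#' density 1032 kg/m^3 sometimes quoted for suspension-grade beads.
#'
#' @param name Preset name.
#' @param diameter Particle diameter (m), 10 um by default.
#' @return An `acoustonav_particle`.
#' @export
particle_preset <- function(name = c("polystyrene", "polystyrene_light"),
                            diameter = 10e-6) {
  name <- match.arg(name)
  switch(name,
         polystyrene = particle_spec(diameter, 1050, 1500),
         polystyrene_light = particle_spec(diameter, 1032, 1500))
}

#' @export
print.acoustonav_particle <- function(x, ...) {
  cat(sprintf("<particle> d = %g um, rho1 = %g kg/m^3, c1 = %g m/s\n",
              x$diameter * 1e6, x$density, x$sound_speed))
  invisible(x)
}

#' Acoustic wavenumber
#'
#' `k = 2 pi f / c0` for a given medium and drive frequency.
#'
#' @param medium An [medium()] object.
#' @param frequency Drive frequency (Hz).
#' @return Wavenumber (1/m).
#' @export
wavenumber <- function(medium, frequency) {
  stopifnot(frequency > 0)
  2 * pi * frequency / medium$sound_speed
}
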