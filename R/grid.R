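# Precomputed radiation-force grid.
#
# The acoustic field is static during a run, while the tracer takes 1e4-1e5
# time steps, so the simulator's default fast path evaluates the complex
# pressure once on a regular grid spanning the lumen, forms the Gor'kov
# potential, differences it into a force field, and trilinearly interpolates
# forces at particle positions. The pointwise stencil operations
# (field_with_derivatives / radiation_force) remain the reference
# implementation; the grid path is cross-checked against them in the tests.

#' Precompute the radiation force on a regular grid
#'
#' Evaluates the array pressure on a regular grid (default spacing one
#' twentieth of a wavelength), differences it into the pressure gradient,
#' forms the Gor'kov potential, and differences that into the force field
#' `F = -grad U`. The box defaults to the bounding box of the vessel lumen
#' plus a margin wide enough for the interior stencils.
#'
#' @param array An `acoustonav_array` (phased and normalised).
#' @param medium An [medium()] object.
#' @param particle A [particle_spec()].
#' @param geometry An [vessel_geometry()]; used only for the default box.
#' @param box 2 x 3 matrix `rbind(lower, upper)` (m); overrides `geometry`.
#' @param spacing Grid spacing (m).
#' @return An object of class `acoustonav_force_grid` with node coordinate
#'   vectors `x, y, z`, force component arrays `Fx, Fy, Fz` (N) and the
#'   potential array `U` (J).
#' @seealso [interpolate_force()]
#' @export
build_force_grid <- function(array, medium, particle, geometry = NULL,
                             box = NULL, spacing = NULL) {
  k <- wavenumber(medium, array$frequency)
  lambda <- 2 * pi / k
  h <- spacing %||% (lambda / 20)
  if (is.null(box)) {
    if (is.null(geometry)) stop("need a geometry or an explicit box")
    gc <- .geom_cache(geometry)
    ap <- gc$apex
    xr <- c(ap[1] - gc$lin - gc$bufin - gc$rin,
            ap[1] + (gc$lb + gc$bufout) * gc$elx + gc$rout)
    yw <- max(gc$rin, (gc$lb + gc$bufout) * gc$ely + gc$rout)
    yr <- c(ap[2] - yw, ap[2] + yw)
    zr <- c(ap[3] - gc$rin, ap[3] + gc$rin)
    m <- 4 * h
    box <- rbind(c(xr[1] - m, yr[1] - m, zr[1] - m),
                 c(xr[2] + m, yr[2] + m, zr[2] + m))
  }
  x <- seq(box[1, 1], box[2, 1], by = h)
  y <- seq(box[1, 2], box[2, 2], by = h)
  z <- seq(box[1, 3], box[2, 3], by = h)
  nx <- length(x); ny <- length(y); nz <- length(z)
  if (min(nx, ny, nz) < 7L) stop("grid box too small for the stencils")
  X <- rep(x, times = ny * nz)
  Y <- rep(rep(y, each = nx), times = nz)
  Z <- rep(z, each = nx * ny)
  p <- .pressure_sum(array$elements, X, Y, Z, k, pi / (2 * k))
  dim(p) <- c(nx, ny, nz)

  dif <- function(arr, axis) {  # central difference along one axis
    d <- array(0, dim(arr))
    if (axis == 1L) d[2:(nx - 1), , ] <- (arr[3:nx, , ] - arr[1:(nx - 2), , ]) / (2 * h)
    if (axis == 2L) d[, 2:(ny - 1), ] <- (arr[, 3:ny, ] - arr[, 1:(ny - 2), ]) / (2 * h)
    if (axis == 3L) d[, , 2:(nz - 1)] <- (arr[, , 3:nz] - arr[, , 1:(nz - 2)]) / (2 * h)
    d
  }
  pr <- Re(p); pi_ <- Im(p)
  grad2 <- dif(pr, 1L)^2 + dif(pi_, 1L)^2 +
    dif(pr, 2L)^2 + dif(pi_, 2L)^2 +
    dif(pr, 3L)^2 + dif(pi_, 3L)^2
  co <- gorkov_coefficients(medium, particle, 2 * pi * array$frequency)
  U <- 2 * co$K1 * (pr^2 + pi_^2) - 2 * co$K2 * grad2
  rm(p, pr, pi_, grad2)
  Fx <- -dif(U, 1L); Fy <- -dif(U, 2L); Fz <- -dif(U, 3L)
  structure(list(x = x, y = y, z = z, Fx = Fx, Fy = Fy, Fz = Fz, U = U,
                 spacing = h, coeffs = co,
                 peak_pressure = array$peak_pressure %||% NA_real_,
                 particle_diameter = particle$diameter),
            class = "acoustonav_force_grid")
}

# rescale a cached grid: force and potential are quadratic in the pressure
# amplitude and linear in the particle volume
.scale_force_grid <- function(grid, factor) {
  grid$Fx <- grid$Fx * factor
  grid$Fy <- grid$Fy * factor
  grid$Fz <- grid$Fz * factor
  grid$U <- grid$U * factor
  grid
}

#' Interpolate the gridded force at arbitrary points
#'
#' Trilinear interpolation of the three force components of a
#' [build_force_grid()] object. Points outside the grid are clamped to the
#' nearest cell (the simulation keeps particles well inside).
#'
#' @param grid An `acoustonav_force_grid`.
#' @param points A 3-vector or n x 3 matrix (m).
#' @return n x 3 matrix of forces (N).
#' @export
interpolate_force <- function(grid, points) {
  P <- .as_points(points)
  .interp_force(grid, P)
}

.interp_force <- function(grid, P) {
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  h <- grid$spacing
  ix <- .clamp(floor((P[, 1] - grid$x[1]) / h) + 1, 1, nx - 1)
  iy <- .clamp(floor((P[, 2] - grid$y[1]) / h) + 1, 1, ny - 1)
  iz <- .clamp(floor((P[, 3] - grid$z[1]) / h) + 1, 1, nz - 1)
  tx <- .clamp((P[, 1] - grid$x[ix]) / h, 0, 1)
  ty <- .clamp((P[, 2] - grid$y[iy]) / h, 0, 1)
  tz <- .clamp((P[, 3] - grid$z[iz]) / h, 0, 1)
  i000 <- ix + nx * (iy - 1 + ny * (iz - 1))
  i100 <- i000 + 1; i010 <- i000 + nx; i110 <- i010 + 1
  i001 <- i000 + nx * ny; i101 <- i001 + 1; i011 <- i001 + nx; i111 <- i011 + 1
  w000 <- (1 - tx) * (1 - ty) * (1 - tz); w100 <- tx * (1 - ty) * (1 - tz)
  w010 <- (1 - tx) * ty * (1 - tz); w110 <- tx * ty * (1 - tz)
  w001 <- (1 - tx) * (1 - ty) * tz; w101 <- tx * (1 - ty) * tz
  w011 <- (1 - tx) * ty * tz; w111 <- tx * ty * tz
  comp <- function(a)
    w000 * a[i000] + w100 * a[i100] + w010 * a[i010] + w110 * a[i110] +
    w001 * a[i001] + w101 * a[i101] + w011 * a[i011] + w111 * a[i111]
  cbind(comp(grid$Fx), comp(grid$Fy), comp(grid$Fz))
}
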