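# Y-bifurcation geometry and the analytic steady laminar velocity field.
#
# The lumen is the union of three finite cylinders (capsules): an inlet along
# +X ending at the apex, and two mirror-image daughter branches in the
# horizontal plane. The signed wall distance is the maximum over the three
# of (radius - distance to axis segment); it is positive inside, zero on the
# wall, continuous everywhere, and its gradient has unit magnitude away from
# the junction seam.
#
# The velocity field is piecewise Poiseuille with a smoothstep blend across
# the junction: upstream of the apex it is the inlet parabola, downstream it
# is the per-branch parabola with the mean speed set by flux conservation,
# and in between the local radius, centreline speed and axial direction are
# blended. The transverse profile is built from the union wall distance, so
# no-slip holds exactly on the whole wall including the junction seam.

#' Y-bifurcation vessel geometry
#'
#' The inlet runs along +X and ends at the apex; the two daughter branches
#' leave the apex symmetrically in the horizontal plane, separated by
#' `branch_angle`. The "left" branch is the one at +Y. The flat end of each
#' branch is its outlet plane; crossing it is the exit event.
#'
#' @param inlet_diameter Inlet diameter (m, default 3.0 mm).
#' @param outlet_diameter Diameter of each daughter branch (m, default
#'   1.5 mm).
#' @param branch_angle Angle between the two daughter branches (rad,
#'   default 60 degrees; a modelling choice).
#' @param inlet_length Length of the inlet segment (m).
#' @param branch_length Length of each daughter branch (m).
#' @param apex Bifurcation point (3-vector, m); default `(0, 0, 31 mm)`,
#'   i.e. the vessel lies in the focal plane of the default array.
#' @return An object of class `acoustonav_vessel`.
#' @seealso [vessel_preset()], [classify_point()], [wall_distance()],
#'   [flow_velocity()].
#' @export
vessel_geometry <- function(inlet_diameter = 3e-3, outlet_diameter = 1.5e-3,
                            branch_angle = pi / 3, inlet_length = 5e-3,
                            branch_length = 4e-3, apex = c(0, 0, 0.031)) {
  stopifnot(inlet_diameter > 0, outlet_diameter > 0,
            branch_angle > 0, branch_angle < pi,
            inlet_length > 0, branch_length > 0, length(apex) == 3L)
  structure(list(inlet_diameter = inlet_diameter,
                 outlet_diameter = outlet_diameter,
                 branch_angle = branch_angle,
                 inlet_length = inlet_length,
                 branch_length = branch_length,
                 apex = as.numeric(apex)),
            class = "acoustonav_vessel")
}

#' Bundled vessel geometries
#'
#' `"bench"`: 3.0 mm inlet tapering to two 1.5 mm outlets — the gelatin
#' bench-phantom geometry, and the package default. `"uniform"`: uniform
#' 2 mm vessel diameter — the geometry of the navigation studies, where
#' the branch flow decelerates instead of accelerating.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [vessel_geometry()].
#' @return An `acoustonav_vessel`.
#' @export
vessel_preset <- function(name = c("bench", "uniform"), ...) {
  name <- match.arg(name)
  switch(name,
         bench = vessel_geometry(...),
         uniform = vessel_geometry(inlet_diameter = 2e-3,
                                  outlet_diameter = 2e-3, ...))
}

#' @export
print.acoustonav_vessel <- function(x, ...) {
  cat(sprintf(paste0("<vessel> inlet %.2f mm -> 2 x %.2f mm, branch angle ",
                     "%.0f deg, apex (%.1f, %.1f, %.1f) mm\n"),
              x$inlet_diameter * 1e3, x$outlet_diameter * 1e3,
              x$branch_angle * 180 / pi, x$apex[1] * 1e3, x$apex[2] * 1e3,
              x$apex[3] * 1e3))
  invisible(x)
}

# precomputed scalars used by the vectorised geometry/flow kernels
.geom_cache <- function(geom) {
  alpha <- geom$branch_angle / 2
  list(apex = geom$apex,
       rin = geom$inlet_diameter / 2,
       rout = geom$outlet_diameter / 2,
       lin = geom$inlet_length,
       lb = geom$branch_length,
       bufin = geom$inlet_diameter,     # capsule extension past release plane
       bufout = geom$outlet_diameter,   # capsule extension past outlet plane
       elx = cos(alpha), ely = sin(alpha))
}

# distances/axial coordinates of points w.r.t. the three lumen capsules,
# plus the union signed wall distance and (optionally) the inward normal
.vessel_frame <- function(gc, P, normals = FALSE) {
  x <- P[, 1] - gc$apex[1]; y <- P[, 2] - gc$apex[2]; z <- P[, 3] - gc$apex[3]
  # inlet capsule: axis from -(lin+bufin) to 0 along +X
  axi <- .clamp(x, -(gc$lin + gc$bufin), 0)
  dxi <- x - axi
  din <- sqrt(dxi * dxi + y * y + z * z)
  # left branch: direction (elx, ely, 0)
  sl <- x * gc$elx + y * gc$ely
  axl <- .clamp(sl, 0, gc$lb + gc$bufout)
  qlx <- x - axl * gc$elx; qly <- y - axl * gc$ely
  dl <- sqrt(qlx * qlx + qly * qly + z * z)
  # right branch: direction (elx, -ely, 0)
  sr <- x * gc$elx - y * gc$ely
  axr <- .clamp(sr, 0, gc$lb + gc$bufout)
  qrx <- x - axr * gc$elx; qry <- y + axr * gc$ely
  dr <- sqrt(qrx * qrx + qry * qry + z * z)

  win <- gc$rin - din; wl <- gc$rout - dl; wr <- gc$rout - dr
  wd <- pmax.int(win, wl, wr)
  out <- list(x = x, y = y, z = z, din = din, dl = dl, dr = dr,
              sl = sl, sr = sr, wd = wd,
              dxi = dxi, qlx = qlx, qly = qly, qrx = qrx, qry = qry,
              win = win, wl = wl, wr = wr)
  if (normals) out <- c(out, .frame_normals(out))
  out
}

# inward wall normals for a (subset of a) frame
.frame_normals <- function(fr, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(fr$x)
  win <- fr$win[idx]; wl <- fr$wl[idx]; wr <- fr$wr[idx]
  n <- length(idx)
  nx <- numeric(n); ny <- numeric(n); nz <- numeric(n)
  i1 <- win >= wl & win >= wr
  i2 <- !i1 & wl >= wr
  i3 <- !(i1 | i2)
  j1 <- idx[i1]; j2 <- idx[i2]; j3 <- idx[i3]
  d1 <- pmax.int(fr$din[j1], 1e-300)
  nx[i1] <- -fr$dxi[j1] / d1; ny[i1] <- -fr$y[j1] / d1; nz[i1] <- -fr$z[j1] / d1
  d2 <- pmax.int(fr$dl[j2], 1e-300)
  nx[i2] <- -fr$qlx[j2] / d2; ny[i2] <- -fr$qly[j2] / d2; nz[i2] <- -fr$z[j2] / d2
  d3 <- pmax.int(fr$dr[j3], 1e-300)
  nx[i3] <- -fr$qrx[j3] / d3; ny[i3] <- -fr$qry[j3] / d3; nz[i3] <- -fr$z[j3] / d3
  list(nx = nx, ny = ny, nz = nz)
}

#' Signed wall distance
#'
#' Distance to the lumen wall, positive inside the lumen, zero on the wall,
#' negative outside. Continuous everywhere; away from the junction seam its
#' gradient has unit magnitude.
#'
#' @param geometry An [vessel_geometry()] object.
#' @param points A 3-vector or n x 3 matrix (m).
#' @return Numeric vector of signed distances (m).
#' @export
wall_distance <- function(geometry, points) {
  P <- .as_points(points)
  .vessel_frame(.geom_cache(geometry), P)$wd
}

#' Classify a point against the vessel
#'
#' @param geometry An [vessel_geometry()] object.
#' @param points A 3-vector or n x 3 matrix (m).
#' @param tol Half-width of the band around zero wall distance that is
#'   reported as `"wall"` (m).
#' @return Character vector with values `"lumen"`, `"wall"`, `"outside"`.
#' @export
classify_point <- function(geometry, points, tol = 1e-9) {
  wd <- wall_distance(geometry, points)
  ifelse(abs(wd) <= tol, "wall", ifelse(wd > 0, "lumen", "outside"))
}

#' Mean-velocity flow specification
#'
#' @param mean_velocity Average (bulk) velocity over the inlet cross-section
#'   (m/s). The volumetric flow is `Q = mean_velocity * A_inlet` and is
#'   conserved across the bifurcation, half through each branch.
#' @return An object of class `acoustonav_flow`.
#' @export
flow_spec <- function(mean_velocity = 1e-3) {
  stopifnot(mean_velocity >= 0)
  structure(list(mean_velocity = mean_velocity), class = "acoustonav_flow")
}

# mean axial speed in one daughter branch from flux conservation
.branch_mean_velocity <- function(gc, v) v * gc$rin^2 / (2 * gc$rout^2)

# vectorised velocity field; returns list(u = n x 3, frame)
.flow_field <- function(gc, v, P, frame = NULL) {
  fr <- frame %||% .vessel_frame(gc, P)
  n <- length(fr$x)
  v2 <- .branch_mean_velocity(gc, v)
  w <- .smoothstep((fr$x + gc$rin) / (2 * gc$rin))
  rloc <- (1 - w) * gc$rin + w * gc$rout
  vax <- 2 * ((1 - w) * v + w * v2)
  q <- pmax.int(0, 1 - ((rloc - pmax.int(fr$wd, 0)) / rloc)^2)
  # branch direction weights from the perpendicular distance to each branch
  # axis, gated on the axial coordinate so the backward extension of one
  # branch axis cannot influence the inlet region
  pl2 <- (fr$x - fr$sl * gc$elx)^2 + (fr$y - fr$sl * gc$ely)^2 + fr$z^2
  pr2 <- (fr$x - fr$sr * gc$elx)^2 + (fr$y + fr$sr * gc$ely)^2 + fr$z^2
  bl <- pmax.int(0, 1 - pl2 / gc$rout^2) *
    .smoothstep((fr$sl + gc$rout) / (2 * gc$rout))
  br <- pmax.int(0, 1 - pr2 / gc$rout^2) *
    .smoothstep((fr$sr + gc$rout) / (2 * gc$rout))
  bs <- bl + br
  none <- bs == 0
  inv <- 1 / (bs + none)
  ebx <- gc$elx + none * (1 - gc$elx)   # unit +X direction where no branch
  eby <- (bl - br) * gc$ely * inv       # weight is active (inlet region)
  dx <- (1 - w) + w * ebx
  dy <- w * eby
  dn <- sqrt(dx * dx + dy * dy)
  speed <- vax * q
  speed[fr$wd <= 0] <- 0
  u <- cbind(dx / dn * speed, dy / dn * speed, 0)
  list(u = u, frame = fr)
}

#' Fluid velocity at points
#'
#' Analytic steady laminar approximation of the bifurcation flow (see the
#' module header / methods vignette): Poiseuille profiles in the straight
#' segments with mean speeds set by flux conservation, a smooth blend within
#' one inlet radius of the apex, exact no-slip on the wall, and zero outside
#' the lumen.
#'
#' @param geometry An [vessel_geometry()] object.
#' @param flow A [flow_spec()].
#' @param points A 3-vector or n x 3 matrix (m).
#' @return n x 3 matrix of velocities (m/s).
#' @export
flow_velocity <- function(geometry, flow, points) {
  P <- .as_points(points)
  .flow_field(.geom_cache(geometry), flow$mean_velocity, P)$u
}

#' Reynolds number
#'
#' `Re = rho0 * velocity * diameter / eta`.
#'
#' @param medium An [medium()] object.
#' @param characteristic_diameter Characteristic length (m).
#' @param velocity Characteristic speed (m/s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(medium, characteristic_diameter, velocity) {
  stopifnot(characteristic_diameter > 0, velocity >= 0)
  medium$density * velocity * characteristic_diameter / medium$viscosity
}
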