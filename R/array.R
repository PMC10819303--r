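# Phased-array construction and far-field piston pressure synthesis.
#
# Each element is a baffled circular piston radiating a spherical wave with
# the far-field directivity 2 J1(a k sin(theta)) / (a k sin(theta)); the array
# field is the coherent sum of the element contributions. Back-lobe
# contributions (theta >= pi/2) are set to zero: the far-field piston
# derivation is forward-only.

#' Single transducer element
#'
#' @param position Element centre (3-vector, m).
#' @param normal Emission axis (3-vector; must be unit length to 1e-12,
#'   it is re-normalised internally after that check).
#' @param radius_a Radius of the emitting aperture (m).
#' @param amplitude Equivalent source strength (Pa m): the product of the
#'   element drive amplitude constants, so that the on-axis far-field
#'   magnitude at distance d is `amplitude / d`.
#' @param phase Phase delay (rad); wrapped into `[0, 2 pi)`.
#' @return A one-row data frame with columns
#'   `x, y, z, nx, ny, nz, radius_a, amplitude, phase`.
#' @export
transducer <- function(position, normal, radius_a, amplitude = 1, phase = 0) {
  stopifnot(length(position) == 3L, length(normal) == 3L, radius_a > 0)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-12)
    stop("transducer normal must be a unit vector (|n| = 1 within 1e-12)")
  normal <- normal / nn
  phase <- phase %% (2 * pi)
  data.frame(x = position[1], y = position[2], z = position[3],
             nx = normal[1], ny = normal[2], nz = normal[3],
             radius_a = radius_a, amplitude = amplitude, phase = phase)
}

.array_layout <- function(elements, frequency, focal_point, aperture_diameter,
                          focal_height, layout_mode, phasing = "none") {
  structure(list(elements = elements, frequency = frequency,
                 focal_point = focal_point,
                 aperture_diameter = aperture_diameter,
                 focal_height = focal_height,
                 layout_mode = layout_mode, phasing = phasing),
            class = "acoustonav_array")
}

#' Build the spherical-cap transducer array
#'
#' Places `n_elements` piston elements on a spherical cap whose centre of
#' curvature is the nominal focus, so that every element sits exactly
#' `focal_height` from the focus and its normal points at it. The cap pole is
#' at the origin and the array axis is +Z, so the nominal focus is at
#' `(0, 0, focal_height)`. The aperture diameter is interpreted as the bowl
#' diameter measured along the curved surface, giving a cap half-angle of
#' `(aperture_diameter / 2) / focal_height` radians.
#'
#' Layout modes: `"rings"` (concentric rings with per-ring counts
#' proportional to circumference, the default), `"spiral"` (golden-angle
#' Fibonacci spiral over the cap), `"from_file"` (read an element table
#' written by [write_array_csv()]).
#'
#' @param layout_mode Element placement scheme.
#' @param n_elements Number of elements (default 30).
#' @param aperture_diameter Bowl surface diameter (m, default 75 mm).
#' @param focal_height Distance from every element to the nominal focus
#'   (m, default 31 mm).
#' @param frequency Drive frequency (Hz, default 1 MHz).
#' @param element_radius Radius of each emitting aperture (m). Not implied
#'   by the bowl geometry; the default 4.5 mm lets 30 elements tile the
#'   default cap without overlap. A warning is issued if elements overlap.
#' @param amplitude Initial per-element source strength (Pa m); usually
#'   rescaled later by [normalize_to_peak()].
#' @param file Element table path for `layout_mode = "from_file"`.
#' @return An `acoustonav_array` object; `$elements` is the element table.
#' @examples
#' arr <- build_array()
#' nrow(arr$elements)  # 30
#' @export
build_array <- function(layout_mode = c("rings", "spiral", "from_file"),
                        n_elements = 30L, aperture_diameter = 0.075,
                        focal_height = 0.031, frequency = 1e6,
                        element_radius = 4.5e-3, amplitude = 1,
                        file = NULL) {
  layout_mode <- match.arg(layout_mode)
  stopifnot(n_elements >= 1L, aperture_diameter > 0, focal_height > 0,
            frequency > 0, element_radius > 0)
  focus <- c(0, 0, focal_height)

  if (layout_mode == "from_file") {
    if (is.null(file)) stop("layout_mode = 'from_file' needs a file")
    elements <- read_array_csv(file)
    return(.array_layout(elements, frequency, focus, aperture_diameter,
                         focal_height, layout_mode))
  }

  r_c <- focal_height
  theta_max <- (aperture_diameter / 2) / r_c
  if (theta_max >= pi / 2 * 0.999)
    stop("aperture too wide for the cap: (D/2)/h must be < pi/2")

  if (n_elements == 1L) {
    ang <- cbind(theta = 0, phi = 0)
  } else if (layout_mode == "rings") {
    n_rings <- min(n_elements, max(1L, ceiling(sqrt(n_elements / 3))))
    thetas <- theta_max * (seq_len(n_rings) - 0.5) / n_rings
    w <- sin(thetas)
    raw <- n_elements * w / sum(w)
    counts <- floor(raw)
    rem <- n_elements - sum(counts)
    if (rem > 0) {
      ord <- order(raw - counts, decreasing = TRUE)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
    }
    while (any(counts == 0L)) {  # keep every ring populated
      i <- which.max(counts); j <- which(counts == 0L)[1L]
      counts[i] <- counts[i] - 1L; counts[j] <- 1L
    }
    ang <- do.call(rbind, lapply(seq_len(n_rings), function(r) {
      m <- counts[r]
      phi <- 2 * pi * (seq_len(m) - 1) / m + (r - 1) * pi / max(1L, m)
      cbind(theta = rep(thetas[r], m), phi = phi)
    }))
  } else {  # spiral
    golden <- pi * (3 - sqrt(5))
    i <- seq_len(n_elements)
    ct <- 1 - (1 - cos(theta_max)) * (i - 0.5) / n_elements
    ang <- cbind(theta = acos(ct), phi = i * golden)
  }

  st <- sin(ang[, "theta"]); ct <- cos(ang[, "theta"])
  pos <- cbind(focus[1] + r_c * st * cos(ang[, "phi"]),
               focus[2] + r_c * st * sin(ang[, "phi"]),
               focus[3] - r_c * ct)
  nrm <- cbind(focus[1] - pos[, 1], focus[2] - pos[, 2],
               focus[3] - pos[, 3]) / r_c

  elements <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                         radius_a = element_radius, amplitude = amplitude,
                         phase = 0)
  if (n_elements >= 2L) {
    dmin <- min(stats::dist(pos))
    if (dmin < 2 * element_radius)
      warning(sprintf(paste0("element radius (%.1f mm) exceeds half the ",
                             "minimum inter-element spacing (%.1f mm): ",
                             "apertures overlap"),
                      element_radius * 1e3, dmin * 1e3))
  }
  .array_layout(elements, frequency, focus, aperture_diameter, focal_height,
                layout_mode)
}

#' @export
print.acoustonav_array <- function(x, ...) {
  cat(sprintf(paste0("<array> %d elements, f = %g MHz, phasing = %s, ",
                     "focal point = (%.1f, %.1f, %.1f) mm\n"),
              nrow(x$elements), x$frequency / 1e6, x$phasing,
              x$focal_point[1] * 1e3, x$focal_point[2] * 1e3,
              x$focal_point[3] * 1e3))
  invisible(x)
}

# directivity as a function of x = a k sin(theta), with the series limit at 0
.directivity_x <- function(x) {
  x <- abs(x)  # even function; besselJ needs a non-negative argument
  out <- rep(1, length(x))
  big <- x >= 1e-5
  out[big] <- 2 * besselJ(x[big], 1) / x[big]
  small <- !big & x > 0
  out[small] <- 1 - x[small]^2 / 8
  out
}

#' Far-field piston directivity
#'
#' `Df(theta) = 2 J1(a k sin theta) / (a k sin theta)`, continuous at
#' `theta = 0` through its series limit (value 1). An even function of
#' `theta` that first vanishes where `a k sin theta` hits the first positive
#' root of J1 (about 3.8317).
#'
#' @param theta Angle from the element normal (rad); vectorised.
#' @param radius_a Piston radius (m).
#' @param k Wavenumber (1/m).
#' @return Dimensionless directivity values.
#' @export
directivity <- function(theta, radius_a, k) {
  stopifnot(radius_a > 0, k > 0)
  .directivity_x(radius_a * k * sin(theta))
}

# Coherent pressure sum over elements at coordinate vectors X, Y, Z.
# elements: data frame with x,y,z,nx,ny,nz,radius_a,amplitude,phase.
.pressure_sum <- function(elements, X, Y, Z, k, min_distance) {
  p <- complex(length(X))
  ex <- elements$x; ey <- elements$y; ez <- elements$z
  nx <- elements$nx; ny <- elements$ny; nz <- elements$nz
  aa <- elements$radius_a; amp <- elements$amplitude; ph <- elements$phase
  for (j in seq_along(ex)) {
    dx <- X - ex[j]; dy <- Y - ey[j]; dz <- Z - ez[j]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    if (any(d < min_distance))
      stop(sprintf(paste0("field point within %.3g m of an element: ",
                          "far-field piston model invalid"), min_distance))
    ct <- (dx * nx[j] + dy * ny[j] + dz * nz[j]) / d
    st <- sqrt(pmax(0, 1 - ct * ct))
    val <- (amp[j] / d) * .directivity_x(aa[j] * k * st) *
      exp(1i * (ph[j] + k * d))
    val[ct <= 0] <- 0i  # forward half-space only
    p <- p + val
  }
  p
}

#' Complex pressure of a single element
#'
#' Far-field piston contribution
#' `p = amplitude * Df(theta) / d * exp(i (phase + k d))`, zero in the
#' element's back half-space. Errors if a query point is closer than
#' `min_distance` (default a quarter wavelength), where the far-field model
#' is invalid.
#'
#' @param element A [transducer()] row (or one row of an array's element
#'   table).
#' @param points A 3-vector or n x 3 matrix of field points (m).
#' @param medium An [medium()] object.
#' @param frequency Drive frequency (Hz).
#' @param min_distance Minimum allowed source-point distance (m).
#' @return Complex pressure (Pa), one value per point.
#' @export
element_pressure <- function(element, points, medium, frequency,
                             min_distance = NULL) {
  P <- .as_points(points)
  k <- wavenumber(medium, frequency)
  lambda <- 2 * pi / k
  min_distance <- min_distance %||% (lambda / 4)
  .pressure_sum(as.data.frame(element), P[, 1], P[, 2], P[, 3], k,
                min_distance)
}

#' Total complex pressure of the array
#'
#' Coherent (complex) sum of all element contributions; superposition is
#' exact, so scaling all amplitudes scales the field linearly.
#'
#' @param array An `acoustonav_array`.
#' @param points A 3-vector or n x 3 matrix of field points (m).
#' @param medium An [medium()] object.
#' @param min_distance Minimum allowed source-point distance (m; default a
#'   quarter wavelength).
#' @return Complex pressure (Pa), one value per point.
#' @export
total_pressure <- function(array, points, medium, min_distance = NULL) {
  P <- .as_points(points)
  k <- wavenumber(medium, array$frequency)
  min_distance <- min_distance %||% (pi / (2 * k))
  .pressure_sum(array$elements, P[, 1], P[, 2], P[, 3], k, min_distance)
}

#' Assign focusing phases
#'
#' Time-reversal focusing: element j gets `phi_j = (-k d_j) mod 2 pi` with
#' `d_j` its distance to the focal point, so all contributions arrive in
#' phase there and the focal pressure magnitude is the sum of the element
#' magnitudes.
#'
#' @param array An `acoustonav_array`.
#' @param focal_point Target focus (3-vector, m); defaults to the array's
#'   nominal focus.
#' @param medium An [medium()] object.
#' @return The array with updated phases and `focal_point`.
#' @export
focus_phases <- function(array, focal_point = NULL, medium) {
  focal_point <- focal_point %||% array$focal_point
  k <- wavenumber(medium, array$frequency)
  el <- array$elements
  d <- sqrt((focal_point[1] - el$x)^2 + (focal_point[2] - el$y)^2 +
              (focal_point[3] - el$z)^2)
  if (any(d == 0)) stop("focal point coincides with an element")
  array$elements$phase <- (-k * d) %% (2 * pi)
  array$focal_point <- focal_point
  array$phasing <- "focus"
  array
}

#' Assign twin-trap phases
#'
#' Focusing phases plus a pi offset for all elements on one side of the
#' plane through `focal_point` with normal `split_axis`. Contributions then
#' cancel at the focal point (a pressure null) and two pressure lobes
#' straddle it along `split_axis`.
#'
#' @param array An `acoustonav_array`.
#' @param focal_point Trap centre (3-vector, m).
#' @param split_axis Unit vector orthogonal to the array axis (+Z) defining
#'   the splitting plane.
#' @param medium An [medium()] object.
#' @return The array with twin-trap phases.
#' @export
twin_trap_phases <- function(array, focal_point = NULL,
                             split_axis = c(0, 1, 0), medium) {
  focal_point <- focal_point %||% array$focal_point
  stopifnot(length(split_axis) == 3L)
  split_axis <- split_axis / sqrt(sum(split_axis^2))
  if (abs(split_axis[3]) > 1e-9)
    stop("split_axis must be orthogonal to the array axis (+Z)")
  array <- focus_phases(array, focal_point, medium)
  el <- array$elements
  s <- (el$x - focal_point[1]) * split_axis[1] +
    (el$y - focal_point[2]) * split_axis[2] +
    (el$z - focal_point[3]) * split_axis[3]
  array$elements$phase <- (el$phase + ifelse(s > 0, pi, 0)) %% (2 * pi)
  array$phasing <- "twin_trap"
  array$split_axis <- split_axis
  array
}

#' Pressure and its spatial derivatives
#'
#' Evaluates the complex pressure and its three spatial derivatives at each
#' point. Derivatives use second-order central differences with step
#' `step_h` (default one two-hundredth of a wavelength); the field varies on
#' the wavelength scale, so halving the step changes the result well below
#' one percent.
#'
#' @param array An `acoustonav_array`.
#' @param points A 3-vector or n x 3 matrix (m).
#' @param medium An [medium()] object.
#' @param step_h Finite-difference step (m).
#' @return A data frame of class `acoustonav_field` with complex columns
#'   `p, px, py, pz`.
#' @export
field_with_derivatives <- function(array, points, medium, step_h = NULL) {
  P <- .as_points(points)
  k <- wavenumber(medium, array$frequency)
  lambda <- 2 * pi / k
  h <- step_h %||% (lambda / 200)
  stopifnot(h > 0)
  n <- nrow(P)
  off <- rbind(c(0, 0, 0),
               c(h, 0, 0), c(-h, 0, 0),
               c(0, h, 0), c(0, -h, 0),
               c(0, 0, h), c(0, 0, -h))
  big <- P[rep(seq_len(n), times = 7L), , drop = FALSE] +
    off[rep(seq_len(7L), each = n), ]
  p_all <- .pressure_sum(array$elements, big[, 1], big[, 2], big[, 3], k,
                         pi / (2 * k))
  blk <- function(i) p_all[((i - 1L) * n + 1L):(i * n)]
  out <- data.frame(p = blk(1L),
                    px = (blk(2L) - blk(3L)) / (2 * h),
                    py = (blk(4L) - blk(5L)) / (2 * h),
                    pz = (blk(6L) - blk(7L)) / (2 * h))
  class(out) <- c("acoustonav_field", "data.frame")
  out
}

#' Scale the array to a target peak pressure
#'
#' Evaluates `|P|` on a regular grid over a search box around the focus and
#' rescales every element amplitude by one common factor so that the grid
#' maximum equals `target_peak`. Because the field is linear in the
#' amplitudes this is exact for the grid maximum and idempotent.
#'
#' @param array An `acoustonav_array` (normally after [focus_phases()]).
#' @param target_peak Desired peak pressure magnitude (Pa).
#' @param medium An [medium()] object.
#' @param search_region 2 x 3 matrix `rbind(lower, upper)` of box corners
#'   (m); default is a box of one wavelength half-width around the focal
#'   point.
#' @param spacing Search grid spacing (m; default one thirtieth of a
#'   wavelength).
#' @return The rescaled array, with the achieved peak stored in
#'   `$peak_pressure`.
#' @export
normalize_to_peak <- function(array, target_peak, medium,
                              search_region = NULL, spacing = NULL) {
  stopifnot(target_peak > 0)
  k <- wavenumber(medium, array$frequency)
  lambda <- 2 * pi / k
  spacing <- spacing %||% (lambda / 30)
  if (is.null(search_region)) {
    f <- array$focal_point
    search_region <- rbind(f - lambda, f + lambda)
  }
  gx <- seq(search_region[1, 1], search_region[2, 1], by = spacing)
  gy <- seq(search_region[1, 2], search_region[2, 2], by = spacing)
  gz <- seq(search_region[1, 3], search_region[2, 3], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  X <- rep(gx, times = ny * nz)
  Y <- rep(rep(gy, each = nx), times = nz)
  Z <- rep(gz, each = nx * ny)
  p <- .pressure_sum(array$elements, X, Y, Z, k, pi / (2 * k))
  peak <- max(Mod(p))
  if (!is.finite(peak) || peak <= 0)
    stop("zero field in the search region; cannot normalise")
  array$elements$amplitude <- array$elements$amplitude * (target_peak / peak)
  array$peak_pressure <- target_peak
  array
}
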