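# Shared fixtures, built once per test run and memoised. All in SI units.

.fix <- new.env(parent = emptyenv())

fix_medium <- function() medium_preset("water")

# default 30-element bowl, unphased
fix_array <- function() {
  if (is.null(.fix$array)) .fix$array <- build_array()
  .fix$array
}

# focused at the nominal focus and normalised to 1 MPa
fix_focused_array <- function() {
  if (is.null(.fix$focused)) {
    arr <- focus_phases(fix_array(), c(0, 0, 0.031), fix_medium())
    .fix$focused <- normalize_to_peak(arr, 1e6, fix_medium())
  }
  .fix$focused
}

fix_geometry <- function() vessel_geometry()

# random points inside a box around the focus, away from the null planes
fix_focal_points <- function(n, half_width = 1.5e-3, seed = 101) {
  set.seed(seed)
  cbind(stats::runif(n, -half_width, half_width),
        stats::runif(n, -half_width, half_width),
        0.031 + stats::runif(n, -half_width, half_width))
}

# random points strictly inside the vessel lumen
fix_lumen_points <- function(n, geometry = fix_geometry(), seed = 202,
                             margin = 0.1) {
  set.seed(seed)
  gc_apex <- geometry$apex
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- cbind(gc_apex[1] + stats::runif(4 * n, -geometry$inlet_length,
                                            geometry$branch_length),
                  gc_apex[2] + stats::runif(4 * n, -2e-3, 2e-3),
                  gc_apex[3] + stats::runif(4 * n, -1.5e-3, 1.5e-3))
    wd <- wall_distance(geometry, cand)
    keep <- wd > margin * geometry$outlet_diameter / 2
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

# numerical flux of the analytic flow through a disk cross-section
flux_through_disk <- function(geometry, flow, centre, axis, radius,
                              nr = 48, na = 64) {
  axis <- axis / sqrt(sum(axis^2))
  a1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a1 - sum(a1 * axis) * axis; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(axis[2] * t1[3] - axis[3] * t1[2],
          axis[3] * t1[1] - axis[1] * t1[3],
          axis[1] * t1[2] - axis[2] * t1[1])
  # midpoint rule in r^2 (uniform in area) and angle
  r <- radius * sqrt((seq_len(nr) - 0.5) / nr)
  th <- 2 * pi * (seq_len(na) - 0.5) / na
  g <- expand.grid(r = r, th = th)
  pts <- matrix(centre, nrow(g), 3, byrow = TRUE) +
    outer(g$r * cos(g$th), t1) + outer(g$r * sin(g$th), t2)
  u <- flow_velocity(geometry, flow, pts)
  un <- u %*% axis
  sum(un) * (pi * radius^2 / nrow(g))
}
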