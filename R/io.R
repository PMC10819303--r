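# File interfaces: element tables, field/force exports (CSV and legacy
# ASCII VTK structured points), trajectories, and YAML scenario configs.

.array_cols <- c("x", "y", "z", "nx", "ny", "nz", "radius_a", "amplitude",
                 "phase")

#' Write / read an array element table
#'
#' One row per element, columns
#' `x, y, z, nx, ny, nz, radius_a, amplitude, phase` (SI units, phase in
#' rad). The reader validates unit normals and positive apertures.
#'
#' @param array An `acoustonav_array`.
#' @param file Path.
#' @return `write_array_csv`: the path, invisibly. `read_array_csv`: the
#'   element data frame.
#' @export
write_array_csv <- function(array, file) {
  utils::write.csv(array$elements[, .array_cols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_array_csv
#' @export
read_array_csv <- function(file) {
  el <- utils::read.csv(file)
  if (!all(.array_cols %in% names(el)))
    stop("element table needs columns: ", paste(.array_cols, collapse = ", "))
  nn <- sqrt(el$nx^2 + el$ny^2 + el$nz^2)
  if (any(abs(nn - 1) > 1e-6)) stop("element normals must be unit vectors")
  if (any(el$radius_a <= 0)) stop("element radius_a must be positive")
  el$phase <- el$phase %% (2 * pi)
  el[, .array_cols]
}

#' Export a sampled pressure field as CSV
#'
#' @param points n x 3 matrix of sample locations (m).
#' @param p Complex pressures at the points (Pa).
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(points, p, file) {
  P <- .as_points(points)
  utils::write.csv(data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                              re_p = Re(p), im_p = Im(p), abs_p = Mod(p)),
                   file, row.names = FALSE)
  invisible(file)
}

#' Export scalar/vector fields on a regular grid as legacy ASCII VTK
#'
#' Writes a STRUCTURED_POINTS dataset readable by ParaView/VisIt. Arrays
#' must have dim `c(length(x), length(y), length(z))`; vectors are given as
#' a list of three such arrays.
#'
#' @param file Path (conventionally `.vtk`).
#' @param x,y,z Node coordinate vectors of a regular grid (m).
#' @param scalars Named list of scalar arrays.
#' @param vectors Named list of 3-component array lists.
#' @return The path, invisibly.
#' @export
write_vtk_grid <- function(file, x, y, z, scalars = list(),
                           vectors = list()) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "acoustonav field export",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("ORIGIN %g %g %g", x[1], y[1], z[1]),
               sprintf("SPACING %g %g %g", x[2] - x[1], y[2] - y[1],
                       z[2] - z[1]),
               sprintf("POINT_DATA %d", nx * ny * nz)), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(scalars[[nm]]), digits = 9), con)
  }
  for (nm in names(vectors)) {
    writeLines(sprintf("VECTORS %s double", nm), con)
    v <- vectors[[nm]]
    writeLines(paste(format(as.vector(v[[1]]), digits = 9),
                     format(as.vector(v[[2]]), digits = 9),
                     format(as.vector(v[[3]]), digits = 9)), con)
  }
  invisible(file)
}

#' Export recorded trajectories as CSV
#'
#' @param outcome An `acoustonav_outcome` simulated with a positive
#'   `trajectory_stride`.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(outcome, file) {
  if (is.null(outcome$trajectories))
    stop("no trajectories recorded; set trajectory_stride > 0")
  utils::write.csv(outcome$trajectories[, c("id", "t", "x", "y", "z")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Read / write a scenario configuration (YAML)
#'
#' A scenario config has optional sections `array`, `medium`, `particle`,
#' `geometry`, `flow`, `release`, `sim`, each holding the arguments of the
#' corresponding constructor ([build_array()], [medium()],
#' [particle_spec()], [vessel_geometry()], [flow_spec()],
#' [release_schedule()], [sim_config()]). `scenario_from_config` builds the
#' objects, filling unspecified sections with package defaults.
#'
#' @param path YAML file.
#' @param cfg A named list of sections (for writing).
#' @return `read_scenario_config`: the raw named list.
#'   `scenario_from_config`: list of constructed objects
#'   (`array` may be `NULL` if the section is absent).
#' @export
read_scenario_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname read_scenario_config
#' @export
scenario_from_config <- function(cfg) {
  build <- function(fun, section) do.call(fun, cfg[[section]] %||% list())
  list(medium = build(medium, "medium"),
       particle = build(particle_spec, "particle"),
       geometry = build(vessel_geometry, "geometry"),
       flow = build(flow_spec, "flow"),
       schedule = build(release_schedule, "release"),
       config = build(sim_config, "sim"),
       array = if (!is.null(cfg$array)) do.call(build_array, cfg$array))
}
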