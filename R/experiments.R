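# In-silico studies: focus-position optimisation, velocity / pressure
# sweeps, and particle-size dependence. A scenario is: build the focused
# array, normalise it to a peak pressure acprmax, precompute the force
# grid, trace the ensemble, and report the navigation efficiency towards
# the open (target) branch while the other branch is blocked by the focus.
#
# The force is exactly quadratic in the peak pressure and exactly cubic in
# the particle diameter, so sweeps over acprmax or diameter at a fixed
# focus reuse one cached force grid with scalar rescaling.

#' Default focus candidates across the blocked branch mouth
#'
#' A transverse line of points spanning the mouth of the branch to be
#' blocked, in the vessel midplane: the mouth centre sits one inlet radius
#' past the apex along the branch axis, and the candidates are offset
#' perpendicular to that axis by up to `span` times the branch radius.
#'
#' @param geometry An [vessel_geometry()].
#' @param blocked Which branch the focus should block (`"left"` = +Y).
#' @param n Number of candidates.
#' @param span Half-extent of the line in units of the branch radius.
#' @return n x 3 matrix of candidate focal points (m).
#' @export
default_focus_candidates <- function(geometry, blocked = c("left", "right"),
                                     n = 5L, span = 0.8) {
  blocked <- match.arg(blocked)
  gc <- .geom_cache(geometry)
  sgn <- if (blocked == "left") 1 else -1
  eb <- c(gc$elx, sgn * gc$ely, 0)
  tv <- c(-eb[2], eb[1], 0)
  centre <- gc$apex + gc$rin * eb
  s <- seq(-span, span, length.out = n) * gc$rout
  t(vapply(s, function(si) centre + si * tv, numeric(3)))
}

#' Run one navigation scenario
#'
#' Builds the array, phases it at `focus`, normalises the field to the peak
#' pressure `acprmax`, precomputes the force grid, traces the ensemble and
#' records the navigation efficiency towards the target (open) branch.
#' With `acprmax = 0` the acoustic field is disabled entirely and the run
#' is the pure-drag baseline.
#'
#' @param acprmax Peak acoustic pressure (Pa).
#' @param velocity Mean inlet velocity (m/s).
#' @param diameter Particle diameter (m).
#' @param focus Focal point (3-vector, m); default the blocked-branch mouth
#'   centre.
#' @param blocked Branch to block (`"left"` or `"right"`); the target is
#'   the other one.
#' @param geometry,medium,frequency,n_elements Scenario building blocks.
#' @param particle Optional [particle_spec()] overriding `diameter`.
#' @param schedule Optional [release_schedule()]; default 100 particles in
#'   4 steps of 25, seeded with `seed`.
#' @param config Optional [sim_config()].
#' @param seed Seed for the default schedule.
#' @param array Optional prebuilt array (it is re-phased and re-normalised).
#' @param force_grid Optional prebuilt force grid (skips field synthesis).
#' @return An `acoustonav_scenario`: list with `record` (one-row data frame
#'   of parameters and outcomes) and `summary` (the full
#'   `acoustonav_outcome`).
#' @export
run_scenario <- function(acprmax, velocity, diameter = 10e-6, focus = NULL,
                         blocked = c("left", "right"),
                         geometry = vessel_geometry(),
                         medium = medium_preset("water"),
                         frequency = 1e6, n_elements = 30L,
                         particle = NULL, schedule = NULL, config = NULL,
                         seed = 1L, array = NULL, force_grid = NULL) {
  blocked <- match.arg(blocked)
  target <- if (blocked == "left") "right" else "left"
  stopifnot(acprmax >= 0, velocity > 0)
  particle <- particle %||% particle_spec(diameter = diameter)
  flow <- flow_spec(velocity)
  schedule <- schedule %||% release_schedule(seed = seed)
  config <- config %||% sim_config()
  if (is.null(focus))
    focus <- default_focus_candidates(geometry, blocked, n = 1L, span = 0)[1, ]

  if (acprmax > 0 && is.null(force_grid)) {
    array <- array %||% build_array(frequency = frequency,
                                    n_elements = n_elements)
    array <- focus_phases(array, focus, medium)
    array <- normalize_to_peak(array, acprmax, medium)
    force_grid <- build_force_grid(array, medium, particle, geometry,
                                   spacing = config$grid_spacing)
  }
  out <- simulate_particles(geometry, flow, particle, schedule, config,
                            medium,
                            force_grid = if (acprmax > 0) force_grid)
  eff <- navigation_efficiency(out, target)
  rec <- data.frame(focus_x = focus[1], focus_y = focus[2],
                    focus_z = focus[3], acprmax = acprmax,
                    velocity = velocity, diameter = particle$diameter,
                    seed = schedule$seed,
                    efficiency = eff,
                    exited_left = out$counts[["exited_left"]],
                    exited_right = out$counts[["exited_right"]],
                    adhered = out$counts[["adhered"]],
                    timed_out = out$counts[["timed_out"]])
  structure(list(record = rec, summary = out, target = target,
                 blocked = blocked, focus = focus),
            class = "acoustonav_scenario")
}

#' @export
print.acoustonav_scenario <- function(x, ...) {
  r <- x$record
  cat(sprintf(paste0("<scenario> acprmax = %.2g MPa, v = %.2g mm/s, d = ",
                     "%.0f um -> efficiency %.1f%% (L %d / R %d, adhered ",
                     "%d, timed out %d)\n"),
              r$acprmax / 1e6, r$velocity * 1e3, r$diameter * 1e6,
              r$efficiency, r$exited_left, r$exited_right, r$adhered,
              r$timed_out))
  invisible(x)
}

#' Scenario grid constructor
#'
#' Enumerates the full factorial of focus positions, peak pressures, inlet
#' velocities, diameters and seeds, in a deterministic order.
#'
#' @param focus_positions n x 3 matrix (or single 3-vector) of focal points.
#' @param acprmax_values Peak pressures (Pa).
#' @param velocities Mean inlet velocities (m/s).
#' @param diameters Particle diameters (m).
#' @param seeds Schedule seeds (replicates).
#' @return Data frame with one row per scenario.
#' @export
scenario_grid <- function(focus_positions, acprmax_values, velocities,
                          diameters = 10e-6, seeds = 1L) {
  fp <- .as_points(focus_positions)
  stopifnot(length(acprmax_values) >= 1L, length(velocities) >= 1L,
            length(diameters) >= 1L)
  g <- expand.grid(focus_id = seq_len(nrow(fp)), acprmax = acprmax_values,
                   velocity = velocities, diameter = diameters,
                   seed = seeds, KEEP.OUT.ATTRS = FALSE)
  g$focus_x <- fp[g$focus_id, 1]
  g$focus_y <- fp[g$focus_id, 2]
  g$focus_z <- fp[g$focus_id, 3]
  g
}

#' Run a scenario sweep
#'
#' Runs [run_scenario()] for every row of a [scenario_grid()], reusing one
#' force grid per focus position (the force rescales exactly with
#' `acprmax^2` and `diameter^3`). Failed rows are recorded with `NA`
#' efficiency and a warning rather than aborting the sweep; pass the
#' returned records as `resume` to skip already-completed rows.
#'
#' @param grid A [scenario_grid()] data frame.
#' @param ... Common arguments passed to [run_scenario()] (geometry,
#'   medium, config, ...).
#' @param resume Optional records from a previous partial run.
#' @return Data frame of scenario records, one per grid row.
#' @export
run_sweep <- function(grid, ..., resume = NULL) {
  stopifnot(nrow(grid) >= 1L)
  common <- list(...)
  cache <- new.env(parent = emptyenv())
  recs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(resume)) {
      hit <- which(resume$focus_x == g$focus_x & resume$focus_y == g$focus_y &
                     resume$acprmax == g$acprmax &
                     resume$velocity == g$velocity &
                     resume$diameter == g$diameter & resume$seed == g$seed)
      if (length(hit)) { recs[[i]] <- resume[hit[1L], ]; next }
    }
    recs[[i]] <- tryCatch({
      sc <- do.call(.cached_scenario,
                    c(list(cache = cache, acprmax = g$acprmax,
                           velocity = g$velocity, diameter = g$diameter,
                           focus = c(g$focus_x, g$focus_y, g$focus_z),
                           seed = g$seed), common))
      sc$record
    }, error = function(e) {
      warning(sprintf("scenario row %d failed: %s", i, conditionMessage(e)))
      cbind(g[, c("focus_x", "focus_y", "focus_z", "acprmax", "velocity",
                  "diameter", "seed")],
            efficiency = NA_real_, exited_left = NA_integer_,
            exited_right = NA_integer_, adhered = NA_integer_,
            timed_out = NA_integer_)
    })
  }
  do.call(rbind, recs)
}

# run_scenario with a per-focus cache of unit-pressure, reference-diameter
# force grids, rescaled per scenario
.cached_scenario <- function(cache, acprmax, velocity, diameter, focus,
                             seed, geometry = vessel_geometry(),
                             medium = medium_preset("water"),
                             frequency = 1e6, n_elements = 30L,
                             blocked = "left", schedule = NULL,
                             config = NULL, ...) {
  config <- config %||% sim_config()
  if (acprmax <= 0)
    return(run_scenario(0, velocity, diameter, focus, blocked = blocked,
                        geometry = geometry, medium = medium,
                        schedule = schedule, config = config, seed = seed,
                        ...))
  key <- paste(signif(focus, 10), collapse = "_")
  ref_d <- 10e-6
  if (is.null(cache[[key]])) {
    arr <- build_array(frequency = frequency, n_elements = n_elements)
    arr <- focus_phases(arr, focus, medium)
    arr <- normalize_to_peak(arr, 1, medium)   # unit peak pressure
    cache[[key]] <- build_force_grid(arr, medium,
                                     particle_spec(diameter = ref_d),
                                     geometry, spacing = config$grid_spacing)
  }
  fg <- .scale_force_grid(cache[[key]], acprmax^2 * (diameter / ref_d)^3)
  run_scenario(acprmax, velocity, diameter, focus, blocked = blocked,
               geometry = geometry, medium = medium, schedule = schedule,
               config = config, seed = seed, force_grid = fg, ...)
}

#' Grid-search the focus position
#'
#' Evaluates every candidate focal point under otherwise fixed conditions
#' and returns the winner of a lexicographic objective: maximum navigation
#' efficiency first, fewest adhered particles as the tie-break.
#'
#' @param candidates n x 3 matrix of focal points; default
#'   [default_focus_candidates()].
#' @param acprmax Peak pressure (Pa).
#' @param velocity Mean inlet velocity (m/s).
#' @param diameter Particle diameter (m).
#' @param geometry An [vessel_geometry()].
#' @param blocked Branch to block.
#' @param ... Passed to [run_scenario()].
#' @return List with `best_focus`, `best_record`, `best_summary`, and the
#'   full candidate `table`.
#' @export
optimize_focus <- function(candidates = NULL, acprmax, velocity,
                           diameter = 10e-6, geometry = vessel_geometry(),
                           blocked = c("left", "right"), ...) {
  blocked <- match.arg(blocked)
  candidates <- candidates %||%
    default_focus_candidates(geometry, blocked)
  candidates <- .as_points(candidates)
  stopifnot(nrow(candidates) >= 1L)
  runs <- lapply(seq_len(nrow(candidates)), function(i)
    run_scenario(acprmax, velocity, diameter, candidates[i, ],
                 blocked = blocked, geometry = geometry, ...))
  tab <- do.call(rbind, lapply(runs, function(r) r$record))
  best <- order(-tab$efficiency, tab$adhered)[1L]
  list(best_focus = candidates[best, ], best_record = tab[best, ],
       best_summary = runs[[best]]$summary, table = tab)
}

#' Particle-size dependence study
#'
#' Runs the navigation scenario for each diameter at fixed field and flow,
#' and measures the peak lateral deflection of a single probe particle
#' released on the inlet centreline for each diameter. Because the
#' radiation force scales with the cube of the diameter and Stokes drag
#' linearly, the quasi-static deflection scales close to the square of the
#' diameter; the fitted log-log slope of deflection against diameter is
#' returned as `exponent`.
#'
#' @param diameters Particle diameters (m); at least one. The scaling
#'   exponent needs at least two.
#' @param acprmax Peak pressure for the efficiency records (Pa).
#' @param velocity Mean inlet velocity (m/s).
#' @param focus Focal point; default the blocked-branch mouth centre.
#' @param geometry An [vessel_geometry()].
#' @param probe_pressure Peak pressure for the deflection probe (Pa);
#'   default `acprmax`. Use a low value to stay in the small-deflection
#'   regime.
#' @param ... Passed to [run_scenario()].
#' @return List with `records` (efficiency per diameter), `deflections`
#'   (probe peak deflection per diameter, m), and `exponent` (log-log
#'   slope, `NA` with fewer than two diameters).
#' @export
size_dependence_study <- function(diameters, acprmax, velocity,
                                  focus = NULL,
                                  geometry = vessel_geometry(),
                                  probe_pressure = NULL, schedule = NULL,
                                  config = NULL, ...) {
  stopifnot(length(diameters) >= 1L)
  if (is.null(focus))
    focus <- default_focus_candidates(geometry, "left", n = 1L, span = 0)[1, ]
  config <- config %||% sim_config()
  cache <- new.env(parent = emptyenv())
  recs <- lapply(diameters, function(d)
    .cached_scenario(cache, acprmax, velocity, d, focus, seed = 1L,
                     geometry = geometry, schedule = schedule,
                     config = config, ...)$record)
  records <- do.call(rbind, recs)

  # single-particle probe: released on the inlet centreline, its lateral
  # displacement is read off when it reaches the apex plane, before the
  # branch geometry takes over
  probe_pressure <- probe_pressure %||% acprmax
  gcg <- .geom_cache(geometry)
  start <- c(gcg$apex[1] - gcg$lin, gcg$apex[2], gcg$apex[3])
  deflections <- vapply(diameters, function(d) {
    sched <- release_schedule(n_total = 1L, n_steps = 1L,
                              spatial_mode = "fixed",
                              positions = rbind(start))
    pcfg <- config
    pcfg$trajectory_stride <- 2L
    sc <- .cached_scenario(cache, probe_pressure, velocity, d, focus,
                           seed = 1L, geometry = geometry,
                           schedule = sched, config = pcfg, ...)
    tr <- sc$summary$trajectories
    if (is.null(tr)) return(NA_real_)
    up <- tr[tr$x <= gcg$apex[1], , drop = FALSE]
    if (nrow(up) == 0L) return(NA_real_)
    abs(up$y[which.max(up$x)] - gcg$apex[2])
  }, numeric(1))

  exponent <- if (length(diameters) >= 2L && all(deflections > 0))
    unname(stats::coef(stats::lm(log(deflections) ~ log(diameters)))[2L])
  else NA_real_
  list(records = records, deflections = deflections, exponent = exponent)
}
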