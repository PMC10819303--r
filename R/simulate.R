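# Particle ensemble tracing.
#
# Equation of motion: mp dv/dt = F_rad + F_drag + F_contact, with Stokes drag
# F_drag = (mp/tau_p)(u - v), tau_p = rho_p dp^2 / (18 eta). At 1 MHz and
# micron scales tau_p ~ 1e-6 s while transit times are seconds, so the
# default integrator is the overdamped (quasi-static) limit
#   v = u + F_rad / (3 pi eta dp),
# with an explicit inertial integrator retained for validation. Contact with
# the wall is a specular reflection of the wall-normal velocity component; a
# particle that is pressed against the wall while moving slower than a
# threshold for a sustained number of steps adheres and never moves again.

#' Particle velocity response time
#'
#' `tau_p = rho_p dp^2 / (18 eta)`: the relaxation time with which the
#' particle velocity approaches the local fluid velocity.
#'
#' @param particle A [particle_spec()].
#' @param medium An [medium()] object.
#' @return Response time (s).
#' @export
particle_response_time <- function(particle, medium) {
  particle$density * particle$diameter^2 / (18 * medium$viscosity)
}

#' Stokes drag force
#'
#' `F_d = (mp / tau_p) (u - v)`, algebraically identical to
#' `3 pi eta dp (u - v)`: linear in the slip velocity and in the particle
#' diameter.
#'
#' @param particle A [particle_spec()].
#' @param medium An [medium()] object.
#' @param u_fluid Fluid velocity: 3-vector or n x 3 matrix (m/s).
#' @param v_particle Particle velocity, same shape (m/s).
#' @return Force (N), same shape as the inputs.
#' @export
drag_force <- function(particle, medium, u_fluid, v_particle) {
  mp <- particle$density * particle$volume
  tau <- particle_response_time(particle, medium)
  (mp / tau) * (u_fluid - v_particle)
}

#' Release schedule for a particle ensemble
#'
#' Default protocol: 100 particles released in 4 temporal steps of 25 on the
#' inlet cross-section. Spatial modes: `"uniform_disk"` (uniform over a disk
#' of `radius_fraction` times the inlet radius), `"mirrored"` (exact +/- y
#' pairs, for symmetric baselines), `"ring_biased"` (rim-weighted radius,
#' mimicking a non-uniform upstream distribution), `"fixed"` (explicit
#' `positions`).
#'
#' @param n_total Total particles.
#' @param n_steps Number of temporal release steps; must divide `n_total`.
#' @param step_interval Time between release steps (s).
#' @param spatial_mode Spatial release distribution.
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @param radius_fraction Release disk radius as a fraction of the inlet
#'   radius (strictly inside the lumen, away from the no-slip layer).
#' @param positions n x 3 matrix of absolute release positions for
#'   `spatial_mode = "fixed"`.
#' @return An object of class `acoustonav_schedule`.
#' @export
release_schedule <- function(n_total = 100L, n_steps = 4L,
                             step_interval = 1,
                             spatial_mode = c("uniform_disk", "mirrored",
                                              "ring_biased", "fixed"),
                             seed = 1L, radius_fraction = 0.9,
                             positions = NULL) {
  spatial_mode <- match.arg(spatial_mode)
  n_total <- as.integer(n_total); n_steps <- as.integer(n_steps)
  stopifnot(n_total >= 1L, n_steps >= 1L, step_interval >= 0,
            radius_fraction > 0, radius_fraction < 1)
  if (n_total %% n_steps != 0L)
    stop("n_steps must divide n_total")
  if (spatial_mode == "mirrored" && n_total %% 2L != 0L)
    stop("mirrored release needs an even n_total")
  if (spatial_mode == "fixed") {
    if (is.null(positions)) stop("fixed mode needs positions")
    positions <- .as_points(positions)
    if (nrow(positions) != n_total) stop("positions must have n_total rows")
  }
  structure(list(n_total = n_total, n_steps = n_steps,
                 per_step = n_total %/% n_steps,
                 step_interval = step_interval, spatial_mode = spatial_mode,
                 seed = as.integer(seed), radius_fraction = radius_fraction,
                 positions = positions),
            class = "acoustonav_schedule")
}

#' Draw the initial particle states
#'
#' Generates release positions on the inlet cross-section according to the
#' schedule's spatial mode and assigns each particle the local fluid
#' velocity as its initial velocity. Reproducible: the schedule's seed fully
#' determines the ensemble, and the caller's RNG state is left untouched.
#'
#' @param schedule A [release_schedule()].
#' @param geometry An [vessel_geometry()].
#' @param flow A [flow_spec()].
#' @return Data frame `id, release_time, x, y, z, vx, vy, vz`.
#' @export
release_particles <- function(schedule, geometry, flow) {
  gc <- .geom_cache(geometry)
  n <- schedule$n_total
  rmax <- gc$rin * schedule$radius_fraction
  if (schedule$spatial_mode == "fixed") {
    pos <- schedule$positions
    if (any(wall_distance(geometry, pos) <= 0))
      stop("fixed release positions must lie strictly inside the lumen")
  } else {
    off <- .with_seed(schedule$seed, {
      if (schedule$spatial_mode == "mirrored") {
        m <- n %/% 2L
        a <- numeric(m); b <- numeric(m)
        for (i in seq_len(m)) {
          repeat {
            r <- rmax * sqrt(stats::runif(1)); t <- 2 * pi * stats::runif(1)
            if (abs(r * cos(t)) > 1e-9 * gc$rin) break
          }
          a[i] <- r * cos(t); b[i] <- r * sin(t)
        }
        # interleave exact +/- y pairs
        cbind(as.vector(rbind(a, -a)), as.vector(rbind(b, b)))
      } else {
        r <- if (schedule$spatial_mode == "ring_biased")
          rmax * stats::runif(n)^(1 / 4) else rmax * sqrt(stats::runif(n))
        t <- 2 * pi * stats::runif(n)
        cbind(r * cos(t), r * sin(t))
      }
    })
    pos <- cbind(gc$apex[1] - gc$lin, gc$apex[2] + off[, 1],
                 gc$apex[3] + off[, 2])
  }
  step_idx <- rep(seq_len(schedule$n_steps) - 1L, each = schedule$per_step)
  u0 <- flow_velocity(geometry, flow, pos)
  data.frame(id = seq_len(n), release_time = step_idx * schedule$step_interval,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             vx = u0[, 1], vy = u0[, 2], vz = u0[, 3])
}

#' Simulation configuration
#'
#' All entries are optional; `NULL` means "derive a default from the
#' scenario" when the simulation starts:
#' `dt` so that a particle at the peak flow speed moves about half a
#' particle diameter per step; `t_max` five mean transit times;
#' `wall_gap` one particle diameter; `speed_threshold` one percent of the
#' mean inlet velocity.
#'
#' @param dt Time step (s).
#' @param t_max Hard stop time (s); particles still in transit then are
#'   `timed_out`.
#' @param integrator `"quasi_static"` (overdamped, default) or
#'   `"inertial"` (explicit update of the full equation of motion; requires
#'   `dt <= tau_p / 5`).
#' @param wall_gap Contact distance delta (m): wall interaction is applied
#'   when the wall distance falls below it.
#' @param speed_threshold Adhesion speed threshold (m/s).
#' @param dwell_steps Consecutive slow, wall-pressed steps before a particle
#'   adheres.
#' @param restitution Restitution factor for the reflected wall-normal
#'   velocity component (1 = specular).
#' @param field_method `"grid"` (precomputed force grid, default) or
#'   `"exact"` (pointwise stencil force every step; slow, for validation).
#' @param grid_spacing Force grid spacing (m); default one twentieth of a
#'   wavelength.
#' @param trajectory_stride Record particle positions every this many steps
#'   (0 = do not record).
#' @return An object of class `acoustonav_simconfig`.
#' @export
sim_config <- function(dt = NULL, t_max = NULL,
                       integrator = c("quasi_static", "inertial"),
                       wall_gap = NULL, speed_threshold = NULL,
                       dwell_steps = 50L, restitution = 1,
                       field_method = c("grid", "exact"),
                       grid_spacing = NULL, trajectory_stride = 0L) {
  integrator <- match.arg(integrator)
  field_method <- match.arg(field_method)
  if (!is.null(dt)) stopifnot(dt > 0)
  stopifnot(dwell_steps >= 1L, restitution >= 0, restitution <= 1)
  structure(list(dt = dt, t_max = t_max, integrator = integrator,
                 wall_gap = wall_gap, speed_threshold = speed_threshold,
                 dwell_steps = as.integer(dwell_steps),
                 restitution = restitution, field_method = field_method,
                 grid_spacing = grid_spacing,
                 trajectory_stride = as.integer(trajectory_stride)),
            class = "acoustonav_simconfig")
}

#' Wall contact rule for a single particle
#'
#' If the particle is within `wall_gap` of the wall: the wall-normal
#' velocity component, if directed into the wall, is reversed and scaled by
#' `restitution` (specular reflection); if instead the net force presses the
#' particle into the wall while it moves slower than `speed_threshold`, a
#' dwell counter increments, and after `dwell_steps` consecutive such calls
#' the particle adheres (a terminal state). A position that has penetrated
#' the wall is pushed back to the contact gap.
#'
#' @param position,velocity 3-vectors (m, m/s).
#' @param force Net non-drag force on the particle (N).
#' @param geometry An [vessel_geometry()].
#' @param wall_gap Contact distance (m).
#' @param speed_threshold Adhesion speed threshold (m/s).
#' @param dwell_steps Steps of sustained slow contact before adhesion.
#' @param restitution Normal restitution factor.
#' @param dwell Current dwell counter.
#' @return List with updated `position`, `velocity`, `dwell`, and `status`
#'   (`"in_transit"` or `"adhered"`).
#' @export
wall_interaction <- function(position, velocity, force, geometry,
                             wall_gap, speed_threshold, dwell_steps = 50L,
                             restitution = 1, dwell = 0L) {
  fr <- .vessel_frame(.geom_cache(geometry), .as_points(position),
                      normals = TRUE)
  if (fr$wd > wall_gap)
    return(list(position = position, velocity = velocity, dwell = 0L,
                status = "in_transit"))
  nrm <- c(fr$nx, fr$ny, fr$nz)
  vn <- sum(velocity * nrm)
  if (vn < 0) velocity <- velocity - (1 + restitution) * vn * nrm
  if (fr$wd < wall_gap)
    position <- position + (wall_gap - fr$wd) * nrm
  pressing <- sum(force * nrm) < 0
  slow <- sqrt(sum(velocity^2)) < speed_threshold
  dwell <- if (pressing && slow) dwell + 1L else 0L
  list(position = position, velocity = velocity, dwell = dwell,
       status = if (dwell >= dwell_steps) "adhered" else "in_transit")
}

.status_levels <- c("in_transit", "exited_left", "exited_right", "adhered",
                    "timed_out")

# resolve NULL config entries against the scenario
.resolve_config <- function(config, geometry, flow, particle, medium) {
  gc <- .geom_cache(geometry)
  v <- flow$mean_velocity
  v2 <- .branch_mean_velocity(gc, v)
  vref <- 2 * max(v, v2)             # centreline peak speed
  cfg <- config
  cfg$dt <- cfg$dt %||% (0.5 * particle$diameter / (1.25 * vref))
  cfg$t_max <- cfg$t_max %||% (12 * (gc$lin + gc$lb) / v)
  cfg$wall_gap <- cfg$wall_gap %||% particle$diameter
  cfg$speed_threshold <- cfg$speed_threshold %||% (0.01 * v)
  if (cfg$integrator == "inertial") {
    tau <- particle_response_time(particle, medium)
    if (is.null(config$dt)) cfg$dt <- tau / 5
    if (cfg$dt > tau / 5)
      stop("inertial integration needs dt <= tau_p / 5")
  }
  cfg
}

#' Trace a particle ensemble through the bifurcation
#'
#' Releases the ensemble, integrates the equation of motion until every
#' particle exits a branch, adheres to the wall, or times out, and counts
#' outcomes. With no array (or zero amplitudes) the particles are passive
#' flow tracers. With `config$field_method = "grid"` (default) the
#' radiation force is taken from a precomputed grid
#' ([build_force_grid()]); `"exact"` evaluates the stencil force every step.
#'
#' @param geometry An [vessel_geometry()].
#' @param flow A [flow_spec()].
#' @param particle A [particle_spec()].
#' @param schedule A [release_schedule()].
#' @param config A [sim_config()].
#' @param medium An [medium()] object.
#' @param array Optional phased, normalised `acoustonav_array`.
#' @param force_grid Optional pre-built `acoustonav_force_grid` (overrides
#'   `array` for the force evaluation).
#' @return An `acoustonav_outcome`: list with `counts` (named integer vector
#'   over the terminal states), `n_total`, `particles` (per-particle data
#'   frame with final status, exit time and position), `trajectories`
#'   (data frame or `NULL`), and the resolved `config`.
#' @examples
#' \donttest{
#' geo <- vessel_geometry()
#' out <- simulate_particles(geo, flow_spec(1e-3), particle_spec(),
#'                           release_schedule(n_total = 20, seed = 7))
#' out$counts
#' }
#' @export
simulate_particles <- function(geometry, flow, particle, schedule,
                               config = sim_config(),
                               medium = medium_preset("water"),
                               array = NULL, force_grid = NULL) {
  gc <- .geom_cache(geometry)
  cfg <- .resolve_config(config, geometry, flow, particle, medium)
  has_field <- !is.null(force_grid) ||
    (!is.null(array) && any(array$elements$amplitude != 0))
  if (has_field && is.null(force_grid) && cfg$field_method == "grid")
    force_grid <- build_force_grid(array, medium, particle, geometry,
                                   spacing = cfg$grid_spacing)

  init <- release_particles(schedule, geometry, flow)
  n <- nrow(init)
  pos <- cbind(init$x, init$y, init$z)
  vel <- cbind(init$vx, init$vy, init$vz)
  status <- rep(1L, n)                    # index into .status_levels
  released <- rep(FALSE, n)
  dwell <- rep(0L, n)
  exit_time <- rep(NA_real_, n)

  gamma <- 3 * pi * medium$viscosity * particle$diameter
  mp <- particle$density * particle$volume
  tau <- particle_response_time(particle, medium)
  dt <- cfg$dt
  quasi <- cfg$integrator == "quasi_static"
  nsteps <- ceiling(cfg$t_max / dt)
  stride <- cfg$trajectory_stride
  traj <- if (stride > 0L) vector("list", nsteps %/% stride + 1L) else NULL
  itraj <- 0L

  rt <- init$release_time
  tnow <- 0
  for (s in seq_len(nsteps)) {
    tnow <- s * dt
    released <- released | (rt <= tnow)
    act <- which(status == 1L & released)
    if (length(act) == 0L) {
      if (all(released)) break else next
    }
    P <- pos[act, , drop = FALSE]
    ff <- .flow_field(gc, flow$mean_velocity, P)
    u <- ff$u
    Fr <- NULL
    if (has_field) {
      Fr <- if (!is.null(force_grid)) .interp_force(force_grid, P)
      else radiation_force(array, P, medium, particle)
      if (anyNA(Fr)) stop("radiation force evaluated to NaN; aborting")
    }
    if (quasi) {
      V <- if (has_field) u + Fr / gamma else u
    } else {
      V <- vel[act, , drop = FALSE]
      V <- V + dt * ((u - V) / tau + if (has_field) Fr / mp else 0)
    }
    newP <- P + V * dt

    fr2 <- .vessel_frame(gc, newP)
    contact <- which(fr2$wd < cfg$wall_gap)
    if (length(contact)) {
      nr <- .frame_normals(fr2, contact)
      nrm <- cbind(nr$nx, nr$ny, nr$nz)
      vn <- rowSums(V[contact, , drop = FALSE] * nrm)
      into <- vn < 0
      if (any(into)) {
        Vc <- V[contact, , drop = FALSE]
        Vc[into, ] <- Vc[into, , drop = FALSE] -
          (1 + cfg$restitution) * vn[into] * nrm[into, , drop = FALSE]
        V[contact, ] <- Vc
        newP[contact, ] <- P[contact, , drop = FALSE] +
          V[contact, , drop = FALSE] * dt
      }
      # push any residual penetration back to the contact gap
      wd3 <- .vessel_frame(gc, newP[contact, , drop = FALSE])$wd
      pen <- wd3 < cfg$wall_gap
      if (any(pen)) {
        ci <- contact[pen]
        newP[ci, ] <- newP[ci, , drop = FALSE] +
          (cfg$wall_gap - wd3[pen]) * nrm[pen, , drop = FALSE]
      }
      pressing <- if (has_field)
        rowSums(Fr[contact, , drop = FALSE] * nrm) < 0 else
          rep(FALSE, length(contact))
      slow <- sqrt(rowSums(V[contact, , drop = FALSE]^2)) < cfg$speed_threshold
      ai <- act[contact]
      dwell[ai] <- ifelse(pressing & slow, dwell[ai] + 1L, 0L)
      adh <- dwell[ai] >= cfg$dwell_steps
      if (any(adh)) {
        status[ai[adh]] <- 4L
        exit_time[ai[adh]] <- tnow
      }
      dwell[act[-contact]] <- 0L
    } else if (any(dwell[act] > 0L)) {
      dwell[act] <- 0L
    }

    pos[act, ] <- newP
    if (!quasi) vel[act, ] <- V

    # exits through the flat outlet planes (same frame as the contact test)
    still <- status[act] == 1L
    exl <- fr2$sl >= gc$lb & still
    if (any(exl)) {
      ii <- act[exl]; status[ii] <- 2L; exit_time[ii] <- tnow
    }
    exr <- fr2$sr >= gc$lb & status[act] == 1L
    if (any(exr)) {
      ii <- act[exr]; status[ii] <- 3L; exit_time[ii] <- tnow
    }

    if (stride > 0L && s %% stride == 0L) {
      itraj <- itraj + 1L
      keep <- which(status == 1L & released)
      if (length(keep))
        traj[[itraj]] <- data.frame(t = tnow, id = init$id[keep],
                                    x = pos[keep, 1], y = pos[keep, 2],
                                    z = pos[keep, 3])
    }
    if (all(status != 1L)) break
  }

  timed <- status == 1L
  status[timed] <- 5L
  exit_time[timed] <- tnow
  lab <- .status_levels[status]
  counts <- vapply(.status_levels[-1L], function(s) sum(lab == s),
                   integer(1))
  if (counts[["timed_out"]] > 0.05 * n)
    warning(sprintf("%d of %d particles timed out: t_max may be too small",
                    counts[["timed_out"]], n))
  out <- list(counts = counts, n_total = n,
              particles = data.frame(id = init$id, status = lab,
                                     release_time = init$release_time,
                                     exit_time = exit_time,
                                     x = pos[, 1], y = pos[, 2],
                                     z = pos[, 3]),
              trajectories = if (stride > 0L)
                do.call(rbind, traj[seq_len(itraj)]) else NULL,
              config = cfg)
  class(out) <- "acoustonav_outcome"
  out
}

#' @export
print.acoustonav_outcome <- function(x, ...) {
  cat("<outcome>", x$n_total, "particles:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Advance particle states by one time step
#'
#' Single-step reference version of the update rule used inside
#' [simulate_particles()], exposed for validation. Quasi-static mode sets
#' `v = u + F_rad / (3 pi eta dp)` (overdamped limit, valid because
#' `tau_p` is microseconds against second-scale transits); inertial mode
#' applies one explicit update of the full equation of motion and requires
#' `dt <= tau_p / 5`.
#'
#' `flow` may be a [flow_spec()] (with `geometry`) or a function
#' `function(P)` returning an n x 3 velocity matrix; `force` may be `NULL`
#' (no field), an `acoustonav_force_grid`, or a function `function(P)`
#' returning an n x 3 force matrix. Wall handling is applied only when a
#' geometry is supplied.
#'
#' @param position,velocity n x 3 matrices (m, m/s).
#' @param dt Time step (s).
#' @param particle A [particle_spec()].
#' @param medium An [medium()] object.
#' @param flow Flow specification or function (see above).
#' @param geometry Optional [vessel_geometry()].
#' @param force Optional force source (see above).
#' @param integrator `"quasi_static"` or `"inertial"`.
#' @return List with updated `position` and `velocity`.
#' @export
step_particles <- function(position, velocity, dt, particle, medium,
                           flow, geometry = NULL, force = NULL,
                           integrator = c("quasi_static", "inertial")) {
  integrator <- match.arg(integrator)
  P <- .as_points(position)
  V0 <- .as_points(velocity)
  u <- if (is.function(flow)) flow(P)
  else flow_velocity(geometry, flow, P)
  Fr <- if (is.null(force)) NULL
  else if (is.function(force)) force(P)
  else .interp_force(force, P)
  gamma <- 3 * pi * medium$viscosity * particle$diameter
  mp <- particle$density * particle$volume
  tau <- particle_response_time(particle, medium)
  if (integrator == "quasi_static") {
    V <- if (is.null(Fr)) u else u + Fr / gamma
  } else {
    if (dt > tau / 5) stop("inertial integration needs dt <= tau_p / 5")
    V <- V0 + dt * ((u - V0) / tau + if (is.null(Fr)) 0 else Fr / mp)
  }
  newP <- P + V * dt
  if (!is.null(geometry)) {
    gc <- .geom_cache(geometry)
    fr <- .vessel_frame(gc, newP)
    contact <- which(fr$wd < 0)
    if (length(contact)) {
      nr <- .frame_normals(fr, contact)
      nrm <- cbind(nr$nx, nr$ny, nr$nz)
      vn <- rowSums(V[contact, , drop = FALSE] * nrm)
      into <- vn < 0
      Vc <- V[contact, , drop = FALSE]
      Vc[into, ] <- Vc[into, , drop = FALSE] -
        2 * vn[into] * nrm[into, , drop = FALSE]
      V[contact, ] <- Vc
      newP[contact, ] <- P[contact, , drop = FALSE] +
        V[contact, , drop = FALSE] * dt
    }
  }
  list(position = newP, velocity = V)
}

#' Navigation efficiency
#'
#' Percentage of released particles that exited through the target branch.
#' Adhered and timed-out particles count against the efficiency.
#'
#' @param outcome An `acoustonav_outcome` from [simulate_particles()].
#' @param target `"right"` or `"left"`.
#' @return Efficiency in percent.
#' @export
navigation_efficiency <- function(outcome, target = c("right", "left")) {
  target <- match.arg(target)
  stopifnot(outcome$n_total > 0)
  100 * outcome$counts[[paste0("exited_", target)]] / outcome$n_total
}
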