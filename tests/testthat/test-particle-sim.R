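geo <- fix_geometry()
med_t2 <- medium_preset("blood_like")

test_that("particle response time follows rho dp^2 / (18 eta)", {
  par <- particle_preset("polystyrene_light")
  expect_equal(particle_response_time(par, med_t2), 1.1467e-6,
               tolerance = 1e-4)
  # quadratic in diameter, inverse in viscosity
  expect_equal(particle_response_time(particle_preset("polystyrene_light", 20e-6),
                                      med_t2),
               4 * particle_response_time(par, med_t2), tolerance = 1e-12)
  med2 <- medium(997, 1450, 2 * med_t2$viscosity)
  expect_equal(particle_response_time(par, med2),
               particle_response_time(par, med_t2) / 2, tolerance = 1e-12)
})

test_that("drag force equals Stokes drag in both algebraic forms", {
  par <- particle_spec()
  med <- fix_medium()
  u <- matrix(c(1e-3, 0, -2e-3, 5e-4, 1e-4, 0), 2, 3, byrow = TRUE)
  v <- matrix(c(0, 2e-4, 0, -1e-4, 0, 3e-4), 2, 3, byrow = TRUE)
  fd <- drag_force(par, med, u, v)
  oracle <- 3 * pi * med$viscosity * par$diameter * (u - v)
  expect_equal(fd, oracle, tolerance = 1e-12)
  expect_equal(drag_force(par, med, u, u), matrix(0, 2, 3))
  # linear in diameter at fixed slip
  par2 <- particle_spec(diameter = 2 * par$diameter)
  expect_equal(drag_force(par2, med, u, v), 2 * fd, tolerance = 1e-12)
})

test_that("release schedules are reproducible and follow the protocol", {
  fl <- flow_spec(1e-3)
  sch <- release_schedule(seed = 9)
  a <- release_particles(sch, geo, fl)
  b <- release_particles(sch, geo, fl)
  expect_identical(a, b)
  expect_equal(nrow(a), 100L)
  expect_equal(sort(unique(a$release_time)), c(0, 1, 2, 3))
  expect_true(all(table(a$release_time) == 25))
  # initial velocity is the local fluid velocity
  u0 <- flow_velocity(geo, fl, cbind(a$x, a$y, a$z))
  expect_equal(cbind(a$vx, a$vy, a$vz), unname(u0), tolerance = 1e-12)
  # all strictly inside the lumen
  expect_true(all(wall_distance(geo, cbind(a$x, a$y, a$z)) > 0))
  # the RNG state of the session is untouched
  set.seed(123); x1 <- stats::runif(1)
  set.seed(123); invisible(release_particles(sch, geo, fl))
  expect_identical(stats::runif(1), x1)
})

test_that("mirrored release produces exact +/- y pairs", {
  sch <- release_schedule(spatial_mode = "mirrored", seed = 4)
  a <- release_particles(sch, geo, flow_spec(1e-3))
  ys <- a$y - geo$apex[2]
  expect_identical(sort(ys), sort(-ys))
  expect_true(all(abs(ys) > 0))
  expect_error(release_schedule(n_total = 25, n_steps = 5,
                                spatial_mode = "mirrored"), "even")
})

test_that("wall interaction reflects specularly and adheres when pressed", {
  wall_pt <- geo$apex + c(-3e-3, geo$inlet_diameter / 2 - 5e-6, 0)
  vin <- c(0, 1e-3, 0)  # normal incidence, towards +y wall
  res <- wall_interaction(wall_pt, vin, c(0, 0, 0), geo,
                          wall_gap = 10e-6, speed_threshold = 1e-5,
                          restitution = 1)
  expect_equal(res$velocity, c(0, -1e-3, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(res$velocity^2)), sqrt(sum(vin^2)),
               tolerance = 1e-12)
  expect_identical(res$status, "in_transit")
  # zero velocity plus a force pressing into the wall accumulates dwell
  st <- list(dwell = 0L)
  for (i in 1:50)
    st <- wall_interaction(wall_pt, c(0, 0, 0), c(0, 1e-12, 0), geo,
                           wall_gap = 10e-6, speed_threshold = 1e-5,
                           dwell_steps = 50, dwell = st$dwell)
  expect_identical(st$status, "adhered")
  # a particle clear of the wall is untouched
  free <- wall_interaction(geo$apex + c(-3e-3, 0, 0), vin, c(0, 0, 0), geo,
                           wall_gap = 10e-6, speed_threshold = 1e-5)
  expect_equal(free$velocity, vin)
})

test_that("quasi-static step advects exactly with the fluid when F = 0", {
  par <- particle_spec()
  med <- fix_medium()
  fl <- flow_spec(1e-3)
  P <- .as_points(geo$apex + c(-4e-3, 2e-4, -1e-4))
  u <- flow_velocity(geo, fl, P)
  st <- step_particles(P, u, 0.01, par, med, fl, geometry = geo)
  expect_equal(st$position, P + u * 0.01, tolerance = 1e-15)
  expect_equal(st$velocity, u)
})

test_that("inertial velocity relaxes to u + tau F / m with time constant tau", {
  par <- particle_spec(diameter = 100e-6)  # larger tau for a resolvable test
  med <- fix_medium()
  tau <- particle_response_time(par, med)
  mp <- par$density * par$volume
  uconst <- matrix(c(2e-3, 0, 0), 1)
  Fconst <- matrix(c(0, 3e-12, 0), 1)
  dt <- tau / 20
  P <- matrix(0, 1, 3); V <- matrix(0, 1, 3)
  nst <- ceiling(5 * tau / dt)
  for (i in seq_len(nst)) {
    st <- step_particles(P, V, dt, par, med,
                         flow = function(p) uconst,
                         force = function(p) Fconst,
                         integrator = "inertial")
    P <- st$position; V <- st$velocity
  }
  vinf <- uconst + tau * Fconst / mp
  expect_equal(V, vinf, tolerance = 0.01)
  expect_error(step_particles(P, V, tau, par, med,
                              flow = function(p) uconst,
                              integrator = "inertial"),
               "tau_p")
})

test_that("quasi-static and inertial trajectories agree on a smooth field", {
  par <- particle_spec(diameter = 100e-6)
  med <- fix_medium()
  tau <- particle_response_time(par, med)
  gamma <- 3 * pi * med$viscosity * par$diameter
  # gently varying synthetic flow and force
  uf <- function(p) cbind(2e-3 * (1 + 0.1 * sin(p[, 1] / 1e-3)), 0, 0)
  ff <- function(p) cbind(0, gamma * 2e-4 * cos(p[, 1] / 2e-3), 0)
  dt_i <- tau / 5
  Pq <- matrix(0, 1, 3); Vq <- matrix(0, 1, 3)
  Pi <- matrix(0, 1, 3); Vi <- uf(Pi)
  # advance the inertial path in lockstep; quasi-static with the same dt
  travelled <- 0
  while (Pi[1, 1] < 1e-3) {
    si <- step_particles(Pi, Vi, dt_i, par, med, uf, force = ff,
                         integrator = "inertial")
    Pi <- si$position; Vi <- si$velocity
    sq <- step_particles(Pq, Vq, dt_i, par, med, uf, force = ff)
    Pq <- sq$position; Vq <- sq$velocity
  }
  expect_lt(max(abs(Pi - Pq)), 0.1 * par$diameter)
})

test_that("ensembles conserve counts, reproduce under a seed, and split 50/50", {
  fl <- flow_spec(1e-3)
  par <- particle_spec()
  sch <- release_schedule(n_total = 20L, n_steps = 4L, seed = 2)
  cfg <- sim_config(dt = 4e-3)
  out <- simulate_particles(geo, fl, par, sch, cfg)
  expect_equal(sum(out$counts), 20L)
  expect_identical(out$counts[["adhered"]], 0L)
  out2 <- simulate_particles(geo, fl, par, sch, cfg)
  expect_identical(out$counts, out2$counts)
  expect_identical(out$particles, out2$particles)
  # a zero-amplitude array is identical to no field at all
  dark <- fix_array(); dark$elements$amplitude <- 0
  out3 <- simulate_particles(geo, fl, par, sch, cfg, array = dark)
  expect_identical(out$particles, out3$particles)
  # mirrored release in the symmetric geometry: exactly even split
  schm <- release_schedule(n_total = 20L, n_steps = 4L,
                           spatial_mode = "mirrored", seed = 3)
  outm <- simulate_particles(geo, fl, par, schm, cfg)
  expect_identical(outm$counts[["exited_left"]],
                   outm$counts[["exited_right"]])
})

test_that("navigation efficiency is the target-branch percentage", {
  fake <- structure(list(counts = c(exited_left = 20L, exited_right = 70L,
                                    adhered = 6L, timed_out = 4L),
                         n_total = 100L), class = "acoustonav_outcome")
  expect_equal(navigation_efficiency(fake, "right"), 70)
  expect_equal(navigation_efficiency(fake, "left"), 20)
})
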