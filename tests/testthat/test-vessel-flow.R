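geo <- fix_geometry()
apex <- geo$apex
alpha <- geo$branch_angle / 2
eL <- c(cos(alpha), sin(alpha), 0)
rin <- geo$inlet_diameter / 2
rout <- geo$outlet_diameter / 2

test_that("points classify as lumen, wall or outside consistently", {
  centre <- apex + c(-3e-3, 0, 0)
  expect_identical(classify_point(geo, centre), "lumen")
  onwall <- apex + c(-3e-3, rin, 0)
  expect_identical(classify_point(geo, onwall), "wall")
  expect_identical(classify_point(geo, apex + c(0, 1, 0)), "outside")
  # classification matches the sign of the wall distance
  pts <- fix_lumen_points(50)
  expect_true(all(classify_point(geo, pts) == "lumen"))
  expect_true(all(wall_distance(geo, pts) > 0))
})

test_that("wall distance is exact on the centreline and the wall", {
  expect_equal(wall_distance(geo, apex + c(-3e-3, 0, 0)), rin)
  expect_lt(abs(wall_distance(geo, apex + c(-3e-3, 0, rin))), 1e-15)
  mouthL <- apex + 2.5e-3 * eL
  expect_equal(wall_distance(geo, mouthL), rout)
})

test_that("wall distance matches a brute-force nearest-surface sampling", {
  # dense point cloud on the three cylinder surfaces
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  surf <- list()
  for (s in seq(-geo$inlet_length, -0.1e-3, by = 0.1e-3))
    surf[[length(surf) + 1]] <-
      cbind(apex[1] + s, apex[2] + rin * cos(th), apex[3] + rin * sin(th))
  tL <- c(-eL[2], eL[1], 0)
  for (s in seq(0.1e-3, geo$branch_length, by = 0.1e-3)) {
    c0 <- apex + s * eL
    surf[[length(surf) + 1]] <-
      cbind(c0[1] + rout * (cos(th) * tL[1]),
            c0[2] + rout * (cos(th) * tL[2]), c0[3] + rout * sin(th))
    c1 <- apex + s * c(eL[1], -eL[2], 0)
    surf[[length(surf) + 1]] <-
      cbind(c1[1] + rout * (cos(th) * tL[1]),
            c1[2] - rout * (cos(th) * tL[2]), c1[3] + rout * sin(th))
  }
  cloud <- do.call(rbind, surf)
  # keep only samples on the union boundary: cylinder-surface patches that
  # fall inside another capsule are lumen, not wall
  cloud <- cloud[wall_distance(geo, cloud) < 1e-9, , drop = FALSE]
  pts <- fix_lumen_points(40, seed = 11)
  wd <- wall_distance(geo, pts)
  for (i in seq_len(nrow(pts))) {
    dmin <- min(.rownorm(sweep(cloud, 2, pts[i, ])))
    # the signed distance can never exceed the distance to any boundary
    # sample, and away from the junction seam (where the filtered cloud
    # has a coverage gap along the inter-branch wedge) it comes close
    expect_lte(wd[i], dmin + 1e-12)
    if (sqrt(sum((pts[i, ] - apex)^2)) > 1.2e-3)
      expect_gte(wd[i], dmin - 5e-4)
    expect_lte(wd[i], max(rin, rout))
  }
})

test_that("the flow is Poiseuille in the straight segments", {
  v <- 1e-3
  fl <- flow_spec(v)
  # inlet centreline peak = 2 v
  u <- flow_velocity(geo, fl, apex + c(-4e-3, 0, 0))
  expect_equal(u[1, ], c(2 * v, 0, 0), tolerance = 1e-12)
  # parabolic profile across the inlet
  r <- 0.6 * rin
  u2 <- flow_velocity(geo, fl, apex + c(-4e-3, r, 0))
  expect_equal(u2[1, 1], 2 * v * (1 - (r / rin)^2), tolerance = 1e-12)
  # branch centreline peak = 2 * branch mean (flux conservation)
  v2 <- v * rin^2 / (2 * rout^2)
  ub <- flow_velocity(geo, fl, apex + 3e-3 * eL)
  expect_equal(sqrt(sum(ub^2)), 2 * v2, tolerance = 1e-9)
  expect_equal(ub[1, ] / sqrt(sum(ub^2)), eL, tolerance = 1e-9)
})

test_that("no-slip holds at 1000 wall points and outside the lumen", {
  fl <- flow_spec(2e-3)
  set.seed(33)
  # random points on the three cylinder surfaces incl. the junction zone
  n <- 1000
  seg <- sample(1:3, n, replace = TRUE)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- matrix(NA_real_, n, 3)
  tL <- c(-eL[2], eL[1], 0)
  for (i in seq_len(n)) {
    if (seg[i] == 1) {
      s <- stats::runif(1, -geo$inlet_length, 0)
      pts[i, ] <- apex + c(s, rin * cos(th[i]), rin * sin(th[i]))
    } else {
      s <- stats::runif(1, 0, geo$branch_length)
      sgn <- if (seg[i] == 2) 1 else -1
      c0 <- apex + s * c(eL[1], sgn * eL[2], 0)
      pts[i, ] <- c0 + rout * cos(th[i]) * c(tL[1], sgn * tL[2], 0) +
        c(0, 0, rout * sin(th[i]))
    }
  }
  wd <- wall_distance(geo, pts)
  on_or_out <- wd <= 1e-12
  u <- flow_velocity(geo, fl, pts)
  # points on (or outside) the union wall carry exactly zero velocity;
  # surface points of one cylinder that lie inside another are lumen
  expect_true(all(.rownorm(u[on_or_out, ]) < 1e-12))
  # and any remaining junction-interior points still respect the profile cap
  expect_true(all(.rownorm(u) <= 2 * 2e-3 * rin^2 / (2 * rout^2) + 1e-12))
})

test_that("volumetric flux is conserved across the bifurcation", {
  v <- 1.3e-3
  fl <- flow_spec(v)
  qin <- flux_through_disk(geo, fl, apex + c(-4e-3, 0, 0), c(1, 0, 0), rin)
  expect_equal(qin, v * pi * rin^2, tolerance = 5e-3)
  cL <- apex + 3.5e-3 * eL
  cR <- apex + 3.5e-3 * c(eL[1], -eL[2], 0)
  qL <- flux_through_disk(geo, fl, cL, eL, rout)
  qR <- flux_through_disk(geo, fl, cR, c(eL[1], -eL[2], 0), rout)
  expect_lt(abs(qL + qR - qin) / qin, 5e-3)
})

test_that("the field is exactly mirror-symmetric in y", {
  fl <- flow_spec(1e-3)
  pts <- fix_lumen_points(200, seed = 5)
  mir <- pts
  mir[, 2] <- 2 * apex[2] - mir[, 2]
  u <- flow_velocity(geo, fl, pts)
  um <- flow_velocity(geo, fl, mir)
  expect_identical(u[, 1], um[, 1])
  expect_identical(u[, 3], um[, 3])
  expect_identical(u[, 2], -um[, 2])
})

test_that("speed never exceeds twice the local mean plus blend tolerance", {
  v <- 1e-3
  fl <- flow_spec(v)
  pts <- fix_lumen_points(500, seed = 17)
  u <- flow_velocity(geo, fl, pts)
  vmax <- 2 * v * rin^2 / (2 * rout^2)
  expect_true(all(.rownorm(u) <= vmax * (1 + 1e-9)))
})

test_that("Reynolds number is the standard expression", {
  m <- medium(997, 1450, 1e-3)
  expect_equal(reynolds_number(m, 2e-3, 1e-3), 1.994)
  expect_equal(reynolds_number(m, 2e-3, 2e-3), 2 * 1.994)
  expect_equal(reynolds_number(m, 2e-3, 0), 0)
})
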