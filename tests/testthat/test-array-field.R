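med <- fix_medium()
k0 <- wavenumber(med, 1e6)

test_that("cap layouts put every element exactly at the focal distance", {
  arr <- fix_array()
  el <- arr$elements
  expect_equal(nrow(el), 30L)
  d <- sqrt(el$x^2 + el$y^2 + (el$z - 0.031)^2)
  expect_lt(max(abs(d - 0.031)), 1e-9)
  # normals are unit vectors aimed at the focus
  nn <- sqrt(el$nx^2 + el$ny^2 + el$nz^2)
  expect_lt(max(abs(nn - 1)), 1e-12)
  to_focus <- cbind(-el$x, -el$y, 0.031 - el$z) / d
  expect_lt(max(abs(to_focus - cbind(el$nx, el$ny, el$nz))), 1e-12)

  sp <- build_array("spiral")
  dsp <- with(sp$elements, sqrt(x^2 + y^2 + (z - 0.031)^2))
  expect_equal(sort(dsp), sort(d), tolerance = 1e-12)
})

test_that("degenerate single-element layout sits on the axis", {
  arr <- build_array(n_elements = 1)
  el <- arr$elements
  expect_equal(c(el$x, el$y, el$z), c(0, 0, 0), tolerance = 1e-15)
  expect_equal(c(el$nx, el$ny, el$nz), c(0, 0, 1), tolerance = 1e-15)
})

test_that("overlapping apertures trigger a warning", {
  expect_warning(build_array(element_radius = 8e-3), "overlap")
})

test_that("directivity has the correct limit, first null and parity", {
  a <- 4.5e-3
  expect_identical(directivity(0, a, k0), 1)
  # first positive root of J1 from an independent root finder
  x1 <- stats::uniroot(function(x) besselJ(x, 1), c(3, 4.5),
                       tol = 1e-14)$root
  expect_equal(x1, 3.8317, tolerance = 1e-4)
  th1 <- asin(x1 / (a * k0))
  expect_lt(abs(directivity(th1, a, k0)), 1e-9)
  th <- seq(-1.2, 1.2, length.out = 41)
  expect_equal(directivity(th, a, k0), directivity(-th, a, k0))
})

test_that("element pressure follows the 1/d spherical decay and k d phase", {
  el <- transducer(c(0, 0, 0), c(0, 0, 1), 4.5e-3, amplitude = 2,
                   phase = 0.3)
  d1 <- 0.02; d2 <- 0.04
  p1 <- element_pressure(el, c(0, 0, d1), med, 1e6)
  p2 <- element_pressure(el, c(0, 0, d2), med, 1e6)
  expect_equal(Mod(p1), 2 / d1, tolerance = 1e-12)
  expect_equal(Mod(p2), Mod(p1) / 2, tolerance = 1e-12)
  dphi <- (Arg(p2) - Arg(p1)) %% (2 * pi)
  expect_equal(dphi, (k0 * (d2 - d1)) %% (2 * pi), tolerance = 1e-9)
  # |p(d)| * d is constant along the axis
  ds <- seq(0.01, 0.05, by = 0.005)
  pp <- element_pressure(el, cbind(0, 0, ds), med, 1e6)
  expect_lt(diff(range(Mod(pp) * ds)), 1e-12 * 2)
  # back half-space is dark, near field is refused
  expect_equal(element_pressure(el, c(0, 0, -0.01), med, 1e6), 0 + 0i)
  expect_error(element_pressure(el, c(0, 0, 1e-4), med, 1e6), "far-field")
})

test_that("total pressure is the exact superposition of element fields", {
  arr <- fix_array()
  pts <- fix_focal_points(5)
  p <- total_pressure(arr, pts, med)
  psum <- Reduce(`+`, lapply(seq_len(nrow(arr$elements)), function(j)
    element_pressure(arr$elements[j, ], pts, med, arr$frequency)))
  expect_equal(p, psum, tolerance = 1e-12)
  # single-element array reduces to the element field
  one <- build_array(n_elements = 1)
  expect_equal(total_pressure(one, c(0, 0, 0.02), med),
               element_pressure(one$elements[1, ], c(0, 0, 0.02), med, 1e6))
  # zero amplitudes give a null field; amplitude scaling is linear
  z <- arr; z$elements$amplitude <- 0
  expect_identical(total_pressure(z, pts, med), complex(5))
  s <- arr; s$elements$amplitude <- 3 * s$elements$amplitude
  expect_equal(total_pressure(s, pts, med), 3 * p, tolerance = 1e-12)
})

test_that("focusing phases align all contributions at the focus", {
  arr <- focus_phases(fix_array(), c(0, 0, 0.031), med)
  # equidistant cap: all phases equal
  expect_lt(diff(range(arr$elements$phase)), 1e-9)
  # per-element complex contributions at the focus share one argument
  args <- vapply(seq_len(30), function(j)
    Arg(element_pressure(arr$elements[j, ], c(0, 0, 0.031), med, 1e6)),
    numeric(1))
  expect_lt(diff(range(args)), 1e-9)
  # so the focal magnitude is the sum of element magnitudes
  mags <- vapply(seq_len(30), function(j)
    Mod(element_pressure(arr$elements[j, ], c(0, 0, 0.031), med, 1e6)),
    numeric(1))
  expect_equal(Mod(total_pressure(arr, c(0, 0, 0.031), med)), sum(mags),
               tolerance = 1e-9)
})

test_that("re-phasing moves the pressure peak to a displaced focus", {
  f2 <- c(5e-3, 0, 0.031)
  arr0 <- focus_phases(fix_array(), c(0, 0, 0.031), med)
  arr2 <- focus_phases(fix_array(), f2, med)
  expect_gte(Mod(total_pressure(arr2, f2, med)),
             Mod(total_pressure(arr0, f2, med)))
})

test_that("the focus is the regional pressure maximum", {
  arr <- fix_focused_array()
  lam <- med$sound_speed / arr$frequency
  set.seed(7)
  dirs <- matrix(stats::rnorm(3 * 120), ncol = 3)
  dirs <- dirs / .rownorm(dirs)
  pf <- Mod(total_pressure(arr, c(0, 0, 0.031), med))
  for (r in c(0.5, 1, 2, 3) * lam) {
    probe <- matrix(c(0, 0, 0.031), nrow(dirs), 3, byrow = TRUE) + r * dirs
    expect_true(all(Mod(total_pressure(arr, probe, med)) <= pf))
  }
})

test_that("twin-trap phasing nulls the focus between two lobes", {
  f <- c(0, 0, 0.031)
  single <- focus_phases(fix_array(), f, med)
  twin <- twin_trap_phases(fix_array(), f, c(0, 1, 0), med)
  p0 <- Mod(total_pressure(single, f, med))
  expect_lt(Mod(total_pressure(twin, f, med)), 0.05 * p0)
  # two pressure maxima straddle the null along the split axis
  ys <- seq(-2e-3, 2e-3, by = 5e-5)
  pp <- Mod(total_pressure(twin, cbind(0, ys, 0.031), med))
  neg <- ys < 0; pos <- ys > 0
  expect_gt(max(pp[neg]), 5 * pp[which.min(abs(ys))])
  expect_gt(max(pp[pos]), 5 * pp[which.min(abs(ys))])
  expect_false(which.max(pp) %in% which(abs(ys) < 2e-4))
  # removing the pi offsets recovers the single-focus field exactly
  back <- twin
  flip <- abs((twin$elements$phase - single$elements$phase) %% (2 * pi) -
                pi) < 1e-9
  back$elements$phase[flip] <-
    (back$elements$phase[flip] - pi) %% (2 * pi)
  pts <- fix_focal_points(5)
  expect_equal(total_pressure(back, pts, med),
               total_pressure(single, pts, med), tolerance = 1e-12)
})

test_that("stencil derivatives match the analytic spherical wave", {
  one <- build_array(n_elements = 1)
  # on the element axis the field is A exp(ikd)/d, so dp/dz = (ik - 1/d) p;
  # a fine stencil reproduces it to 1e-6 relative
  pt <- c(0, 0, 0.025)
  lam <- 2 * pi / k0
  fd <- field_with_derivatives(one, pt, med, step_h = lam / 5000)
  expect_equal(fd$pz, (1i * k0 - 1 / 0.025) * fd$p, tolerance = 1e-6)
  expect_equal(Mod(fd$px), 0, tolerance = 1e-9 * Mod(fd$p))
  # halving the default step barely changes the derivatives (smoothness)
  fd1 <- field_with_derivatives(one, pt, med)
  fd2 <- field_with_derivatives(one, pt, med, step_h = lam / 400)
  expect_equal(Mod(fd2$pz - fd1$pz) / Mod(fd1$pz), 0, tolerance = 0.01)
})

test_that("focused-field derivatives agree with a 10x finer stencil", {
  arr <- fix_focused_array()
  lam <- med$sound_speed / arr$frequency
  pts <- fix_focal_points(100)
  fd <- field_with_derivatives(arr, pts, med)
  fine <- field_with_derivatives(arr, pts, med, step_h = lam / 2000)
  scale <- sqrt(Mod(fine$px)^2 + Mod(fine$py)^2 + Mod(fine$pz)^2)
  for (comp in c("px", "py", "pz")) {
    err <- Mod(fd[[comp]] - fine[[comp]]) / scale
    expect_lt(max(err), 0.005)
  }
})

test_that("on the axis of an axisymmetric focus lateral derivatives vanish", {
  arr <- fix_focused_array()
  fd <- field_with_derivatives(arr, cbind(0, 0, c(0.029, 0.031, 0.033)),
                               med)
  expect_true(all(Mod(fd$px) < 1e-6 * Mod(fd$pz) + 1e-6))
  expect_true(all(Mod(fd$py) < 1e-6 * Mod(fd$pz) + 1e-6))
})

test_that("peak normalisation hits the target, scales linearly, idempotent", {
  arr <- focus_phases(fix_array(), c(0, 0, 0.031), med)
  n2 <- normalize_to_peak(arr, 2e6, med)
  expect_equal(Mod(total_pressure(n2, c(0, 0, 0.031), med)), 2e6,
               tolerance = 1e-3)
  n4 <- normalize_to_peak(arr, 4e6, med)
  expect_equal(n4$elements$amplitude, 2 * n2$elements$amplitude,
               tolerance = 1e-12)
  again <- normalize_to_peak(n2, 2e6, med)
  expect_equal(again$elements$amplitude, n2$elements$amplitude,
               tolerance = 1e-9)
  zero <- arr; zero$elements$amplitude <- 0
  expect_error(normalize_to_peak(zero, 1e6, med), "zero field")
})
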