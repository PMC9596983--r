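test_that("noiseless straight lines are represented exactly", {
  ln <- make_curve("line", length = 10, n_points = 50)
  fit <- fit_free_knot_spline(ln)
  expect_lt(fit$rms, 1e-9)
  prof <- geometry_profile(fit, 100)
  expect_lt(max(prof$kappa), 1e-6)
  expect_equal(max(abs(prof$tau)), 0) # degeneracy rule zeroes torsion
  m <- tortuosity_metrics(prof, fit)
  expect_equal(m$DM, 1)
  expect_equal(m$L, 10, tolerance = 1e-9)
  expect_equal(m$l, 10, tolerance = 1e-9)
  expect_equal(m$mean_curvature + m$mean_torsion + m$range_torsion, 0,
               tolerance = 1e-6)
})

test_that("the fitted curve reproduces a noiseless helix to sub-micron", {
  hx <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200)
  fit <- fit_free_knot_spline(hx)
  tt <- seq(0, 1, length.out = 400)
  pr <- predict(fit, tt)
  truth <- cbind(3 * cos(2 * pi * tt), 3 * sin(2 * pi * tt), 4 * 2 * pi * tt)
  expect_lt(max(sqrt(rowSums((pr - truth)^2))), 1e-3)
})

test_that("helix curvature and torsion recover the Frenet closed forms", {
  hx <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200)
  fit <- fit_free_knot_spline(hx, degree = 5, max_interior_knots = 25)
  prof <- geometry_profile(fit, 200)
  expect_lt(max(abs(prof$kappa - 0.12)), 1e-3)
  expect_lt(max(abs(prof$tau - 0.16)), 1e-3)
  m <- tortuosity_metrics(prof, fit)
  expect_equal(m$L, 2 * pi * 5, tolerance = 1e-4)
  expect_equal(m$l, 2 * pi * 4, tolerance = 1e-4)
  expect_equal(m$DM, 0.8, tolerance = 1e-5)
})

test_that("planar circles have constant curvature and zero torsion", {
  circ <- make_curve("arc", a = 2, angle = 2 * pi * 0.999, n_points = 300)
  fit <- fit_free_knot_spline(circ, degree = 5, max_interior_knots = 30)
  prof <- geometry_profile(fit, 200)
  expect_lt(max(abs(prof$kappa - 0.5)), 1e-3)
  expect_lt(max(abs(prof$tau)), 1e-6)
})

test_that("semicircle metrics match arc-length geometry", {
  semi <- make_curve("arc", a = 10, angle = pi, n_points = 100)
  m <- tortuosity(semi, degree = 5, max_interior_knots = 20)
  expect_equal(m$DM, 2 / pi, tolerance = 1e-6)
  expect_equal(m$mean_curvature, 0.1, tolerance = 1e-4)
  expect_equal(m$max_curvature, 0.1, tolerance = 1e-3)
  expect_lt(m$range_curvature, 1e-3) # constant-curvature curve
  # range equals max whenever the minimum kappa is ~0, as on vessels that
  # contain a straight stretch (composite starts with a line)
  hx <- tortuosity(make_curve("composite", a = 4, b = 1, length = 8,
                              n_points = 150))
  prof_c <- attr(hx, "profile")
  expect_lt(min(prof_c$kappa), 1e-3 * max(prof_c$kappa))
  expect_equal(hx$range_curvature, hx$max_curvature,
               tolerance = 1e-2 * hx$max_curvature)
  expect_lte(hx$range_curvature, hx$max_curvature)
})

test_that("noisy fits absorb the noise level instead of interpolating it", {
  rms <- vapply(1:20, function(i) {
    noisy <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200,
                        noise_sd = 0.05, seed = i)
    fit_free_knot_spline(noisy)$rms
  }, numeric(1))
  expect_true(all(rms > 0.03 & rms < 0.07))
})

test_that("metrics are invariant under rigid motion", {
  hx <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200)
  m0 <- tortuosity(hx, degree = 5, max_interior_knots = 25)
  p0 <- attr(m0, "profile")
  for (s in 1:3) {
    moved <- apply_rigid(hx, random_rotation(s), c(5, -3, 2) * s)
    m1 <- tortuosity(moved, degree = 5, max_interior_knots = 25)
    p1 <- attr(m1, "profile")
    expect_lt(max(abs(p1$kappa - p0$kappa)) / max(p0$kappa), 1e-8)
    expect_lt(max(abs(p1$tau - p0$tau)) / max(p0$tau), 1e-8)
    for (col in c("mean_curvature", "max_curvature", "mean_torsion",
                  "max_torsion", "DM", "L", "l")) {
      expect_lt(abs(m1[[col]] - m0[[col]]) / abs(m0[[col]]), 1e-8)
    }
  }
})

test_that("metrics scale covariantly: kappa, tau ~ 1/s; L, l ~ s; DM fixed", {
  hx <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 150)
  m0 <- tortuosity(hx, degree = 5, max_interior_knots = 20)
  for (s in c(0.5, 2.5)) {
    scaled <- new_vt_curve(as.matrix(hx[, c("x", "y", "z")]) * s)
    m1 <- tortuosity(scaled, degree = 5, max_interior_knots = 20)
    expect_equal(m1$mean_curvature, m0$mean_curvature / s, tolerance = 1e-6)
    expect_equal(m1$max_curvature, m0$max_curvature / s, tolerance = 1e-6)
    expect_equal(m1$mean_torsion, m0$mean_torsion / s, tolerance = 1e-6)
    expect_equal(m1$L, m0$L * s, tolerance = 1e-8)
    expect_equal(m1$l, m0$l * s, tolerance = 1e-8)
    expect_equal(m1$DM, m0$DM, tolerance = 1e-8)
  }
})

test_that("spline kappa/tau agree with a finite-difference oracle", {
  for (spec in list(list(a = 3, b = 4), list(a = 5, b = 1))) {
    hx <- make_curve("helix", a = spec$a, b = spec$b, turns = 1,
                     n_points = 400)
    fd <- fd_frenet(as.matrix(hx[, c("x", "y", "z")]))
    fit <- fit_free_knot_spline(hx, degree = 5, max_interior_knots = 25)
    prof <- geometry_profile(fit, 100)
    inner <- prof$s > 0.05 * max(prof$s) & prof$s < 0.95 * max(prof$s)
    expect_lt(max(abs(prof$kappa[inner] - median(fd$kappa))) /
                median(fd$kappa), 1e-3)
    expect_lt(max(abs(prof$tau[inner] - median(fd$tau))) /
                median(fd$tau), 1e-3)
  }
})

test_that("degenerate and undersized inputs are rejected", {
  ln <- make_curve("line", length = 5, n_points = 10)
  expect_error(fit_free_knot_spline(ln[1:3, ]), "degree \\+ 2")
  fit <- fit_free_knot_spline(ln)
  expect_error(geometry_profile(fit, 5), "at least 10")
})

test_that("tidy and glance expose the fit summary", {
  hx <- make_curve("helix", a = 3, b = 1, turns = 1, n_points = 80)
  fit <- fit_free_knot_spline(hx, max_interior_knots = 8)
  td <- generics::tidy(fit)
  expect_true(all(td$position > 0 & td$position < 1))
  gl <- generics::glance(fit)
  expect_identical(gl$n_points, 80L)
  expect_gt(gl$arc_length, 0)
})

test_that("metrics and profile CSVs use the canonical column layout", {
  m <- tortuosity(make_curve("line", length = 10, n_points = 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(m, f)
  back <- read.csv(f)
  expect_identical(names(back),
                   c("mean_curvature", "max_curvature", "range_curvature",
                     "mean_torsion", "max_torsion", "range_torsion",
                     "DM", "L", "l"))
  expect_equal(back$DM, 1)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(attr(m, "profile"), fp)
  prof <- read.csv(fp)
  expect_identical(names(prof), c("s", "kappa", "tau"))
  expect_equal(nrow(prof), nrow(attr(m, "profile")))
})
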