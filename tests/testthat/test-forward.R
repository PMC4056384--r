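test_that("surface depth finds the first non-air voxel (axis-aligned slab)", {
  ph <- single_voxel_phantom(5, z_surface = 10, nz = 80)
  for (xy in list(c(0, 0), c(0.4, -0.4))) {
    expect_equal(surface_depth(ph, parallel_lor(xy[1], xy[2])), 10,
                 tolerance = 1e-9)
  }
})

test_that("a LOR entirely in air reports +Inf and projects zero counts", {
  act <- array(0, c(4, 4, 4))
  med <- array("air", c(4, 4, 4))
  act[2, 2, 2] <- 1   # hot voxel in air: no surface, no counts
  ph <- phantom(act, med, 1, c(-2, -2, 5))
  expect_identical(surface_depth(ph, parallel_lor(0, 0)), Inf)
  cam <- ideal_parallel_camera()
  spec <- project(ph, cam, pixels = central_pixel)
  expect_true(all(spec$values == 0))
})

test_that("surface depth on a tilted box matches fine ray marching", {
  # water box seen by off-axis pinhole LORs (obliquely incident rays)
  act <- array(0, c(8, 8, 8)); med <- array("water", c(8, 8, 8))
  ph <- phantom(act, med, 1, c(-6, -4, 22))
  for (pix in list(c(6, 3), c(-4, 7), c(0.5, -2))) {
    lor <- pinhole_lor(pix[1], pix[2], 15)
    expect_equal(surface_depth(ph, lor), march_surface_depth(ph, lor),
                 tolerance = 2e-3)
  }
})

test_that("projector matches the single-voxel closed form at several depths", {
  cam <- ideal_parallel_camera()
  E <- energy_grid()$centers
  G <- geometric_efficiency(parallel_collimator(), c(0, 0, 5))
  for (d in c(5, 10, 15)) {
    ph <- single_voxel_phantom(d, z_surface = 2, nz = 80)
    spec <- project(ph, cam, E, pixels = central_pixel)
    d_true <- ph$source_z - ph$z_surface   # voxel-center depth below surface
    mu <- attenuation_coefficient("water", E)
    closed <- brems_yield(E) * 1 * G * ph$voxel * exp(-mu * d_true)
    expect_true(all(abs(spec$values[1, ] / closed - 1) < 0.005))
  }
})

test_that("projector matches a 10 micron brute-force integrator on a random phantom", {
  set.seed(7)
  act <- array(runif(8^3), c(8, 8, 8))
  med <- array(sample(c("water", "water", "water", "air"), 8^3, replace = TRUE),
               c(8, 8, 8))
  ph <- phantom(act, med, 1, c(-4, -4, 20))
  E <- c(80, 180, 320)
  cam_par <- ideal_parallel_camera()
  cam_pin <- camera_model(collimator = pinhole_collimator(focal_length_cm = 15),
                          resolution = 0, efficiency = "ideal")
  cases <- list(
    list(cam = cam_par, pix = c(1.3, -0.7),
         lor = parallel_lor(1.3, -0.7),
         G = function(p) geometric_efficiency(parallel_collimator(), p[1, , drop = FALSE])[1] + 0 * p[, 3]),
    list(cam = cam_pin, pix = c(4.1, 2.3),
         lor = pinhole_lor(4.1, 2.3, 15),
         G = function(p) {
           g <- numeric(nrow(p)); ok <- p[, 3] > 15
           if (any(ok)) g[ok] <- geometric_efficiency(
             pinhole_collimator(focal_length_cm = 15), p[ok, , drop = FALSE])
           g
         }))
  for (cs in cases) {
    spec <- project(ph, cs$cam, E, pixels = data.frame(x = cs$pix[1], y = cs$pix[2]))
    ref <- march_spectrum(ph, cs$lor, E, cs$G, step = 1e-3, l_max = 40)
    expect_true(all(abs(spec$values[1, ] / ref - 1) < 0.005))
  }
})

test_that("projection is linear in activity and monotone in source depth", {
  cam <- ideal_parallel_camera()
  E <- c(100, 200, 300)
  ph1 <- single_voxel_phantom(5, nz = 70)
  ph2 <- single_voxel_phantom(12, nz = 70)
  ph_sum <- ph1
  ph_sum$activity <- ph1$activity + ph2$activity
  s1 <- project(ph1, cam, E, pixels = central_pixel)$values
  s2 <- project(ph2, cam, E, pixels = central_pixel)$values
  s12 <- project(ph_sum, cam, E, pixels = central_pixel)$values
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
  expect_true(all(s2 < s1))   # deeper source attenuated more at every energy
  ph0 <- ph1; ph0$activity[] <- 0
  expect_true(all(project(ph0, cam, E, pixels = central_pixel)$values == 0))
})

test_that("normalization applies the surface and yield correction pointwise", {
  cam <- ideal_parallel_camera()
  E <- energy_grid()$centers
  ph <- single_voxel_phantom(8, z_surface = 3, nz = 70)
  spec <- project(ph, cam, E, pixels = central_pixel)
  lp <- surface_depth(ph, parallel_lor(0, 0))
  ns <- normalize_spectrum(spec, lp)
  mu <- attenuation_coefficient("water", E)
  expect_equal(ns$values[1, ],
               spec$values[1, ] * exp(-mu * lp) / brems_yield(E),
               tolerance = 1e-12)
  # log C is linear in mu with slope -l_source (depth from the detector)
  fit <- lm(log(ns$values[1, ]) ~ mu)
  expect_equal(-unname(coef(fit)[2]), ph$source_z, tolerance = 0.01)
  # residual curvature only from the finite voxel (sinh correction), tiny
  expect_lt(summary(fit)$sigma, 1e-3)
  expect_error(normalize_spectrum(spec, Inf), "finite")
})

test_that("normalization refuses energies at or beyond the beta endpoint", {
  fake <- structure(list(pixels = central_pixel, energies = c(2295, 2305),
                         bin_width = 10, values = matrix(1, 1, 2),
                         unit = "rate"),
                    class = "energy_spectrum")
  expect_error(normalize_spectrum(fake, 0), "endpoint")
})

test_that("mu re-parameterization is a monotone relabeling", {
  cam <- ideal_parallel_camera()
  E <- energy_grid()$centers
  ph <- single_voxel_phantom(10, nz = 70)
  ns <- normalize_spectrum(project(ph, cam, E, pixels = central_pixel),
                           surface_depth(ph, parallel_lor(0, 0)))
  ms <- rebin_to_mu(ns)
  expect_true(all(diff(ms$mu) > 0))
  expect_true(all(diff(ms$energies) < 0))  # energy axis reversed
  # round trip: Chat(mu(E)) = C(E), a pure relabeling
  expect_equal(sort(ms$values[1, ]), sort(ns$values[1, ]))
  # single voxel: ln Chat linear in mu recovers the source depth within 1%
  d_est <- point_source_depth(ms)
  expect_equal(d_est, ph$source_z, tolerance = 0.01)
})

test_that("mu spectra from nonnegative phantoms are positive, decreasing and convex", {
  set.seed(12)
  act <- array(runif(6^3), c(6, 6, 6))
  med <- array("water", c(6, 6, 6))
  ph <- phantom(act, med, 1, c(-3, -3, 4))
  cam <- ideal_parallel_camera()
  ns <- normalize_spectrum(project(ph, cam, pixels = central_pixel),
                           surface_depth(ph, parallel_lor(0, 0)))
  ms <- rebin_to_mu(ns)
  v <- ms$values[1, ]
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))            # completely monotone: decreasing
  slopes <- diff(v) / diff(ms$mu)          # mu grid is non-uniform
  expect_true(all(diff(slopes) > -1e-12))  # and convex (divided differences)
})

test_that("detector response: identity limit, windowing and count conservation", {
  E <- energy_grid(10, 800, by = 2)$centers
  base <- structure(list(pixels = central_pixel, energies = E, bin_width = 2,
                         values = matrix(0, 1, length(E)), unit = "rate"),
                    class = "energy_spectrum")
  set.seed(5)
  base$values[1, ] <- runif(length(E))
  # null response
  cam0 <- camera_model(collimator = parallel_collimator(), resolution = 0,
                       window = c(0, Inf), efficiency = "ideal")
  expect_equal(apply_detector_response(base, cam0)$values, base$values)
  # acquisition window removes all mass outside (50, 350)
  camw <- camera_model(collimator = parallel_collimator(), resolution = 0,
                       window = c(50, 350), efficiency = "ideal")
  vw <- apply_detector_response(base, camw)$values[1, ]
  expect_true(all(vw[E < 50 | E > 350] == 0))
  expect_equal(vw[E >= 50 & E <= 350], base$values[1, E >= 50 & E <= 350])
  # Gaussian blur conserves total counts before windowing
  camb <- camera_model(collimator = parallel_collimator(), resolution = 0.2,
                       window = c(0, Inf), efficiency = "ideal")
  for (k in 1:100) {
    base$values[1, ] <- runif(length(E))
    vb <- apply_detector_response(base, camb)$values[1, ]
    expect_equal(sum(vb), sum(base$values), tolerance = 1e-9)
  }
  # efficiency scaling uses the crystal slab interaction probability
  # (energy grid restricted to the bundled table range)
  E2 <- energy_grid(40, 800, by = 2)$centers
  base2 <- base
  base2$energies <- E2
  set.seed(6)
  base2$values <- matrix(runif(length(E2)), 1)
  came <- camera_model(collimator = parallel_collimator(), resolution = 0,
                       window = c(0, Inf), efficiency = "analytic",
                       crystal = crystal_slab("BGO", 3))
  ve <- apply_detector_response(base2, came)$values[1, ]
  expect_equal(ve, base2$values[1, ] * absorption_probability("BGO", 3, E2),
               tolerance = 1e-12)
})
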