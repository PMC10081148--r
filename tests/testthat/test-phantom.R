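test_that("gamma-variate curve rises at t0 and peaks with value A at t0 + alpha*beta", {
  p <- list(A = 2.3, t0 = 5, alpha = 2.5, beta = 1.5)
  expect_equal(enhancement_curve(p, 5), 0)
  expect_equal(enhancement_curve(p, 0:5), rep(0, 6))
  # analytic maximiser of A (tau/(alpha beta))^alpha exp(alpha - tau/beta)
  expect_equal(enhancement_curve(p, 5 + 2.5 * 1.5), 2.3)
  tgrid <- seq(5.01, 20, by = 0.01)
  expect_lt(max(enhancement_curve(p, tgrid)), 2.3 + 1e-10)
  # continuity across the onset
  expect_lt(enhancement_curve(p, 5 + 1e-6), 1e-4)
  expect_equal(enhancement_curve(list(A = 0, t0 = 1, alpha = 2, beta = 1), 0:10),
               rep(0, 11))
  expect_error(enhancement_curve(list(A = 1, t0 = 0, alpha = -1, beta = 1), 3),
               "alpha")
  expect_error(enhancement_curve(list(A = 1, t0 = 0, alpha = 1, beta = 0), 3),
               "beta")
})

test_that("phantom_spec validates its fields by name", {
  expect_error(phantom_spec(grid_size = 8), "grid_size")
  expect_error(phantom_spec(n_frames = 1), "n_frames")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  ell <- default_ellipses()
  ell$cx[1] <- 0.8  # pushes the body ellipse outside the unit FOV
  expect_error(phantom_spec(ellipses = ell), "unit field of view")
  expect_error(phantom_spec(bolus = list()), "bolus")
})

test_that("phantom frames: phase, dynamics, support and determinism behave as specified", {
  sp0 <- phantom_spec(grid_size = 32, n_frames = 4, phase_amplitude = 0)
  ph0 <- generate_phantom(sp0)
  expect_true(all(Im(ph0) == 0))

  static_bolus <- lapply(default_bolus(), function(p) { p$A <- 0; p })
  sps <- phantom_spec(grid_size = 32, n_frames = 5, bolus = static_bolus)
  phs <- generate_phantom(sps)
  for (k in 2:5) expect_identical(phs[, , k], phs[, , 1])

  sp <- phantom_spec(grid_size = 32, n_frames = 6)
  expect_identical(unclass(generate_phantom(sp)), unclass(generate_phantom(sp)))

  # support: zero outside the union of ellipses (corners are outside)
  ph <- generate_phantom(sp)
  expect_equal(max(abs(ph[1:3, 1:3, ])), 0)
})

test_that("region-mean enhancement matches the closed-form gamma-variate curve", {
  sp <- phantom_spec(grid_size = 64, n_frames = 12)
  ph <- generate_phantom(sp)
  co <- (seq_len(64) - 1 - 32) / 32
  X <- matrix(co, 64, 64); Y <- matrix(co, 64, 64, byrow = TRUE)
  # probe strictly inside the myocardium ellipse but outside the ventricle
  myo <- (X / 0.45)^2 + (Y / 0.55)^2 <= 0.9
  th <- 20 * pi / 180
  xr <- (X - 0.05) * cos(th) + Y * sin(th)
  yr <- -(X - 0.05) * sin(th) + Y * cos(th)
  lv_halo <- (xr / 0.2)^2 + (yr / 0.25)^2 <= 1.3
  probe <- myo & !lv_halo
  expect_gt(sum(probe), 100)
  expected <- 0.3 + 0.2 +
    enhancement_curve(default_bolus()$myo, attr(ph, "frame_times"))
  measured <- sapply(seq_len(12), function(t) mean(abs(ph[, , t])[probe]))
  expect_equal(measured, expected, tolerance = 1e-12)
})

test_that("total temporal variation of the phantom grows with the bolus amplitude", {
  energies <- sapply(c(0, 0.5, 1, 2), function(A) {
    bol <- default_bolus()
    bol$lv$A <- A; bol$myo$A <- A / 2
    ph <- generate_phantom(phantom_spec(grid_size = 32, n_frames = 8, bolus = bol))
    sum(abs(ph[, , -1] - ph[, , -8])^2)
  })
  expect_true(all(diff(energies) > 0))
})

test_that("phantom spec YAML round trip reproduces the phantom bit for bit", {
  sp <- phantom_spec(grid_size = 32, n_frames = 3, noise_sigma = 2.5, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, path)
  sp2 <- read_phantom_spec(path)
  expect_identical(unclass(generate_phantom(sp)), unclass(generate_phantom(sp2)))
})

test_that("combine_norm is the elementwise complex modulus", {
  z <- array(3 + 4i, c(2, 2, 2))
  expect_equal(combine_norm(dynamic_series(z))[1, 1, 1], 5)
  r <- array(c(-2, 1, 0, 3, -1, 2, 0, -4), c(2, 2, 2))
  expect_equal(unclass(combine_norm(dynamic_series(r))), abs(r),
               ignore_attr = TRUE)
  expect_equal(combine_norm(array(0 + 0i, c(2, 2, 1)))[1, 1, 1], 0)
})
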