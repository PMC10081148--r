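test_that("the regularised ramp transfer function has the stated values and limits", {
  expect_equal(filter_transfer(0, 0), 0)
  expect_equal(filter_transfer(0, 5), 0)
  expect_equal(filter_transfer(1, 0), 1)        # beta = 0: exact ramp
  expect_equal(filter_transfer(1, 1), 0.5)
  om <- seq(0, 10, by = 0.25)
  expect_identical(filter_transfer(om, 0), om)  # exact, not approximate
  expect_error(filter_transfer(1, -0.1), "beta")
  expect_error(filter_transfer(-1, 0), "omega")
})

test_that("line filtering is linear, zeroes DC, and reproduces the ramp pattern", {
  ones <- radialrecon:::new_radial_kspace(radial_sampling(3, 16),
                                          matrix(1 + 0i, 3, 16))
  zero <- radialrecon:::new_radial_kspace(radial_sampling(3, 16),
                                          matrix(0 + 0i, 3, 16))
  expect_equal(max(abs(filter_lines(zero, 1)$lines)), 0)
  f <- radialrecon:::freq_index(16)
  filt0 <- filter_lines(ones, 0)
  expect_equal(Re(filt0$lines[2, ]), abs(f))    # beta = 0: |f| pattern
  expect_equal(filt0$lines[1, which(f == 0)], 0 + 0i)
  filt2 <- filter_lines(ones, 2)
  expect_equal(filt2$lines[1, which(f == 0)], 0 + 0i)
  expect_equal(Re(filt2$lines[1, ]), abs(f) / (1 + 2 * abs(f) / 16))
})

test_that("backprojection is linear and exactly adjoint to the forward splatter", {
  set.seed(5)
  angs <- radial_sampling(7, 16)$angles_deg
  a <- matrix(rnorm(7 * 16), 7)
  b <- matrix(rnorm(7 * 16), 7)
  expect_equal(backproject(a + b, angs, 16),
               backproject(a, angs, 16) + backproject(b, angs, 16),
               tolerance = 1e-12)
  expect_equal(max(abs(backproject(matrix(0, 7, 16), angs, 16))), 0)
  # <P f, g> == <f, B g> with P = project_image, B = backproject, as
  # explicit matrices would have it
  for (rep in 1:5) {
    f <- matrix(rnorm(16 * 16), 16)
    g <- matrix(rnorm(7 * 16), 7)
    expect_equal(sum(project_image(f, angs, 16) * g),
                 sum(f * backproject(g, angs, 16)),
                 tolerance = 1e-10)
  }
  expect_error(backproject(a, angs[1:3], 16), "match")
})

test_that("FBP recovers a disk and reduces to magnitude recon for real objects", {
  expect_equal(max(fbp_reconstruct(radialrecon:::new_radial_kspace(
    radial_sampling(4, 32), matrix(0 + 0i, 4, 32)))), 0)

  disk <- hard_disk(128)
  fr <- simulate_acquisition(disk + 0i, radial_sampling(72, 128))
  rec <- fbp_reconstruct(fr)
  expect_true(all(rec >= 0))
  expect_lt(rmse(rec, disk), 0.1)  # normalised: disk amplitude is 1

  # real object: conjugate-symmetric lines make the filtered projections
  # real, so the imaginary channel contributes nothing
  filt <- filter_lines(fr, 0)
  proj <- t(apply(filt$lines, 1, function(z)
    radialrecon:::fftshift_vec(fft(radialrecon:::ifftshift_vec(z),
                                   inverse = TRUE)) / 128^2))
  expect_lt(max(abs(Im(proj))), 1e-9 * max(abs(Re(proj))))
})

test_that("version dispatch matches its definitions", {
  img <- abs(generate_phantom(phantom_spec(grid_size = 64, n_frames = 3))[, , 2])
  fr72 <- simulate_acquisition(img + 0i, radial_sampling(72, 64),
                               noise_sigma = 4, seed = 4)
  fr24 <- undersample(fr72, 3)
  expect_identical(run_version(fr24, version = "V2", beta = 0),
                   run_version(fr24, version = "V3"))
  expect_error(run_version(frame24 = fr24, version = "V4"), "frame72")
  expect_error(run_version(frame72 = fr72, version = "V1"), "frame24")
  gold <- run_version(frame72 = fr72, version = "V4")
  expect_identical(gold, fbp_reconstruct(fr72))
  # extension beats the raw sparse reconstruction, per-frame
  mfi <- median_filter_image
  expect_lt(rmse(mfi(run_version(fr24, version = "V1", beta = 0)), mfi(gold)),
            rmse(mfi(run_version(fr24, version = "V3")), mfi(gold)))
})

test_that("more views monotonically improve the noiseless reconstruction", {
  img <- abs(generate_phantom(phantom_spec(grid_size = 64, n_frames = 3))[, , 2])
  errs <- sapply(c(12, 24, 48, 72), function(nv)
    rmse(fbp_reconstruct(simulate_acquisition(img + 0i,
                                              radial_sampling(nv, 64))), img))
  expect_true(all(diff(errs) < 0))
})

test_that("reconstruction is approximately equivariant to a one-view rotation", {
  img <- soft_disk(64, r = 0.4) + 0.4 * rotate_image(soft_disk(64, r = 0.15), 0)
  img[20:30, 35:45] <- img[20:30, 35:45] + 0.5
  img <- img * (soft_disk(64, r = 0.8) > 0.5)
  delta <- 180 / 72
  rec1 <- fbp_reconstruct(simulate_acquisition(rotate_image(img, delta) + 0i,
                                               radial_sampling(72, 64)))
  rec2 <- rotate_image(fbp_reconstruct(simulate_acquisition(img + 0i,
                                                            radial_sampling(72, 64))),
                       delta)
  interior <- soft_disk(64, r = 0.75) > 0.5
  expect_lt(sqrt(mean((rec1 - rec2)[interior]^2)) / sqrt(mean(img^2)), 0.05)
})

test_that("stronger regularisation cannot increase flat-region noise", {
  img <- abs(generate_phantom(phantom_spec(grid_size = 64, n_frames = 3))[, , 2])
  fr24 <- undersample(simulate_acquisition(img + 0i, radial_sampling(72, 64),
                                           noise_sigma = 4, seed = 9), 3)
  co <- (seq_len(64) - 1 - 32) / 32
  X <- matrix(co, 64, 64); Y <- matrix(co, 64, 64, byrow = TRUE)
  flat <- X^2 + Y^2 < 0.3^2
  vars <- sapply(c(0, 1, 2), function(b) var(fbp_reconstruct(fr24, beta = b)[flat]))
  expect_true(all(diff(vars) <= 0))
})
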