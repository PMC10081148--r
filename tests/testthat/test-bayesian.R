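test_that("objective matches a direct loop-summation oracle", {
  set.seed(17)
  cfg <- bayes_config(alpha1 = 0.04, alpha2 = 0.006)
  for (rep in 1:3) {
    data <- random_kspace_frames(8, 3)
    m <- random_complex_array(c(8, 8, 3))
    o <- objective(m, data, cfg)
    expect_equal(o$total, objective_oracle(m, data, cfg), tolerance = 1e-12)
    expect_true(all(c(o$fidelity, o$temporal, o$tv) >= 0))
    expect_equal(o$total, o$fidelity + o$temporal + o$tv)
  }
  # all-zero series and data: only the epsilon floor of the TV term remains
  data0 <- random_kspace_frames(8, 3)
  for (t in 1:3) data0[[t]]$d[] <- 0 + 0i
  o0 <- objective(array(0 + 0i, c(8, 8, 3)), data0, cfg)
  expect_equal(o0$fidelity, 0)
  expect_equal(o0$temporal, 0)
  expect_equal(o0$tv, 0.006 * 3 * 64 * sqrt(cfg$epsilon))
})

test_that("gradient passes central-difference checks on random instances", {
  set.seed(23)
  cfg <- bayes_config()
  h <- 1e-5
  for (rep in 1:20) {
    data <- random_kspace_frames(8, 3)
    m <- random_complex_array(c(8, 8, 3))
    g <- gradient(m, data, cfg)
    dm <- random_complex_array(c(8, 8, 3))
    fd <- (objective(m + h * dm, data, cfg)$total -
             objective(m - h * dm, data, cfg)$total) / (2 * h)
    ip <- sum(Re(g) * Re(dm) + Im(g) * Im(dm))
    expect_equal(ip, fd, tolerance = 1e-4)
  }
})

test_that("gradient vanishes at the fully sampled consistent optimum", {
  set.seed(29)
  m <- random_complex_array(c(8, 8, 2))
  data <- lapply(1:2, function(t) {
    structure(list(d = radialrecon:::kspace_forward(m[, , t]),
                   W = matrix(1, 8, 8), N = 8L), class = "cartesian_kspace")
  })
  g <- gradient(m, data, bayes_config(alpha1 = 0, alpha2 = 0))
  expect_lt(max(abs(g)), 1e-9)
})

test_that("the fidelity gradient has no spatial coupling beyond the Fourier response", {
  set.seed(37)
  data <- random_kspace_frames(8, 1)
  cfg <- bayes_config(alpha1 = 0.04, alpha2 = 0)
  m1 <- random_complex_array(c(8, 8, 1))
  m2 <- m1; m2[3, 5, 1] <- m2[3, 5, 1] + (2 - 1i)
  dg <- gradient(m2, data, cfg) - gradient(m1, data, cfg)
  lin <- 2 * radialrecon:::kspace_inverse(
    data[[1]]$W * radialrecon:::kspace_forward(m2[, , 1] - m1[, , 1]))
  expect_equal(dg[, , 1], lin, tolerance = 1e-10)
})

test_that("backtracking descent is monotone on random sparse instances", {
  set.seed(41)
  for (rep in 1:3) {
    data <- random_kspace_frames(16, 3)
    rec <- reconstruct(data, bayes_config(n_iter = 120, backtracking = TRUE))
    tr <- attr(rec, "objective_trace")
    expect_equal(length(tr), 121L)
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("fully sampled consistent data with no regularisation recovers F^-1 d", {
  set.seed(43)
  m <- random_complex_array(c(16, 16, 2))
  data <- lapply(1:2, function(t) {
    structure(list(d = radialrecon:::kspace_forward(m[, , t]),
                   W = matrix(1, 16, 16), N = 16L), class = "cartesian_kspace")
  })
  rec <- reconstruct(data, bayes_config(alpha1 = 0, alpha2 = 0, n_iter = 100))
  expect_lt(max(abs(rec - m)) / max(abs(m)), 1e-6)
})

test_that("zero data reconstructs to zero and divergence raises a named error", {
  data <- random_kspace_frames(8, 2)
  for (t in 1:2) data[[t]]$d[] <- 0 + 0i
  rec <- reconstruct(data, bayes_config(n_iter = 150))
  expect_lt(max(abs(rec)), 1e-8)

  set.seed(47)
  bad <- random_kspace_frames(8, 2)
  expect_error(reconstruct(bad, bayes_config(n_iter = 50, step_size = 1e6,
                                             backtracking = FALSE)),
               "iteration")
})

test_that("the temporal constraint biases a step change, increasingly with alpha1", {
  st <- step_series()
  fr <- acquire_series(st$series, radial_sampling(72, 64), noise_sigma = 0)
  fr24 <- lapply(fr, undersample, keep_every = 3)
  grids <- lapply(fr24, grid_radial)
  truth_step <- st$step
  est_step <- sapply(c(0.004, 0.04), function(a1) {
    rec <- combine_norm(reconstruct(grids, bayes_config(alpha1 = a1,
                                                        n_iter = 600)))
    mean(rec[, , st$step_frame][st$region]) -
      mean(rec[, , st$step_frame - 1][st$region])
  })
  # both underestimate; the stronger temporal weight underestimates more
  expect_true(all(est_step < truth_step))
  expect_lt(est_step[2], est_step[1])
})

test_that("config validation rejects invalid parameters", {
  expect_error(bayes_config(alpha1 = -1), "alpha1")
  expect_error(bayes_config(epsilon = 0), "epsilon")
  expect_error(bayes_config(n_iter = 0), "n_iter")
  expect_error(bayes_config(step_size = -2), "step_size")
  expect_error(objective(random_complex_array(c(4, 4, 2)),
                         random_kspace_frames(8, 2), bayes_config()),
               "match")
})
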