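test_that("segment geometry implements the arc-length construction", {
  g <- segment_geometry(cbind(x = c(0, 3e-9), y = c(0, 4e-9)))
  expect_equal(g$ds, 5e-9)
  expect_equal(g$length, 5e-9)
  expect_equal(g$mid, 2.5e-9)
  straight <- cbind(x = seq(0, 9e-6, by = 1e-6), y = rep(0, 10))
  expect_equal(segment_geometry(straight)$length, 9e-6)
  # midpoints are strictly increasing and interior
  set.seed(5)
  for (i in 1:10) {
    sh <- cbind(x = cumsum(runif(12, 0.5, 1.5)),
                y = cumsum(rnorm(12, 0, 0.3)))
    g <- segment_geometry(sh)
    expect_true(!is.unsorted(g$mid, strictly = TRUE))
    expect_true(all(g$mid > 0 & g$mid < g$length))
    # contour length dominates the end-to-end distance
    expect_gte(g$length, sqrt(sum((sh[12, ] - sh[1, ])^2)))
  }
  expect_error(segment_geometry(cbind(x = 0, y = 0)), "2 points")
  expect_error(
    segment_geometry(cbind(x = c(0, 1, 1), y = c(0, 0, 0))),
    "segment 2")
})

test_that("mode decomposition is linear and bounded by the point count", {
  b <- mode_basis(20)
  flat <- cbind(x = seq(0, 10e-6, by = 100e-9), y = rep(0, 101))
  expect_equal(decompose_modes(flat, 6, b), rep(0, 6))
  cfg <- sim_config(length = 10e-6, spacing = 100e-9, seed = 1)
  sh <- synthesize_shape(c(2e-11, 1e-11, 6e-12, 4e-12, rep(0, 16)),
                         cfg, b)
  a1 <- decompose_modes(sh, 4, b)
  sh2 <- sh
  sh2[, "y"] <- 2 * sh2[, "y"]
  # linearity in y holds approximately (the arc geometry of the doubled
  # shape differs at second order only)
  expect_equal(decompose_modes(sh2, 4, b) / a1, rep(2, 4),
               tolerance = 1e-3)
  expect_error(decompose_modes(flat, 100, b), "N - 1")
})

test_that("decomposition round-trips synthesized single-mode shapes", {
  b <- mode_basis(20)
  cfg <- sim_config(length = 10e-6, spacing = 10e-9, seed = 1)
  A <- 3e-11
  sh <- synthesize_shape(c(A, rep(0, 19)), cfg, b)
  a <- decompose_modes(sh, 4, b)
  expect_equal(a[1], A, tolerance = 5e-3)
  expect_lt(abs(a[2] / A), 0.02)
  # halving the spacing shrinks the quadrature residual
  cfg2 <- sim_config(length = 10e-6, spacing = 5e-9, seed = 1)
  a2 <- decompose_modes(synthesize_shape(c(A, rep(0, 19)), cfg2, b), 4, b)
  expect_lt(abs(a2[1] - A), abs(a[1] - A) + 1e-18)
})

test_that("amplitude variances are computed across frames about the mean", {
  b <- mode_basis(20)
  ens <- tiny_ensemble(seed = 9, n_frames = 200)
  av <- amplitude_variances(ens, 4, b)
  expect_length(av$var, 4L)
  expect_true(all(av$var > 0))
  expect_equal(av$mean_length, 10e-6, tolerance = 1e-3)
  # identical frames give zero variance
  same <- shape_ensemble(rep(ens$frames[1], 12))
  expect_equal(amplitude_variances(same, 3, b)$var, rep(0, 3))
  # a static bend common to all frames leaves variances unchanged
  bend <- synthesize_shape(c(5e-11, rep(0, 19)),
                           sim_config(seed = 1), b)[, "y"]
  bent <- ens
  bent$frames <- lapply(ens$frames, function(f) {
    f[, 2] <- f[, 2] + bend
    f
  })
  av_b <- amplitude_variances(bent, 4, b)
  expect_equal(av_b$var, av$var, tolerance = 5e-3)
  expect_error(amplitude_variances(tiny_ensemble(n_frames = 9), 4, b),
               "at least 10 frames")
})

test_that("variance recovery stays inside the chi-square sampling band", {
  b <- mode_basis(20)
  cfg <- sim_config(length = 10e-6, kappa = 0.3e-23, n_frames = 500,
                    seed = 21)
  av <- amplitude_variances(simulate_ensemble(cfg, b), 4, b)
  v1 <- mode_variance(cfg$kappa, cfg$length, cfg$temperature, 1)
  band <- qchisq(c(0.005, 0.995), 499) / 499
  expect_gt(av$var[1] / v1, band[1])
  expect_lt(av$var[1] / v1, band[2])
})

test_that("the equipartition fit inverts exact mode variances", {
  b <- mode_basis(20)
  kap0 <- 0.7e-23
  v <- mode_variance(kap0, 10e-6, 298, 1:6, b)
  exact <- list(var = v, mean_length = 10e-6)
  for (m in c("log", "linear")) {
    f <- fit_rigidity(exact, n_max = 6, temperature = 298, basis = b,
                      method = m)
    expect_equal(f$kappa, kap0, tolerance = 1e-12)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
  }
  # n_max = 1 reduces to the single-mode equipartition formula
  f1 <- fit_rigidity(list(var = v[1], mean_length = 10e-6), n_max = 1,
                     temperature = 298, basis = b)
  expect_equal(f1$kappa, kB * 298 * (10e-6 / 1.875)^4 / v[1])
  expect_error(
    fit_rigidity(list(var = c(v[1], 0), mean_length = 10e-6), n_max = 2,
                 temperature = 298, basis = b),
    "degenerate")
})

test_that("rigidity is recovered from simulated ensembles without bias", {
  b <- mode_basis(20)
  errs <- vapply(1:10, function(s) {
    cfg <- sim_config(length = 10e-6, kappa = 0.3e-23, n_frames = 500,
                      seed = 500 + s)
    fit <- fit_rigidity(simulate_ensemble(cfg, b), n_max = 4, basis = b)
    relative_error(fit, 0.3e-23)
  }, numeric(1))
  expect_true(all(abs(errs) < 0.10))   # each run within 10%
  expect_lt(abs(mean(errs)), 0.03)     # seed-mean within 3%
})

test_that("a static bend shifts the rigidity estimate by under 1%", {
  b <- mode_basis(20)
  ens <- tiny_ensemble(seed = 31, n_frames = 300)
  f0 <- fit_rigidity(ens, basis = b)
  bend <- synthesize_shape(c(4e-11, 2e-11, rep(0, 18)),
                           sim_config(seed = 1), b)[, "y"]
  ens$frames <- lapply(ens$frames, function(f) {
    f[, 2] <- f[, 2] + bend
    f
  })
  f1 <- fit_rigidity(ens, basis = b)
  expect_lt(abs(f1$kappa / f0$kappa - 1), 0.01)
})

test_that("mode linearity survives fine precision and fails at coarse", {
  b <- mode_basis(20)
  r2 <- function(delta) {
    cfg <- sim_config(length = 10e-6, kappa = 0.3e-23, n_frames = 500,
                      precision = delta, seed = 77)
    fit_rigidity(simulate_ensemble(cfg, b), n_max = 8, basis = b,
                 method = "linear")$r_squared
  }
  expect_gt(r2(0), 0.99)
  expect_lt(r2(100e-9), 0.9)
})

test_that("relative error is the signed underestimation fraction", {
  expect_identical(relative_error(1, 1), 0)
  expect_equal(relative_error(0.95, 1), 0.05)
  expect_equal(relative_error(2, 1), -1)
  expect_error(relative_error(1, 0), "positive")
})

test_that("rigidity_fit methods expose the fit consistently", {
  f <- fit_rigidity(tiny_ensemble(seed = 2, n_frames = 120))
  expect_s3_class(f, "rigidity_fit")
  expect_named(coef(f), "kappa")
  expect_length(fitted(f), 4L)
  expect_equal(residuals(f), f$per_mode$L4_over_var - fitted(f))
  expect_output(print(f), "Flexural rigidity")
  expect_output(print(summary(f)), "Per-mode diagnostics")
  sims <- simulate(f, nsim = 2, seed = 4, n_frames = 20)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$config$kappa, unname(coef(f)))
})
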