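test_that("exponential correlation has its closed-form values and decays monotonically", {
  expect_identical(exp_correlation(0, 3.7), 1)
  expect_equal(exp_correlation(5, 5), exp(-1))
  expect_equal(exp_correlation(15, 5), exp(-3))
  for (phi in c(0.5, 2, 10)) {
    h <- seq(0, 40, by = 0.5)
    r <- exp_correlation(h, phi)
    expect_true(all(diff(r) < 0))
    expect_true(all(r > 0 & r <= 1))
  }
  expect_error(exp_correlation(-1, 2), "h")
  expect_error(exp_correlation(1, 0), "phi")
})

test_that("covariance matrix matches hand evaluation on collinear points", {
  p <- gp_params(beta = 0, sigma2 = 2.5, phi = 3, tau2_rel = 0.4)
  locs <- cbind(c(0, 3, 6), 0)  # spacing phi
  v <- covariance_matrix(locs, p)
  expect_equal(diag(v), rep(2.5 * 1.4, 3))
  expect_equal(v[1, 2], 2.5 * exp(-1))
  expect_equal(v[1, 3], 2.5 * exp(-2))
  expect_equal(v, t(v))
  v1 <- covariance_matrix(cbind(1, 1), p)
  expect_equal(dim(v1), c(1L, 1L))
  expect_equal(v1[1, 1], 2.5 * 1.4)
})

test_that("GRF simulation is reproducible and honors degenerate limits", {
  locs <- random_points(20, seed = 1)
  p <- gp_params(beta = 2, sigma2 = 1, phi = 4)
  f1 <- simulate_grf(locs, p, seed = 42)
  f2 <- simulate_grf(locs, p, seed = 42)
  expect_identical(f1$values, f2$values)
  expect_false(isTRUE(all.equal(f1$values, simulate_grf(locs, p, seed = 43)$values)))
  # near-zero variance pins the field to its mean
  f0 <- simulate_grf(cbind(3, 4), gp_params(beta = 5, sigma2 = 1e-12, phi = 2),
                     seed = 1)
  expect_equal(f0$values, 5, tolerance = 1e-5)
  # coincident locations without nugget share their value (jitter-limited)
  fc <- simulate_grf(rbind(c(1, 1), c(1, 1)), gp_params(0, 1, 3, 0), seed = 7)
  expect_equal(fc$values[1], fc$values[2], tolerance = 1e-3)
})

test_that("empirical variogram of the GRF approaches the sill at three correlation scales", {
  locs <- random_points(400, seed = 3)
  gams <- vapply(1:12, function(r) {
    f <- simulate_grf(locs, gp_params(0, 1, 5, 0), seed = 300 + r)
    semivariance_band(locs, f$values, 14, 16)
  }, 0)
  # true semivariance at h = 15 = 3*phi is 1 - exp(-3) ~ 0.95; field-level
  # replication dominates the Monte-Carlo error
  expect_equal(mean(gams), 1 - exp(-3), tolerance = 0.15)
})

test_that("posterior masses are normalized, scale-equivariant, and concentrate correctly", {
  locs <- random_points(60, seed = 5)
  f <- simulate_grf(locs, gp_params(beta = 3, sigma2 = 2, phi = 5, tau2_rel = 0.2),
                    seed = 11)
  grid <- parameter_grid(phi_support = c(1, 2.5, 5, 10, 20),
                         tau2rel_support = c(0, 0.2, 0.5))
  post <- log_marginal_posterior(f, grid)
  expect_equal(sum(post$mass), 1, tolerance = 1e-10)
  expect_true(all(post$mass >= 0))
  # doubling the data shifts beta and sigma^2 summaries but not the masses
  f2 <- spatial_field(f$locations, 2 * f$values)
  post2 <- log_marginal_posterior(f2, grid)
  expect_equal(post2$mass, post$mass, tolerance = 1e-9)
  expect_equal(post2$beta_hat, 2 * post$beta_hat, tolerance = 1e-9)
  expect_equal(post2$qhat, 4 * post$qhat, tolerance = 1e-9)
  # single grid point carries all mass
  p1 <- log_marginal_posterior(f, parameter_grid(5, 0.2))
  expect_equal(p1$mass, 1)
  expect_error(log_marginal_posterior(
    spatial_field(matrix(1, 4, 2), rnorm(4)), grid), "coincident")
})

test_that("posterior draws follow the table masses and are seed-stable", {
  locs <- random_points(40, seed = 6)
  f <- simulate_grf(locs, gp_params(0, 1, 4, 0.1), seed = 12)
  grid <- parameter_grid(phi_support = c(2, 4, 8), tau2rel_support = c(0, 0.2))
  post <- log_marginal_posterior(f, grid)
  d1 <- sample_posterior(post, 5000, seed = 9)
  d2 <- sample_posterior(post, 5000, seed = 9)
  expect_identical(d1, d2)
  freq <- tabulate(d1$grid_index, nbins = nrow(post)) / nrow(d1)
  se <- sqrt(post$mass * (1 - post$mass) / nrow(d1))
  expect_true(all(abs(freq - post$mass) <= 3 * se + 1e-12))
  # degenerate table: all draws share the single grid point
  p1 <- log_marginal_posterior(f, parameter_grid(4, 0.1))
  dd <- sample_posterior(p1, 50, seed = 2)
  expect_true(all(dd$phi == 4 & dd$tau2_rel == 0.1))
  expect_error(sample_posterior(post, 0), "n_draws")
})

test_that("kriging interpolates exactly without a nugget and relaxes to the trend far away", {
  locs <- random_points(30, width = 10, height = 10, seed = 8)
  f <- simulate_grf(locs, gp_params(beta = 4, sigma2 = 1, phi = 2), seed = 13)
  grid <- parameter_grid(phi_support = c(1, 2, 4), tau2rel_support = 0)
  post <- log_marginal_posterior(f, grid)
  draws <- sample_posterior(post, 500, seed = 3)
  at_data <- krige_predict(f, draws, f$locations[1:5, , drop = FALSE])
  expect_equal(at_data$pred_mean, f$values[1:5], tolerance = 1e-6)
  expect_true(all(at_data$pred_var <= 1e-6))
  # far beyond the effective range the prediction reverts to the trend
  far <- krige_predict(f, draws, cbind(1000, 1000))
  expect_equal(far$pred_mean, mean(draws$beta), tolerance = 1e-6)
  expect_equal(far$pred_var,
               mean(draws$sigma2) + var(draws$beta) * (nrow(draws) - 1) / nrow(draws),
               tolerance = 1e-6)
  # a single draw reduces to plug-in kriging
  one <- draws[1, ]
  v <- exp(-as.matrix(dist(f$locations)) / one$phi)
  r0 <- exp(-meadowpath:::cross_dist(cbind(5, 5), f$locations) / one$phi)
  w <- drop(r0 %*% solve(v, f$values - one$beta))
  plug <- krige_predict(f, one, cbind(5, 5))
  expect_equal(plug$pred_mean, one$beta + w, tolerance = 1e-8)
})

test_that("leave-one-out downdating reproduces explicit per-fold refits", {
  locs <- random_points(12, seed = 10)
  f <- simulate_grf(locs, gp_params(beta = 1, sigma2 = 1, phi = 4, tau2_rel = 0.3),
                    seed = 21)
  grid <- parameter_grid(phi_support = c(2, 4, 8), tau2rel_support = c(0, 0.3))
  fast <- loo_validate(f, grid)
  n <- length(f$values)
  for (i in c(1, 5, 12)) {
    sub <- spatial_field(f$locations[-i, , drop = FALSE], f$values[-i])
    post <- log_marginal_posterior(sub, grid)
    # mixture predictive at the held-out point, by direct conditioning
    mix_m <- 0; mix_v <- 0
    for (k in seq_len(nrow(post))) {
      v <- exp(-meadowpath:::cross_dist(sub$locations, sub$locations) / post$phi[k])
      diag(v) <- 1 + post$tau2_rel[k]
      r0 <- drop(exp(-meadowpath:::cross_dist(f$locations[i, , drop = FALSE],
                                              sub$locations) / post$phi[k]))
      vi <- solve(v)
      w1 <- sum(vi %*% rep(1, n - 1) * r0)
      m <- post$beta_hat[k] + drop(r0 %*% vi %*% (sub$values - post$beta_hat[k]))
      s2 <- post$qhat[k] / max(n - 1 - 3, 1)
      vv <- s2 * (1 + post$tau2_rel[k] - drop(r0 %*% vi %*% r0) +
                    (1 - w1)^2 / post$s11[k])
      mix_m <- mix_m + post$mass[k] * m
      mix_v <- mix_v + post$mass[k] * (vv + m^2)
    }
    mix_v <- mix_v - mix_m^2
    expect_equal(fast$pred_mean[i], mix_m, tolerance = 1e-8)
    expect_equal(fast$pred_var[i], mix_v, tolerance = 1e-8)
  }
})

test_that("leave-one-out on a constant field returns the constant", {
  locs <- random_points(10, seed = 14)
  f <- spatial_field(locs, rep(7, 10))
  lo <- loo_validate(f, parameter_grid(c(2, 5), c(0.1, 0.5)))
  expect_equal(lo$pred_mean, rep(7, 10), tolerance = 1e-6)
})
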