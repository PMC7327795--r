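# Baseline independent localization: integrated likelihood and MCMC
# posterior against dense-grid Bayes-rule oracles.

test_that("integrated likelihood matches a radial quadrature oracle", {
  rec <- toy_receivers(cbind(0, 0))
  dp <- det_params(p0 = 0.6, sigma_det = 0.5)
  sp <- state_space(rec, 10)
  # one receiver, y = (1): integrand is the half-normal ring density, so
  # the integral over a large region is p0 * 2 * pi * sigma^2
  ll <- independent_loglik(dp, rbind(1L), rec, sp, grid_n = 400)
  expect_equal(ll, log(0.6 * 2 * pi * 0.25 / 400), tolerance = 1e-3)
  # permutation symmetry: relabeling receivers leaves the likelihood alone
  rec4 <- toy_receivers(cbind(c(0, 2, 1, 3), c(0, 1, 2, 0)))
  dp2 <- bench_det()
  y <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 0L))
  perm <- c(3, 1, 4, 2)
  sp4 <- state_space(rec4, 3)
  expect_equal(
    independent_loglik(dp2, y, rec4, sp4, grid_n = 120),
    independent_loglik(dp2, y[, perm, drop = FALSE],
                       toy_receivers(cbind(rec4$x, rec4$y)[perm, ]),
                       sp4, grid_n = 120))
  expect_error(independent_loglik(dp2, rbind(c(0L, 0L, 0L, 0L)), rec4, sp4),
               "detected occasions")
})

test_that("posterior localization matches the Bayes-rule grid oracle", {
  o <- oracle_independent_check()
  expect_equal(o$mcmc_mean, o$oracle_mean, tolerance = 0.06)
  expect_equal(o$mcmc_sd, o$oracle_sd, tolerance = 0.06)
  # draws never leave the state space (uniform prior support)
  expect_true(all(o$draws[, 1] >= o$space$xmin & o$draws[, 1] <= o$space$xmax))
  expect_true(all(o$draws[, 2] >= o$space$ymin & o$draws[, 2] <= o$space$ymax))
})

test_that("a symmetric single-detection posterior centres on the receiver", {
  rec <- toy_receivers(cbind(c(0, -1.5, 1.5, 0, 0), c(0, 0, 0, -1.5, 1.5)))
  dp <- det_params(p0 = 0.6, sigma_det = 0.6)
  sp <- state_space(rec, 2.5)
  det_tbl <- detections_from_Y(rbind(c(1L, 0L, 0L, 0L, 0L)), 0, rec)
  fit <- fit_independent(det_tbl, rec, space = sp,
                         settings = mcmc_settings(2, 5000, 1000, 2, seed = 2),
                         fix_params = list(p0 = 0.6, sigma_det = 0.6))
  m <- colMeans(fit$tags[[1]]$traj[, 1, ])
  expect_equal(m, c(0, 0), tolerance = 0.05)
})
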