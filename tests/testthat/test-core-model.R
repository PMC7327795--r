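# Probability kernels: detection functions, movement density, encounter
# likelihood.

test_that("detection_prob matches closed forms and limits", {
  hn <- bench_det()
  expect_equal(detection_prob(0, hn), 0.562, tolerance = 1e-3)
  expect_equal(detection_prob(0.75, hn), plogis(0.25) * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(detection_prob(1e6, hn), 0)

  lg <- det_params(family = "logistic", alpha0 = 2, alpha1 = -1.5)
  expect_equal(detection_prob(0, lg), plogis(2))
  expect_equal(detection_prob(1e6, lg), 0)

  hz <- det_params(p0 = 1, sigma_det = 1, family = "hazard", theta = 2)
  expect_equal(detection_prob(0, hz), 1)  # continuity limit at the receiver
  expect_equal(detection_prob(1e6, hz), 0)

  # in [0,1] and non-increasing for all families
  d <- seq(0, 10, by = 0.05)
  for (p in list(hn, lg, hz)) {
    v <- detection_prob(d, p)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_error(detection_prob(-0.1, hn), "non-negative")
  expect_error(det_params(p0 = 1.3, sigma_det = 1), "p0")
  expect_error(det_params(p0 = 0.5, sigma_det = -1), "sigma_det")
})

test_that("movement log-density is a symmetric Gaussian kernel in sqrt-time", {
  expect_equal(movement_logdensity(c(1, 2), c(1, 2), 0.25, 1),
               2 * (-0.5 * log(2 * pi * 0.0625)), tolerance = 1e-12)
  u1 <- c(0.3, -1.2); u2 <- c(1.1, 0.4)
  expect_equal(movement_logdensity(u1, u2, 0.4, 2.5),
               movement_logdensity(u2, u1, 0.4, 2.5))
  # variance linear in delta: quadrupling delta doubles the per-axis sd
  expect_equal(movement_logdensity(c(1, 0), c(0, 0), 0.25, 4),
               dnorm(1, 0, 0.5, log = TRUE) + dnorm(0, 0, 0.5, log = TRUE))
  expect_error(movement_logdensity(u1, u2, 0.25, 0), "delta")

  # integrates to 1 over the plane (quadrature on a grid)
  g <- seq(-2, 2, length.out = 401)
  gr <- expand.grid(x = g, y = g)
  ld <- movement_logdensity(as.matrix(gr), c(0, 0), 0.3, 1)
  expect_equal(sum(exp(ld)) * diff(g)[1]^2, 1, tolerance = 1e-3)
})

test_that("encounter log-likelihood equals the Bernoulli product oracle", {
  set.seed(42)
  rec <- toy_receivers(cbind(runif(7, 0, 4), runif(7, 0, 4)))
  dp <- bench_det()
  for (rep in 1:20) {
    u <- runif(2, -1, 5)
    y <- rbinom(7, 1, 0.4)
    d <- sqrt((u[1] - rec$x)^2 + (u[2] - rec$y)^2)
    p <- detection_prob(d, dp)
    oracle <- sum(dbinom(y, 1, p, log = TRUE))
    expect_equal(encounter_loglik(y, u, rec, dp), oracle, tolerance = 1e-9)
  }
  # single receiver, detection at the receiver -> log(p0)
  one <- toy_receivers(cbind(0, 0))
  expect_equal(encounter_loglik(1, c(0, 0), one, dp), log(dp$p0))
  # all-zero far from every receiver -> likelihood ~ 1
  expect_equal(encounter_loglik(rep(0, 7), c(1e4, 1e4), rec, dp), 0,
               tolerance = 1e-6)
  # all-zero log-likelihood increases toward 0 with distance from the array
  lls <- sapply(c(2, 4, 8, 16), function(s)
    encounter_loglik(rep(0, 7), c(s, s), rec, dp))
  expect_true(all(diff(lls) >= 0))
  expect_error(encounter_loglik(c(1, 0), c(0, 0), rec, dp), "per receiver")
})

test_that("location full conditional is the sum of its three kernels", {
  set.seed(7)
  rec <- toy_receivers(cbind(0:2, c(0, 1, 0)))
  dp <- bench_det()
  for (rep in 1:10) {
    u <- runif(2, -1, 3); up <- runif(2, -1, 3); un <- runif(2, -1, 3)
    y <- rbinom(3, 1, 0.5)
    full <- location_conditional_logdensity(u, y, rec, dp, 0.3,
                                            u_prev = up, delta_prev = 1.2,
                                            u_next = un, delta_next = 0.7)
    oracle <- encounter_loglik(y, u, rec, dp) +
      movement_logdensity(u, up, 0.3, 1.2) +
      movement_logdensity(un, u, 0.3, 0.7)
    expect_equal(full, oracle, tolerance = 1e-12)
  }
  # no neighbours: reduces to the encounter term
  y <- c(1, 0, 0)
  expect_equal(location_conditional_logdensity(c(0, 0), y, rec, dp, 0.3),
               encounter_loglik(y, c(0, 0), rec, dp))
})
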