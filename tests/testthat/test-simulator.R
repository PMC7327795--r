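# Synthetic-data generator: array geometry, schedules, trajectories,
# encounter histories.

test_that("grid arrays have the stated geometry", {
  g <- make_grid_array(10, 10, 1)
  expect_equal(nrow(g), 100)
  expect_equal(range(g$x), c(0, 9))
  expect_equal(range(g$y), c(0, 9))
  expect_equal(nrow(make_grid_array(1, 1, 2)), 1)
  g2 <- make_grid_array(2, 3, 0.5)
  expect_equal(nrow(g2), 6)
  d <- as.matrix(dist(cbind(g2$x, g2$y)))
  expect_equal(min(d[d > 0]), 0.5)
  expect_error(make_grid_array(0, 3, 1), "dimensions")
})

test_that("schedules respect the interval bounds and renewal rate", {
  set.seed(11)
  # degenerate uniform: exactly unit spacing
  s <- simulate_schedule(1, 1, 10)
  expect_equal(diff(s), rep(1, length(s) - 1))
  # intervals in [a, b], times within [0, duration]
  lens <- replicate(300, {
    s <- simulate_schedule(1, 2, 150)
    expect_true(all(diff(s) >= 1 & diff(s) <= 2))
    expect_true(all(s >= 0 & s <= 150))
    length(s)
  })
  # renewal theory: ~ duration / E[interval] = 100 signals per tag
  expect_equal(mean(lens), 100, tolerance = 0.03)
  ints <- diff(simulate_schedule(1, 2, 5000))
  expect_equal(mean(ints), 1.5, tolerance = 0.02)
  expect_error(simulate_schedule(0, 1, 10), "a <= b")
})

test_that("trajectories are Brownian with variance sigma_u^2 * delta", {
  set.seed(12)
  expect_equal(simulate_trajectory(c(2, 3), 0, rep(1, 5)),
               cbind(x = rep(2, 6), y = rep(3, 6)))
  deltas <- runif(4000, 0.5, 3)
  tr <- simulate_trajectory(c(0, 0), 0.25, deltas)
  z <- diff(tr) / sqrt(deltas)  # scaled increments recover sigma_u
  expect_equal(sd(c(z)), 0.25, tolerance = 0.03)
  # independent-increment additivity of total displacement variance
  tot <- replicate(2000, {
    tr <- simulate_trajectory(c(0, 0), 0.25, rep(1.5, 10))
    tr[11, 1]
  })
  expect_equal(var(tot), 0.25^2 * 15, tolerance = 0.1)
})

test_that("initial positions are uniform on the buffered box", {
  set.seed(13)
  rec <- make_grid_array(10, 10, 1)
  u <- simulate_initial_positions(rec, 0.75, 5, 4000)
  expect_true(all(u >= -3.75 & u <= 12.75))
  expect_gt(max(u), 12)   # actually reaches the buffered margin
  expect_lt(min(u), -3)
  # chi-square uniformity over the four quadrants of the box
  qx <- u[, 1] > 4.5; qy <- u[, 2] > 4.5
  tab <- table(qx, qy)
  expect_gt(chisq.test(tab)$p.value, 1e-4)
  u0 <- simulate_initial_positions(rec, 0.75, 0, 100)
  expect_true(all(u0 >= 0 & u0 <= 9))
})

test_that("detection frequencies match the detection function", {
  set.seed(14)
  rec <- make_grid_array(10, 10, 1)
  expect_true(all(simulate_detections(rbind(c(4.5, 4.5)), rec,
    det_params(p0 = 1e-12, sigma_det = 0.75)) == 0))
  u <- rbind(c(4.5, 4.5))
  dp <- bench_det()
  Y <- do.call(rbind, replicate(3000, simulate_detections(u, rec, dp),
                                simplify = FALSE))
  d <- sqrt((4.5 - rec$x)^2 + (4.5 - rec$y)^2)
  p <- detection_prob(d, dp)
  keep <- p > 0.01
  freq <- colMeans(Y)[keep]
  expect_true(all(abs(freq - p[keep]) <
                    4 * sqrt(p[keep] * (1 - p[keep]) / 3000) + 1e-3))
  # interior point: almost always detected somewhere
  expect_gt(mean(rowSums(matrix(Y, ncol = nrow(rec))) > 0), 0.85)
})

test_that("simulate_dataset is reproducible and internally consistent", {
  cfg <- sim_config(n_individuals = 4, duration = 40, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$detections, s2$detections)
  # schedule/trajectory/encounter alignment and interval bounds
  for (tg in split(s1$truth, s1$truth$tag_id)) {
    expect_true(all(diff(tg$time) >= 1 & diff(tg$time) <= 2))
    expect_false(any(is.na(tg$x)))
  }
  # detections reference true signal times
  expect_true(all(s1$detections$time %in% s1$truth$time))
  # benchmark design: ~ duration/1.5 signals per tag
  expect_equal(nrow(s1$truth) / 4, 40 / 1.5, tolerance = 0.2)
})
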