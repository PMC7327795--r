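# Movement-assisted sampler against the dense-grid two-node smoother, plus
# qualitative information-flow properties.

test_that("two-signal trajectory posterior matches the grid smoother", {
  o <- oracle_hmm_check()
  expect_equal(o$mcmc1$mean, o$oracle1$mean, tolerance = 0.07)
  expect_equal(o$mcmc2$mean, o$oracle2$mean, tolerance = 0.07)
  expect_equal(o$mcmc1$sd, o$oracle1$sd, tolerance = 0.07)
  expect_equal(o$mcmc2$sd, o$oracle2$sd, tolerance = 0.07)
})

test_that("zero-detection locations are less precise than detected ones", {
  # one tag, known schedule 0/1/2, detected only at the ends
  rec <- make_grid_array(5, 5, 1)
  dp <- det_params(p0 = 0.7, sigma_det = 0.7)
  y1 <- as.integer(rec$x == 1 & rec$y == 2)
  y3 <- as.integer(rec$x == 3 & rec$y == 2)
  det_tbl <- detections_from_Y(rbind(y1, y3), c(0, 2), rec)
  sched <- tibble::tibble(tag_id = "tagA", time = c(0, 1, 2))
  fit <- fit_movement(det_tbl, rec, "known_interval", schedule = sched,
                      settings = mcmc_settings(2, 5000, 1000, 2, seed = 9),
                      space = state_space(rec, 3),
                      fix_params = list(p0 = 0.7, sigma_det = 0.7,
                                        sigma_u = 0.4))
  sds <- apply(fit$tags[[1]]$traj, 2, function(m) mean(apply(m, 2, sd)))
  expect_gt(sds[2], sds[1])   # middle (all-zero) wider than ends (detected)
  expect_gt(sds[2], sds[3])
})

test_that("a diffuse movement prior recovers independent localization", {
  # two detections far apart in time: with sigma_u large the movement link
  # is uninformative and each marginal matches the single-occasion
  # Bayes-rule posterior
  o <- oracle_independent_check()
  rec <- toy_receivers(cbind(c(0, 1), c(0, 0)))
  y <- c(1L, 0L)
  det_tbl <- dplyr::bind_rows(
    detections_from_Y(rbind(y), 0, rec),
    detections_from_Y(rbind(y), 1000, rec))
  fit <- fit_movement(det_tbl, rec, "detection_only",
                      settings = mcmc_settings(2, 8000, 1500, 2, seed = 3),
                      space = o$space,
                      fix_params = list(p0 = 0.7, sigma_det = 0.6,
                                        sigma_u = 2))
  # compare the first signal's marginal against the independent oracle;
  # the flat-prior sampler roams the whole plane, so clip to the oracle's
  # support before comparing moments
  dr <- fit$tags[[1]]$traj[, 1, ]
  keep <- dr[, 1] >= o$space$xmin & dr[, 1] <= o$space$xmax &
          dr[, 2] >= o$space$ymin & dr[, 2] <= o$space$ymax
  expect_gt(mean(keep), 0.9)
  expect_equal(colMeans(dr[keep, ]), o$oracle_mean, tolerance = 0.12)
})

test_that("detection-only input rules are enforced", {
  rec <- make_grid_array(3, 3, 1)
  # a tag with a single detected occasion carries no movement information
  d1 <- tibble::tibble(tag_id = c("a", "a", "b"),
                       receiver_id = c("r1", "r2", "r5"),
                       time = c(0, 2, 1))
  expect_warning(
    fit_movement(d1, rec, "detection_only",
                 settings = mcmc_settings(1, 200, 50, 1, seed = 1)),
    "< 2 detected")
  expect_error(
    fit_movement(d1, rec, "known_interval",
                 settings = mcmc_settings(1, 200, 50, 1, seed = 1)),
    "schedule")
})
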