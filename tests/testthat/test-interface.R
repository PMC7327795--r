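# Tidy accessors on fitted objects.

test_that("tidy, glance, localize and draw accessors are consistent", {
  rec <- toy_receivers(cbind(c(0, 1, 0), c(0, 0, 1)))
  det_tbl <- tibble::tibble(tag_id = "a", receiver_id = c("r1", "r3"),
                            time = c(0, 1.4))
  fit <- fit_movement(det_tbl, rec, "detection_only",
                      settings = mcmc_settings(2, 1200, 400, 2, seed = 44),
                      space = state_space(rec, 2))
  td <- tidy(fit)
  expect_equal(td$term, c("p0", "sigma_det", "sigma_u"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_signals, 2L)
  expect_equal(gl$n_draws, 2 * 400L)
  loc <- localize(fit)
  expect_equal(nrow(loc), 2)
  expect_equal(loc$detections, c(1, 1))
  dr <- trajectory_draws(fit, max_draws = 50)
  expect_equal(nrow(dr), 2 * 50)
  expect_true(all(is.finite(dr$x)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
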