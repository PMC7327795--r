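# Evaluation metrics: bias, RMSE, precision, HPD coverage, stratification.

test_that("relative bias is (mean - truth) / truth", {
  expect_equal(relative_bias(c(0.75, 0.75), 0.75), 0)
  expect_equal(relative_bias(0.79, 0.75), 0.0533, tolerance = 1e-3)
  expect_equal(relative_bias(0.65, 0.562), 0.157, tolerance = 1e-2)
  expect_error(relative_bias(1, 0), "non-zero")
})

test_that("RMSE and precision follow their definitions", {
  expect_equal(localization_rmse(rbind(c(1, 2)), rbind(c(1, 2))), 0)
  expect_equal(localization_rmse(rbind(c(0.3, 0.4)), rbind(c(0, 0))), 0.5)
  expect_error(localization_rmse(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0))),
               "align")
  th <- seq(0, 2 * pi, length.out = 100)
  expect_equal(posterior_precision(cbind(cos(th), sin(th)), c(0, 0)), 1)
  expect_equal(posterior_precision(rbind(c(2, 3)), c(2, 3)), 0)
  expect_error(posterior_precision(matrix(0, 0, 2), c(0, 0)), "draws")
})

test_that("detection-count strata follow the tabulation rule", {
  Y <- rbind(rep(0, 10), c(rep(1, 3), rep(0, 7)), rep(1, 10))
  expect_equal(stratify_by_detection_count(Y), c(0L, 3L, NA))
})

test_that("HPD coverage behaves on stylized draw clouds", {
  set.seed(123)
  draws <- cbind(rnorm(500), rnorm(500))
  # truth at the posterior mode of a unimodal cloud is always covered
  expect_equal(hpd_coverage(list(draws), rbind(c(0, 0))), 1)
  # level 1 covers anything inside the draw cloud's support
  expect_equal(hpd_coverage(list(draws), rbind(c(1.5, -0.5)), level = 1), 1)
  # degenerate cloud falls back to exact matching
  expect_warning(
    cov0 <- hpd_coverage(list(cbind(rep(1, 50), rep(2, 50))), rbind(c(1, 2))),
    "degenerate")
  expect_equal(cov0, 1)
})

test_that("HPD coverage is calibrated on Gaussian self-consistency", {
  set.seed(321)
  n_rep <- 250
  draws_list <- replicate(n_rep, cbind(rnorm(400), rnorm(400)),
                          simplify = FALSE)
  truths <- cbind(rnorm(n_rep), rnorm(n_rep))
  cov <- hpd_coverage(draws_list, truths, level = 0.95)
  expect_equal(cov, 0.95, tolerance = 0.05)
  cov80 <- hpd_coverage(draws_list, truths, level = 0.80)
  expect_equal(cov80, 0.80, tolerance = 0.07)
})
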