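# Missed-signal bounds and the signal-rate (gap) likelihood.

test_that("missed_signal_bounds enumerates exactly the feasible tilings", {
  # a gap that is itself one valid interval holds no missed signal
  expect_equal(missed_signal_bounds(1.5, 1, 2), 0L)
  expect_equal(missed_signal_bounds(3, 1, 2), c(1L, 2L))
  # transmitter example: 600 s gap, intervals in [90, 150] s
  expect_equal(missed_signal_bounds(600, 90, 150), 3:5)
  expect_equal(missed_signal_bounds(600, 90, 150, convention = "n"), 4:6)
  # exhaustive-enumeration identity: n admissible iff k = n + 1 intervals
  # in [a, b] can sum to delta
  for (delta in c(0.7, 1, 2.3, 3.8, 7.1)) {
    ks <- Filter(function(k) k * 1 <= delta + 1e-9 && delta <= k * 2 + 1e-9,
                 1:20)
    expect_equal(missed_signal_bounds(delta, 1, 2),
                 as.integer(unlist(ks) - 1), info = paste("delta =", delta))
  }
  # a gap shorter than the minimum interval admits nothing
  expect_length(missed_signal_bounds(0.5, 1, 2), 0)
  # degenerate schedule: only exact multiples tile
  expect_equal(missed_signal_bounds(4, 2, 2), 1L)
  expect_length(missed_signal_bounds(5, 2, 2), 0)
  expect_error(missed_signal_bounds(-1, 1, 2), "positive")
})

test_that("gap likelihood is the normal approximation to a sum of uniforms", {
  expect_equal(gap_loglik(3, 1, 1, 2), -0.5 * log(2 * pi / 6),
               tolerance = 1e-12)
  # maximized over delta at k (a + b) / 2
  k <- 3; a <- 1; b <- 2
  dd <- seq(3, 6, by = 0.01)
  ll <- vapply(dd, function(d) {
    adm <- missed_signal_bounds(d, a, b)
    if (!(k - 1) %in% adm) return(-Inf)
    gap_loglik(d, k - 1, a, b)
  }, numeric(1))
  expect_equal(dd[which.max(ll)], k * (a + b) / 2, tolerance = 0.02)
  # mean and variance scale linearly in the interval count
  for (n in 1:4) {
    k <- n + 1
    expect_equal(gap_loglik(k * 1.5, n, 1, 2),
                 dnorm(k * 1.5, k * 1.5, sqrt(k / 12), log = TRUE))
  }
  expect_error(gap_loglik(3, 5, 1, 2), "admissible")
})
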