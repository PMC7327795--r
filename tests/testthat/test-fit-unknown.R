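# Trans-dimensional missed-signal sampler: exhaustive-enumeration oracle,
# bound invariants, interior/exterior behaviour, degenerate-schedule
# collapse.

test_that("gap count posterior matches exhaustive enumeration", {
  o <- oracle_gap_check()
  # admissible set of a 3.6-unit gap with intervals in [1, 2]
  expect_equal(o$bounds$n_min, 1)
  expect_equal(o$bounds$n_max, 2)
  expect_true(all(o$n_draws %in% 1:2))
  expect_equal(o$mcmc_p1, o$oracle_p1, tolerance = 0.04)
})

test_that("a singleton admissible set pins the count", {
  rec <- toy_receivers(cbind(c(0, 1), c(0, 0)))
  det_tbl <- tibble::tibble(tag_id = "tagA", receiver_id = c("r1", "r2"),
                            time = c(0, 2.6))  # only n = 1 tiles [1,2]
  fit <- fit_unknown_interval(det_tbl, rec, a = 1, b = 2,
                              settings = mcmc_settings(1, 600, 100, 1,
                                                       seed = 5),
                              space = state_space(rec, 2),
                              fix_params = list(p0 = 0.6, sigma_det = 0.6,
                                                sigma_u = 0.3))
  expect_true(all(fit$tags[[1]]$n_draws == 1))
})

test_that("interior gaps favour fewer missed signals than exterior gaps", {
  rec <- make_grid_array(10, 10, 1)
  st <- mcmc_settings(2, 3000, 600, 2, seed = 6)
  fx <- list(p0 = plogis(0.25), sigma_det = 0.75, sigma_u = 0.3)
  gap_fit <- function(p1, r1, p2, r2) {
    det_tbl <- tibble::tibble(tag_id = "tagA", receiver_id = c(r1, r2),
                              time = c(0, 5.3))  # n admissible: 2..4
    fit_unknown_interval(det_tbl, rec, a = 1, b = 2, settings = st,
                         space = state_space(rec, 3.75), fix_params = fx)
  }
  # same gap geometry at the array centre vs hugging the outer edge
  interior <- gap_fit(NULL, "r45", NULL, "r56")  # (4,4) -> (5,5)
  exterior <- gap_fit(NULL, "r10", NULL, "r20")  # (9,0) -> (9,1), edge column
  expect_true(all(interior$tags[[1]]$n_draws %in% 2:4))
  expect_lt(mean(interior$tags[[1]]$n_draws),
            mean(exterior$tags[[1]]$n_draws))
})

test_that("a degenerate schedule collapses to the known-interval model", {
  o <- collapse_check()
  # same parameter posteriors within Monte Carlo error
  expect_equal(o$ui[["p0"]], o$ki[["p0"]], tolerance = 0.05)
  expect_equal(o$ui[["sigma_det"]], o$ki[["sigma_det"]], tolerance = 0.05)
  expect_equal(o$ui[["sigma_u"]], o$ki[["sigma_u"]], tolerance = 0.05)
  # with a = b the count per gap is known exactly, so estimated missed
  # totals equal the truth
  expect_equal(o$missed$est_missed, o$missed$true_missed, tolerance = 1e-8)
})

test_that("unusable gaps are refused with guidance", {
  rec <- toy_receivers(cbind(c(0, 1), c(0, 0)))
  det_tbl <- tibble::tibble(tag_id = "tagA", receiver_id = c("r1", "r2"),
                            time = c(0, 400))
  expect_error(
    fit_unknown_interval(det_tbl, rec, a = 1, b = 2,
                         settings = mcmc_settings(1, 200, 50, 1, seed = 1)),
    "cap")
})
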