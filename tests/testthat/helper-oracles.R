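# Independent oracles for the samplers, computed by dense-grid enumeration
# and cached so that module tests and the acceptance property suite share
# one computation.

.oracle_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.oracle_cache[[key]])) .oracle_cache[[key]] <- fn()
  .oracle_cache[[key]]
}

# --- Bayes-rule localization on a 2-receiver toy --------------------------
# Posterior of a single signal location under a uniform prior (dense grid)
# vs the Metropolis sampler with detection parameters fixed.
oracle_independent_check <- function() memo("ind", function() {
  rec <- toy_receivers(cbind(c(0, 1), c(0, 0)))
  dp <- det_params(p0 = 0.7, sigma_det = 0.6)
  y <- c(1L, 0L)
  sp <- state_space(rec, 3)
  # grid oracle for Pr(u | y) (Bayes' rule, uniform prior)
  g <- seq(sp$xmin, sp$xmax, length.out = 220)
  gr <- expand.grid(x = g, y = seq(sp$ymin, sp$ymax, length.out = 220))
  ll <- vapply(seq_len(nrow(gr)), function(i)
    encounter_loglik(y, c(gr$x[i], gr$y[i]), rec, dp), numeric(1))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  oracle_mean <- c(sum(w * gr$x), sum(w * gr$y))
  oracle_sd <- c(sqrt(sum(w * gr$x^2) - oracle_mean[1]^2),
                 sqrt(sum(w * gr$y^2) - oracle_mean[2]^2))
  det_tbl <- detections_from_Y(rbind(y), 0, rec)
  fit <- fit_independent(det_tbl, rec, space = sp,
                         settings = mcmc_settings(2, 6000, 1000, 2, seed = 4),
                         fix_params = list(p0 = 0.7, sigma_det = 0.6))
  draws <- fit$tags[[1]]$traj[, 1, ]
  list(oracle_mean = oracle_mean, oracle_sd = oracle_sd,
       mcmc_mean = colMeans(draws), mcmc_sd = apply(draws, 2, sd),
       draws = draws, space = sp)
})

# --- Two-node hidden-Markov smoother ---------------------------------------
# Dense-grid forward-backward posterior of a 2-signal trajectory vs the
# movement-assisted sampler with all parameters fixed.
oracle_hmm_check <- function() memo("hmm", function() {
  rec <- toy_receivers(cbind(rep(0:2, 3), rep(0:2, each = 3)))
  dp <- det_params(p0 = 0.65, sigma_det = 0.7)
  su <- 0.4; delta <- 2
  y1 <- as.integer(rec$receiver_id == "r1")  # detected at (0,0)
  y2 <- as.integer(rec$receiver_id == "r9")  # detected at (2,2)
  g <- seq(-2.5, 4.5, length.out = 46)
  gr <- as.matrix(expand.grid(x = g, y = g))
  e1 <- exp(vapply(seq_len(nrow(gr)), function(i)
    encounter_loglik(y1, gr[i, ], rec, dp), numeric(1)))
  e2 <- exp(vapply(seq_len(nrow(gr)), function(i)
    encounter_loglik(y2, gr[i, ], rec, dp), numeric(1)))
  M <- exp(outer(gr[, 1], gr[, 1], function(a, b) dnorm(b, a, su * sqrt(delta),
                                                        log = TRUE))) *
       exp(outer(gr[, 2], gr[, 2], function(a, b) dnorm(b, a, su * sqrt(delta),
                                                        log = TRUE)))
  # joint weight w(u1, u2) = e1(u1) M(u1,u2) e2(u2); marginals by row/col sums
  W1 <- e1 * as.vector(M %*% e2)        # marginal of u1
  W2 <- e2 * as.vector(crossprod(M, e1))  # marginal of u2
  stat <- function(w) {
    w <- w / sum(w)
    m <- c(sum(w * gr[, 1]), sum(w * gr[, 2]))
    s <- c(sqrt(sum(w * gr[, 1]^2) - m[1]^2), sqrt(sum(w * gr[, 2]^2) - m[2]^2))
    list(mean = m, sd = s)
  }
  det_tbl <- detections_from_Y(rbind(y1, y2), c(0, delta), rec)
  fit <- fit_movement(det_tbl, rec, "detection_only",
                      settings = mcmc_settings(2, 8000, 1500, 2, seed = 8),
                      space = state_space(rec, 3),
                      fix_params = list(p0 = 0.65, sigma_det = 0.7,
                                        sigma_u = su))
  list(oracle1 = stat(W1), oracle2 = stat(W2),
       mcmc1 = list(mean = colMeans(fit$tags[[1]]$traj[, 1, ]),
                    sd = apply(fit$tags[[1]]$traj[, 1, ], 2, sd)),
       mcmc2 = list(mean = colMeans(fit$tags[[1]]$traj[, 2, ]),
                    sd = apply(fit$tags[[1]]$traj[, 2, ], 2, sd)))
})

# --- Trans-dimensional gap posterior ---------------------------------------
# Single-gap toy with two admissible missed-signal counts: exhaustive
# enumeration of the joint (count, bridge, endpoints) posterior on a coarse
# lattice vs the trans-dimensional sampler, all parameters fixed.
oracle_gap_check <- function() memo("gap", function() {
  rec <- toy_receivers(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  dp <- det_params(p0 = 0.6, sigma_det = 0.6)
  su <- 0.35; a <- 1; b <- 2; delta <- 3.6   # admissible n: 1 or 2
  y1 <- c(1L, 0L, 0L, 0L); y2 <- c(0L, 0L, 0L, 1L)
  g <- seq(-2.2, 3.2, length.out = 34)
  gr <- as.matrix(expand.grid(x = g, y = g))
  np <- nrow(gr)
  e1 <- exp(vapply(seq_len(np), function(i)
    encounter_loglik(y1, gr[i, ], rec, dp), numeric(1)))
  e2 <- exp(vapply(seq_len(np), function(i)
    encounter_loglik(y2, gr[i, ], rec, dp), numeric(1)))
  enc0 <- exp(vapply(seq_len(np), function(i)
    encounter_loglik(rep(0L, 4), gr[i, ], rec, dp), numeric(1)))
  trans <- function(dseg) {
    exp(outer(gr[, 1], gr[, 1], function(p, q) dnorm(q, p, su * sqrt(dseg),
                                                     log = TRUE))) *
    exp(outer(gr[, 2], gr[, 2], function(p, q) dnorm(q, p, su * sqrt(dseg),
                                                     log = TRUE)))
  }
  # P(n) = gap_lik(n) * e1' [A_n diag(enc0)]^n A_n e2 * cell^n, marginalizing
  # the detected endpoints and every latent location on the lattice (one
  # lattice-cell area factor per integrated latent location)
  cell <- diff(g)[1]^2
  mass_n <- vapply(1:2, function(n) {
    A <- trans(delta / (n + 1))
    v <- A %*% e2
    for (q in seq_len(n)) v <- A %*% (enc0 * v)
    exp(gap_loglik(delta, n, a, b)) * sum(e1 * v) * cell^n
  }, numeric(1))
  oracle_p <- mass_n / sum(mass_n)
  det_tbl <- detections_from_Y(rbind(y1, y2), c(0, delta), rec)
  fit <- fit_unknown_interval(det_tbl, rec, a = a, b = b,
                              settings = mcmc_settings(2, 12000, 2000, 2,
                                                       seed = 12),
                              space = state_space(rec, 2.5),
                              fix_params = list(p0 = 0.6, sigma_det = 0.6,
                                                sigma_u = su))
  ndr <- fit$tags[[1]]$n_draws[, 1]
  list(oracle_p1 = oracle_p[1], mcmc_p1 = mean(ndr == 1),
       bounds = fit$tags[[1]]$gaps, n_draws = ndr)
})

# --- Degenerate-schedule collapse ------------------------------------------
# With a = b the emission schedule is deterministic, so the unknown-interval
# model must reproduce the known-interval model on the same data.
collapse_check <- function() memo("collapse", function() {
  sim <- simulate_dataset(sim_config(n_individuals = 3, duration = 36,
                                     a = 1.5, b = 1.5, seed = 61))
  sp <- state_space(sim$receivers, 5 * 0.75)
  st <- mcmc_settings(2, 4000, 1500, 2, seed = 31)
  fk <- fit_movement(sim$detections, sim$receivers, "known_interval",
                     schedule = sim_schedule(sim), space = sp, settings = st)
  fu <- fit_unknown_interval(sim$detections, sim$receivers, a = 1.5, b = 1.5,
                             space = sp, settings = st)
  ms <- missed_signal_summary(fu, sim$truth)
  list(ki = setNames(tidy(fk)$estimate, tidy(fk)$term),
       ui = setNames(tidy(fu)$estimate, tidy(fu)$term),
       missed = ms)
})
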