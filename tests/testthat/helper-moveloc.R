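# Shared fixtures and the memoized scaled simulation study used by the
# acceptance tests.  Everything is generated in code at test time.

bench_det <- function() det_params(p0 = plogis(0.25), sigma_det = 0.75)

toy_receivers <- function(coords) {
  tibble::tibble(receiver_id = paste0("r", seq_len(nrow(coords))),
                 x = coords[, 1], y = coords[, 2])
}

# Detections tibble from one encounter matrix + times, for a single tag.
detections_from_Y <- function(Y, times, receivers, tag_id = "tagA") {
  idx <- which(Y == 1, arr.ind = TRUE)
  tibble::tibble(tag_id = tag_id,
                 receiver_id = receivers$receiver_id[idx[, 2]],
                 time = times[idx[, 1]])
}

# Pool stratified localization tables across replicate datasets
# (signal-count-weighted; RMSE pooled on the squared scale).
pool_metrics <- function(tables) {
  all <- do.call(rbind, lapply(tables, as.data.frame))
  out <- lapply(sort(unique(all$detections)), function(st) {
    g <- all[all$detections == st, ]
    w <- g$n_signals
    data.frame(detections = st,
               rmse = sqrt(sum(g$rmse^2 * w) / sum(w)),
               precision = sum(g$precision * w) / sum(w),
               coverage = sum(g$coverage * w) / sum(w),
               n_signals = sum(w))
  })
  do.call(rbind, out)
}

# The replicated simulation study at desk scale: 5 datasets of 10 tags
# sampled for 75 time units under the benchmark design, analysed with all
# four models.  Computed once per test run and cached.
.study_cache <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  truth_pars <- c(p0 = plogis(0.25), sigma_det = 0.75, sigma_u = 0.25)
  st <- mcmc_settings(n_chains = 3, n_iter = 4000, n_burn = 1500, thin = 2,
                      seed = 260929)
  reps <- lapply(1:5, function(d) {
    sim <- simulate_dataset(sim_config(n_individuals = 10, duration = 75,
                                       seed = 52000 + d))
    sp <- state_space(sim$receivers, 5 * 0.75)
    fi <- fit_independent(sim$detections, sim$receivers, space = sp,
                          settings = st)
    fd <- fit_movement(sim$detections, sim$receivers, "detection_only",
                       space = sp, settings = st)
    fk <- fit_movement(sim$detections, sim$receivers, "known_interval",
                       schedule = sim_schedule(sim), space = sp, settings = st)
    fu <- fit_unknown_interval(sim$detections, sim$receivers, a = 1, b = 2,
                               space = sp, settings = st)
    ms <- missed_signal_summary(fu, sim$truth)
    list(
      est = list(independent = setNames(tidy(fi)$estimate, tidy(fi)$term),
                 detection_only = setNames(tidy(fd)$estimate, tidy(fd)$term),
                 known_interval = setNames(tidy(fk)$estimate, tidy(fk)$term),
                 unknown_interval = setNames(tidy(fu)$estimate, tidy(fu)$term)),
      metrics = list(independent = localization_metrics(fi, sim$truth),
                     known_interval = localization_metrics(fk, sim$truth)),
      missed = c(est = sum(ms$est_missed), true = sum(ms$true_missed)))
  })
  bias <- function(model, par) {
    est <- vapply(reps, function(r) r$est[[model]][[par]], numeric(1))
    relative_bias(est, truth_pars[[par]])
  }
  study <- list(
    reps = reps, truth = truth_pars,
    bias = bias,
    metrics_ind = pool_metrics(lapply(reps, function(r) r$metrics$independent)),
    metrics_ki = pool_metrics(lapply(reps, function(r) r$metrics$known_interval)),
    missed_bias = {
      tot <- rowSums(vapply(reps, function(r) r$missed, numeric(2)))
      (tot[["est"]] - tot[["true"]]) / tot[["true"]]
    })
  .study_cache$study <- study
  study
}
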