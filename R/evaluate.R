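#' Relative bias of point estimates
#'
#' `(mean(estimates) - truth) / truth`, the frequentist relative bias of a
#' collection of point estimates (e.g. posterior means across replicated
#' simulated datasets).
#'
#' @param estimates Numeric vector of point estimates.
#' @param truth True parameter value (non-zero).
#' @return Relative bias as a fraction.
#' @export
relative_bias <- function(estimates, truth) {
  if (truth == 0) stop("`truth` must be non-zero", call. = FALSE)
  (mean(estimates) - truth) / truth
}

#' Localization RMSE
#'
#' Root mean squared Euclidean distance between per-signal point
#' localizations (posterior means) and the true locations.
#'
#' @param estimates,truths Two-column matrices (or data frames with columns
#'   `x`, `y`) of matched locations.
#' @return RMSE (distance units).
#' @export
localization_rmse <- function(estimates, truths) {
  estimates <- loc_matrix(estimates); truths <- loc_matrix(truths)
  if (nrow(estimates) != nrow(truths))
    stop("`estimates` and `truths` must align", call. = FALSE)
  sqrt(mean(rowSums((estimates - truths)^2)))
}

#' Posterior localization precision
#'
#' Mean Euclidean distance between the posterior draws of one signal's
#' location and its true location -- a dispersion-plus-error summary of the
#' full posterior (smaller is better).
#'
#' @param draws Matrix of posterior location draws (rows) for one signal.
#' @param truth Length-2 true location.
#' @return Mean draw-to-truth distance.
#' @export
posterior_precision <- function(draws, truth) {
  draws <- loc_matrix(draws)
  if (!nrow(draws)) stop("no posterior draws supplied", call. = FALSE)
  mean(sqrt((draws[, 1] - truth[1])^2 + (draws[, 2] - truth[2])^2))
}

#' Highest-posterior-density coverage of true locations
#'
#' For each signal, a 2-D Gaussian kernel density is built from its posterior
#' location draws (normal-reference bandwidths, as in
#' [MASS::kde2d()]); the true location is covered when its estimated density
#' is at least the empirical `1 - level` quantile of the density evaluated
#' at the draws themselves, i.e. when it falls inside the estimated
#' `level`-HPD region.  Degenerate draw clouds (zero variance) fall back to
#' an exact-match rule with a warning.
#'
#' @param draws_list List of per-signal draw matrices (rows = draws).
#' @param truths Matrix of true locations, one row per signal.
#' @param level HPD level (default 0.95).
#' @param max_draws Draws are thinned to at most this many per signal before
#'   the kernel computation.
#' @return Fraction of signals whose truth falls in the HPD region.
#' @export
hpd_coverage <- function(draws_list, truths, level = 0.95, max_draws = 500) {
  truths <- loc_matrix(truths)
  stopifnot(length(draws_list) == nrow(truths))
  covered <- vapply(seq_along(draws_list), function(i) {
    hpd_covered_one(loc_matrix(draws_list[[i]]), truths[i, ], level, max_draws)
  }, logical(1))
  mean(covered)
}

hpd_covered_one <- function(draws, truth, level, max_draws) {
  if (nrow(draws) > max_draws)
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                   drop = FALSE]
  sx <- sd(draws[, 1]); sy <- sd(draws[, 2])
  if (!is.finite(sx) || !is.finite(sy) || sx < 1e-12 || sy < 1e-12) {
    warning("degenerate posterior draws; using exact-match coverage rule",
            call. = FALSE)
    return(all(abs(colMeans(draws) - truth) < 1e-8))
  }
  h1 <- MASS::bandwidth.nrd(draws[, 1]) / 4
  h2 <- MASS::bandwidth.nrd(draws[, 2]) / 4
  dens <- kde2d_density_at(draws, rbind(draws, truth), h1, h2)
  m <- nrow(draws)
  thr <- quantile(dens[seq_len(m)], probs = 1 - level, type = 1)
  dens[m + 1] >= thr
}

#' Per-signal detection-count strata
#'
#' Number of receivers at which each signal was detected, the stratification
#' used to tabulate localization performance.  Counts of seven or more are
#' returned as `NA` (excluded from tabulation due to their rarity).
#'
#' @param Y Binary encounter matrix (signals x receivers).
#' @return Integer vector of per-signal detection counts (`NA` for >= 7).
#' @export
stratify_by_detection_count <- function(Y) {
  n <- as.integer(rowSums(Y))
  n[n >= 7L] <- NA_integer_
  n
}

loc_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  x <- rbind(x)
  stopifnot(ncol(x) == 2)
  unname(x)
}

#' Localization performance table
#'
#' RMSE of posterior mean locations, posterior precision, and HPD coverage,
#' stratified by per-signal detection count, for one fitted model against
#' simulation truth.  Fit signals are matched to truth rows by tag and
#' emission time.
#'
#' @param fit A `maloc_fit`.
#' @param truth Truth tibble from [simulate_dataset()] (`tag_id`, `time`,
#'   `x`, `y`).
#' @param level HPD level for coverage.
#' @param max_draws Per-signal draw cap for the coverage kernel.
#' @param time_tol Matching tolerance between fit and truth times.
#' @return Tibble: `detections` (stratum), `n_signals`, `rmse`, `precision`,
#'   `coverage`.
#' @export
localization_metrics <- function(fit, truth, level = 0.95, max_draws = 500,
                                 time_tol = 1e-6) {
  stopifnot(inherits(fit, "maloc_fit"))
  per_sig <- list(); k <- 0
  for (tg in fit$tags) {
    tt <- truth[truth$tag_id == tg$tag_id, ]
    for (s in seq_along(tg$times)) {
      j <- which.min(abs(tt$time - tg$times[s]))
      if (!length(j) || abs(tt$time[j] - tg$times[s]) > time_tol + 1e-9)
        stop("fit signal at time ", tg$times[s], " has no matching truth row",
             call. = FALSE)
      k <- k + 1
      per_sig[[k]] <- list(stratum = sum(tg$Y[s, ]),
                           draws = tg$traj[, s, ],
                           truth = c(tt$x[j], tt$y[j]))
    }
  }
  strata <- vapply(per_sig, `[[`, numeric(1), "stratum")
  strata[strata >= 7] <- NA
  out <- lapply(sort(unique(strata[!is.na(strata)])), function(st) {
    sel <- which(!is.na(strata) & strata == st)
    means <- t(vapply(sel, function(i) colMeans(per_sig[[i]]$draws),
                      numeric(2)))
    tru <- t(vapply(sel, function(i) per_sig[[i]]$truth, numeric(2)))
    prec <- mean(vapply(sel, function(i)
      posterior_precision(per_sig[[i]]$draws, per_sig[[i]]$truth), numeric(1)))
    cov <- hpd_coverage(lapply(sel, function(i) per_sig[[i]]$draws), tru,
                        level = level, max_draws = max_draws)
    tibble::tibble(detections = st, n_signals = length(sel),
                   rmse = localization_rmse(means, tru), precision = prec,
                   coverage = cov)
  })
  dplyr::bind_rows(out)
}
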