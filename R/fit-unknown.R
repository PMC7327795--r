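#' Movement-assisted localization with unknown signal intervals
#'
#' The most realistic field protocol: tags emit on a random schedule with
#' intervals `Uniform(a, b)` whose emission times are not logged, so the
#' number of signals missed between consecutive detections is latent.  Each
#' inter-detection gap of length `delta_obs` admits a bounded set of
#' missed-signal counts `n` (see [missed_signal_bounds()]); the signal-rate
#' sub-model links `delta_obs` to `n` through the normal approximation of a
#' sum of uniform intervals (see [gap_loglik()]).
#'
#' Sampling combines the fixed-schedule movement updates for detected-signal
#' locations and parameters with, per gap and sweep: (i) per-location
#' Metropolis updates of the current missed-signal sub-trajectory against
#' its bridge full conditional (movement kernels to both neighbours plus the
#' all-zero encounter likelihood at each missed location); (ii) a refresh of
#' the sub-trajectories maintained for the other admissible counts by
#' independence draws from the Brownian bridge between the bounding detected
#' locations; and (iii) a trans-dimensional Metropolis-Hastings move that
#' proposes a count uniformly on the admissible set together with its
#' bridge-drawn sub-trajectory.  Because the bridge density is also the
#' proposal density, the acceptance ratio reduces to the signal-rate
#' likelihood and the all-zero encounter terms -- which is what lets the
#' sampler reject large counts for gaps in the array interior, where
#' undetected emissions are unlikely.
#'
#' Within a gap holding `n` missed signals the movement bridge uses `n + 1`
#' equal segment durations `delta_obs / (n + 1)` (so durations sum exactly
#' to the gap), and the schedule information is carried by the normal
#' approximation rather than by individually sampled interval durations.
#' Gaps before the first and after the last detection have no bounding
#' location on one side and are excluded.  Tags with fewer than two detected
#' occasions are dropped with a warning.
#'
#' @inheritParams fit_movement
#' @param a,b Transmitter interval bounds (data, known from tag settings).
#' @param convention Missed-signal counting convention, see
#'   [missed_signal_bounds()].
#' @param gap_cap Maximum admissible-range width per gap; wider gaps
#'   (observed with intervals that are tiny relative to the gap) are refused
#'   with guidance to coarsen the analysis.
#' @param save_gap_traj Record the latent missed-signal locations of the
#'   current count per gap (memory-hungry; used for validation on toys).
#' @return A `maloc_fit` object whose `tags` additionally carry `gaps`
#'   (tibble: `gap`, `delta_obs`, `n_min`, `n_max`) and `n_draws` (posterior
#'   draws x gaps matrix of missed-signal counts).
#' @export
fit_unknown_interval <- function(detections, receivers, a, b, space = NULL,
                                 settings = mcmc_settings(3, 60000, 10000, 10),
                                 tol = 1e-6,
                                 convention = c("n_plus_1", "n"),
                                 gap_cap = 50, fix_params = NULL,
                                 sigma_u_max = NULL, save_gap_traj = FALSE) {
  convention <- match.arg(convention)
  koff <- if (convention == "n_plus_1") 1L else 0L
  enc <- build_encounters(detections, receivers, tol)
  if (is.null(space)) space <- default_space(receivers)
  X <- receiver_coords(receivers)

  few <- vapply(enc, function(e) nrow(e$Y) < 2, logical(1))
  if (any(few)) {
    warning(sum(few), " tag(s) with < 2 detected occasions dropped",
            call. = FALSE)
    enc <- enc[!few]
  }
  if (!length(enc)) stop("no tags left to fit", call. = FALSE)

  gaps <- lapply(enc, function(e) {
    d <- diff(e$times)
    bounds <- lapply(d, function(dd) {
      adm <- missed_signal_bounds(dd, a, b, convention)
      if (!length(adm))
        stop("gap of length ", signif(dd, 4), " admits no interval tiling ",
             "with a = ", a, ", b = ", b, call. = FALSE)
      adm
    })
    width <- vapply(bounds, function(x) diff(range(x)), numeric(1))
    if (any(width > gap_cap))
      stop("a gap admits ", max(width) + 1, " missed-signal counts ",
           "(cap ", gap_cap, "); consider coarser fixed-interval averaging ",
           "for such sparse detections", call. = FALSE)
    tibble::tibble(gap = seq_along(d), delta_obs = d,
                   n_min = vapply(bounds, min, numeric(1)),
                   n_max = vapply(bounds, max, numeric(1)))
  })

  u_init <- lapply(enc, function(e) init_locations(e$Y, X))
  delta <- lapply(enc, function(e) c(NA_real_, diff(e$times)))
  sigdet_max <- half_diag(space)
  if (is.null(sigma_u_max)) sigma_u_max <- half_diag(space)
  p0_init <- if (!is.null(fix_params)) fix_params$p0 else 0.5
  sd_init <- if (!is.null(fix_params)) fix_params$sigma_det
             else median_spacing(receivers)
  su_init <- if (!is.null(fix_params)) fix_params$sigma_u
             else min(init_sigma_u(u_init, delta), sigma_u_max / 2)

  seeds <- chain_seeds(settings)
  chains <- lapply(seq_len(settings$n_chains), function(cidx) {
    set.seed(seeds[cidx])
    mcmc_unknown_cpp(lapply(enc, `[[`, "Y"), lapply(enc, `[[`, "times"), X,
                     a, b, koff,
                     lapply(gaps, function(g) as.integer(g$n_min)),
                     lapply(gaps, function(g) as.integer(g$n_max)),
                     sigdet_max, sigma_u_max, u_init, p0_init, sd_init,
                     su_init, settings$n_iter, settings$n_burn, settings$thin,
                     !is.null(fix_params), save_gap_traj)
  })
  fit <- assemble_fit("unknown_interval", chains, enc, receivers, space,
                      settings, c("p0", "sigma_det", "sigma_u"),
                      extra = list(a = a, b = b, convention = convention))
  for (i in seq_along(fit$tags)) {
    fit$tags[[i]]$gaps <- gaps[[i]]
    fit$tags[[i]]$n_draws <- do.call(rbind, lapply(chains, function(ch) ch$n[[i]]))
    if (save_gap_traj) {
      gt <- lapply(chains, function(ch) ch$gap_traj[[i]])
      all_d <- dim(gt[[1]])
      comb <- array(NA_real_, c(sum(vapply(gt, function(a2) dim(a2)[1],
                                           integer(1))), all_d[-1]))
      off <- 0
      for (g2 in gt) {
        comb[off + seq_len(dim(g2)[1]), , , ] <- g2
        off <- off + dim(g2)[1]
      }
      fit$tags[[i]]$gap_traj <- comb
    }
  }
  fit
}

#' Posterior summary of missed signals
#'
#' Per-tag posterior of the total number of signals missed between the first
#' and last detection.  When simulation `truth` (from [simulate_dataset()])
#' is supplied, the true number of undetected emissions within the detected
#' span is attached for comparison.
#'
#' @param fit A fit from [fit_unknown_interval()].
#' @param truth Optional truth tibble with columns `tag_id`, `time`,
#'   `n_detections`.
#' @return Tibble with columns `tag_id`, `n_gaps`, `est_missed` (sum over
#'   gaps of posterior mean counts) and, with truth, `true_missed`.
#' @export
missed_signal_summary <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "maloc_fit_unknown_interval"))
  out <- purrr::map_dfr(fit$tags, function(tg) {
    tibble::tibble(tag_id = tg$tag_id, n_gaps = nrow(tg$gaps),
                   est_missed = sum(colMeans(tg$n_draws)))
  })
  if (!is.null(truth)) {
    tm <- purrr::map_dbl(fit$tags, function(tg) {
      tt <- truth[truth$tag_id == tg$tag_id, ]
      span <- range(tg$times)
      sum(tt$n_detections == 0 & tt$time > span[1] + 1e-9 &
            tt$time < span[2] - 1e-9)
    })
    out$true_missed <- tm
  }
  out
}
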