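#' Movement-assisted localization with a fixed schedule
#'
#' Joint Metropolis-within-Gibbs over all latent signal locations and the
#' parameters `(p0, sigma_det, sigma_u)`: a half-normal detection function
#' links locations to encounter vectors, and Brownian motion links
#' successive locations through their elapsed times.  Each location is
#' updated against its full conditional (the encounter likelihood of its own
#' occasion times the movement kernels to the previous and next locations);
#' parameters are updated against the pooled joint likelihood across tags.
#'
#' Two variants:
#' \describe{
#'   \item{`detection_only`}{only detected occasions are used; the elapsed
#'     time between consecutive *detected* signals serves as the movement
#'     interval, so missed signals are silently absorbed into longer
#'     intervals.  Tags with fewer than two detected occasions carry no
#'     movement information and are dropped with a warning.}
#'   \item{`known_interval`}{the full emission schedule (including occasions
#'     with zero detections) is supplied via `schedule`; all-zero encounter
#'     vectors enter the likelihood.  Leading and trailing undetected
#'     occasions are trimmed to `buffer` (default five) signals beyond the
#'     first and last detection to avoid an inordinate number of
#'     unconstrained end locations.}
#' }
#'
#' Priors: as in [fit_independent()], plus `sigma_u ~ Uniform(0, L)` with a
#' generous upper bound (half the state-space diagonal by default).  The
#' first location of each tag carries a flat prior.
#'
#' @inheritParams fit_independent
#' @param variant `"detection_only"` or `"known_interval"`.
#' @param schedule Tibble (`tag_id`, `time`) of all emission times; required
#'   for the known-interval variant (the schedule is known by design there).
#' @param buffer Number of leading/trailing undetected occasions retained
#'   around the detected span (known-interval variant).
#' @param sigma_u_max Upper bound of the uniform prior on `sigma_u`.
#' @param fix_params Optional `list(p0 =, sigma_det =, sigma_u =)` to hold
#'   parameters fixed.
#' @return A `maloc_fit` object.
#' @export
fit_movement <- function(detections, receivers,
                         variant = c("detection_only", "known_interval"),
                         schedule = NULL, space = NULL,
                         settings = mcmc_settings(), tol = 1e-6, buffer = 5,
                         sigma_u_max = NULL, fix_params = NULL) {
  variant <- match.arg(variant)
  enc <- build_encounters(detections, receivers, tol)
  if (is.null(space)) space <- default_space(receivers)
  X <- receiver_coords(receivers)

  if (variant == "detection_only") {
    few <- vapply(enc, function(e) nrow(e$Y) < 2, logical(1))
    if (any(few)) {
      warning(sum(few), " tag(s) with < 2 detected occasions dropped ",
              "(no movement information)", call. = FALSE)
      enc <- enc[!few]
    }
    if (!length(enc)) stop("no tags left to fit", call. = FALSE)
    delta <- lapply(enc, function(e) c(NA_real_, diff(e$times)))
  } else {
    if (is.null(schedule))
      stop("the known-interval variant requires `schedule`", call. = FALSE)
    enc <- lapply(enc, expand_to_schedule, schedule = schedule,
                  J = nrow(receivers), tol = tol, buffer = buffer)
    delta <- lapply(enc, function(e) c(NA_real_, diff(e$times)))
  }

  u_init <- lapply(enc, function(e) init_locations(e$Y, X))
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
    mcmc_movement_cpp(lapply(enc, `[[`, "Y"), delta, X, sigdet_max,
                      sigma_u_max, u_init, p0_init, sd_init, su_init,
                      settings$n_iter, settings$n_burn, settings$thin,
                      !is.null(fix_params))
  })
  assemble_fit(variant, chains, enc, receivers, space, settings,
               c("p0", "sigma_det", "sigma_u"))
}

# Expand a tag's detected encounter occasions onto its full known schedule,
# inserting all-zero rows for undetected emissions and trimming the
# leading/trailing undetected run to `buffer` occasions.
expand_to_schedule <- function(e, schedule, J, tol, buffer) {
  st <- sort(schedule$time[schedule$tag_id == e$tag_id])
  if (!length(st))
    stop("no schedule entries for tag ", e$tag_id, call. = FALSE)
  idx <- vapply(e$times, function(tt) {
    k <- which.min(abs(st - tt))
    if (abs(st[k] - tt) > tol + 1e-9)
      stop("detection at time ", tt, " does not match any schedule entry ",
           "for tag ", e$tag_id, call. = FALSE)
    k
  }, integer(1))
  lo <- max(1L, min(idx) - buffer)
  hi <- min(length(st), max(idx) + buffer)
  Y <- matrix(0L, hi - lo + 1L, J)
  for (r in seq_along(idx)) Y[idx[r] - lo + 1L, ] <- e$Y[r, ]
  list(tag_id = e$tag_id, times = st[lo:hi], Y = Y)
}
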