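#' Independent per-signal localization
#'
#' The baseline comparator: every detected signal is localized on its own by
#' Bayes' rule, with a uniform location prior over the state space and no
#' movement model.  Detection parameters `(p0, sigma_det)` of a half-normal
#' detection function are estimated jointly with the locations by
#' Metropolis-within-Gibbs, pooling all tags.  Occasions with zero
#' detections never enter (they are unobservable without a known schedule),
#' which is the known source of positive bias in `p0` for this estimator;
#' the observed zeros at non-detecting receivers *are* used.
#'
#' Priors: `p0 ~ Uniform(0, 1)`, `sigma_det ~ Uniform(0, L)` with `L` half
#' the state-space diagonal, locations uniform over `space`.
#'
#' @param detections Detection records (`tag_id`, `receiver_id`, `time`).
#' @param receivers Receiver table (`receiver_id`, `x`, `y`).
#' @param space A [state_space()]; defaults to the receiver bounding box
#'   buffered by five times a detection-scale guess of 3/4 the receiver
#'   spacing.
#' @param settings An [mcmc_settings()].
#' @param tol Time-binning tolerance for grouping detections into signals.
#' @param fix_params Optional named list `list(p0 =, sigma_det =)`; when
#'   given, detection parameters are held fixed (useful for validation
#'   against grid oracles).
#' @return A `maloc_fit` object; see [tidy.maloc_fit()], [localize()].
#' @export
fit_independent <- function(detections, receivers, space = NULL,
                            settings = mcmc_settings(), tol = 1e-6,
                            fix_params = NULL) {
  enc <- build_encounters(detections, receivers, tol)
  if (is.null(space)) space <- default_space(receivers)
  X <- receiver_coords(receivers)
  for (e in enc)
    if (any(rowSums(e$Y) == 0))
      stop("independent localization uses detected occasions only", call. = FALSE)

  u_init <- lapply(enc, function(e) init_locations(e$Y, X))
  # clamp initial locations into the state space
  u_init <- lapply(u_init, function(u) {
    u[, 1] <- pmin(pmax(u[, 1], space$xmin), space$xmax)
    u[, 2] <- pmin(pmax(u[, 2], space$ymin), space$ymax)
    u
  })
  sigdet_max <- half_diag(space)
  p0_init <- if (!is.null(fix_params)) fix_params$p0 else 0.5
  sd_init <- if (!is.null(fix_params)) fix_params$sigma_det
             else median_spacing(receivers)

  seeds <- chain_seeds(settings)
  chains <- lapply(seq_len(settings$n_chains), function(cidx) {
    set.seed(seeds[cidx])
    mcmc_independent_cpp(lapply(enc, `[[`, "Y"), X, as_space_vec(space),
                         sigdet_max, u_init, p0_init, sd_init,
                         settings$n_iter, settings$n_burn, settings$thin,
                         !is.null(fix_params))
  })
  assemble_fit("independent", chains, enc, receivers, space, settings,
               c("p0", "sigma_det"))
}
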