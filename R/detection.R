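#' Detection-function parameters
#'
#' Bundle the parameters of a distance-dependent detection function.  Three
#' families are supported: the half-normal kernel common in distance sampling
#' and spatial capture-recapture, `p(d) = p0 * exp(-d^2 / (2 * sigma_det^2))`;
#' a logistic curve on the logit scale, `logit(p) = alpha0 + alpha1 * d`; and
#' a hazard form, `p(d) = 1 - exp(-(d^2 / sigma_det)^(-theta))`, which keeps
#' detection high close to a receiver before declining.
#'
#' @param p0 Detection probability at distance zero (half-normal and hazard
#'   families), in `(0, 1]`.
#' @param sigma_det Detection-range scale in the distance units of the
#'   receiver coordinates; must be positive.
#' @param family One of `"halfnormal"`, `"logistic"`, `"hazard"`.
#' @param alpha0,alpha1 Logistic intercept and slope (logit scale); required
#'   for the logistic family only.
#' @param theta Hazard shape parameter (> 0); required for the hazard family
#'   only.
#' @return An object of class `det_params`.
#' @examples
#' det_params(p0 = 0.562, sigma_det = 0.75)
#' @export
det_params <- function(p0 = NULL, sigma_det = NULL,
                       family = c("halfnormal", "logistic", "hazard"),
                       alpha0 = NULL, alpha1 = NULL, theta = NULL) {
  family <- match.arg(family)
  if (family %in% c("halfnormal", "hazard")) {
    if (is.null(p0) || !is.numeric(p0) || p0 <= 0 || p0 > 1)
      stop("`p0` must lie in (0, 1] for the ", family, " family", call. = FALSE)
    if (is.null(sigma_det) || !is.numeric(sigma_det) || sigma_det <= 0)
      stop("`sigma_det` must be positive", call. = FALSE)
  }
  if (family == "logistic" && (is.null(alpha0) || is.null(alpha1)))
    stop("the logistic family requires `alpha0` and `alpha1`", call. = FALSE)
  if (family == "hazard" && (is.null(theta) || theta <= 0))
    stop("the hazard family requires `theta` > 0", call. = FALSE)
  structure(
    list(p0 = p0, sigma_det = sigma_det, family = family,
         alpha0 = alpha0, alpha1 = alpha1, theta = theta),
    class = "det_params"
  )
}

#' @export
print.det_params <- function(x, ...) {
  cat("<det_params>", x$family, "\n")
  flds <- switch(x$family,
    halfnormal = c(p0 = x$p0, sigma_det = x$sigma_det),
    logistic   = c(alpha0 = x$alpha0, alpha1 = x$alpha1),
    hazard     = c(p0 = x$p0, sigma_det = x$sigma_det, theta = x$theta))
  print(flds)
  invisible(x)
}

#' Distance-dependent detection probability
#'
#' Probability that a signal emitted at distance `dist` from a receiver is
#' detected by it, under the chosen detection family.  The hazard family is
#' defined by continuity as 1 at distance zero.
#'
#' @param dist Vector of non-negative source-receiver distances.
#' @param params A [det_params()] object.
#' @return A vector of probabilities in `[0, 1]`.
#' @examples
#' detection_prob(c(0, 0.75), det_params(p0 = 0.562, sigma_det = 0.75))
#' @export
detection_prob <- function(dist, params) {
  stopifnot(inherits(params, "det_params"))
  if (any(!is.finite(dist)) || any(dist < 0))
    stop("`dist` must be finite and non-negative", call. = FALSE)
  switch(params$family,
    halfnormal = params$p0 * exp(-dist^2 / (2 * params$sigma_det^2)),
    logistic = plogis(params$alpha0 + params$alpha1 * dist),
    hazard = {
      p <- ifelse(dist == 0, 1,
                  1 - exp(-(dist^2 / params$sigma_det)^(-params$theta)))
      p
    })
}

#' Brownian-motion movement transition log-density
#'
#' Log-density of a displacement from `u_prev` to `u` over elapsed time
#' `delta`, under Brownian motion with per-unit-time standard deviation
#' `sigma_u`: each coordinate axis moves independently as
#' `Normal(u_prev, sigma_u^2 * delta)`.
#'
#' @param u,u_prev Locations: length-2 vectors or 2-column matrices.
#' @param sigma_u Movement standard deviation per square-root time unit.
#' @param delta Positive elapsed time (scalar or vector matching rows).
#' @return Log-density (one value per location pair).
#' @examples
#' movement_logdensity(c(0, 0), c(0, 0), sigma_u = 0.25, delta = 1)
#' @export
movement_logdensity <- function(u, u_prev, sigma_u, delta) {
  if (any(delta <= 0)) stop("`delta` must be positive", call. = FALSE)
  if (sigma_u <= 0) stop("`sigma_u` must be positive", call. = FALSE)
  u <- rbind(u); u_prev <- rbind(u_prev)
  sdv <- sigma_u * sqrt(delta)
  unname(dnorm(u[, 1], u_prev[, 1], sdv, log = TRUE) +
           dnorm(u[, 2], u_prev[, 2], sdv, log = TRUE))
}

#' Encounter-history log-likelihood of one signal
#'
#' Bernoulli log-likelihood of the binary detection vector `y` over all
#' receivers, given the source location `u`.  Detections at different
#' receivers are conditionally independent given the source location; the
#' likelihood therefore factors over receivers, and the "observed zeros" at
#' non-detecting receivers contribute through `1 - p_j`.  Probabilities are
#' clipped to `[1e-12, 1 - 1e-12]`, which only matters at distances beyond
#' roughly seven detection scales.
#'
#' @param y Binary vector, one element per receiver.
#' @param u Source location (length-2 vector).
#' @param receivers Receiver table with columns `x`, `y` (see
#'   [make_grid_array()]), or a 2-column coordinate matrix.
#' @param params A [det_params()] object.
#' @return The log-likelihood (scalar).
#' @export
encounter_loglik <- function(y, u, receivers, params) {
  X <- receiver_coords(receivers)
  if (length(y) != nrow(X))
    stop("`y` must have one element per receiver (", nrow(X), ")", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  d <- sqrt((u[1] - X[, 1])^2 + (u[2] - X[, 2])^2)
  p <- pmin(pmax(detection_prob(d, params), 1e-12), 1 - 1e-12)
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

# Coordinates of a receiver table as a plain matrix.
receiver_coords <- function(receivers) {
  if (is.matrix(receivers)) {
    stopifnot(ncol(receivers) == 2)
    return(unname(receivers))
  }
  stopifnot(all(c("x", "y") %in% names(receivers)))
  cbind(receivers$x, receivers$y)
}
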