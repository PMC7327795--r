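#' Full-conditional log-density of one signal location
#'
#' The unnormalized log-density targeted by the per-location Metropolis
#' updates of the movement-assisted samplers: the encounter log-likelihood
#' of the signal's own occasion plus the Brownian-motion kernels to the
#' previous and next locations.  Neighbour terms are dropped at trajectory
#' ends (pass `NULL`); with both neighbours missing the density reduces to
#' the encounter log-likelihood alone.
#'
#' @param u Location being evaluated (length-2).
#' @param y Binary encounter vector of this occasion.
#' @param receivers Receiver table.
#' @param det A [det_params()] object.
#' @param sigma_u Movement standard deviation.
#' @param u_prev,u_next Neighbouring locations or `NULL`.
#' @param delta_prev,delta_next Elapsed times to the neighbours.
#' @return Unnormalized log-density (scalar).
#' @export
location_conditional_logdensity <- function(u, y, receivers, det, sigma_u,
                                            u_prev = NULL, delta_prev = NULL,
                                            u_next = NULL, delta_next = NULL) {
  ld <- encounter_loglik(y, u, receivers, det)
  if (!is.null(u_prev))
    ld <- ld + movement_logdensity(u, u_prev, sigma_u, delta_prev)
  if (!is.null(u_next))
    ld <- ld + movement_logdensity(u_next, u, sigma_u, delta_next)
  as.numeric(ld)
}

#' Integrated likelihood of independent localization
#'
#' Log-likelihood of the detection parameters under the independent
#' per-signal model, with every latent location integrated out against the
#' uniform prior over the state space:
#' `sum_t log( mean over a quadrature grid of Pr(y_t | u) )`.
#' Only detected occasions enter, and no correction for the condition of
#' being detected at all is applied -- this reproduces the baseline
#' estimator, whose exclusion of all-zero occasions is a known source of
#' positive bias in `p0`.
#'
#' @param params A [det_params()] object.
#' @param encounters Binary matrix (occasions x receivers), each row with at
#'   least one detection, or a list of such matrices (tags are pooled).
#' @param receivers Receiver table.
#' @param space A [state_space()].
#' @param grid_n Quadrature resolution per axis.
#' @return Log-likelihood (scalar).
#' @export
independent_loglik <- function(params, encounters, receivers, space,
                               grid_n = 200) {
  if (is.list(encounters) && !is.matrix(encounters))
    encounters <- do.call(rbind, encounters)
  encounters <- rbind(encounters)
  if (!nrow(encounters)) stop("no encounter occasions supplied", call. = FALSE)
  if (any(rowSums(encounters) == 0))
    stop("independent likelihood is defined for detected occasions only",
         call. = FALSE)
  X <- receiver_coords(receivers)
  if (ncol(encounters) != nrow(X))
    stop("encounter columns must match receivers", call. = FALSE)
  gx <- seq(space$xmin, space$xmax, length.out = grid_n)
  gy <- seq(space$ymin, space$ymax, length.out = grid_n)
  g <- expand.grid(x = gx, y = gy)
  d <- sqrt(outer(g$x, X[, 1], "-")^2 + outer(g$y, X[, 2], "-")^2)
  P <- matrix(pmin(pmax(detection_prob(as.vector(d), params), 1e-12),
                   1 - 1e-12), nrow = nrow(g))
  logP <- log(P); log1mP <- log1p(-P)
  sum(apply(encounters, 1, function(y) {
    ll_u <- logP %*% y + log1mP %*% (1 - y)  # grid-point log Pr(y | u)
    m <- max(ll_u)
    m + log(mean(exp(ll_u - m)))
  }))
}
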