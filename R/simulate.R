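#' Simulation configuration
#'
#' Study conditions for a simulated receiver-array telemetry system: tagged
#' individuals move by Brownian motion, emit signals on a random schedule
#' with inter-signal intervals `Uniform(a, b)`, and are detected by receivers
#' according to a distance-dependent detection function.  The defaults are a
#' benchmark design: 25 tags sampled by a 10 x 10 unit-spaced grid over 150
#' time units, half-normal detection with `p0 = plogis(0.25) = 0.562` and
#' `sigma_det = 0.75`, movement scale `sigma_u = 0.25`, and initial positions
#' uniform on the array buffered by `5 * sigma_det`.
#'
#' @param n_individuals Number of tagged individuals.
#' @param grid_nx,grid_ny,spacing Receiver grid dimensions and spacing.
#' @param a,b Inter-signal interval bounds, `0 < a <= b` (time units).
#' @param duration Total sampling duration (time units).
#' @param det Detection parameters, a [det_params()] object.
#' @param sigma_u Movement standard deviation per square-root time unit.
#' @param buffer_mult Initial-position / state-space buffer in units of the
#'   detection scale `sigma_det`.
#' @param seed Optional RNG seed for [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 25, grid_nx = 10, grid_ny = 10,
                       spacing = 1, a = 1, b = 2, duration = 150,
                       det = det_params(p0 = plogis(0.25), sigma_det = 0.75),
                       sigma_u = 0.25, buffer_mult = 5, seed = NULL) {
  if (a <= 0 || a > b) stop("need 0 < a <= b", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (buffer_mult < 0) stop("`buffer_mult` must be >= 0", call. = FALSE)
  if (sigma_u < 0) stop("`sigma_u` must be >= 0", call. = FALSE)
  structure(
    list(n_individuals = n_individuals, grid_nx = grid_nx, grid_ny = grid_ny,
         spacing = spacing, a = a, b = b, duration = duration, det = det,
         sigma_u = sigma_u, buffer_mult = buffer_mult, seed = seed),
    class = "sim_config")
}

#' Random signal-emission schedule
#'
#' Emission times of one tag over `[0, duration]`.  The first emission is
#' drawn `Uniform(0, b)` so that tag phases are offset, and subsequent
#' inter-signal intervals are iid `Uniform(a, b)`; the schedule stops at the
#' last emission not exceeding `duration`.
#'
#' @param a,b Interval bounds, `0 < a <= b`.
#' @param duration Total sampling duration.
#' @return Numeric vector of strictly increasing emission times.
#' @export
simulate_schedule <- function(a, b, duration) {
  if (a <= 0 || a > b) stop("need 0 < a <= b", call. = FALSE)
  times <- runif(1, 0, b)
  # expected count ~ duration / mean interval; draw in blocks
  repeat {
    block <- cumsum(runif(ceiling(2 + 2 * duration / a), a, b))
    times <- c(times, times[length(times)] + block)
    if (times[length(times)] > duration) break
  }
  times[times <= duration]
}

#' Brownian-motion trajectory
#'
#' One latent location per emitted signal: each displacement is Gaussian on
#' both axes with variance `sigma_u^2 * delta`.
#'
#' @param u0 Initial location (length-2).
#' @param sigma_u Movement standard deviation per square-root time unit.
#' @param intervals Positive elapsed times between consecutive signals.
#' @return Matrix with `length(intervals) + 1` rows and columns `x`, `y`.
#' @export
simulate_trajectory <- function(u0, sigma_u, intervals) {
  if (length(intervals) && any(intervals <= 0))
    stop("`intervals` must be positive", call. = FALSE)
  n <- length(intervals)
  sdv <- sigma_u * sqrt(intervals)
  u <- cbind(x = cumsum(c(u0[1], rnorm(n, 0, sdv))),
             y = cumsum(c(u0[2], rnorm(n, 0, sdv))))
  u
}

#' Uniform initial positions around an array
#'
#' Draw `n` points uniformly on the receiver bounding box expanded by
#' `buffer_mult * sigma_det` on each side.
#'
#' @param receivers Receiver table.
#' @param sigma_det Detection scale used to size the buffer.
#' @param buffer_mult Buffer in multiples of `sigma_det` (>= 0).
#' @param n Number of points.
#' @return An `n` x 2 matrix of coordinates.
#' @export
simulate_initial_positions <- function(receivers, sigma_det, buffer_mult, n) {
  if (buffer_mult < 0) stop("`buffer_mult` must be >= 0", call. = FALSE)
  sp <- state_space(receivers, buffer_mult * sigma_det)
  cbind(x = runif(n, sp$xmin, sp$xmax), y = runif(n, sp$ymin, sp$ymax))
}

#' Simulate spatial encounter histories
#'
#' Bernoulli detections of every signal at every receiver, with probability
#' given by the detection function of the source-receiver distance.
#'
#' @param trajectory Matrix of signal locations (rows) from
#'   [simulate_trajectory()].
#' @param receivers Receiver table.
#' @param det A [det_params()] object.
#' @return Binary matrix, signals x receivers.
#' @export
simulate_detections <- function(trajectory, receivers, det) {
  X <- receiver_coords(receivers)
  trajectory <- rbind(trajectory)
  d <- sqrt(outer(trajectory[, 1], X[, 1], "-")^2 +
            outer(trajectory[, 2], X[, 2], "-")^2)
  P <- detection_prob(as.vector(d), det)
  matrix(rbinom(length(P), 1, P), nrow = nrow(trajectory))
}

#' Simulate a complete telemetry dataset
#'
#' Generate receiver coordinates, per-tag signal schedules, latent Brownian
#' trajectories, and spatial encounter histories under a [sim_config()].
#' Truth (schedules and trajectories, with per-signal detection counts) is
#' returned alongside the observable detection records so that evaluation
#' never has to re-align signals with encounters.  A master seed spawns an
#' independent RNG stream per tag, so per-tag simulation is
#' order-independent.
#'
#' @param config A [sim_config()].
#' @return An object of class `telemetry_sim`: a list with tibbles
#'   `receivers` (`receiver_id`, `x`, `y`), `detections` (`tag_id`,
#'   `receiver_id`, `time`), `truth` (`tag_id`, `signal`, `time`, `x`, `y`,
#'   `n_detections`), the `state_space` used for initial positions, and the
#'   `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_individuals = 2, duration = 20, seed = 1))
#' head(sim$truth)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  receivers <- make_grid_array(config$grid_nx, config$grid_ny, config$spacing)
  tag_seeds <- sample.int(.Machine$integer.max, config$n_individuals)
  space <- state_space(receivers, config$buffer_mult * config$det$sigma_det)

  one_tag <- function(i) {
    set.seed(tag_seeds[i])
    times <- simulate_schedule(config$a, config$b, config$duration)
    u0 <- simulate_initial_positions(receivers, config$det$sigma_det,
                                     config$buffer_mult, 1)
    traj <- simulate_trajectory(u0, config$sigma_u, diff(times))
    Y <- simulate_detections(traj, receivers, config$det)
    list(tag_id = sprintf("tag%02d", i), times = times, traj = traj, Y = Y)
  }
  tags <- lapply(seq_len(config$n_individuals), one_tag)

  truth <- purrr::map_dfr(tags, function(tg) {
    tibble::tibble(tag_id = tg$tag_id, signal = seq_along(tg$times),
                   time = tg$times, x = tg$traj[, 1], y = tg$traj[, 2],
                   n_detections = rowSums(tg$Y))
  })
  detections <- purrr::map_dfr(tags, function(tg) {
    idx <- which(tg$Y == 1, arr.ind = TRUE)
    if (!nrow(idx)) return(tibble::tibble(tag_id = character(),
                                          receiver_id = character(),
                                          time = numeric()))
    tibble::tibble(tag_id = tg$tag_id,
                   receiver_id = receivers$receiver_id[idx[, 2]],
                   time = tg$times[idx[, 1]])
  })
  detections <- dplyr::arrange(detections, .data$tag_id, .data$time,
                               .data$receiver_id)
  structure(list(receivers = receivers, detections = detections,
                 truth = truth, space = space, config = config),
            class = "telemetry_sim")
}

#' @export
print.telemetry_sim <- function(x, ...) {
  cat("<telemetry_sim>", x$config$n_individuals, "tags,",
      nrow(x$receivers), "receivers,", nrow(x$truth), "signals,",
      nrow(x$detections), "detections\n")
  invisible(x)
}

#' Full signal schedule of a simulated dataset
#'
#' The per-tag emission times, as supplied to the known-interval model (for
#' which the schedule is assumed known by design).
#'
#' @param sim A `telemetry_sim` object.
#' @return Tibble with columns `tag_id`, `time`.
#' @export
sim_schedule <- function(sim) {
  stopifnot(inherits(sim, "telemetry_sim"))
  dplyr::select(sim$truth, "tag_id", "time")
}
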