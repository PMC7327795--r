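#' Tidy posterior parameter summaries
#'
#' One row per model parameter with posterior mean, standard deviation,
#' central 95% credible interval, and the split-chain potential scale
#' reduction factor (reported, never auto-failed on).
#'
#' @param x A `maloc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.maloc_fit <- function(x, ...) {
  pars <- setdiff(names(x$params), c("chain", "iter"))
  purrr::map_dfr(pars, function(p) {
    v <- x$params[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)),
                   rhat = split_rhat(v, x$params$chain))
  })
}

#' One-row fit summary
#'
#' @param x A `maloc_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, data dimensions, and sampler size.
#' @export
glance.maloc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_tags = length(x$tags),
    n_signals = sum(vapply(x$tags, function(tg) length(tg$times), integer(1))),
    n_receivers = nrow(x$receivers),
    n_chains = x$settings$n_chains,
    n_draws = nrow(x$params))
}

#' Per-signal localizations
#'
#' Posterior mean and standard deviation of every signal location in a fit.
#'
#' @param fit A `maloc_fit`.
#' @return Tibble: `tag_id`, `signal`, `time`, `detections`, `x`, `y`
#'   (posterior means), `sd_x`, `sd_y`.
#' @export
localize <- function(fit) {
  stopifnot(inherits(fit, "maloc_fit"))
  purrr::map_dfr(fit$tags, function(tg) {
    X <- matrix(tg$traj[, , 1], nrow = dim(tg$traj)[1])
    Y <- matrix(tg$traj[, , 2], nrow = dim(tg$traj)[1])
    tibble::tibble(tag_id = tg$tag_id, signal = seq_along(tg$times),
                   time = tg$times, detections = rowSums(tg$Y),
                   x = colMeans(X), y = colMeans(Y),
                   sd_x = apply(X, 2, sd), sd_y = apply(Y, 2, sd))
  })
}

#' Posterior trajectory draws in long form
#'
#' @param fit A `maloc_fit`.
#' @param tag_id Optional tag filter.
#' @param max_draws Cap on the number of draws returned per signal.
#' @return Tibble: `tag_id`, `draw`, `signal`, `time`, `x`, `y`.
#' @export
trajectory_draws <- function(fit, tag_id = NULL, max_draws = 500) {
  stopifnot(inherits(fit, "maloc_fit"))
  tags <- fit$tags
  if (!is.null(tag_id)) tags <- Filter(function(tg) tg$tag_id %in% tag_id, tags)
  purrr::map_dfr(tags, function(tg) {
    nk <- dim(tg$traj)[1]
    keep <- if (nk > max_draws) round(seq(1, nk, length.out = max_draws))
            else seq_len(nk)
    T_ <- length(tg$times)
    tibble::tibble(
      tag_id = tg$tag_id,
      draw = rep(keep, times = T_),
      signal = rep(seq_len(T_), each = length(keep)),
      time = rep(tg$times, each = length(keep)),
      x = as.vector(tg$traj[keep, , 1]),
      y = as.vector(tg$traj[keep, , 2]))
  })
}

#' Plot a fitted localization
#'
#' Receiver array, posterior draw clouds, and posterior mean trajectories.
#'
#' @param object A `maloc_fit`.
#' @param tag_id Optional tag filter.
#' @param max_draws Draws plotted per signal.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maloc_fit <- function(object, tag_id = NULL, max_draws = 100, ...) {
  dr <- trajectory_draws(object, tag_id = tag_id, max_draws = max_draws)
  mn <- localize(object)
  if (!is.null(tag_id)) mn <- mn[mn$tag_id %in% tag_id, ]
  ggplot2::ggplot() +
    ggplot2::geom_point(data = dr, ggplot2::aes(.data$x, .data$y),
                        colour = "grey60", alpha = 0.15, size = 0.4) +
    ggplot2::geom_path(data = mn, ggplot2::aes(.data$x, .data$y,
                                               group = .data$tag_id),
                       colour = "firebrick") +
    ggplot2::geom_point(data = object$receivers,
                        ggplot2::aes(.data$x, .data$y), shape = 4,
                        colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Movement-assisted localization:",
                                object$model),
                  x = NULL, y = NULL)
}

#' Plot a simulated dataset
#'
#' @param object A `telemetry_sim`.
#' @param ... Unused.
#' @return A ggplot object showing the array and the true trajectories,
#'   with detected signals filled.
#' @export
autoplot.telemetry_sim <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_path(data = object$truth,
                       ggplot2::aes(.data$x, .data$y, group = .data$tag_id),
                       colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_point(data = object$truth,
                        ggplot2::aes(.data$x, .data$y,
                                     shape = .data$n_detections > 0),
                        size = 0.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "detected") +
    ggplot2::geom_point(data = object$receivers,
                        ggplot2::aes(.data$x, .data$y), shape = 4,
                        colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
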