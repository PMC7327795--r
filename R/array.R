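#' Regular receiver grid
#'
#' Lay out `nx * ny` receivers on a regular grid with the given spacing,
#' origin at `(0, 0)`.
#'
#' @param nx,ny Number of receiver columns and rows (>= 1).
#' @param spacing Distance between adjacent receivers (> 0).
#' @return A tibble with columns `receiver_id`, `x`, `y`.
#' @examples
#' make_grid_array(10, 10, 1)
#' @export
make_grid_array <- function(nx, ny, spacing = 1) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  g <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                   y = (seq_len(ny) - 1) * spacing)
  tibble::tibble(receiver_id = paste0("r", seq_len(nrow(g))), x = g$x, y = g$y)
}

#' Rectangular state space
#'
#' The planar region over which source locations are assumed to lie.  The
#' default is the receiver bounding box expanded by `buffer` on every side.
#' Used as the support of the uniform location prior in independent
#' localization, and as the region over which initial positions are simulated.
#'
#' @param receivers Receiver table (columns `x`, `y`).
#' @param buffer Non-negative expansion of the bounding box, in coordinate
#'   units.  A common choice is five times the detection scale `sigma_det`.
#' @return An object of class `state_space` with fields `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @export
state_space <- function(receivers, buffer) {
  if (buffer < 0) stop("`buffer` must be non-negative", call. = FALSE)
  X <- receiver_coords(receivers)
  ss <- structure(
    list(xmin = min(X[, 1]) - buffer, xmax = max(X[, 1]) + buffer,
         ymin = min(X[, 2]) - buffer, ymax = max(X[, 2]) + buffer),
    class = "state_space")
  ss
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> [%.3g, %.3g] x [%.3g, %.3g]\n",
              x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

as_space_vec <- function(space) {
  stopifnot(inherits(space, "state_space"))
  c(space$xmin, space$xmax, space$ymin, space$ymax)
}

# Default estimation state space when none is supplied: receiver bounding box
# buffered by five times a detection-scale guess of 3/4 the typical receiver
# spacing (arrays are normally designed with sigma_det below the spacing).
default_space <- function(receivers) {
  state_space(receivers, buffer = 5 * 0.75 * median_spacing(receivers))
}

# Median nearest-neighbour distance between receivers.
median_spacing <- function(receivers) {
  X <- receiver_coords(receivers)
  if (nrow(X) < 2) return(1)
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}
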