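#' Admissible missed-signal counts for an inter-detection gap
#'
#' A gap of elapsed time `delta_obs` between two consecutive detected signals
#' must be tiled by `k` inter-signal intervals, each in `[a, b]`, summing to
#' `delta_obs`; `k` is therefore constrained to
#' `ceiling(delta_obs / b) <= k <= floor(delta_obs / a)`.  Under the default
#' counting convention a gap holding `n` missed signals is crossed by
#' `k = n + 1` intervals (the physically coherent count: `n` interior
#' emissions split the gap into `n + 1` segments).  The alternative `"n"`
#' convention takes `k = n` and is exposed because verbal descriptions of
#' missed-signal counts are sometimes ambiguous between the two.
#'
#' @param delta_obs Positive gap length (time units).
#' @param a,b Interval bounds, `0 < a <= b`.
#' @param convention `"n_plus_1"` (default) or `"n"`: how the number of
#'   missed signals maps to the number of tiling intervals.
#' @return Integer vector of admissible missed-signal counts (possibly
#'   empty: a gap shorter than `a` admits no tiling and is flagged as a
#'   zero-length gap class).
#' @examples
#' missed_signal_bounds(3, a = 1, b = 2)     # 1 or 2 missed signals
#' missed_signal_bounds(1.5, a = 1, b = 2)   # 0: the gap is one interval
#' @export
missed_signal_bounds <- function(delta_obs, a, b, convention = c("n_plus_1", "n")) {
  convention <- match.arg(convention)
  if (delta_obs <= 0) stop("`delta_obs` must be positive", call. = FALSE)
  if (a <= 0 || a > b) stop("need 0 < a <= b", call. = FALSE)
  koff <- if (convention == "n_plus_1") 1L else 0L
  k_min <- as.integer(ceiling(delta_obs / b - 1e-9))
  k_max <- as.integer(floor(delta_obs / a + 1e-9))
  k_min <- max(k_min, 1L)
  if (k_max < k_min) return(integer(0))
  n <- seq.int(k_min, k_max) - koff
  n[n >= 0L]
}

#' Signal-rate likelihood of a gap
#'
#' Normal approximation to the probability of observing a gap of length
#' `delta_obs` when it is tiled by `k` iid `Uniform(a, b)` intervals:
#' `delta_obs ~ Normal(k (a + b) / 2, k (b - a)^2 / 12)`, with `k` given by
#' the missed-signal counting convention (`k = n + 1` by default).  With a
#' degenerate schedule (`a == b`) the likelihood is a point mass and the
#' log-likelihood of any admissible count is 0.
#'
#' @inheritParams missed_signal_bounds
#' @param n Missed-signal count; must be admissible for this gap.
#' @return Log-likelihood (scalar).
#' @examples
#' gap_loglik(3, n = 1, a = 1, b = 2)
#' @export
gap_loglik <- function(delta_obs, n, a, b, convention = c("n_plus_1", "n")) {
  convention <- match.arg(convention)
  adm <- missed_signal_bounds(delta_obs, a, b, convention)
  if (!n %in% adm)
    stop("n = ", n, " is not admissible for this gap (admissible: ",
         if (length(adm)) paste(range(adm), collapse = "..") else "none", ")",
         call. = FALSE)
  k <- n + if (convention == "n_plus_1") 1L else 0L
  if (b - a < 1e-12) return(0)
  dnorm(delta_obs, k * (a + b) / 2, sqrt(k * (b - a)^2 / 12), log = TRUE)
}
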