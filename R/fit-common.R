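#' MCMC sampler settings
#'
#' @param n_chains Number of independent chains (run sequentially).
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burn Burn-in iterations discarded per chain; proposal scales
#'   adapt during burn-in toward a 25-45% acceptance rate.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer; chain `c` uses `seed + c - 1`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 15000, n_burn = 5000,
                          thin = 2, seed = NULL) {
  if (n_burn < 0 || n_iter <= n_burn)
    stop("need n_iter > n_burn >= 0", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_settings")
}

chain_seeds <- function(settings) {
  base <- if (is.null(settings$seed)) sample.int(2^31 - 10, 1) else settings$seed
  base + seq_len(settings$n_chains) - 1
}

# Initial locations: detected occasions at the mean coordinate of their
# detecting receivers; all-zero occasions by linear interpolation between the
# nearest detected occasions (constant extrapolation at the ends).  This
# guarantees a finite initial log-posterior.
init_locations <- function(Y, X) {
  T_ <- nrow(Y)
  u <- matrix(NA_real_, T_, 2)
  det_rows <- which(rowSums(Y) > 0)
  for (t in det_rows) {
    j <- which(Y[t, ] == 1)
    u[t, ] <- c(mean(X[j, 1]), mean(X[j, 2]))
  }
  if (!length(det_rows)) stop("tag has no detections", call. = FALSE)
  if (length(det_rows) == 1L) {
    u[, 1] <- u[det_rows, 1]; u[, 2] <- u[det_rows, 2]
  } else if (length(det_rows) < T_) {
    u[, 1] <- stats::approx(det_rows, u[det_rows, 1], xout = seq_len(T_),
                            rule = 2)$y
    u[, 2] <- stats::approx(det_rows, u[det_rows, 2], xout = seq_len(T_),
                            rule = 2)$y
  }
  u
}

# Crude movement-scale guess from initial locations and elapsed times.
init_sigma_u <- function(u_list, delta_list) {
  num <- 0; den <- 0
  for (i in seq_along(u_list)) {
    u <- u_list[[i]]; d <- delta_list[[i]]
    if (nrow(u) < 2) next
    inc <- diff(u)
    num <- num + sum(inc^2 / d[-1])
    den <- den + 2 * (nrow(u) - 1)
  }
  if (den == 0) return(0.5)
  max(sqrt(num / den), 1e-3)
}

half_diag <- function(space) {
  sqrt((space$xmax - space$xmin)^2 + (space$ymax - space$ymin)^2) / 2
}

# Assemble per-chain sampler outputs into one fit object.
assemble_fit <- function(model, chains, enc, receivers, space, settings,
                         par_names, extra = list()) {
  n_chains <- length(chains)
  params <- purrr::map_dfr(seq_len(n_chains), function(cidx) {
    p <- chains[[cidx]]$params
    colnames(p) <- par_names
    dplyr::bind_cols(tibble::tibble(chain = cidx, iter = seq_len(nrow(p))),
                     tibble::as_tibble(p))
  })
  tags <- purrr::map(seq_along(enc), function(i) {
    per_chain <- lapply(chains, function(ch) ch$traj[[i]])
    k <- vapply(per_chain, function(a) dim(a)[1], integer(1))
    T_ <- dim(per_chain[[1]])[2]
    traj <- array(NA_real_, c(sum(k), T_, 2))
    off <- 0
    for (ch in per_chain) {
      traj[off + seq_len(dim(ch)[1]), , ] <- ch
      off <- off + dim(ch)[1]
    }
    list(tag_id = enc[[i]]$tag_id, times = enc[[i]]$times, Y = enc[[i]]$Y,
         traj = traj)
  })
  structure(c(list(model = model, params = params, tags = tags,
                   space = space, settings = settings, receivers = receivers),
              extra),
            class = c(paste0("maloc_fit_", model), "maloc_fit"))
}

#' @export
print.maloc_fit <- function(x, ...) {
  cat("<maloc_fit>", x$model, "model:", length(x$tags), "tags,",
      sum(vapply(x$tags, function(tg) length(tg$times), integer(1))),
      "signals,", nrow(x$params), "posterior draws\n")
  print(tidy(x))
  invisible(x)
}

# Split-chain potential scale reduction factor of one parameter vector.
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(z) {
    h <- length(z) %/% 2
    if (h < 2) return(list(z))
    list(z[seq_len(h)], z[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- min(lengths(halves))
  if (m < 2 || n < 2) return(NA_real_)
  halves <- lapply(halves, function(z) z[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
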