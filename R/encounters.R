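#' Group detection records into per-signal encounter vectors
#'
#' Field receivers log `(tag, receiver, time)` rows independently; detections
#' of one signal at several receivers share (approximately) one time stamp.
#' Records of a tag are sorted by time and clustered: a record starts a new
#' signal when its time exceeds the first time of the current cluster by more
#' than `tol`.  Each cluster becomes one binary encounter vector over all
#' receivers, stamped with the cluster's first time.
#'
#' @param detections Tibble with columns `tag_id`, `receiver_id`, `time`.
#' @param receivers Receiver table (`receiver_id`, `x`, `y`).
#' @param tol Time-binning tolerance.  Defaults to half the minimum
#'   inter-signal interval when known (pass `a / 2`), else 1 time unit is a
#'   reasonable field default; simultaneous simulated detections share exact
#'   times, so any small tolerance works there.
#' @return A list with one element per tag: `tag_id`, `times` (one per
#'   signal), and binary matrix `Y` (signals x receivers, receiver order as
#'   in `receivers`).
#' @export
build_encounters <- function(detections, receivers, tol = 1e-6) {
  check_detections(detections, receivers)
  if (!nrow(detections))
    stop("no detection records: nothing to localize", call. = FALSE)
  J <- nrow(receivers)
  ridx <- setNames(seq_len(J), receivers$receiver_id)
  detections <- dplyr::arrange(detections, .data$tag_id, .data$time)
  split_det <- split(detections, detections$tag_id)
  lapply(split_det, function(d) {
    # cluster by time: new signal when time - cluster start > tol
    t0 <- d$time[1]
    sig <- integer(nrow(d))
    s <- 1L
    for (k in seq_len(nrow(d))) {
      if (d$time[k] - t0 > tol) { s <- s + 1L; t0 <- d$time[k] }
      sig[k] <- s
    }
    times <- tapply(d$time, sig, function(z) z[1])
    Y <- matrix(0L, nrow = max(sig), ncol = J)
    Y[cbind(sig, ridx[d$receiver_id])] <- 1L
    list(tag_id = d$tag_id[1], times = as.numeric(times), Y = Y)
  })
}

check_detections <- function(detections, receivers) {
  need <- c("tag_id", "receiver_id", "time")
  miss <- setdiff(need, names(detections))
  if (length(miss))
    stop("`detections` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(detections)) {
    if (!is.numeric(detections$time)) {
      bad <- which(is.na(suppressWarnings(as.numeric(detections$time))))
      stop("non-numeric `time` values at row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    unknown <- !detections$receiver_id %in% receivers$receiver_id
    if (any(unknown))
      stop("unknown receiver_id at row(s) ",
           paste(head(which(unknown), 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
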