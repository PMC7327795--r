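#' Read and write telemetry tables
#'
#' Plain-CSV interchange for the two field inputs: receiver coordinates
#' (header exactly `receiver_id,x,y`) and detection records (header exactly
#' `tag_id,receiver_id,time`).  Values round-trip at full precision;
#' detections are sorted by `(tag_id, time)` on load.  Parse problems are
#' reported with row numbers.
#'
#' @param path File path.
#' @return `read_receivers()`: a receiver tibble; `read_detections()`: a
#'   detections tibble.
#' @name telemetry_io
NULL

#' @rdname telemetry_io
#' @export
read_receivers <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("receiver file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in c("x", "y")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[cl]]))))
    if (length(bad))
      stop("non-numeric `", cl, "` in receiver file at row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    d[[cl]] <- as.numeric(d[[cl]])
  }
  if (anyDuplicated(d$receiver_id))
    stop("duplicate receiver_id values", call. = FALSE)
  tibble::as_tibble(d[need])
}

#' @rdname telemetry_io
#' @param receivers,detections Tables to write.
#' @export
write_receivers <- function(receivers, path) {
  write.csv(receivers[c("receiver_id", "x", "y")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname telemetry_io
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "receiver_id", "time")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("detections file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d$time))))
    if (length(bad))
      stop("non-numeric `time` in detections file at row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    d$time <- as.numeric(d$time)
  }
  d <- tibble::as_tibble(d[need])
  dplyr::arrange(d, .data$tag_id, .data$time)
}

#' @rdname telemetry_io
#' @export
write_detections <- function(detections, path) {
  write.csv(detections[c("tag_id", "receiver_id", "time")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Record the configuration, seed, and content hashes of the input files of
#' an analysis run, sufficient to reproduce its deterministic stages
#' bit-for-bit.
#'
#' @param path Output file (YAML-formatted key/value lines).
#' @param config Named list of configuration values (scalars).
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input file paths to hash (md5).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character()) {
  lines <- c("# moveloc run manifest",
             paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(seed)) lines <- c(lines, paste0("seed: ", seed))
  for (nm in names(config)) {
    v <- config[[nm]]
    if (is.null(v) || length(v) != 1 || is.list(v)) next
    lines <- c(lines, paste0(nm, ": ", format(v)))
  }
  if (length(inputs)) {
    lines <- c(lines, "inputs:")
    for (f in inputs) {
      h <- unname(tools::md5sum(f))
      lines <- c(lines, paste0("  - path: ", f), paste0("    md5: ", h))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write posterior draws as CSV
#'
#' Long-format parameter draws (`chain`, `iter`, `param`, `value`), the
#' interchange format used by the command-line interface.
#'
#' @param fit A `maloc_fit`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_param_draws <- function(fit, path) {
  stopifnot(inherits(fit, "maloc_fit"))
  long <- tidyr::pivot_longer(fit$params, -c("chain", "iter"),
                              names_to = "param", values_to = "value")
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
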