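#' A single fluorescence trace
#'
#' @param time Uniform, strictly increasing time grid, minutes.
#' @param values Fluorescence values, arbitrary units.
#' @param label Condition identifier.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(time, values, label = "trace") {
  time <- as.numeric(time); values <- as.numeric(values)
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (length(time) < 2L || any(diff(time) <= 0))
    stop("time must be strictly increasing")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1))
    stop("non-uniform time grid; traces are analysed on uniform grids only")
  structure(list(time = time, values = values, label = label),
            class = "fluor_trace")
}

#' Normalise a trace to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1, preserving
#' order.  A trace with zero dynamic range cannot be normalised; it is
#' returned unchanged with a `degenerate` attribute so the downstream
#' flat-trace path applies (never divides by zero).
#'
#' @param trace A [fluor_trace()].
#' @return The normalised `fluor_trace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  rng <- range(trace$values)
  if (diff(rng) == 0) {
    attr(trace, "degenerate") <- TRUE
    return(trace)
  }
  trace$values <- (trace$values - rng[1]) / diff(rng)
  attr(trace, "degenerate") <- FALSE
  trace
}

#' Extract the switching time (Cq) of a fluorescence trace
#'
#' The trace is normalised to `[0, 1]`; forward differences between
#' points `window` minutes apart are computed for every start point whose
#' window still fits (start points in the final `window` minutes are
#' excluded); Cq is the earliest start time attaining the maximum
#' difference, i.e. the onset of the steepest fluorescence rise.  Flat
#' traces are assigned `inv_cq = 0`: a trace is called flat when its raw
#' dynamic range is below `min_range` (so that pure measurement noise is
#' not normalised into a fake response) or when the maximum normalised
#' window difference is below `flat_threshold`.
#'
#' @param trace A [fluor_trace()] (raw; normalisation is applied
#'   internally).
#' @param window Difference window, minutes; must be a multiple of the
#'   grid spacing (default 10).
#' @param flat_threshold Minimum normalised window difference for a trace
#'   to count as switching (default 0.05).
#' @param min_range Minimum raw dynamic range, in the trace's fluorescence
#'   units, for a trace to count as switching (default 0.05).
#' @return A `cq_result`: list with `cq` (minutes, `NA` when flat),
#'   `inv_cq` (per minute, 0 when flat), `flat`, `max_diff` (maximum
#'   normalised window difference) and `label`.
#' @export
extract_cq <- function(trace, window = 10, flat_threshold = 0.05,
                       min_range = 0.05) {
  stopifnot(inherits(trace, "fluor_trace"))
  dt <- trace$time[2] - trace$time[1]
  steps <- window / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("window must be a multiple of the grid spacing")
  steps <- as.integer(round(steps))
  n <- length(trace$values)
  if (n <= steps)
    stop("trace '", trace$label, "' shorter than the difference window")

  raw_range <- diff(range(trace$values))
  norm <- normalize_trace(trace)
  if (isTRUE(attr(norm, "degenerate")) || raw_range < min_range) {
    return(structure(list(cq = NA_real_, inv_cq = 0, flat = TRUE,
                          max_diff = 0, label = trace$label),
                     class = "cq_result"))
  }
  v <- norm$values
  d <- v[(steps + 1L):n] - v[1L:(n - steps)]
  max_diff <- max(d)
  # earliest start point wins on ties (up to floating-point noise)
  i <- which(d >= max_diff - 1e-9)[1L]
  if (max_diff < flat_threshold) {
    return(structure(list(cq = NA_real_, inv_cq = 0, flat = TRUE,
                          max_diff = max_diff, label = trace$label),
                     class = "cq_result"))
  }
  cq <- trace$time[i]
  structure(list(cq = cq, inv_cq = 1 / cq, flat = FALSE,
                 max_diff = max_diff, label = trace$label),
            class = "cq_result")
}

#' @export
print.cq_result <- function(x, ...) {
  if (x$flat) cat("<cq_result> '", x$label, "': flat (1/Cq = 0)\n", sep = "")
  else cat(sprintf("<cq_result> '%s': Cq = %g min (1/Cq = %.5g /min)\n",
                   x$label, x$cq, x$inv_cq))
  invisible(x)
}

#' Cq extraction over a whole trace set
#'
#' Applies [normalize_trace()] + [extract_cq()] to every trace,
#' preserving the set's condition annotations.  Deterministic; per-trace
#' errors are re-raised with the offending condition label.
#'
#' @param ts A [trace_set()].
#' @inheritParams extract_cq
#' @param min_range Minimum raw dynamic range for a trace to count as
#'   switching.  Default `NULL`: resolved to 5% of the set's fluorescence
#'   full scale (the `full_scale` recorded on simulated sets, otherwise
#'   the largest dynamic range in the set), so sub-threshold reporter
#'   creep and pure noise are assigned `1/Cq = 0`.
#' @return A data frame with the set's condition columns plus `cq_min`,
#'   `inv_cq`, `flat` and `max_diff`.
#' @export
batch_cq <- function(ts, window = 10, flat_threshold = 0.05,
                     min_range = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(min_range)) {
    scale <- ts$full_scale %||%
      (if (nrow(ts$traces)) max(apply(ts$traces, 1,
                                      function(v) diff(range(v)))) else 1)
    min_range <- 0.05 * scale
  }
  n <- nrow(ts$traces)
  out <- ts$conditions
  out$cq_min <- rep(NA_real_, n)
  out$inv_cq <- rep(NA_real_, n)
  out$flat <- rep(NA, n)
  out$max_diff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      extract_cq(fluor_trace(ts$time, ts$traces[i, ],
                             label = ts$conditions$label[i]),
                 window = window, flat_threshold = flat_threshold,
                 min_range = min_range),
      error = function(e) stop("condition '", ts$conditions$label[i],
                               "': ", conditionMessage(e), call. = FALSE))
    out$cq_min[i] <- res$cq
    out$inv_cq[i] <- res$inv_cq
    out$flat[i] <- res$flat
    out$max_diff[i] <- res$max_diff
  }
  attr(out, "cq_params") <- list(window = window,
                                 flat_threshold = flat_threshold,
                                 min_range = min_range)
  out
}
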