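#' Construct a set of fluorescence time traces
#'
#' A `trace_set` holds minute-sampled reporter fluorescence for one or
#' more conditions on a shared, strictly increasing, uniform time grid.
#'
#' @param time Time grid, minutes.
#' @param traces Numeric matrix, one row per condition.
#' @param conditions Data frame with one row per trace; must contain a
#'   `label` column.
#' @param flags Character vector of quality flags attached to the set.
#' @param full_scale Fluorescence full scale of the measurement, in the
#'   trace units (e.g. the total reporter-template concentration for
#'   simulated traces); used to resolve the default flat-trace range
#'   threshold in [batch_cq()].  `NULL` when unknown.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(time, traces, conditions = NULL, flags = character(),
                      full_scale = NULL) {
  time <- as.numeric(time)
  if (length(time) < 2L || any(diff(time) <= 0))
    stop("time must be strictly increasing")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniform")
  traces <- as.matrix(traces)
  if (ncol(traces) != length(time))
    stop("traces must have one column per time point")
  if (is.null(conditions))
    conditions <- data.frame(
      label = if (!is.null(rownames(traces))) rownames(traces)
              else paste0("trace", seq_len(nrow(traces))),
      stringsAsFactors = FALSE)
  if (!is.data.frame(conditions) || nrow(conditions) != nrow(traces) ||
      !"label" %in% names(conditions))
    stop("conditions must be a data frame with a 'label' column, one row per trace")
  rownames(traces) <- conditions$label
  structure(list(time = time, traces = traces, conditions = conditions,
                 flags = as.character(flags), full_scale = full_scale),
            class = "trace_set")
}

#' Bind several trace sets on a shared time grid
#'
#' @param ... `trace_set` objects with identical time grids.
#' @return A combined `trace_set`.
#' @export
bind_traces <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "trace_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "trace_set")))
  t0 <- sets[[1]]$time
  for (s in sets)
    if (!isTRUE(all.equal(s$time, t0))) stop("time grids differ")
  conds <- do.call(rbind, lapply(sets, function(s) {
    cn <- unique(unlist(lapply(sets, function(x) names(x$conditions))))
    for (m in setdiff(cn, names(s$conditions))) s$conditions[[m]] <- NA
    s$conditions[cn]
  }))
  fs <- unlist(lapply(sets, `[[`, "full_scale"))
  trace_set(t0, do.call(rbind, lapply(sets, `[[`, "traces")), conds,
            flags = unique(unlist(lapply(sets, `[[`, "flags"))),
            full_scale = if (length(fs)) max(fs) else NULL)
}

#' Add measurement noise to a trace set
#'
#' Multiplicative Gaussian noise of relative standard deviation
#' `sigma_rel` per sample, plus an optional linear baseline drift.
#' Reproducible for a given seed; with `sigma_rel = 0` and `drift = 0`
#' the input is returned unchanged.  Fluorescence is clipped at zero.
#'
#' @param ts A [trace_set()].
#' @param sigma_rel Relative noise standard deviation (>= 0).
#' @param drift Linear drift slope, fluorescence units per minute.
#' @param seed Integer RNG seed (required when `sigma_rel > 0`).
#' @return A noisy `trace_set`; the noise settings are recorded in the
#'   `noise` attribute.
#' @export
add_noise <- function(ts, sigma_rel = 0.02, drift = 0, seed = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  if (!is.numeric(sigma_rel) || sigma_rel < 0)
    stop("sigma_rel must be >= 0")
  if (sigma_rel == 0 && drift == 0) return(ts)
  if (sigma_rel > 0) {
    if (is.null(seed)) stop("a seed is required for noisy generation")
    set.seed(as.integer(seed))
  }
  scale <- max(abs(ts$traces), 1e-12)
  eps <- matrix(stats::rnorm(length(ts$traces), sd = sigma_rel),
                nrow = nrow(ts$traces))
  # relative to the set's full scale so flat traces get absolute noise too
  vals <- ts$traces + eps * pmax(abs(ts$traces), 0.02 * scale) +
    drift * matrix(ts$time, nrow = nrow(ts$traces), ncol = ncol(ts$traces),
                   byrow = TRUE)
  vals <- pmax(vals, 0)
  out <- trace_set(ts$time, vals, ts$conditions, flags = ts$flags,
                   full_scale = ts$full_scale)
  out$conditions$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "noise") <- list(sigma_rel = sigma_rel, drift = drift, seed = seed)
  out
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", nrow(x$traces), " trace(s) x ", length(x$time),
      " time points (", x$time[1], "-", utils::tail(x$time, 1), " min)\n",
      sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  df <- data.frame(time_min = x$time, t(x$traces), check.names = FALSE)
  names(df) <- c("time_min", x$conditions$label)
  df
}
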