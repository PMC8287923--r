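#' Hill response function
#'
#' `increasing`: \eqn{b + A\,c^n/(K^n + c^n)};
#' `decreasing`: \eqn{b + A\,K^n/(K^n + c^n)}.
#' Evaluated in linear concentration space so `c = 0` is a valid point.
#'
#' @param conc Concentration(s), uM.
#' @param baseline Response at the low end, per minute.
#' @param amplitude Response span, per minute.
#' @param kd Apparent half-effect concentration, uM (> 0).
#' @param n Hill coefficient (> 0).
#' @param direction `"increasing"` or `"decreasing"`.
#' @return Response value(s), per minute.
#' @export
hill_response <- function(conc, baseline, amplitude, kd, n,
                          direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(kd > 0, n > 0, all(conc >= 0))
  f <- conc^n / (kd^n + conc^n)
  if (direction == "decreasing") f <- 1 - f
  baseline + amplitude * f
}

#' Assemble a dose-response curve from per-trace Cq results
#'
#' Averages replicate `1/Cq` values per concentration.  Flat replicates
#' enter the mean as 0.  Following the error convention of the reference
#' workflow, the error bar is the maximum absolute single-replicate
#' deviation from its group mean, taken over the whole data set and
#' applied uniformly to every concentration.
#'
#' @param cq A data frame from [batch_cq()] (or equivalent) with an
#'   `inv_cq` column.
#' @param conc_col Name of the concentration column to group by.
#' @param ligand Ligand name recorded on the curve (defaults to
#'   `conc_col`).
#' @return An object of class `dose_response`: data frame with columns
#'   `conc`, `inv_cq_mean`, `inv_cq_err`, `n_replicates`, sorted by
#'   increasing concentration.
#' @export
assemble_dose_response <- function(cq, conc_col = "conc", ligand = conc_col) {
  stopifnot(is.data.frame(cq), "inv_cq" %in% names(cq))
  if (!conc_col %in% names(cq))
    stop("no column '", conc_col, "' in the Cq table")
  conc <- cq[[conc_col]]
  if (anyNA(conc)) stop("missing concentrations")
  groups <- sort(unique(conc))
  m <- vapply(groups, function(g) mean(cq$inv_cq[conc == g]), 0)
  dev <- abs(cq$inv_cq - m[match(conc, groups)])
  err <- if (length(dev)) max(dev) else 0
  nrep <- vapply(groups, function(g) sum(conc == g), 0L)
  if (length(unique(nrep)) > 1L)
    warning("unequal replicate counts across concentrations", call. = FALSE)
  out <- data.frame(conc = groups, inv_cq_mean = m,
                    inv_cq_err = rep(err, length(groups)),
                    n_replicates = nrep)
  class(out) <- c("dose_response", "data.frame")
  attr(out, "ligand") <- ligand
  out
}

#' Fit a Hill function to a dose-response curve
#'
#' Four-parameter fit (baseline, amplitude, apparent Kd, Hill
#' coefficient) of [hill_response()] by Levenberg-Marquardt least squares
#' with multi-start initialisation: Kd is started at the geometric mean
#' of the positive concentrations (and a decade either side) and the Hill
#' coefficient at 1, 2 and 8, because steep fits have narrow convergence
#' basins.  The fit is unweighted and performed in linear concentration
#' space, so zero-concentration points are retained.  Direction is
#' inferred from the Spearman rank correlation of concentration and
#' response unless supplied.
#'
#' @param curve A [assemble_dose_response()] result, or any data frame
#'   with `conc` and `inv_cq_mean` columns.
#' @param direction `"auto"` (default), `"increasing"` or `"decreasing"`.
#' @return An object of class `hill_fit`: list with `baseline`,
#'   `amplitude`, `kd_app`, `n_hill`, `direction`, `residual_norm` and
#'   the fitted model.
#' @export
fit_hill <- function(curve, direction = c("auto", "increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(curve),
            all(c("conc", "inv_cq_mean") %in% names(curve)))
  conc <- curve$conc
  resp <- curve$inv_cq_mean
  if (length(conc) < 4L)
    stop("at least 4 distinct concentrations are required for a Hill fit")
  span <- diff(range(resp))
  if (span <= 0 || span < 1e-12)
    stop("no response to fit: curve '", attr(curve, "ligand") %||% "curve",
         "' is flat")
  if (direction == "auto") {
    rho <- suppressWarnings(
      stats::cor(conc, resp, method = "spearman"))
    if (is.na(rho) || rho == 0)
      stop("cannot infer direction for curve '",
           attr(curve, "ligand") %||% "curve", "'")
    direction <- if (rho > 0) "increasing" else "decreasing"
  }

  pos <- conc[conc > 0]
  k_gm <- exp(mean(log(pos)))
  starts <- expand.grid(K = c(k_gm / 10, k_gm, k_gm * 10), n = c(1, 2, 8))
  b0 <- min(resp)
  a0 <- max(span, 1e-9)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      resp ~ hill_response(conc, b, a, K, n, direction = direction),
      start = list(b = b0, a = a0, K = starts$K[i], n = starts$n[i]),
      lower = c(b = -Inf, a = 1e-12, K = 1e-9, n = 1e-3),
      upper = c(b = Inf, a = Inf, K = Inf, n = 100),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Hill fit did not converge for curve '",
         attr(curve, "ligand") %||% "curve", "'")
  cf <- stats::coef(best$fit)
  structure(list(baseline = unname(cf["b"]), amplitude = unname(cf["a"]),
                 kd_app = unname(cf["K"]), n_hill = unname(cf["n"]),
                 direction = direction,
                 residual_norm = sqrt(best$rss),
                 model = best$fit),
            class = "hill_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("<hill_fit> %s: Kd(app) = %.4g uM, n = %.4g, ",
                     "baseline = %.4g, amplitude = %.4g /min ",
                     "(residual norm %.3g)\n"),
              x$direction, x$kd_app, x$n_hill, x$baseline, x$amplitude,
              x$residual_norm))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, conc, ...) {
  hill_response(conc, object$baseline, object$amplitude, object$kd_app,
                object$n_hill, object$direction)
}
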