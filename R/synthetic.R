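#' Generate a logistic switch-activation trace
#'
#' The canonical shape of a fired switch: a sigmoid rising from baseline
#' to `baseline + amplitude` with midpoint `t_mid` and slope scale `tau`.
#'
#' @param time Time grid, minutes.
#' @param t_mid Midpoint (steepest rise), minutes.
#' @param tau Logistic time scale, minutes.
#' @param baseline Baseline fluorescence, a.u.
#' @param amplitude Fluorescence span, a.u.
#' @return Numeric vector of fluorescence values.
#' @export
synth_logistic_trace <- function(time, t_mid, tau = 5, baseline = 0,
                                 amplitude = 1) {
  baseline + amplitude * stats::plogis((time - t_mid) / tau)
}

#' Generate a synthetic dose-response trace set from a Hill law
#'
#' Emulates the study design of a ligand titration read out by switching
#' time: the response `1/Cq` follows [hill_response()] in the ligand
#' concentration, each condition is rendered as a logistic trace whose
#' steepest 10-min rise starts at `Cq = 1/response`, replicates receive
#' independent multiplicative noise.  Used for estimator-recovery
#' studies where the ground-truth Hill parameters must be known exactly.
#'
#' @param concs Ligand concentrations, uM.
#' @param kd,n Ground-truth Hill parameters.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param baseline_inv Response floor, per minute (slowest Cq).
#' @param amplitude_inv Response span, per minute.
#' @param replicates Replicates per concentration.
#' @param duration Trace length, minutes (must exceed the slowest Cq
#'   plus the difference window).
#' @param tau Logistic time scale of the traces, minutes.
#' @param window Difference window the traces are designed for, minutes.
#' @param sigma_rel Relative measurement noise (0 = noise-free).
#' @param seed RNG seed (required when `sigma_rel > 0`).
#' @return A [trace_set()] whose conditions carry `conc` and `replicate`
#'   columns.
#' @export
synth_hill_traceset <- function(concs, kd, n,
                                direction = c("increasing", "decreasing"),
                                baseline_inv = 1 / 360,
                                amplitude_inv = 1 / 60 - 1 / 360,
                                replicates = 3, duration = 480, tau = 5,
                                window = 10, sigma_rel = 0, seed = NULL) {
  direction <- match.arg(direction)
  r <- hill_response(concs, baseline_inv, amplitude_inv, kd, n, direction)
  cq_target <- 1 / r
  if (max(cq_target) > duration - 2 * window)
    stop("duration too short for the slowest target Cq (",
         round(max(cq_target)), " min)")
  time <- seq(0, duration, by = 1)
  # the steepest forward window of a symmetric sigmoid starts window/2
  # before the midpoint, so place the midpoint at Cq + window/2
  rows <- vector("list", length(concs) * replicates)
  conds <- vector("list", length(rows))
  k <- 0L
  for (i in seq_along(concs)) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      rows[[k]] <- synth_logistic_trace(time, cq_target[i] + window / 2,
                                        tau = tau, amplitude = 10)
      conds[[k]] <- data.frame(
        label = sprintf("c%.6g_r%d", concs[i], rep_i),
        conc = concs[i], replicate = rep_i, stringsAsFactors = FALSE)
    }
  }
  ts <- trace_set(time, do.call(rbind, rows), do.call(rbind, conds),
                  full_scale = 10)
  if (sigma_rel > 0) ts <- add_noise(ts, sigma_rel = sigma_rel, seed = seed)
  ts
}
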