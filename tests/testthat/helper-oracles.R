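# Independent oracles and small generators used across test files.

# Brute-force Cq oracle: explicit all-pairs scan over every start/end pair
# exactly `window` minutes apart, with the same flat rules, written without
# vectorised shortcuts so it shares no code path with extract_cq().
brute_cq <- function(time, values, window = 10, flat_threshold = 0.05,
                     min_range = 0.05) {
  if (diff(range(values)) < min_range || diff(range(values)) == 0)
    return(list(cq = NA_real_, inv_cq = 0, flat = TRUE))
  v <- (values - min(values)) / (max(values) - min(values))
  best_d <- -Inf
  best_t <- NA_real_
  for (i in seq_along(time)) {
    # all end points exactly `window` minutes after this start point
    for (j in which(abs(time - time[i] - window) < 1e-9)) {
      d <- v[j] - v[i]
      if (d > best_d + 1e-9) {  # strict improvement => earliest tie wins
        best_d <- d
        best_t <- time[i]
      }
    }
  }
  if (best_d < flat_threshold)
    return(list(cq = NA_real_, inv_cq = 0, flat = TRUE))
  list(cq = best_t, inv_cq = 1 / best_t, flat = FALSE)
}

# Bisection oracle for the two-species binding equilibrium: the bound
# concentration solves (P - b)(T - b) = Kd * b on [0, min(P, T)],
# independent of the closed-form quadratic root.
binding_bisect <- function(tf_total, template_total, kd, tol = 1e-12) {
  g <- function(b) (tf_total - b) * (template_total - b) - kd * b
  lo <- 0
  hi <- min(tf_total, template_total)
  if (g(hi) >= 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Random trace generator covering sigmoids, ramps, walks and flats.
random_trace <- function(seed) {
  set.seed(seed)
  n <- sample(30:500, 1)
  time <- seq(0, n - 1)
  kind <- sample(4, 1)
  values <- switch(kind,
    # noisy sigmoid
    10 * plogis((time - runif(1, 12, n - 12)) / runif(1, 2, 15)) +
      rnorm(n, sd = 0.1),
    # monotone random walk
    cumsum(abs(rnorm(n, sd = 0.3))),
    # near-flat noise
    rnorm(n, mean = 5, sd = runif(1, 0.001, 0.2)),
    # ramp plus blip
    0.02 * time + c(rep(0, n %/% 2), rep(runif(1, 0, 2), n - n %/% 2)) +
      rnorm(n, sd = 0.05))
  list(time = time, values = values)
}

# Shared circuit shorthands (cheap constructors, no simulation).
fast_switch <- function(...) switch_circuit(...)
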