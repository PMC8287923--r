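test_that("sourceless switch stays at baseline", {
  ts <- simulate_circuit(switch_circuit(), duration = 300)
  expect_lt(max(ts$traces), 1e-6)
  expect_true(batch_cq(ts)$flat)
})

test_that("initial signal separates flat and fired outcomes around a unique threshold", {
  sw <- switch_circuit()
  thr <- switching_threshold(sw, tol = 0.01)
  expect_gt(thr, 0)
  low <- sw; low$initial_signal <- 0.1 * thr
  high <- sw; high$initial_signal <- 10 * thr
  expect_true(batch_cq(simulate_circuit(low, duration = 600))$flat)
  expect_false(batch_cq(simulate_circuit(high, duration = 600))$flat)
  # outcome is monotone in the initial signal, so the threshold is unique
  fired <- vapply(thr * c(0.1, 0.5, 2, 10), function(s0) {
    sp <- sw; sp$initial_signal <- s0
    utils::tail(simulate_circuit(sp, duration = 600)$traces[1, ], 1) > 5
  }, TRUE)
  expect_true(all(diff(fired) >= 0))
})

test_that("raising the threshold sink delays switching", {
  cqs <- vapply(c(4, 5, 6, 7, 8), function(pt) {
    cq <- batch_cq(simulate_circuit(direct_lacI_circuit(tf_dimer = 0,
                                                        pT = pt)))
    ifelse(cq$flat, Inf, cq$cq_min)
  }, 0)
  expect_true(all(diff(cqs) >= 0))
})

test_that("measurement noise is reproducible and bounded in its Cq effect", {
  ts <- simulate_circuit(direct_lacI_circuit(tf_dimer = 0), duration = 400)
  expect_identical(add_noise(ts, sigma_rel = 0, drift = 0), ts)
  n1 <- add_noise(ts, sigma_rel = 0.02, seed = 11)
  n2 <- add_noise(ts, sigma_rel = 0.02, seed = 11)
  expect_identical(n1$traces, n2$traces)
  expect_false(identical(add_noise(ts, sigma_rel = 0.02, seed = 12)$traces,
                         n1$traces))
  expect_error(add_noise(ts, sigma_rel = 0.02), "seed")

  # 2% noise moves the Cq of a sharp sigmoid by at most the grid scale
  time <- 0:300
  sig <- trace_set(time, matrix(10 * plogis((time - 150) / 5), nrow = 1),
                   data.frame(label = "sig"), full_scale = 10)
  cq0 <- batch_cq(sig)$cq_min
  shifts <- vapply(1:100, function(s)
    batch_cq(add_noise(sig, sigma_rel = 0.02, seed = s))$cq_min - cq0, 0)
  expect_lte(max(abs(shifts)), 3)
})
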