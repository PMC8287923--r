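test_that("replicate assembly uses the maximum single-point deviation as error", {
  cq <- data.frame(conc = rep(10, 3), inv_cq = c(0.010, 0.011, 0.013))
  cv <- assemble_dose_response(cq)
  expect_equal(cv$inv_cq_mean, mean(c(0.010, 0.011, 0.013)))
  expect_equal(cv$inv_cq_err, 0.013 - mean(c(0.010, 0.011, 0.013)))
  expect_equal(cv$n_replicates, 3L)
  # identical replicates give zero error bars
  same <- assemble_dose_response(data.frame(conc = rep(1, 3),
                                            inv_cq = rep(0.02, 3)))
  expect_equal(same$inv_cq_err, 0)
})

test_that("flat replicates enter the mean as zero and the error is uniform", {
  cq <- data.frame(conc = rep(c(1, 10), each = 3),
                   inv_cq = c(0, 0.009, 0.012, 0.019, 0.020, 0.021))
  cv <- assemble_dose_response(cq)
  expect_equal(cv$inv_cq_mean[1], mean(c(0, 0.009, 0.012)))
  # max deviation anywhere (the flat replicate) applied to every point
  expect_equal(cv$inv_cq_err, rep(0.007, 2))
})

test_that("Hill fits round-trip noise-free curves across the studied regimes", {
  concs <- 10^seq(0, 3, length.out = 10)
  grid <- expand.grid(K = c(24, 69, 100, 500), n = c(1, 1.9, 10.5),
                      dir = c("increasing", "decreasing"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    y <- hill_response(concs, baseline = 0.002, amplitude = 0.014,
                       kd = grid$K[i], n = grid$n[i], direction = grid$dir[i])
    fit <- fit_hill(data.frame(conc = concs, inv_cq_mean = y))
    expect_equal(fit$direction, grid$dir[i])
    expect_equal(fit$kd_app, grid$K[i], tolerance = 1e-6)
    expect_equal(fit$n_hill, grid$n[i], tolerance = 1e-6)
    expect_equal(fit$baseline, 0.002, tolerance = 1e-5)
    expect_equal(fit$amplitude, 0.014, tolerance = 1e-5)
  }
})

test_that("fitted response at the apparent Kd is the half-amplitude point", {
  concs <- c(0, 10^seq(-1, 3, length.out = 9))
  y <- hill_response(concs, 0, 1, kd = 10, n = 1, direction = "increasing")
  fit <- fit_hill(data.frame(conc = concs, inv_cq_mean = y))
  expect_equal(predict(fit, 10), 0.5, tolerance = 1e-6)
})

test_that("concentration rescaling rescales Kd and leaves the Hill coefficient", {
  concs <- 10^seq(0, 3, length.out = 10)
  y <- hill_response(concs, 0.001, 0.012, kd = 40, n = 3,
                     direction = "increasing")
  f1 <- fit_hill(data.frame(conc = concs, inv_cq_mean = y))
  f2 <- fit_hill(data.frame(conc = concs * 7, inv_cq_mean = y))
  expect_equal(f2$kd_app / f1$kd_app, 7, tolerance = 1e-6)
  expect_equal(f2$n_hill, f1$n_hill, tolerance = 1e-6)
})

test_that("degenerate curves are rejected with informative errors", {
  flat <- data.frame(conc = 10^(0:5), inv_cq_mean = rep(0.01, 6))
  expect_error(fit_hill(flat), "no response to fit")
  short <- data.frame(conc = c(1, 10, 100), inv_cq_mean = c(0, 0.5, 1))
  expect_error(fit_hill(short), "at least 4")
})
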