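test_that("normalisation maps the range onto [0, 1] affinely", {
  tr <- fluor_trace(0:2, c(100, 200, 300))
  expect_equal(normalize_trace(tr)$values, c(0, 0.5, 1))
  ident <- fluor_trace(0:3, c(0, 0.25, 0.75, 1))
  expect_equal(normalize_trace(ident)$values, ident$values)
  flat <- normalize_trace(fluor_trace(0:4, rep(5, 5)))
  expect_true(attr(flat, "degenerate"))
  expect_equal(flat$values, rep(5, 5))  # untouched, no division by zero
})

test_that("Cq of a symmetric sigmoid is the window start at the inflection", {
  time <- 0:240
  tr <- fluor_trace(time, plogis((time - 120) / 5))
  res <- extract_cq(tr)
  expect_false(res$flat)
  expect_equal(res$cq, 115)
  expect_equal(res$inv_cq, 1 / 115)
  oracle <- brute_cq(time, tr$values)
  expect_equal(res$cq, oracle$cq)
})

test_that("flat and degenerate traces are assigned 1/Cq = 0", {
  res <- extract_cq(fluor_trace(0:100, rep(3, 101)))
  expect_true(res$flat)
  expect_identical(res$inv_cq, 0)
  expect_true(is.na(res$cq))
  # raw range below min_range: noise never normalised into a response
  noise <- fluor_trace(0:100, 3 + 0.001 * sin(0:100))
  expect_true(extract_cq(noise, min_range = 0.05)$flat)
})

test_that("ties break to the earliest start point", {
  ramp <- fluor_trace(0:100, seq(0, 1, length.out = 101))
  res <- extract_cq(ramp)
  expect_false(res$flat)
  expect_equal(res$cq, 0)
  # an offset ramp shows the same tie-break at its own first point
  res5 <- extract_cq(fluor_trace(5:105, seq(0, 1, length.out = 101)))
  expect_equal(res5$cq, 5)
  expect_equal(res5$inv_cq, 1 / 5)
})

test_that("Cq equals the brute-force all-pairs oracle on random traces", {
  for (seed in 1:200) {
    rt <- random_trace(seed)
    got <- extract_cq(fluor_trace(rt$time, rt$values))
    want <- brute_cq(rt$time, rt$values)
    expect_identical(got$flat, want$flat)
    if (!got$flat) expect_equal(got$cq, want$cq)
  }
})

test_that("Cq is shift-equivariant and amplitude-invariant", {
  time <- 0:400
  base <- extract_cq(fluor_trace(time, plogis((time - 150) / 8)))$cq
  for (s in c(20, 57, 130)) {
    shifted <- extract_cq(fluor_trace(time, plogis((time - 150 - s) / 8)))$cq
    expect_equal(shifted, base + s)
  }
  scaled <- extract_cq(fluor_trace(time, 37 * plogis((time - 150) / 8) + 4))$cq
  expect_equal(scaled, base)
})

test_that("input validation rejects unusable traces", {
  expect_error(extract_cq(fluor_trace(0:5, 1:6)), "shorter than")
  expect_error(fluor_trace(c(0, 1, 3), 1:3), "uniform")
  expect_error(extract_cq(fluor_trace(seq(0, 30, by = 4), rnorm(8)),
                          window = 10), "multiple")
})

test_that("batch extraction preserves labels and order structure", {
  time <- 0:120
  traces <- rbind(rep(1, 121), 10 * plogis((time - 60) / 4))
  ts <- trace_set(time, traces,
                  data.frame(label = c("flat", "sig")), full_scale = 10)
  res <- batch_cq(ts)
  expect_equal(res$label, c("flat", "sig"))
  expect_true(res$flat[1])
  expect_false(res$flat[2])
  expect_equal(res$cq_min[2], 55)
  # permutation equivariance
  ts2 <- trace_set(time, traces[2:1, ],
                   data.frame(label = c("sig", "flat")), full_scale = 10)
  res2 <- batch_cq(ts2)
  expect_equal(res2$cq_min, res$cq_min[2:1])
  # empty set gives an empty table
  ts0 <- trace_set(time, matrix(numeric(), nrow = 0, ncol = 121),
                   data.frame(label = character()))
  expect_equal(nrow(batch_cq(ts0)), 0)
})
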