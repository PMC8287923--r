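test_that("corepressor activation follows the ligand Hill law", {
  trpr <- trpR_tf()
  expect_equal(active_tf_fraction(trpr, 0), 0)
  # half-saturation with unit cooperativity
  trpr_h1 <- tf_spec("TrpR1", 210, 30, "L-trp", ligand_kd = 20,
                     ligand_hill = 1, mode = "corepressor")
  expect_equal(active_tf_fraction(trpr_h1, 20), 0.5)
  # monotone increasing in ligand
  L <- seq(0, 200, by = 5)
  expect_true(all(diff(active_tf_fraction(trpr, L)) > 0))
  expect_error(active_tf_fraction(trpr, -1), ">= 0")
})

test_that("inducer competence falls from 1 to the residual 1/fold", {
  laci <- lacI_tf()
  expect_equal(active_tf_fraction(laci, 0), 1)
  expect_equal(active_tf_fraction(laci, 1e9), 1e-4, tolerance = 1e-6)
  L <- 10^seq(-1, 5, by = 0.25)
  expect_true(all(diff(active_tf_fraction(laci, L)) < 0))
})

test_that("template occupancy solves the binding quadratic exactly", {
  # tight-binding titration: 4 nM TF saturates ~4 nM of a 5 nM template
  expect_equal(template_occupancy(4, 5, 0.001), 4, tolerance = 1e-2)
  expect_equal(template_occupancy(0, 5, 0.001), 0)
  # comparable Kd regime, cross-checked against a fixed-point oracle
  expect_equal(template_occupancy(10, 10, 10), 15 - 5 * sqrt(5),
               tolerance = 1e-9)
  for (p in c(0.5, 2, 8, 50)) {
    for (kd in c(0.01, 1, 25)) {
      expect_equal(template_occupancy(p, 5, kd),
                   binding_bisect(p, 5, kd), tolerance = 1e-8)
    }
  }
})

test_that("occupancy is bounded and monotone in TF and Kd", {
  p <- 10^seq(-2, 3, by = 0.25)
  b <- template_occupancy(p, 5, 1)
  expect_true(all(b <= pmin(p, 5) + 1e-12))
  expect_true(all(diff(b) > 0))
  kd <- 10^seq(-3, 2, by = 0.5)
  expect_true(all(diff(template_occupancy(3, 5, kd)) < 0))
  expect_error(template_occupancy(-1, 5, 1), ">= 0")
  expect_error(template_occupancy(1, 5, 0), "> 0")
})

test_that("tf_for_occupancy inverts template_occupancy", {
  for (f in c(0.2, 0.5, 0.8, 0.95)) {
    p <- tf_for_occupancy(f, 5, 0.001)
    expect_equal(template_occupancy(p, 5, 0.001) / 5, f, tolerance = 1e-8)
  }
})
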