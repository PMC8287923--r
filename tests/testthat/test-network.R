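test_that("empty circuit has an identically zero right-hand side", {
  sp <- circuit_spec(list(template_spec("aT", "aT", 0),
                          template_spec("rT", "rT", 0)))
  net <- build_network(sp)
  expect_true(all(unlist(net$rhs(0, net$state0, NULL)) == 0))
})

test_that("linear source network matches its closed-form solution", {
  # with aT/pT/rT at zero the network reduces to ds/dt = k*sT - d*s,
  # whose solution is the exponential relaxation to k*sT/d
  sp <- circuit_spec(list(template_spec("aT", "aT", 0),
                          template_spec("rT", "rT", 0),
                          template_spec("sT", "sT", 2)))
  r <- sp$rates
  net <- build_network(sp)
  times <- seq(0, 400, by = 1)
  sol <- deSolve::lsoda(net$state0, times, net$rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  analytic <- (r$k_source * 2 / r$k_degr) * (1 - exp(-r$k_degr * times))
  expect_equal(sol[, "s"], analytic, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("total reporter template is conserved along trajectories", {
  net <- build_network(direct_lacI_circuit(tf_dimer = 0))
  sol <- deSolve::lsoda(net$state0, seq(0, 300, by = 1), net$rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(sol[, "rU"] + sol[, "rR"] - 10)), 1e-6)
})

test_that("a fully TF-bound sensing template cannot start the switch", {
  ts_rep <- simulate_circuit(direct_lacI_circuit(tf_dimer = 110))
  expect_true(batch_cq(ts_rep)$flat)
  # and the unrepressed counterpart fires
  ts_free <- simulate_circuit(direct_lacI_circuit(tf_dimer = 0))
  expect_false(batch_cq(ts_free)$flat)
})

test_that("an unconditional source fires the switch", {
  sp <- circuit_spec(list(template_spec("aT", "aT", 50),
                          template_spec("pT", "pT", 4),
                          template_spec("rT", "rT", 10),
                          template_spec("sT", "sT", 3)))
  cq <- batch_cq(simulate_circuit(sp))
  expect_false(cq$flat)
  expect_gt(cq$inv_cq, 0)
})

test_that("noise-free reporter traces are non-decreasing", {
  for (sp in list(direct_lacI_circuit(tf_dimer = 0),
                  inverted_trpR_circuit())) {
    ts <- simulate_circuit(sp, duration = 300)
    expect_true(all(diff(ts$traces[1, ]) > -1e-9))
  }
})
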