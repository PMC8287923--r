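test_that("two-substrate kinetics has the Michaelis-Menten limits", {
  ez <- enzyme_spec("E", 2, kcat = 60, km_indole = 100, km_serine = 1)
  expect_equal(enzyme_rate(ez, 0, 10), 0)
  none <- enzyme_spec("none", 0, kcat = 60)
  expect_equal(enzyme_rate(none, 1000, 10), 0)
  # saturating both substrates approaches kcat * E
  expect_equal(enzyme_rate(ez, 1e9, 1e9), 60 * 2, tolerance = 1e-6)
  # half-saturation in each substrate separately
  expect_equal(enzyme_rate(ez, 100, 1e9), 60, tolerance = 1e-6)
  expect_equal(enzyme_rate(ez, 1e9, 1), 60, tolerance = 1e-6)
  expect_equal(enzyme_layer(ez, 100, 1e9, 0.5), 30, tolerance = 1e-6)
  expect_error(enzyme_rate(ez, -1, 1), ">= 0")
})

test_that("faster enzyme variants fire the metabolic sensor earlier", {
  cqs <- vapply(list(ecB_enzyme(), pfB_t292s_enzyme(), pfB_wt_enzyme()),
                function(ez) {
                  cq <- batch_cq(simulate_circuit(metabolic_circuit(ez),
                                                  duration = 700))
                  ifelse(cq$flat, Inf, cq$cq_min)
                }, 0)
  expect_true(all(is.finite(cqs)))
  expect_true(all(diff(cqs) > 0))  # EcB < PfB T292S < PfB wt
  # without enzymatic activity the sensor stays off
  dead <- metabolic_circuit(enzyme_spec("dead", 1e-9, kcat = 120))
  expect_true(batch_cq(simulate_circuit(dead, duration = 600))$flat)
})

test_that("ligand is produced at the expense of its substrates", {
  sp <- metabolic_circuit(ecB_enzyme(0.05), indole = 50, serine = 10)
  net <- build_network(sp)
  sol <- deSolve::lsoda(net$state0, seq(0, 300, by = 1), net$rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  trp <- sol[, "lig_L-trp"]
  indole <- sol[, "lig_indole"]
  expect_true(all(diff(trp) >= -1e-9))
  expect_true(all(diff(indole) <= 1e-9))
  # produced ligand balances consumed indole
  expect_equal(utils::tail(trp, 1), 50 - utils::tail(indole, 1),
               tolerance = 1e-6)
  expect_lte(utils::tail(trp, 1), 50 + 1e-9)
})

test_that("excess enzyme triggers the disruption flag", {
  expect_warning(ts <- simulate_circuit(metabolic_circuit(ecB_enzyme(15)),
                                        duration = 30),
                 "disruption")
  expect_true("non-specific disruption regime" %in% ts$flags)
  ok <- simulate_circuit(metabolic_circuit(ecB_enzyme(0.01)), duration = 30)
  expect_length(ok$flags, 0)
})
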