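test_that("template_spec enforces role/operator rules", {
  expect_error(template_spec("x", "zT", 1), "unknown role")
  expect_error(template_spec("x", "psT", 1), "requires an 'operator'")
  expect_error(template_spec("x", "aT", 1, operator = "LacI"),
               "must not carry an operator")
  expect_error(template_spec("x", "aT", -1), ">= 0")
  # polarity defaults follow the role
  expect_equal(template_spec("k", "pskT", 1, operator = "LacI")$output_polarity,
               "antisignal")
  expect_equal(template_spec("s", "sT", 1)$output_polarity, "signal")
})

test_that("tf_spec and enzyme_spec validate their constants", {
  expect_error(tf_spec("T", 1, 0, "x", 1), "positive")
  expect_error(tf_spec("T", 1, 1, "x", 1, mode = "inducer",
                       induction_fold = 0.5), "induction_fold")
  expect_error(tf_spec("T", 1, 1, "x", 1, ligand_hill = 0.5), "ligand_hill")
  expect_error(enzyme_spec("E", 1, kcat = -1), "positive")
  expect_equal(enzyme_spec("E", 1, 10)$disruption_threshold, 10)
})

test_that("circuit invariants are enforced at assembly", {
  core <- list(template_spec("aT", "aT", 50), template_spec("rT", "rT", 10))
  expect_error(circuit_spec(core[2]), "exactly one aT")
  expect_error(circuit_spec(c(core, core)), "exactly one aT")
  expect_error(
    circuit_spec(c(core, list(template_spec("p", "psT", 5,
                                            operator = "LacI")))),
    "undeclared TF")
  expect_error(
    circuit_spec(c(core, list(template_spec("p", "psT", 5,
                                            operator = "LacI"))),
                 tfs = list(lacI_tf())),
    "undeclared ligand")
  ok <- circuit_spec(c(core, list(template_spec("p", "psT", 5,
                                                operator = "LacI"))),
                     tfs = list(lacI_tf()),
                     ligand_inputs = c(IPTG = 0))
  expect_s3_class(ok, "circuit_spec")
})

test_that("set_ligand updates declared inputs only", {
  sp <- direct_lacI_circuit()
  expect_equal(set_ligand(sp, "IPTG", 50)$ligand_inputs[["IPTG"]], 50)
  expect_error(set_ligand(sp, "L-trp", 1), "not declared")
  expect_error(set_ligand(sp, "IPTG", -1), ">= 0")
})

test_that("default switch has a stable off state with limited sink capacity", {
  sp <- switch_circuit()
  expect_gt(off_stability_margin(sp), 0)
  r <- sp$rates
  # amplification capacity exceeds the sink's, the bistability requirement
  expect_gt(r$k_amp * 50, r$k_deact * 7)
  expect_error(rate_parameters(k_amp = 0), "positive")
})
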