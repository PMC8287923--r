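test_that("a 1x1 grid reproduces a single simulate + Cq run", {
  sp <- two_input_circuit("psT", "psT")
  g <- simulate_grid(sp, "IPTG", 100, "L-trp", 5, duration = 400)
  direct <- set_ligand(set_ligand(sp, "IPTG", 100), "L-trp", 5)
  cq <- batch_cq(simulate_circuit(direct, duration = 400))
  expect_equal(dim(g$inv_cq), c(1, 1))
  expect_equal(g$inv_cq[1, 1], cq$inv_cq)
})

test_that("input logic reflects the gating template polarity", {
  expect_equal(unname(simulate_grid(two_input_circuit("psT", "pskT"),
                                    "IPTG", 10, "L-trp", 10,
                                    duration = 30)$logic),
               c("direct", "inverted"))
  expect_error(input_logic(direct_lacI_circuit(), "lactose"), "no TF senses")
})

test_that("plane data in log-inputs is recovered exactly", {
  x <- 10^seq(0, 3, length.out = 5)
  y <- 10^seq(0, 2, length.out = 4)
  w <- c(w0 = 0.003, wx = 0.0011, wy = -0.0007)
  inv <- outer(log(y), log(x),
               function(ly, lx) w["w0"] + w["wx"] * lx + w["wy"] * ly)
  # keep the synthetic plane positive so no cell is treated as flat
  inv <- inv + 0.01
  g <- structure(list(ligand_x = "a", ligand_y = "b", x_concs = x,
                      y_concs = y, inv_cq = inv,
                      logic = c(x = "direct", y = "inverted")),
                 class = "grid_result")
  fit <- fit_logsum(g)
  expect_equal(fit$w_x, unname(w["wx"]), tolerance = 1e-10)
  expect_equal(fit$w_y, unname(w["wy"]), tolerance = 1e-10)
  expect_equal(fit$w0, unname(w["w0"]) + 0.01, tolerance = 1e-10)
  # relabelling one axis by a constant factor only moves the intercept
  g2 <- g
  g2$y_concs <- y * 2
  fit2 <- fit_logsum(g2)
  expect_equal(fit2$w_y, fit$w_y, tolerance = 1e-10)
  expect_equal(fit2$w_x, fit$w_x, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fit2$w0, fit$w0)))
})

test_that("an all-flat grid cannot be fit", {
  g <- structure(list(ligand_x = "a", ligand_y = "b", x_concs = c(1, 10),
                      y_concs = c(1, 10), inv_cq = matrix(0, 2, 2),
                      logic = c(x = "direct", y = "direct")),
                 class = "grid_result")
  expect_error(fit_logsum(g), "all grid cells are flat")
})

test_that("strengthening one input's template raises its weight magnitude", {
  concs <- 10^seq(0, 3, length.out = 4)
  w_weak <- fit_logsum(simulate_grid(
    two_input_circuit("psT", "psT", trpR_conc = 1.5),
    "IPTG", concs, "L-trp", concs))
  w_strong <- fit_logsum(simulate_grid(
    two_input_circuit("psT", "psT", trpR_conc = 4),
    "IPTG", concs, "L-trp", concs))
  expect_gt(abs(w_strong$w_y), abs(w_weak$w_y))
})
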