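#' Simulate a two-input concentration grid
#'
#' Runs the circuit at every combination of two ligand concentration
#' ranges (one condition per cell), extracts `1/Cq` per cell, and records
#' the sensing logic of each input: `direct` when the input's TF path
#' goes through a signal-producing psT, `inverted` when it goes through an
#' antisignal-producing pskT.  Deterministic (noise-free simulation).
#'
#' @param spec A [circuit_spec()] containing a TF for each of the two
#'   ligands.
#' @param ligand_x,ligand_y Declared ligand names for the grid axes.
#' @param x_concs,y_concs Concentration ranges, uM.
#' @param duration Simulation horizon per cell, minutes.
#' @param ... Passed to [batch_cq()].
#' @return An object of class `grid_result`: list with `inv_cq` matrix
#'   (rows = `y_concs`, columns = `x_concs`), the axes, and `logic`.
#' @export
simulate_grid <- function(spec, ligand_x, x_concs, ligand_y, y_concs,
                          duration = 500, ...) {
  stopifnot(inherits(spec, "circuit_spec"))
  for (lg in c(ligand_x, ligand_y))
    if (!lg %in% names(spec$ligand_inputs))
      stop("ligand '", lg, "' is not declared in this circuit")
  inv <- matrix(NA_real_, nrow = length(y_concs), ncol = length(x_concs),
                dimnames = list(signif(y_concs, 4), signif(x_concs, 4)))
  for (j in seq_along(x_concs)) {
    for (i in seq_along(y_concs)) {
      sp <- set_ligand(spec, ligand_x, x_concs[j])
      sp <- set_ligand(sp, ligand_y, y_concs[i])
      label <- sprintf("%s=%.4g,%s=%.4g", ligand_x, x_concs[j],
                       ligand_y, y_concs[i])
      cq <- tryCatch({
        ts <- simulate_circuit(sp, duration = duration, label = label)
        batch_cq(ts, ...)
      }, error = function(e)
        stop("grid cell (", i, ",", j, ") [", label, "]: ",
             conditionMessage(e), call. = FALSE))
      inv[i, j] <- cq$inv_cq[1]
    }
  }
  structure(list(ligand_x = ligand_x, ligand_y = ligand_y,
                 x_concs = x_concs, y_concs = y_concs, inv_cq = inv,
                 logic = c(x = input_logic(spec, ligand_x),
                           y = input_logic(spec, ligand_y))),
            class = "grid_result")
}

#' Sensing logic of a ligand input in a circuit
#'
#' @param spec A [circuit_spec()].
#' @param ligand A declared ligand name.
#' @return `"direct"` if the ligand's TF gates a signal-producing
#'   template (psT), `"inverted"` if it gates an antisignal-producing
#'   template (pskT).
#' @export
input_logic <- function(spec, ligand) {
  stopifnot(inherits(spec, "circuit_spec"))
  tf <- Filter(function(x) x$ligand_name == ligand, spec$tfs)
  if (!length(tf)) stop("no TF senses ligand '", ligand, "'")
  tfn <- vapply(tf, `[[`, "", "name")
  tmpl <- Filter(function(tp) !is.null(tp$operator) && tp$operator %in% tfn,
                 spec$templates)
  if (!length(tmpl)) stop("no sensing template gated by ligand '", ligand, "'")
  pol <- unique(vapply(tmpl, `[[`, "", "output_polarity"))
  if (length(pol) > 1L)
    stop("ligand '", ligand, "' gates templates of mixed polarity")
  if (pol == "signal") "direct" else "inverted"
}

#' Weighted log-sum readout of a two-input grid
#'
#' Least-squares plane fit
#' \eqn{1/C_q \approx w_0 + w_x \log c_x + w_y \log c_y}
#' over the non-flat cells of the grid (flat cells, `1/Cq = 0`, are
#' censoring values, not response levels, and are excluded).  The signs
#' of the fitted weights characterise the logic of the two inputs.
#'
#' @param grid A [simulate_grid()] result with strictly positive
#'   concentration axes.
#' @return List with `w0`, `w_x`, `w_y`, `residual_norm`, `n_cells`
#'   (number of non-flat cells used) and the underlying `lm` fit.
#' @export
fit_logsum <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  if (any(grid$x_concs <= 0) || any(grid$y_concs <= 0))
    stop("log-sum fit requires strictly positive concentrations")
  df <- expand.grid(y = grid$y_concs, x = grid$x_concs)
  df$inv_cq <- as.vector(grid$inv_cq)
  df <- df[df$inv_cq > 0, ]
  if (!nrow(df))
    stop("all grid cells are flat; no log-sum readout to fit")
  fit <- stats::lm(inv_cq ~ log(x) + log(y), data = df)
  cf <- stats::coef(fit)
  list(w0 = unname(cf[1]), w_x = unname(cf["log(x)"]),
       w_y = unname(cf["log(y)"]),
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       n_cells = nrow(df), model = fit)
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> ", x$ligand_x, " (", length(x$x_concs), " levels, ",
      x$logic[["x"]], ") x ", x$ligand_y, " (", length(x$y_concs),
      " levels, ", x$logic[["y"]], ")\n", sep = "")
  print(signif(x$inv_cq, 3))
  invisible(x)
}
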