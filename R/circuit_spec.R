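#' Declare a DNA template of the switch circuit
#'
#' Templates are the short protected oligonucleotides that encode the
#' reaction network: `aT` (autocatalytic template, exponential signal
#' amplification), `pT` (pseudotemplate, a saturable deactivation sink that
#' creates the switching threshold), `rT` (reporter hairpin, irreversibly
#' unquenched by signal extension), `sT` (unconditional source of signal),
#' and the protein-sensing templates `psT` / `pskT`, whose nicking site is
#' occluded when a transcription factor binds their operator.  `psT` outputs
#' signal (direct logic); `pskT` outputs antisignal (inverted logic).
#'
#' @param name Identifier, unique within a circuit.
#' @param role One of `"aT"`, `"pT"`, `"rT"`, `"sT"`, `"psT"`, `"pskT"`.
#' @param concentration Total template concentration in nM (>= 0).
#' @param output_polarity `"signal"` or `"antisignal"`.  Defaults to
#'   `"antisignal"` for `pskT` and `"signal"` otherwise.
#' @param operator Name of the transcription factor whose operator the
#'   template carries.  Required for `psT`/`pskT`, forbidden otherwise.
#' @return An object of class `template_spec`.
#' @export
template_spec <- function(name, role, concentration,
                          output_polarity = NULL, operator = NULL) {
  roles <- c("aT", "pT", "rT", "sT", "psT", "pskT")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("template 'name' must be a non-empty string")
  if (length(role) != 1L || !role %in% roles)
    stop("template '", name, "': unknown role '", role,
         "' (must be one of ", paste(roles, collapse = ", "), ")")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0)
    stop("template '", name, "': concentration must be a single number >= 0 (nM)")
  sensing <- role %in% c("psT", "pskT")
  if (sensing && (is.null(operator) || !nzchar(operator)))
    stop("template '", name, "': role ", role, " requires an 'operator' TF name")
  if (!sensing && !is.null(operator))
    stop("template '", name, "': role ", role, " must not carry an operator")
  if (is.null(output_polarity))
    output_polarity <- if (role == "pskT") "antisignal" else "signal"
  if (!output_polarity %in% c("signal", "antisignal"))
    stop("template '", name, "': output_polarity must be 'signal' or 'antisignal'")
  structure(list(name = name, role = role,
                 concentration = as.numeric(concentration),
                 output_polarity = output_polarity,
                 operator = operator),
            class = "template_spec")
}

#' Declare an allosteric transcription factor
#'
#' The TF layer is treated as a quasi-equilibrium: at every instant the
#' operator-competent fraction of the TF pool is set by the current ligand
#' concentration, and template occupancy follows the exact two-species
#' binding equilibrium.  An *inducer* (e.g. IPTG on LacI) releases the TF
#' from DNA, weakening effective operator binding by up to
#' `induction_fold` at saturation; a *corepressor* (e.g. L-tryptophan on
#' TrpR) is required for DNA binding, so the competent fraction rises from
#' 0 with ligand.
#'
#' @param name TF identifier (matched by template `operator` fields).
#' @param dimer_concentration Total TF dimer concentration, nM.
#' @param operator_kd Dissociation constant of the active TF for its
#'   operator, nM.
#' @param ligand_name Identifier of the allosteric effector.
#' @param ligand_kd Half-effect ligand concentration, uM.
#' @param ligand_hill Cooperativity of the allosteric transition (>= 1).
#' @param mode `"inducer"` or `"corepressor"`.
#' @param induction_fold Factor by which saturating inducer weakens
#'   operator binding (inducer mode only; must be > 1).
#' @return An object of class `tf_spec`.
#' @export
tf_spec <- function(name, dimer_concentration, operator_kd,
                    ligand_name, ligand_kd, ligand_hill = 2,
                    mode = c("inducer", "corepressor"),
                    induction_fold = 1e4) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), nzchar(name),
            is.character(ligand_name), nzchar(ligand_name))
  num1 <- function(x, what, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0))
      stop("TF '", name, "': ", what, " must be a single ",
           if (strict) "positive" else "non-negative", " number")
    as.numeric(x)
  }
  dimer_concentration <- num1(dimer_concentration, "dimer_concentration (nM)",
                              strict = FALSE)
  operator_kd <- num1(operator_kd, "operator_kd (nM)")
  ligand_kd <- num1(ligand_kd, "ligand_kd (uM)")
  ligand_hill <- num1(ligand_hill, "ligand_hill")
  if (ligand_hill < 1) stop("TF '", name, "': ligand_hill must be >= 1")
  if (mode == "inducer") {
    induction_fold <- num1(induction_fold, "induction_fold")
    if (induction_fold <= 1)
      stop("TF '", name, "': induction_fold must be > 1 for an inducer")
  } else {
    induction_fold <- NA_real_  # unused in corepressor mode
  }
  structure(list(name = name, dimer_concentration = dimer_concentration,
                 operator_kd = operator_kd, ligand_name = ligand_name,
                 ligand_kd = ligand_kd, ligand_hill = ligand_hill,
                 mode = mode, induction_fold = induction_fold),
            class = "tf_spec")
}

#' Declare a ligand-producing enzyme
#'
#' Models a two-substrate Michaelis-Menten enzyme (tryptophan synthase
#' subunit B in the reference application) that converts indole and
#' L-serine into the TF effector during the run, so the circuit senses the
#' enzyme's metabolic activity in situ.  The Km defaults are
#' order-of-magnitude placeholders, not measured values.
#'
#' @param name Enzyme identifier.
#' @param concentration Enzyme concentration, uM.
#' @param kcat Turnover number, per minute.
#' @param km_indole Michaelis constant for indole, uM.
#' @param km_serine Michaelis constant for L-serine, mM.
#' @param product Name of the ligand produced (must be declared in the
#'   circuit's `ligand_inputs`).
#' @param disruption_threshold Enzyme concentration (uM) above which the
#'   circuit is flagged as being in a non-specific disruption regime.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, concentration, kcat,
                        km_indole = 100, km_serine = 1,
                        product = "L-trp", disruption_threshold = 10) {
  stopifnot(is.character(name), nzchar(name), is.character(product))
  for (v in c("concentration", "kcat", "km_indole", "km_serine",
              "disruption_threshold")) {
    x <- get(v)
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (x > 0 || (v == "concentration" && x >= 0))
    if (!ok) stop("enzyme '", name, "': ", v, " must be a single positive number")
  }
  structure(list(name = name, concentration = as.numeric(concentration),
                 kcat = as.numeric(kcat), km_indole = as.numeric(km_indole),
                 km_serine = as.numeric(km_serine), product = product,
                 disruption_threshold = as.numeric(disruption_threshold)),
            class = "enzyme_spec")
}

#' Kinetic rate parameters of the switch network
#'
#' The reference experiments report behaviour, not rate constants, so these
#' are calibration parameters with frozen defaults.  The defaults were
#' chosen once so that (i) an unrepressed 5 nM protein-sensing template
#' fires the standard switch (aT 50 / pT 7 / rT 10 nM) at Cq in the
#' 60-120 min range, and (ii) the off state of that switch is stable: at
#' low signal the deactivation flux through pT exceeds the amplification
#' flux through aT (`k_deact * pT / km_deact > k_amp * aT / km_amp`),
#' while pT's limited capacity (`k_deact * pT`) is exceeded by aT's
#' (`k_amp * aT`), which is what makes the switch bistable.
#'
#' Units: first-order rates per minute; second-order rates per nM per
#' minute; Michaelis constants nM.
#'
#' @param k_amp Autocatalytic production rate constant on free aT
#'   (per nM aT per min at saturation).
#' @param km_amp Michaelis constant of signal on aT, nM.
#' @param k_deact Deactivation rate constant on free pT.
#' @param km_deact Michaelis constant of signal on pT, nM (below `km_amp`:
#'   trigger binding is biased in favour of pT).
#' @param k_report Reporting rate constant on unreported rT, per nM per min.
#' @param k_source Output production rate per free source template
#'   (sT/psT/pskT), per min.
#' @param k_degr First-order exonuclease degradation rate of free signal
#'   and antisignal strands, per min.
#' @param k_hyb Signal-antisignal annihilation rate, per nM per min.
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(k_amp = 0.01, km_amp = 2,
                            k_deact = 0.0135, km_deact = 0.2,
                            k_report = 0.0007, k_source = 0.017,
                            k_degr = 0.0033, k_hyb = 1.4) {
  vals <- c(k_amp = k_amp, km_amp = km_amp, k_deact = k_deact,
            km_deact = km_deact, k_report = k_report, k_source = k_source,
            k_degr = k_degr, k_hyb = k_hyb)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0))
    stop("all rate parameters must be positive numbers")
  structure(as.list(vals), class = "rate_parameters")
}

#' Assemble and validate a full circuit specification
#'
#' @param templates List of [template_spec()] objects.  Exactly one `aT`,
#'   at most one `pT` and exactly one `rT` are required.
#' @param tfs List of [tf_spec()] objects; every `psT`/`pskT` operator must
#'   reference one of them.
#' @param enzymes List of [enzyme_spec()] objects.
#' @param ligand_inputs Named numeric vector of initial ligand
#'   concentrations, uM (L-serine in mM).  Every ligand referenced by a TF
#'   or produced by an enzyme must be declared here (possibly at 0).
#' @param initial_signal Initial free signal concentration, nM.
#' @param rates A [rate_parameters()] object.
#' @param temperature_note Informational string (the model is isothermal).
#' @param name Optional circuit name.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(templates, tfs = list(), enzymes = list(),
                         ligand_inputs = numeric(), initial_signal = 0,
                         rates = rate_parameters(), temperature_note = NULL,
                         name = NULL) {
  if (inherits(templates, "template_spec")) templates <- list(templates)
  if (inherits(tfs, "tf_spec")) tfs <- list(tfs)
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  stopifnot(all(vapply(templates, inherits, TRUE, "template_spec")),
            all(vapply(tfs, inherits, TRUE, "tf_spec")),
            all(vapply(enzymes, inherits, TRUE, "enzyme_spec")),
            inherits(rates, "rate_parameters"))
  ligand_inputs <- unlist(ligand_inputs)
  if (is.null(ligand_inputs))
    ligand_inputs <- stats::setNames(numeric(), character())
  if (length(ligand_inputs) && (is.null(names(ligand_inputs)) ||
                                any(!nzchar(names(ligand_inputs)))))
    stop("ligand_inputs must be a named numeric vector")
  if (any(ligand_inputs < 0)) stop("ligand concentrations must be >= 0")
  if (!is.numeric(initial_signal) || length(initial_signal) != 1L ||
      initial_signal < 0)
    stop("initial_signal must be a single number >= 0 (nM)")

  roles <- vapply(templates, `[[`, "", "role")
  if (sum(roles == "aT") != 1L) stop("exactly one aT required")
  if (sum(roles == "pT") > 1L) stop("at most one pT allowed")
  if (sum(roles == "rT") != 1L) stop("exactly one rT required")
  tnames <- vapply(templates, `[[`, "", "name")
  if (anyDuplicated(tnames)) stop("duplicate template names")
  tf_names <- vapply(tfs, `[[`, "", "name")
  if (anyDuplicated(tf_names)) stop("duplicate TF names")
  for (tp in templates) {
    if (!is.null(tp$operator) && !tp$operator %in% tf_names)
      stop("template '", tp$name, "' references undeclared TF '",
           tp$operator, "'")
  }
  declared <- names(ligand_inputs)
  for (tf in tfs) {
    if (!tf$ligand_name %in% declared)
      stop("TF '", tf$name, "' references undeclared ligand '",
           tf$ligand_name, "' (declare it in ligand_inputs, possibly at 0)")
  }
  for (ez in enzymes) {
    if (!ez$product %in% declared)
      stop("enzyme '", ez$name, "' product '", ez$product,
           "' not declared in ligand_inputs")
    for (sub in c("indole", "serine")) {
      if (!sub %in% declared)
        stop("enzyme '", ez$name, "' requires '", sub,
             "' in ligand_inputs")
    }
  }
  structure(list(name = name, templates = templates, tfs = tfs,
                 enzymes = enzymes,
                 ligand_inputs = ligand_inputs,
                 initial_signal = as.numeric(initial_signal),
                 rates = rates, temperature_note = temperature_note),
            class = "circuit_spec")
}

#' Set a ligand input concentration on a circuit
#'
#' @param spec A [circuit_spec()].
#' @param ligand Ligand name (must be declared in the circuit).
#' @param value New concentration (uM; mM for serine).
#' @return The modified `circuit_spec`.
#' @export
set_ligand <- function(spec, ligand, value) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!ligand %in% names(spec$ligand_inputs))
    stop("ligand '", ligand, "' is not declared in this circuit")
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("ligand concentration must be a single number >= 0")
  spec$ligand_inputs[[ligand]] <- as.numeric(value)
  spec
}

#' Off-state stability margin of a switch
#'
#' Difference between the low-signal deactivation + degradation rate and
#' the low-signal amplification rate.  Positive means the unsignalled
#' state is locally stable (the switch thresholds); negative means any
#' signal leak eventually fires the switch.
#'
#' @param spec A [circuit_spec()].
#' @return Stability margin in units of per minute.
#' @export
off_stability_margin <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  r <- spec$rates
  conc <- function(role) {
    i <- vapply(spec$templates, `[[`, "", "role") == role
    if (any(i)) sum(vapply(spec$templates[i], `[[`, 0, "concentration")) else 0
  }
  r$k_deact * conc("pT") / r$km_deact + r$k_degr -
    r$k_amp * conc("aT") / r$km_amp
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec>", if (!is.null(x$name)) paste0(" '", x$name, "'"), "\n",
      sep = "")
  for (tp in x$templates)
    cat(sprintf("  %-6s %-14s %8.3g nM%s\n", tp$role, tp$name,
                tp$concentration,
                if (!is.null(tp$operator)) paste0("  [", tp$operator, "]") else ""))
  for (tf in x$tfs)
    cat(sprintf("  TF     %-14s %8.3g nM  %s of %s (Kd %.3g uM)\n",
                tf$name, tf$dimer_concentration, tf$mode, tf$ligand_name,
                tf$ligand_kd))
  for (ez in x$enzymes)
    cat(sprintf("  enzyme %-14s %8.3g uM  kcat %.3g/min -> %s\n",
                ez$name, ez$concentration, ez$kcat, ez$product))
  if (length(x$ligand_inputs))
    cat("  ligands:", paste(sprintf("%s=%.4g", names(x$ligand_inputs),
                                    x$ligand_inputs), collapse = ", "), "\n")
  cat("  initial signal:", x$initial_signal, "nM\n")
  invisible(x)
}
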