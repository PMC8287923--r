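#' Standard transcription factors of the reference circuits
#'
#' `lacI_tf()` is an inducer-mode TF: IPTG releases it from its operator,
#' weakening binding by four orders of magnitude at saturation; the
#' operator dissociation constant defaults to the tight O1 value (1 pM)
#' and the IPTG half-effect to 23 uM.  `trpR_tf()` is a corepressor-mode
#' TF: it only binds its operator in the presence of L-tryptophan
#' (half-effect 20 uM, cooperativity 2 for the two tryptophan sites);
#' its operator affinity default (5 nM) is a tight-operator design choice,
#' not a printed value.
#'
#' @param dimer Dimer concentration, nM.
#' @param operator_kd Operator dissociation constant of the active form, nM.
#' @param ligand_kd Ligand half-effect concentration, uM.
#' @return A [tf_spec()].
#' @name standard_tfs
NULL

#' @rdname standard_tfs
#' @export
lacI_tf <- function(dimer = 110, operator_kd = 0.001, ligand_kd = 23) {
  tf_spec("LacI", dimer_concentration = dimer, operator_kd = operator_kd,
          ligand_name = "IPTG", ligand_kd = ligand_kd, ligand_hill = 2,
          mode = "inducer", induction_fold = 1e4)
}

#' @rdname standard_tfs
#' @export
trpR_tf <- function(dimer = 210, operator_kd = 5, ligand_kd = 20) {
  tf_spec("TrpR", dimer_concentration = dimer, operator_kd = operator_kd,
          ligand_name = "L-trp", ligand_kd = ligand_kd, ligand_hill = 2,
          mode = "corepressor")
}

core_templates <- function(pT = 7, aT = 50, rT = 10) {
  out <- list(template_spec("aT", "aT", aT),
              template_spec("rT", "rT", rT))
  if (pT > 0) out <- c(out, list(template_spec("pT", "pT", pT)))
  out
}

#' The bare bistable amplification switch
#'
#' Autocatalytic template (50 nM), pseudotemplate threshold sink and
#' reporter (10 nM) with no input module; its state is set by the initial
#' signal concentration.
#'
#' @param pT Pseudotemplate concentration, nM (default 7).
#' @param initial_signal Initial free signal, nM.
#' @param rates A [rate_parameters()] object.
#' @return A [circuit_spec()].
#' @export
switch_circuit <- function(pT = 7, initial_signal = 0,
                           rates = rate_parameters()) {
  circuit_spec(core_templates(pT = pT), rates = rates,
               initial_signal = initial_signal, name = "switch")
}

#' Direct-sensing circuits (psT input module)
#'
#' `direct_lacI_circuit()`: the switch plus a LacI-gated psT; IPTG frees
#' the template, so the response increases with IPTG (lactose is
#' declared as an uncoupled specificity control).
#' `direct_trpR_circuit()`: a TrpR-gated psT; L-tryptophan activates
#' TrpR, which represses the template, so the response decreases with
#' L-trp (L-threonine declared as the uncoupled control).
#'
#' @param psT Protein-sensing template concentration, nM.
#' @param tf_dimer TF dimer concentration, nM (0 = unrepressed circuit).
#' @param pT Pseudotemplate concentration, nM.
#' @param rates A [rate_parameters()] object.
#' @return A [circuit_spec()].
#' @name direct_circuits
NULL

#' @rdname direct_circuits
#' @export
direct_lacI_circuit <- function(psT = 5, tf_dimer = 110, pT = 7,
                                rates = rate_parameters()) {
  tf <- lacI_tf(dimer = tf_dimer)
  circuit_spec(
    c(core_templates(pT = pT),
      list(template_spec("psT_LacI", "psT", psT, operator = "LacI"))),
    tfs = list(tf),
    ligand_inputs = c(IPTG = 0, lactose = 0),
    rates = rates, name = "direct_LacI")
}

#' @rdname direct_circuits
#' @export
direct_trpR_circuit <- function(psT = 1, tf_dimer = 210, pT = 7,
                                rates = rate_parameters()) {
  circuit_spec(
    c(core_templates(pT = pT),
      list(template_spec("psT_TrpR", "psT", psT, operator = "TrpR"))),
    tfs = list(trpR_tf(dimer = tf_dimer)),
    ligand_inputs = c("L-trp" = 0, "L-thr" = 0),
    rates = rates, name = "direct_TrpR")
}

#' Inverted-sensing circuits (sT + pskT competition)
#'
#' The switch is driven unconditionally by a source template sT and
#' opposed by a TF-gated antisignal source pskT; the TF shifts the
#' balance.  `inverted_lacI_circuit()`: IPTG frees pskT, so the response
#' decreases with IPTG.  `inverted_trpR_circuit()`: L-trp-activated TrpR
#' blocks pskT, so the response increases with L-trp.  The competitive
#' titration makes the transition much sharper than the direct design.
#'
#' @param pskT Protein-sensing killer template concentration, nM.
#' @param sT Source template concentration, nM.
#' @param tf_dimer TF dimer concentration, nM.
#' @param pT Pseudotemplate concentration, nM.
#' @param rates A [rate_parameters()] object.
#' @return A [circuit_spec()].
#' @name inverted_circuits
NULL

#' @rdname inverted_circuits
#' @export
inverted_lacI_circuit <- function(pskT = 10, sT = 1.2, tf_dimer = 110, pT = 4,
                                  rates = rate_parameters()) {
  circuit_spec(
    c(core_templates(pT = pT),
      list(template_spec("sT", "sT", sT),
           template_spec("pskT_LacI", "pskT", pskT, operator = "LacI"))),
    tfs = list(lacI_tf(dimer = tf_dimer)),
    ligand_inputs = c(IPTG = 0, lactose = 0),
    rates = rates, name = "inverted_LacI")
}

#' @rdname inverted_circuits
#' @export
inverted_trpR_circuit <- function(pskT = 10, sT = 1.2, tf_dimer = 210, pT = 4,
                                  rates = rate_parameters()) {
  circuit_spec(
    c(core_templates(pT = pT),
      list(template_spec("sT", "sT", sT),
           template_spec("pskT_TrpR", "pskT", pskT, operator = "TrpR"))),
    tfs = list(trpR_tf(dimer = tf_dimer)),
    ligand_inputs = c("L-trp" = 0, "L-thr" = 0),
    rates = rates, name = "inverted_TrpR")
}

#' Two-input classifier circuit
#'
#' Combines a LacI-gated and a TrpR-gated sensing template on one switch,
#' giving the four logic combinations of direct (psT) and inverted (pskT)
#' sensing for IPTG and L-trp.  When both inputs are inverted an sT
#' drives the switch.
#'
#' @param lacI_role,trpR_role `"psT"` (direct) or `"pskT"` (inverted).
#' @param lacI_conc,trpR_conc Sensing-template concentrations, nM.
#'   Defaults depend on the role: 3 nM for a psT (so its signal flux is
#'   well above the firing threshold and the response stays graded) and
#'   10 nM for a pskT (so its antisignal flux can overrule the signal
#'   sources).
#' @param pT Pseudotemplate concentration, nM.
#' @param sT Source-template concentration, nM; used only when it is
#'   needed to drive the switch (no psT present).
#' @param rates A [rate_parameters()] object.
#' @return A [circuit_spec()].
#' @export
two_input_circuit <- function(lacI_role = c("psT", "pskT"),
                              trpR_role = c("psT", "pskT"),
                              lacI_conc = NULL, trpR_conc = NULL,
                              pT = 4, sT = 1.2,
                              rates = rate_parameters()) {
  lacI_role <- match.arg(lacI_role)
  trpR_role <- match.arg(trpR_role)
  if (is.null(lacI_conc)) lacI_conc <- if (lacI_role == "psT") 3 else 10
  if (is.null(trpR_conc)) trpR_conc <- if (trpR_role == "psT") 3 else 10
  tmpl <- c(core_templates(pT = pT),
            list(template_spec(paste0(lacI_role, "_LacI"), lacI_role,
                               lacI_conc, operator = "LacI"),
                 template_spec(paste0(trpR_role, "_TrpR"), trpR_role,
                               trpR_conc, operator = "TrpR")))
  if (lacI_role == "pskT" && trpR_role == "pskT")
    tmpl <- c(tmpl, list(template_spec("sT", "sT", sT)))
  # a moderate-affinity LacI operator (10 nM, an O2/O3-like choice) keeps
  # template occupancy graded across the IPTG range, which is what lets
  # the two-input map approximate a weighted log-sum instead of a step
  circuit_spec(tmpl, tfs = list(lacI_tf(operator_kd = 10), trpR_tf()),
               ligand_inputs = c(IPTG = 0, "L-trp" = 0),
               rates = rates,
               name = sprintf("two_input_%s_%s", lacI_role, trpR_role))
}

#' Metabolic sensing circuit (enzyme layer)
#'
#' The inverted TrpR switch driven by L-tryptophan produced in situ from
#' indole and L-serine by a tryptophan-synthase B enzyme: enzymatic
#' activity turns the switch on.  Default substrate loads follow the
#' reference assembly (5 mM indole, 10 mM L-serine).
#'
#' @param enzyme An [enzyme_spec()] (product must be `"L-trp"`).
#' @param indole Initial indole, uM.
#' @param serine Initial L-serine, mM.
#' @param pskT,sT,pT Template concentrations, nM.
#' @param tf_dimer TrpR dimer concentration, nM.
#' @param rates A [rate_parameters()] object.
#' @return A [circuit_spec()].
#' @export
metabolic_circuit <- function(enzyme, indole = 5000, serine = 10,
                              pskT = 10, sT = 2.5, pT = 5, tf_dimer = 50,
                              rates = rate_parameters()) {
  # a tight TrpR operator (5 nM) lets the 50 nM dimer fully occlude the
  # 10 nM pskT once L-trp accumulates, so enzymatic activity can flip the
  # sT/pskT balance and fire the switch
  circuit_spec(
    c(core_templates(pT = pT),
      list(template_spec("sT", "sT", sT),
           template_spec("pskT_TrpR", "pskT", pskT, operator = "TrpR"))),
    tfs = list(trpR_tf(dimer = tf_dimer)),
    enzymes = list(enzyme),
    ligand_inputs = c("L-trp" = 0, indole = indole, serine = serine),
    rates = rates, name = "metabolic_TrpR")
}

#' Tryptophan synthase B variants
#'
#' Convenience constructors for the three enzyme variants compared in the
#' reference application, with turnover defaults ordered to match their
#' observed activity at 37 C (mesophilic EcB fastest, thermophilic PfB
#' wild type slowest).  kcat and Km defaults are order-of-magnitude
#' placeholders, not measured values; the default enzyme concentration
#' (10 nM) puts ligand accumulation on the hour scale of the switch.
#'
#' @param concentration Enzyme concentration, uM.
#' @return An [enzyme_spec()].
#' @name trpB_variants
NULL

#' @rdname trpB_variants
#' @export
ecB_enzyme <- function(concentration = 0.01)
  enzyme_spec("EcB", concentration, kcat = 120)

#' @rdname trpB_variants
#' @export
pfB_t292s_enzyme <- function(concentration = 0.01)
  enzyme_spec("PfB_T292S", concentration, kcat = 40)

#' @rdname trpB_variants
#' @export
pfB_wt_enzyme <- function(concentration = 0.01)
  enzyme_spec("PfB_wt", concentration, kcat = 10)
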