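#' Two-substrate Michaelis-Menten rate of a ligand-producing enzyme
#'
#' \eqn{v = k_{cat} E \cdot \frac{S_1}{K_{m,1}+S_1} \cdot
#' \frac{S_2}{K_{m,2}+S_2}} with indole (uM) and L-serine (mM) as
#' substrates.  At saturating substrates the rate tends to `kcat * E`.
#'
#' @param enzyme An [enzyme_spec()].
#' @param indole Indole concentration, uM.
#' @param serine L-serine concentration, mM.
#' @return Product formation rate, uM per minute.
#' @export
enzyme_rate <- function(enzyme, indole, serine) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (any(indole < 0) || any(serine < 0)) stop("substrates must be >= 0")
  enzyme$kcat * enzyme$concentration *
    (indole / (enzyme$km_indole + indole)) *
    (serine / (enzyme$km_serine + serine))
}

#' Ligand production increment over a short time step
#'
#' Convenience wrapper around [enzyme_rate()]: the amount of product made
#' in `dt` minutes at the current substrate concentrations.  During full
#' simulations the rate is integrated continuously with substrate
#' depletion; this explicit-increment form is the unit-testable primitive.
#'
#' @inheritParams enzyme_rate
#' @param dt Time step, minutes.
#' @return Ligand production, uM.
#' @export
enzyme_layer <- function(enzyme, indole, serine, dt) {
  enzyme_rate(enzyme, indole, serine) * dt
}

#' Build the kinetic reaction network of a circuit
#'
#' Translates a [circuit_spec()] into a right-hand-side function over the
#' state variables: free signal `s` (B11), free antisignal `a` (aB11),
#' deactivated signal `d`, unreported and reported reporter template
#' (`rU`, `rR`, whose sum is conserved), and one pool per declared ligand
#' (prefixed `lig_`).  Template fluxes are Michaelis-type so that the pT
#' sink has limited capacity; source-template flux is proportional to the
#' TF-free template concentration, recomputed from the instantaneous
#' ligand pool at every evaluation (quasi-equilibrium TF binding); signal
#' and antisignal annihilate pairwise; free strands are degraded by the
#' exonuclease.  The fluorescence observable is `rR`.
#'
#' @param spec A valid [circuit_spec()].
#' @return An object of class `pen_network` with elements `state0` (named
#'   initial state), `rhs` (deSolve-style function) and `spec`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  r <- spec$rates
  roles <- vapply(spec$templates, `[[`, "", "role")
  conc_of <- function(role)
    sum(vapply(spec$templates[roles == role], `[[`, 0, "concentration"), 0)
  aT <- conc_of("aT"); pT <- conc_of("pT"); rT <- conc_of("rT")

  tf_by_name <- stats::setNames(spec$tfs, vapply(spec$tfs, `[[`, "", "name"))
  sources <- spec$templates[roles %in% c("sT", "psT", "pskT")]
  lig_names <- names(spec$ligand_inputs) %||% character()
  lig_states <- if (length(lig_names)) paste0("lig_", lig_names) else character()

  state0 <- c(s = spec$initial_signal, a = 0, d = 0, rU = rT, rR = 0,
              stats::setNames(as.numeric(spec$ligand_inputs), lig_states))

  rhs <- function(t, y, parms) {
    s <- y[["s"]]; a <- y[["a"]]
    rU <- y[["rU"]]
    lig <- y[lig_states]
    names(lig) <- lig_names

    src_sig <- 0
    src_anti <- 0
    for (tp in sources) {
      free <- tp$concentration
      if (!is.null(tp$operator)) {
        tf <- tf_by_name[[tp$operator]]
        L <- max(lig[[tf$ligand_name]], 0)
        p_act <- tf$dimer_concentration * active_tf_fraction(tf, L)
        free <- tp$concentration -
          template_occupancy(p_act, tp$concentration, tf$operator_kd)
      }
      flux <- r$k_source * free
      if (tp$output_polarity == "signal") src_sig <- src_sig + flux
      else src_anti <- src_anti + flux
    }

    amp <- r$k_amp * aT * s / (r$km_amp + s)
    sink <- r$k_deact * pT * s / (r$km_deact + s)
    rep_flux <- r$k_report * rU * s
    annih <- r$k_hyb * s * a

    ds <- amp + src_sig - sink - rep_flux - r$k_degr * s - annih
    da <- src_anti - r$k_degr * a - annih
    dd <- sink - r$k_degr * y[["d"]]
    drU <- -rep_flux
    drR <- rep_flux

    dlig <- stats::setNames(numeric(length(lig_names)), lig_names)
    for (ez in spec$enzymes) {
      v <- enzyme_rate(ez, max(lig[["indole"]], 0), max(lig[["serine"]], 0))
      dlig[[ez$product]] <- dlig[[ez$product]] + v
      dlig[["indole"]] <- dlig[["indole"]] - v
      dlig[["serine"]] <- dlig[["serine"]] - v / 1000  # uM -> mM
    }

    list(c(ds, da, dd, drU, drR, unname(dlig)))
  }

  structure(list(spec = spec, state0 = state0, rhs = rhs,
                 lig_states = lig_states),
            class = "pen_network")
}

#' Simulate a circuit and return its fluorescence trace
#'
#' Integrates the network with a stiff-capable solver (deSolve's `lsoda`,
#' rtol 1e-8 / atol 1e-10 on the nM scale) and reports the reporter
#' fluorescence on a uniform 1-minute grid, matching the acquisition
#' cadence of the reference experiments.  The noise-free trace is
#' non-decreasing because reporting is irreversible.
#'
#' @param spec A [circuit_spec()].
#' @param duration Simulated time, minutes (> 0).
#' @param dt Output grid spacing, minutes (default 1).
#' @param label Condition label for the trace (defaults to the circuit
#'   name or `"condition"`).
#' @return A [trace_set()] with a single trace.  If any enzyme exceeds its
#'   disruption threshold the set carries the flag
#'   `"non-specific disruption regime"` and a warning is raised.
#' @export
simulate_circuit <- function(spec, duration = 500, dt = 1, label = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  net <- build_network(spec)
  times <- seq(0, duration, by = dt)
  if (is.null(label)) label <- if (!is.null(spec$name)) spec$name else "condition"
  sol <- try(deSolve::lsoda(net$state0, times, net$rhs, parms = NULL,
                            rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times))
    stop("stiff integration failed for condition '", label, "'")
  values <- sol[, "rR"]
  conditions <- data.frame(label = label, replicate = 1L, seed = NA_integer_,
                           stringsAsFactors = FALSE)
  for (ln in names(spec$ligand_inputs))
    conditions[[ln]] <- spec$ligand_inputs[[ln]]
  flags <- character()
  over <- vapply(spec$enzymes,
                 function(ez) ez$concentration > ez$disruption_threshold, TRUE)
  if (any(over)) {
    flags <- "non-specific disruption regime"
    warning("enzyme concentration above disruption threshold: ",
            "non-specific disruption regime", call. = FALSE)
  }
  trace_set(times, matrix(values, nrow = 1,
                          dimnames = list(label, NULL)),
            conditions, flags = flags,
            full_scale = sum(vapply(spec$templates, function(tp)
              if (tp$role == "rT") tp$concentration else 0, 0)))
}

#' Locate the bistable switching threshold in initial signal
#'
#' Bisects on `initial_signal` between a level that leaves the reporter at
#' baseline and one that fires the switch, using the long-time reported
#' fraction as the outcome.  Valid because the switch outcome is monotone
#' in the initial signal.
#'
#' @param spec A source-free [circuit_spec()] (aT/pT/rT switch).
#' @param lower,upper Bracketing initial-signal concentrations, nM.
#' @param duration Simulation horizon per probe, minutes.
#' @param tol Bisection tolerance on the threshold, nM.
#' @return Threshold initial-signal concentration, nM.
#' @export
switching_threshold <- function(spec, lower = 1e-4, upper = 20,
                                duration = 500, tol = 1e-3) {
  stopifnot(inherits(spec, "circuit_spec"))
  rT <- sum(vapply(spec$templates,
                   function(tp) if (tp$role == "rT") tp$concentration else 0, 0))
  fires <- function(s0) {
    sp <- spec; sp$initial_signal <- s0
    ts <- simulate_circuit(sp, duration = duration)
    utils::tail(ts$traces[1, ], 1) > 0.5 * rT
  }
  if (fires(lower)) stop("lower bracket already fires the switch")
  if (!fires(upper)) stop("upper bracket does not fire the switch")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (fires(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
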