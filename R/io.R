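#' Load a circuit configuration from a YAML file
#'
#' Strict parsing: every section is validated field by field, unknown
#' keys are rejected with their path, and the assembled [circuit_spec()]
#' is re-validated by its constructor.
#'
#' @param path Path to a YAML circuit configuration.
#' @return A [circuit_spec()].
#' @export
load_circuit <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  known_top <- c("name", "temperature_note", "initial_signal", "templates",
                 "tfs", "enzymes", "ligand_inputs", "rates")
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) at ", where, ": ", paste(extra, collapse = ", "))
  }
  check_keys(doc, known_top, "top level")
  get_fields <- function(item, required, optional, where) {
    check_keys(item, c(required, optional), where)
    miss <- setdiff(required, names(item))
    if (length(miss))
      stop("missing key(s) at ", where, ": ", paste(miss, collapse = ", "))
    item
  }
  templates <- lapply(seq_along(doc$templates), function(i) {
    it <- get_fields(doc$templates[[i]],
                     required = c("name", "role", "concentration"),
                     optional = c("output_polarity", "operator"),
                     where = paste0("templates[", i, "]"))
    template_spec(it$name, it$role, it$concentration,
                  output_polarity = it$output_polarity,
                  operator = it$operator)
  })
  tfs <- lapply(seq_along(doc$tfs), function(i) {
    it <- get_fields(doc$tfs[[i]],
                     required = c("name", "dimer_concentration",
                                  "operator_kd", "ligand_name", "ligand_kd",
                                  "mode"),
                     optional = c("ligand_hill", "induction_fold"),
                     where = paste0("tfs[", i, "]"))
    args <- it
    args$ligand_hill <- it$ligand_hill %||% 2
    if (it$mode == "inducer") args$induction_fold <- it$induction_fold %||% 1e4
    else args$induction_fold <- 1e4  # ignored in corepressor mode
    do.call(tf_spec, args)
  })
  enzymes <- lapply(seq_along(doc$enzymes), function(i) {
    it <- get_fields(doc$enzymes[[i]],
                     required = c("name", "concentration", "kcat"),
                     optional = c("km_indole", "km_serine", "product",
                                  "disruption_threshold"),
                     where = paste0("enzymes[", i, "]"))
    do.call(enzyme_spec, it)
  })
  rates <- if (is.null(doc$rates)) rate_parameters() else {
    check_keys(doc$rates, names(formals(rate_parameters)), "rates")
    do.call(rate_parameters, doc$rates)
  }
  circuit_spec(templates, tfs = tfs, enzymes = enzymes,
               ligand_inputs = unlist(doc$ligand_inputs) %||% numeric(),
               initial_signal = doc$initial_signal %||% 0,
               rates = rates,
               temperature_note = doc$temperature_note,
               name = doc$name)
}

#' Save a circuit configuration to a YAML file
#'
#' Inverse of [load_circuit()]: `load_circuit(save_circuit(x, f))`
#' reproduces `x`.
#'
#' @param spec A [circuit_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_circuit <- function(spec, path) {
  stopifnot(inherits(spec, "circuit_spec"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, function(v) is.null(v) || (length(v) == 1L && is.na(v)),
              TRUE)]
  }
  doc <- list(name = spec$name,
              temperature_note = spec$temperature_note,
              initial_signal = spec$initial_signal,
              templates = lapply(spec$templates, strip),
              tfs = lapply(spec$tfs, strip),
              enzymes = lapply(spec$enzymes, strip),
              ligand_inputs = as.list(spec$ligand_inputs),
              rates = unclass(spec$rates))
  doc <- doc[!vapply(doc, is.null, TRUE)]
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load one of the bundled circuit fixtures
#'
#' The package ships configurations reproducing the template
#' compositions of the reference experiments: `lacI_titration` (5 nM psT),
#' `lacI_iptg` (2.5 nM psT), `trpR_direct` (1 nM psT), `lacI_inverted` /
#' `trpR_inverted` (10 nM pskT + sT), the four two-input
#' `classifier_<iptg logic>_<trp logic>` compositions, and
#' `metabolic_trpB` (enzyme-driven sensing).
#'
#' @param which Fixture name, e.g. `"trpR_inverted"`.
#' @return A [circuit_spec()].
#' @export
bundled_circuit <- function(which) {
  path <- system.file("extdata", paste0(which, ".yaml"), package = "pensense")
  if (!nzchar(path)) stop("no bundled circuit '", which, "'")
  load_circuit(path)
}

#' Write / read fluorescence traces as CSV with a JSON sidecar
#'
#' The CSV holds `time_min` plus one column per condition label; the
#' sidecar holds the condition table, quality flags and noise settings so
#' a round trip preserves the full [trace_set()].
#'
#' @param ts A [trace_set()].
#' @param path CSV output path.
#' @param meta_path Sidecar path (default: `path` with `.meta.json`).
#' @return `path`, invisibly (for `write_traces`); a `trace_set` (for
#'   `read_traces`).
#' @export
write_traces <- function(ts, path, meta_path = paste0(path, ".meta.json")) {
  stopifnot(inherits(ts, "trace_set"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  meta <- list(conditions = ts$conditions, flags = ts$flags,
               noise = attr(ts, "noise"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, meta_path = paste0(path, ".meta.json")) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_min") stop("first column must be time_min")
  conditions <- NULL
  flags <- character()
  noise <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    conditions <- as.data.frame(meta$conditions)
    flags <- meta$flags %||% character()
    noise <- meta$noise
  }
  ts <- trace_set(df$time_min, t(as.matrix(df[-1])), conditions,
                  flags = flags)
  attr(ts, "noise") <- noise
  ts
}

#' Simulate a full ligand titration with replicates
#'
#' The simulate -> noise -> Cq -> assemble pipeline for one ligand: each
#' concentration is simulated once (deterministic), replicate noisy
#' copies are generated with per-replicate seeds derived from `seed`,
#' Cq is extracted per trace and the replicate `1/Cq` values are
#' averaged into a [assemble_dose_response()] curve.
#'
#' @param spec A [circuit_spec()].
#' @param ligand Declared ligand name to titrate.
#' @param concentrations Concentrations, uM.
#' @param replicates Replicates per concentration.
#' @param sigma_rel Relative trace noise (0 = noise-free, single
#'   replicate behaviour per concentration).
#' @param duration Simulation horizon, minutes.
#' @param seed Base integer seed for the replicate noise.
#' @param ... Passed to [batch_cq()].
#' @return List with `traces` (a [trace_set()]), `cq` (per-trace table)
#'   and `curve` (the assembled dose-response).
#' @export
run_dose_response <- function(spec, ligand, concentrations, replicates = 3,
                              sigma_rel = 0, duration = 500, seed = 1, ...) {
  stopifnot(inherits(spec, "circuit_spec"))
  sets <- list()
  k <- 0L
  for (i in seq_along(concentrations)) {
    sp <- set_ligand(spec, ligand, concentrations[i])
    base <- simulate_circuit(sp, duration = duration,
                             label = sprintf("%s=%.6g", ligand,
                                             concentrations[i]))
    for (r in seq_len(replicates)) {
      k <- k + 1L
      rs <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      tsr <- if (sigma_rel > 0)
        add_noise(base, sigma_rel = sigma_rel, seed = rs) else base
      tsr$conditions$label <- sprintf("%s_r%d", base$conditions$label[1], r)
      tsr$conditions$replicate <- r
      tsr$conditions$conc <- concentrations[i]
      sets[[k]] <- tsr
    }
  }
  traces <- bind_traces(sets)
  cq <- batch_cq(traces, ...)
  curve <- assemble_dose_response(cq, conc_col = "conc", ligand = ligand)
  list(traces = traces, cq = cq, curve = curve)
}

#' Run the simulate -> Cq -> fit pipeline and write its outputs
#'
#' Composes [run_dose_response()] and [fit_hill()], writing
#' `traces.csv` (+ metadata sidecar), `cq.csv`, `curve.csv`, `fit.json`
#' and `manifest.json` under `out_dir`.  Re-running with the same
#' arguments and seed reproduces identical outputs.
#'
#' @param spec A [circuit_spec()] or path to a YAML configuration.
#' @param ligand,concentrations Titration definition (uM).
#' @param out_dir Output directory (created if needed).
#' @param seed Base integer seed.
#' @param replicates,sigma_rel,duration Passed to [run_dose_response()].
#' @param direction Passed to [fit_hill()].
#' @param window,flat_threshold,min_range Passed to [batch_cq()].
#' @return Invisibly, a list with the pipeline products and the manifest.
#' @export
run_pipeline <- function(spec, ligand, concentrations, out_dir,
                         seed = 1, replicates = 3, sigma_rel = 0.02,
                         duration = 500, direction = "auto",
                         window = 10, flat_threshold = 0.05,
                         min_range = 0.05) {
  config_path <- NULL
  if (is.character(spec)) {
    config_path <- spec
    spec <- load_circuit(spec)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_dose_response(spec, ligand, concentrations,
                           replicates = replicates, sigma_rel = sigma_rel,
                           duration = duration, seed = seed,
                           window = window, flat_threshold = flat_threshold,
                           min_range = min_range)
  fit <- fit_hill(res$curve, direction = direction)
  write_traces(res$traces, file.path(out_dir, "traces.csv"))
  utils::write.csv(res$cq, file.path(out_dir, "cq.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(res$curve)),
                   file.path(out_dir, "curve.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(baseline = fit$baseline, amplitude = fit$amplitude,
         kd_app = fit$kd_app, n_hill = fit$n_hill,
         direction = fit$direction, residual_norm = fit$residual_norm),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = config_path,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    circuit = spec$name, ligand = ligand,
    concentrations = concentrations, replicates = replicates,
    sigma_rel = sigma_rel, duration = duration, seed = seed,
    cq_params = list(window = window, flat_threshold = flat_threshold,
                     min_range = min_range),
    package_version = as.character(utils::packageVersion("pensense")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(res, list(fit = fit, manifest = manifest)))
}
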