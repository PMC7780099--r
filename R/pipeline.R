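#' Build and validate a pipeline run configuration
#'
#' Flat key-value configuration shared by the pipeline commands.  Values given
#' in `overrides` (typically command-line flags) win over values from the
#' `config_file` (YAML, flat keys), which win over defaults.  The merged
#' configuration is echoed into every summary the commands write, so a run is
#' reproducible from its own output.
#'
#' @param ... named overrides.
#' @param config_file optional path to a flat YAML config file.
#' @return A `RunConfig` list.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(
    structure = NULL, structure2 = NULL, chain_a = "A", chain_b = "B",
    loop_start = NA_integer_, loop_end = NA_integer_,
    d_strong = 3.0, d_weak_max = 5.0, d_min = 2.2,
    salt_cutoff = 5.0, water_d_hb = 3.4,
    flex_threshold = 0.10, min_run = 5L,
    aggregation = "mainchain-mean", atom_set = "mainchain",
    csv = NULL, enzyme_conc = NULL,
    variant = "wildtype", seed = 1L, outdir = ".")
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("run_config: the 'yaml' package is required to read config files",
           call. = FALSE)
    }
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  with(cfg, {
    if (!(d_min > 0 && d_min < d_strong && d_strong <= d_weak_max)) {
      stop("run_config: thresholds must satisfy 0 < d_min < d_strong <= d_weak_max",
           call. = FALSE)
    }
    if (salt_cutoff <= 0 || water_d_hb <= 0 || flex_threshold <= 0 || min_run < 1) {
      stop("run_config: thresholds must be positive", call. = FALSE)
    }
  })
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "RunConfig"
  cfg
}

provenance_block <- function(config) {
  list(package = "loopdimer",
       version = as.character(utils::packageVersion("loopdimer")),
       seed = config$seed,
       config = unclass(config)[!vapply(unclass(config), is.null, logical(1))])
}

load_structure_or_stop <- function(path, stage) {
  if (is.null(path)) stop(sprintf("%s: no structure file given", stage), call. = FALSE)
  tryCatch(read_structure(path),
           error = function(e) stop(sprintf("%s: %s", stage, conditionMessage(e)),
                                    call. = FALSE))
}

#' Flexibility / asymmetry comparison command
#'
#' Runs the superposition and B-factor stages: with one structure, superposes
#' chain B onto chain A of the dimer; with two structures, superposes the
#' second structure's chain A onto the first's.  Writes the deviation trace,
#' raw and max-normalized B-factor profiles, the flexibility comparison with
#' flagged differential regions, and a JSON summary.
#'
#' @param config a [run_config()] with `structure` (and optionally
#'   `structure2`) set.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
cmd_compare <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  model <- load_structure_or_stop(config$structure, "compare")
  if (!is.null(config$structure2)) {
    model2 <- load_structure_or_stop(config$structure2, "compare")
    sup <- compare_structures(model, config$chain_a, model2, config$chain_a,
                              atom_set = config$atom_set)
    prof_y <- residue_bfactor_profile(model2, config$chain_a, config$aggregation)
  } else {
    sup <- superpose_chains(model, config$chain_a, config$chain_b,
                            atom_set = config$atom_set)
    prof_y <- residue_bfactor_profile(model, config$chain_b, config$aggregation)
  }
  prof_x <- residue_bfactor_profile(model, config$chain_a, config$aggregation)
  norm_x <- normalize_profile(prof_x)
  norm_y <- normalize_profile(prof_y)
  flex <- compare_flexibility(norm_x, norm_y, threshold = config$flex_threshold,
                              min_run = config$min_run)

  paths <- list(trace = file.path(config$outdir, "deviation_trace.tsv"),
                bfactor_raw = file.path(config$outdir, "bfactor_raw.tsv"),
                bfactor_norm = file.path(config$outdir, "bfactor_normalized.tsv"),
                flex = file.path(config$outdir, "flexibility_comparison.tsv"),
                regions = file.path(config$outdir, "flagged_regions.bed"),
                summary = file.path(config$outdir, "compare_summary.json"))
  write_deviation_trace(sup, paths$trace)
  raw <- merge(as.data.frame(prof_x)[, c("resno", "label", "value")],
               as.data.frame(prof_y)[, c("resno", "value")],
               by = "resno", suffixes = c("_x", "_y"))
  write_profile_tsv(raw, paths$bfactor_raw)
  write_profile_tsv(as.data.frame(flex), paths$bfactor_norm)
  write_profile_tsv(as.data.frame(flex), paths$flex)
  write_regions_bed(flex, paths$regions)
  summary <- list(
    provenance = provenance_block(config),
    rmsd = sup$fit$rmsd, n_fit_atoms = sup$fit$n_atoms,
    atom_set = sup$fit$atom_set,
    trace_mean = attr(sup$trace, "mean"), trace_rms = attr(sup$trace, "rms"),
    normalizer_x = attr(norm_x, "normalizer"),
    normalizer_y = attr(norm_y, "normalizer"),
    flagged_regions = attr(flex, "regions"))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(summary)
}

#' Interaction-network command
#'
#' Enumerates hydrogen bonds, salt bridges and water bridges around the
#' configured loop range, writes the edge table and a census summary, and
#' reports the active-site metal separation when metal sites are present.
#'
#' @param config a [run_config()] with `structure`, `loop_start`, `loop_end`.
#' @return Invisibly, the summary list.
#' @export
cmd_network <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  model <- load_structure_or_stop(config$structure, "network")
  if (is.na(config$loop_start) || is.na(config$loop_end)) {
    stop("network: loop_start and loop_end are required", call. = FALSE)
  }
  net <- loop_interaction_summary(model, config$chain_a,
                                  c(config$loop_start, config$loop_end),
                                  d_strong = config$d_strong,
                                  d_weak_max = config$d_weak_max,
                                  d_min = config$d_min,
                                  salt_cutoff = config$salt_cutoff,
                                  water_d_hb = config$water_d_hb)
  site_sep <- tryCatch(active_site_separation(model), error = function(e) NULL)
  paths <- list(edges = file.path(config$outdir, "interactions.tsv"),
                summary = file.path(config$outdir, "network_summary.json"))
  write_interactions_tsv(net$edges, paths$edges)
  summary <- list(provenance = provenance_block(config),
                  focal = net$focal, census = net$summary,
                  by_class = net$by_class, thresholds = net$thresholds,
                  active_site_separation = site_sep)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(summary)
}

#' Stability-analytics command
#'
#' Reads one stability CSV (schema auto-detected: inactivation series, melt
#' curve, or substrate-rate table), runs the matching fit and writes a JSON
#' report with all parameters and the formula applied.
#'
#' @param config a [run_config()] with `csv` set (and optionally
#'   `enzyme_conc`).
#' @return Invisibly, the report list.
#' @export
cmd_stability <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$csv)) stop("stability: no csv given", call. = FALSE)
  input <- read_stability_csv(config$csv)
  report <- list(provenance = provenance_block(config), schema = input$schema)
  if (input$schema == "inactivation") {
    fit <- fit_arrhenius(input$data)
    t50 <- t50_from_fit(fit)
    report$fit <- list(model = "ln k = lnA - Ea/(R*T); T50 = Ea*1000/(R*(lnA - ln(ln2/1800)))",
                       ea_kj = fit$ea_kj, lnA = fit$lnA,
                       r_squared = fit$r_squared, n = fit$n_points,
                       t50_C = t50$t50_C, k_half = t50$k_half)
  } else if (input$schema == "melt") {
    fit <- fit_two_state_melt(input$data)
    report$fit <- list(model = "two-state sigmoid with linear baselines; Tm at F_U = 0.5",
                       tm_C = fit$tm_C, steepness_C = fit$steepness_C,
                       baseline_folded = fit$baseline_folded,
                       baseline_unfolded = fit$baseline_unfolded,
                       residual_sd = fit$residual_sd,
                       n = nrow(fit$fraction_unfolded))
  } else {
    fit <- fit_michaelis_menten(input$data, enzyme_conc = config$enzyme_conc)
    report$fit <- c(list(model = "v = Vmax*S/(KM+S)"), unclass(fit))
  }
  path <- file.path(config$outdir, "stability_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Fixture-generation command
#'
#' Generates the synthetic dimer for the configured variant and seed, writes
#' the PDB fixture and its JSON ground-truth sidecar, plus simulated
#' stability CSVs from the planted wild-type parameters.
#'
#' @param config a [run_config()]; `variant` selects `"wildtype"` or
#'   `"R336L"`.
#' @return Invisibly, list of written paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  spec <- vap_dimer_spec(variant = config$variant, seed = config$seed)
  gen <- make_toy_dimer(spec)  # errors before any file is written
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pdb = file.path(config$outdir, sprintf("synthetic_%s.pdb", config$variant)),
    truth = file.path(config$outdir, sprintf("synthetic_%s_truth.json", config$variant)),
    inactivation = file.path(config$outdir, "inactivation.csv"),
    melt = file.path(config$outdir, "melt.csv"),
    kinetics = file.path(config$outdir, "kinetics.csv"))
  write_structure(gen$model, paths$pdb)
  write_ground_truth(gen$truth, paths$truth)
  pars <- vap_stability_params()
  inact <- simulate_inactivation(pars$ea_kj, pars$lnA, noise_sd = 0.05,
                                 seed = config$seed)
  utils::write.csv(data.frame(temperature_C = inact$temperature_C,
                              k_per_s = inact$k), paths$inactivation,
                   row.names = FALSE)
  melt <- simulate_melt(pars$tm_C, pars$steepness, noise_sd = 0.36,
                        seed = config$seed)
  utils::write.csv(data.frame(temperature_C = melt$temperature_C,
                              signal = melt$signal), paths$melt,
                   row.names = FALSE)
  mm <- simulate_mm(pars$kcat, pars$km_mM, noise_sd = 0.05, seed = config$seed)
  utils::write.csv(mm, paths$kinetics, row.names = FALSE)
  invisible(paths)
}
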