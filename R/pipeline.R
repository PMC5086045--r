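# Orchestration layer: each run_* function wraps one stage of the study
# (enumerate, analyze, compare, scan, integrate, fixtures), writes TSV
# outputs plus a machine-readable summary into the configured output
# directory, and returns its results invisibly. A thin Rscript dispatcher
# over these functions ships in inst/scripts/leafefm-cli.R.

#' Run configuration
#'
#' Bundles a model source, scenario, the analysis thresholds (all default to
#' the fixed values used throughout: p = 0.05, |log2| = 0.5, amplitude 0.8,
#' top 1 percent, futile k = 5), electron-flow ratios and output directory.
#'
#' @param model `NULL` (built-in mini leaf), a `MetabolicNetwork`, or a path
#'   (`.xml` read as SBML, anything else as the tabular dialect).
#' @param scenario scenario id for [leaf_scenario()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for any stochastic fixture generation.
#' @param p_cutoff,log2_cutoff,amplitude_cutoff,percentile,futile_k thresholds.
#' @param ratios list of electron-flow ratio pairs for the scan (default all
#'   15 from 14:0 to 0:14).
#' @return object of class `RunConfig`.
#' @export
run_config <- function(model = NULL, scenario = "autotrophy_light",
                       out_dir = tempfile("leafefm_run_"), seed = 1,
                       p_cutoff = 0.05, log2_cutoff = 0.5,
                       amplitude_cutoff = 0.8, percentile = 0.01,
                       futile_k = 5, ratios = NULL) {
  thr <- c(p_cutoff, log2_cutoff, amplitude_cutoff, percentile, futile_k)
  if (any(!is.finite(thr) & thr != Inf) || any(thr <= 0))
    stop("run_config: all thresholds must be positive")
  structure(list(model = model, scenario = scenario, out_dir = out_dir,
                 seed = as.integer(seed), p_cutoff = p_cutoff,
                 log2_cutoff = log2_cutoff,
                 amplitude_cutoff = amplitude_cutoff, percentile = percentile,
                 futile_k = futile_k, ratios = ratios),
            class = "RunConfig")
}

#' @noRd
load_model <- function(config) {
  m <- config$model
  if (is.null(m)) return(make_mini_leaf())
  if (inherits(m, "MetabolicNetwork")) return(m)
  if (!file.exists(m)) stop("model file not found: ", m)
  if (grepl("\\.(xml|sbml)$", m, ignore.case = TRUE)) read_sbml(m)
  else read_table(m)
}

#' @noRd
ensure_out <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  config$out_dir
}

#' @noRd
log_line <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", sep = "", file = file.path(config$out_dir, "run.log"),
      append = TRUE)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @noRd
write_summary <- function(config, stage, values) {
  df <- data.frame(key = names(values),
                   value = vapply(values, function(v)
                     format(v, digits = 12, scientific = FALSE), ""),
                   stringsAsFactors = FALSE)
  write_tsv(df, file.path(config$out_dir, paste0(stage, "_summary.tsv")))
}

# enumerate the scenario's modes and keep everything downstream needs
#' @noRd
stage_modes <- function(config, scenario = config$scenario) {
  net <- apply_scenario(load_model(config), leaf_scenario(scenario))
  ms <- enumerate_efms(net, scenario_id = scenario)
  norm <- normalize_modes(ms, net)
  list(network = net, modeset = ms, norm = norm)
}

#' Enumerate EFMs for the configured scenario
#'
#' Writes the mode matrix (`modes.tsv`, reactions as columns) and a count
#' report, and returns the `ModeSet`.
#'
#' @param config a `RunConfig`.
#' @return list(modeset, network, files), invisibly.
#' @export
run_enumerate <- function(config) {
  ensure_out(config)
  log_line(config, "enumerate: scenario ", config$scenario)
  st <- stage_modes(config)
  M <- as.data.frame(st$modeset$modes)
  names(M) <- st$modeset$reaction_ids
  f1 <- write_tsv(cbind(mode = seq_len(nrow(M)), M),
                  file.path(config$out_dir, "modes.tsv"))
  f2 <- write_summary(config, "enumerate",
                      list(scenario = config$scenario,
                           n_modes = nrow(M),
                           n_reactions = length(st$modeset$reaction_ids),
                           n_reversible = sum(st$modeset$reversible)))
  log_line(config, "enumerate: ", nrow(M), " modes")
  invisible(list(modeset = st$modeset, network = st$network,
                 files = c(f1, f2)))
}

#' Analyze the configured scenario's modes
#'
#' Normalizes, computes yields, filters futile modes, averages the top
#' percentile, runs the quantum analysis (light scenarios) and the
#' precursor/energy/CO2 accounting on the optimal flux. Writes `yields.tsv`,
#' `top_flux.tsv`, `accounting.tsv` and a summary.
#'
#' @param config a `RunConfig`.
#' @return list(yields, top, quantum, accounting, lp, files), invisibly.
#' @export
run_analyze <- function(config) {
  ensure_out(config)
  log_line(config, "analyze: scenario ", config$scenario)
  st <- stage_modes(config)
  filt <- filter_futile(st$norm, k = config$futile_k, network = st$network)
  yl <- mode_yields(filt$kept, st$network)
  top <- top_percentile_mean(filt$kept, p = config$percentile, st$network)
  lp <- max_biomass_yield_lp(st$network)
  quant <- tryCatch(quantum_analysis(filt$kept, st$network,
                                     p = config$percentile),
                    error = function(e) NULL)
  acc <- rbind(precursor_contributions(top$mean, st$network),
               energy_accounting(top$mean, st$network))
  co2 <- co2_accounting(top$mean, st$network)
  if (!is.null(co2$shares)) acc <- rbind(acc, co2$shares)
  f <- c(write_tsv(yl, file.path(config$out_dir, "yields.tsv")),
         write_tsv(data.frame(reaction = names(top$mean),
                              mean_flux = as.numeric(top$mean),
                              sd_flux = as.numeric(top$sd)),
                   file.path(config$out_dir, "top_flux.tsv")),
         write_tsv(acc, file.path(config$out_dir, "accounting.tsv")))
  ok <- !is.na(yl$biomass_yield)
  f <- c(f, write_summary(config, "analyze", list(
    scenario = config$scenario,
    n_modes = nrow(st$norm$modes),
    n_kept = nrow(filt$kept$modes),
    n_futile_removed = nrow(filt$removed$modes),
    max_yield = max(yl$biomass_yield[ok]),
    mean_yield = mean(yl$biomass_yield[ok]),
    max_carbon_efficiency = max(yl$carbon_efficiency[ok]),
    lp_yield = lp$yield,
    quantum_band_lo = if (is.null(quant)) NA else quant$optimal_band[1],
    quantum_band_hi = if (is.null(quant)) NA else quant$optimal_band[2],
    net_co2_release_percent = co2$net_release_percent)))
  log_line(config, "analyze: max yield ", format(max(yl$biomass_yield[ok])))
  invisible(list(yields = yl, top = top, quantum = quant, accounting = acc,
                 co2 = co2, lp = lp, files = f))
}

# C-mol flux matrix of the top-percentile modes of one scenario
#' @noRd
top_cmol_matrix <- function(config, scenario) {
  st <- stage_modes(config, scenario)
  filt <- filter_futile(st$norm, k = config$futile_k, network = st$network)
  top <- top_percentile_mean(filt$kept, p = config$percentile, st$network,
                             min_n = 5)
  M <- cmol_fluxes(filt$kept, st$network)[top$indices, , drop = FALSE]
  colnames(M) <- reaction_ids(st$network)
  M
}

#' Compare two scenarios reaction by reaction
#'
#' Runs the full pipeline on both scenarios and applies
#' [compare_conditions()] to the C-mol fluxes of their top-percentile modes.
#' Writes `comparison.tsv` and a verdict tally summary.
#'
#' @param config a `RunConfig`; its scenario is condition A.
#' @param scenario_b scenario id for condition B.
#' @return list(comparison, tallies, files), invisibly.
#' @export
run_compare <- function(config, scenario_b = "heterotrophy_dark") {
  ensure_out(config)
  log_line(config, "compare: ", config$scenario, " vs ", scenario_b)
  A <- top_cmol_matrix(config, config$scenario)
  B <- top_cmol_matrix(config, scenario_b)
  common <- intersect(colnames(A), colnames(B))
  cmp <- compare_conditions(A[, common, drop = FALSE],
                            B[, common, drop = FALSE],
                            p_cutoff = config$p_cutoff,
                            log2_cutoff = config$log2_cutoff)
  tal <- table(factor(cmp$verdict, levels = c("reversed", "increased",
                                              "decreased", "unchanged")))
  f <- c(write_tsv(cmp, file.path(config$out_dir, "comparison.tsv")),
         write_summary(config, "compare",
                       c(list(scenario_a = config$scenario,
                              scenario_b = scenario_b),
                         as.list(tal))))
  log_line(config, "compare: ", tal[["reversed"]], " reversed, ",
           tal[["increased"]] + tal[["decreased"]], " changed")
  invisible(list(comparison = cmp, tallies = tal, files = f))
}

#' Scan electron-flow ratios
#'
#' Runs [scan_electron_flow()] over the configured ratio grid and writes the
#' per-ratio yield table, the top-flux matrix and the trend classification.
#'
#' @param config a `RunConfig` (light scenario).
#' @return the scan result list plus `files`, invisibly.
#' @export
run_scan_light <- function(config) {
  ensure_out(config)
  log_line(config, "scan-light: start")
  net <- load_model(config)
  sc <- scan_electron_flow(net, ratios = config$ratios,
                           config = leaf_scenario(config$scenario),
                           percentile = config$percentile,
                           futile_k = config$futile_k)
  fx <- data.frame(reaction = rownames(sc$flux), sc$flux,
                   check.names = FALSE, stringsAsFactors = FALSE)
  f <- c(write_tsv(sc$table, file.path(config$out_dir, "scan_table.tsv")),
         write_tsv(fx, file.path(config$out_dir, "scan_flux.tsv")),
         write_tsv(data.frame(reaction = names(sc$trends),
                              trend = as.character(sc$trends)),
                   file.path(config$out_dir, "scan_trends.tsv")),
         write_summary(config, "scan", list(
           n_ratios = nrow(sc$table),
           max_yield_overall = max(sc$table$max_yield),
           yield_at_zero_noncyclic = sc$table$max_yield[
             sc$table$non_cyclic == 0])))
  log_line(config, "scan-light: ", nrow(sc$table), " ratios")
  invisible(c(sc, list(files = f)))
}

#' Integrate transcript and fluxome data
#'
#' Classifies diurnal genes (amplitude cutoff from the config), maps them to
#' reactions, crosses them with the light-vs-dark flux comparison
#' (concordance), and overlays a measured fluxome on the light-optimal flux.
#' Writes `concordance.tsv` and `overlay.tsv`.
#'
#' @param config a `RunConfig` (light scenario = condition A).
#' @param transcripts path to a transcript table, or a profiles data.frame.
#' @param fluxome optional path to a fluxome table, or a named vector.
#' @param scenario_b dark scenario id.
#' @return list(concordance, overlay, comparison, files), invisibly.
#' @export
run_integrate <- function(config, transcripts, fluxome = NULL,
                          scenario_b = "heterotrophy_dark") {
  ensure_out(config)
  log_line(config, "integrate: start")
  net <- load_model(config)
  prof <- if (is.character(transcripts)) read_transcripts(transcripts)
    else transcripts
  prof <- classify_diurnal(prof, cutoff = config$amplitude_cutoff)
  mapped <- map_genes_to_reactions(net, prof)
  cmp <- run_compare(config, scenario_b)$comparison
  conc <- concordance(cmp, mapped)
  files <- write_tsv(conc, file.path(config$out_dir, "concordance.tsv"))
  ov <- NULL
  if (!is.null(fluxome)) {
    meas <- if (is.character(fluxome)) read_fluxome(fluxome, net) else fluxome
    st <- stage_modes(config)
    filt <- filter_futile(st$norm, k = config$futile_k, network = st$network)
    top <- top_percentile_mean(filt$kept, p = config$percentile, st$network)
    pred <- top$mean * carbon_transfer(st$network)
    basis <- mean(filt$kept$substrate_cmol[top$indices])
    ov <- fluxome_overlay(meas, pred, predicted_cmol = basis)
    files <- c(files, write_tsv(ov$pairs,
                                file.path(config$out_dir, "overlay.tsv")))
  }
  files <- c(files, write_summary(config, "integrate", list(
    n_diurnal_genes = sum(prof$diurnal),
    n_both = sum(conc$class == "both"),
    n_flux_only = sum(conc$class == "flux_only"),
    n_transcript_only = sum(conc$class == "transcript_only"),
    overlay_correlation = if (is.null(ov)) NA else ov$correlation)))
  log_line(config, "integrate: ", sum(conc$class == "both"),
           " concordant reactions")
  invisible(list(concordance = conc, overlay = ov, comparison = cmp,
                 files = files))
}

#' Generate all synthetic fixtures
#'
#' Writes the mini leaf model (SBML and tabular dialect), a set of seeded toy
#' networks, a transcript table and a matching fluxome into the output
#' directory. Deterministic: same seed, same bytes.
#'
#' @param config a `RunConfig` (`seed` and `out_dir` are used).
#' @param n_toys number of toy networks.
#' @return named vector of written files, invisibly.
#' @export
run_fixtures <- function(config, n_toys = 3) {
  ensure_out(config)
  log_line(config, "fixtures: seed ", config$seed)
  net <- make_mini_leaf()
  files <- c(
    mini_sbml = write_sbml(net, file.path(config$out_dir, "mini_leaf.xml")),
    mini_tsv = write_table(net, file.path(config$out_dir, "mini_leaf.tsv")))
  for (i in seq_len(n_toys)) {
    toy <- make_toy_network(config$seed + i)
    files[paste0("toy_", i)] <-
      write_table(toy, file.path(config$out_dir, sprintf("toy_%02d.tsv", i)))
  }
  tr <- make_transcripts(config$seed, net,
                         phase_hints = mini_leaf_phase_hints())
  files["transcripts"] <-
    write_transcripts(tr, file.path(config$out_dir, "transcripts.tsv"))
  scn <- apply_scenario(net, leaf_scenario(config$scenario))
  lp <- max_biomass_yield_lp(scn)
  fl <- make_fluxome(config$seed, lp$flux * carbon_transfer(scn))
  files["fluxome"] <-
    write_tsv(fl, file.path(config$out_dir, "fluxome.tsv"))
  write_summary(config, "fixtures",
                list(seed = config$seed, n_files = length(files)))
  log_line(config, "fixtures: ", length(files), " files")
  invisible(files)
}
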