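# Deterministic generators for synthetic fixtures: small oracle-enumerable
# toy networks, a miniature three-compartment leaf model with light/starch
# scenarios, diurnal transcript profiles and noisy fluxome tables.

# run code under a fixed seed without disturbing the caller's RNG stream
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a small random metabolic network
#'
#' Builds a connected backbone chain (influx -> M1 -> ... -> Mk -> efflux)
#' and adds random internal reactions between metabolite pairs, a fraction of
#' them reversible. Small enough for the brute-force EFM oracle.
#'
#' @param seed integer seed (same seed, identical network).
#' @param n_met number of internal metabolites (>= 2).
#' @param n_rxn total internal reactions including the backbone (<= 15 for
#'   oracle tractability; the two exchanges come on top).
#' @param rev_frac fraction of the extra reactions drawn reversible.
#' @param max_coef stoichiometric coefficients drawn from 1..max_coef.
#' @return a `MetabolicNetwork`.
#' @export
make_toy_network <- function(seed, n_met = 5, n_rxn = 8, rev_frac = 0.3,
                             max_coef = 2) {
  if (n_rxn < 1) stop("make_toy_network: need at least one reaction")
  if (n_met < 2) stop("make_toy_network: need at least two metabolites")
  if (n_rxn < n_met - 1)
    stop("make_toy_network: n_rxn too small for a connected backbone")
  with_seed(seed, {
    ids <- paste0("M", seq_len(n_met))
    mets <- metabolites(ids, compartment = "cytosol", carbon_atoms = 1)
    rxns <- list()
    # backbone chain
    for (i in seq_len(n_met - 1)) {
      st <- stats::setNames(c(-1, 1), c(ids[i], ids[i + 1]))
      rxns <- c(rxns, list(reaction(sprintf("R%02d", i), st,
                                    reversible = FALSE, pathway = "other")))
    }
    # random extras
    k <- n_met - 1
    while (k < n_rxn) {
      k <- k + 1
      pair <- sample(n_met, 2)
      st <- stats::setNames(c(-sample(max_coef, 1), sample(max_coef, 1)),
                            ids[pair])
      rxns <- c(rxns, list(reaction(sprintf("R%02d", k), st,
                                    reversible = stats::runif(1) < rev_frac,
                                    pathway = "other")))
    }
    net <- metabolic_network(mets, rxns,
                             provenance = sprintf("toy seed=%d", seed))
    net <- add_exchanges(net, ids[1], direction = "in")
    net <- add_exchanges(net, ids[n_met], direction = "out")
    net
  })
}

#' Miniature compartmented leaf network
#'
#' A structural miniature of leaf central carbon metabolism across cytosol,
#' plastid and mitochondrion: a lumped Calvin-cycle carboxylation, plastidic
#' and cytosolic triose/hexose interconversion, a starch store with
#' synthesis/degradation, oxidative and non-oxidative pentose-phosphate
#' routes, glycolytic pyruvate formation, a lumped TCA cycle and oxidative
#' phosphorylation, malate-valve style redox shuttles, ATP translocators, a
#' transhydrogenase, photophosphorylation at the standard 12:2
#' non-cyclic:cyclic electron-flow ratio, and a biomass reaction drawing
#' four precursors (hexose, pentose, pyruvate, plus ATP and NADPH). Both the
#' light (CO2 + photons) and dark (starch) scenarios are feasible, and the
#' plastidic triose<->hexose interconversion reverses direction between
#' them.
#'
#' Attributes: `species_roles`, `light_species`, `biomass_mass` (grams per
#' unit biomass flux; the 14-carbon biomass unit weighs 430 g).
#'
#' @param electron_flow_ratio initial (non-cyclic, cyclic) ratio.
#' @return a `MetabolicNetwork` with the five leaf exchanges attached.
#' @export
make_mini_leaf <- function(electron_flow_ratio = c(12, 2)) {
  mets <- rbind(
    metabolites("photon", compartment = "plastid", carbon_atoms = 0,
                is_balanced = FALSE),
    metabolites("CO2", compartment = "cytosol", carbon_atoms = 1),
    metabolites(c("GAP_p", "G6P_p", "R5P_p"), compartment = "plastid",
                carbon_atoms = c(3, 6, 5)),
    metabolites("starch_p", compartment = "plastid", carbon_atoms = 12,
                is_balanced = FALSE),
    metabolites(c("ATP_p", "NADPH_p"), compartment = "plastid"),
    metabolites(c("GAP_c", "G6P_c", "PYR_c"), compartment = "cytosol",
                carbon_atoms = c(3, 6, 3)),
    metabolites(c("ATP_c", "NADPH_c", "NADH_c"), compartment = "cytosol"),
    metabolites("PYR_m", compartment = "mitochondrion", carbon_atoms = 3),
    metabolites(c("ATP_m", "NADH_m"), compartment = "mitochondrion"),
    metabolites("biomass", compartment = "cytosol", carbon_atoms = 14,
                is_balanced = FALSE))

  light <- build_light_reactions(light_stoichiometry(), electron_flow_ratio,
                                 photon_id = "photon", nadph_id = "NADPH_p",
                                 atp_id = "ATP_p")
  light$genes <- c("AT4G02770", "AT1G31330")

  rx <- list(
    light,
    reaction("R_cbb", c(CO2 = -3, NADPH_p = -6, ATP_p = -9, GAP_p = 1),
             kind = "internal", compartment = "plastid", pathway = "CBB",
             genes = c("AT1G67090", "AT5G38430")),
    reaction("R_hex_p", c(GAP_p = -2, G6P_p = 1), reversible = TRUE,
             compartment = "plastid", pathway = "EMP-plastid",
             genes = c("AT2G21330", "AT1G43670")),
    reaction("R_starch_syn", c(G6P_p = -2, ATP_p = -2, starch_p = 1),
             compartment = "plastid", pathway = "starch",
             genes = "AT5G48300"),
    reaction("R_starch_deg", c(starch_p = -1, G6P_p = 2),
             compartment = "plastid", pathway = "starch",
             genes = "AT1G10760"),
    reaction("R_oxppp_p", c(G6P_p = -1, R5P_p = 1, CO2 = 1, NADPH_p = 2),
             compartment = "plastid", pathway = "oxPPP",
             genes = "AT1G24280"),
    reaction("R_ppp_nonox_p", c(G6P_p = -2, GAP_p = -1, R5P_p = 3),
             reversible = TRUE, compartment = "plastid", pathway = "PPP",
             genes = "AT3G04790"),
    reaction("T_gap", c(GAP_p = -1, GAP_c = 1), reversible = TRUE,
             kind = "transport", compartment = "plastid|cytosol",
             pathway = "transport", genes = "AT5G46110"),
    reaction("T_g6p", c(G6P_p = -1, G6P_c = 1), reversible = TRUE,
             kind = "transport", compartment = "plastid|cytosol",
             pathway = "transport", genes = "AT5G54800"),
    # hexose/triose interconversion is plastid-only (R_hex_p) in this
    # miniature, so its direction must flip between the light (GAP -> G6P
    # for starch and biomass hexose) and the dark (starch-derived G6P ->
    # GAP feeding glycolysis)
    reaction("R_glyc_c", c(GAP_c = -1, PYR_c = 1, ATP_c = 1, NADH_c = 1),
             compartment = "cytosol", pathway = "EMP-cytosol",
             genes = c("AT5G08570", "AT5G56350", "AT3G49160")),
    reaction("T_pyr", c(PYR_c = -1, PYR_m = 1), reversible = TRUE,
             kind = "transport", compartment = "cytosol|mitochondrion",
             pathway = "transport", genes = "AT5G20090"),
    reaction("R_tca", c(PYR_m = -1, CO2 = 3, NADH_m = 4, ATP_m = 1),
             compartment = "mitochondrion", pathway = "TCA",
             genes = c("AT2G44350", "AT3G55410")),
    reaction("R_oxphos", c(NADH_m = -2, ATP_m = 5),
             compartment = "mitochondrion", pathway = "oxphos",
             genes = "AT2G07698"),
    reaction("T_redox_pc", c(NADPH_p = -1, NADH_c = 1), reversible = TRUE,
             kind = "transport", compartment = "plastid|cytosol",
             pathway = "shuttle", genes = "AT5G11670"),
    reaction("T_redox_cm", c(NADH_c = -1, NADH_m = 1), reversible = TRUE,
             kind = "transport", compartment = "cytosol|mitochondrion",
             pathway = "shuttle", genes = "AT2G22780"),
    reaction("R_transhyd", c(NADPH_c = -1, NADH_c = 1), reversible = TRUE,
             compartment = "cytosol", pathway = "shuttle",
             genes = "AT3G15020"),
    reaction("T_atp_pc", c(ATP_p = -1, ATP_c = 1), reversible = TRUE,
             kind = "transport", compartment = "plastid|cytosol",
             pathway = "transport", genes = "AT1G15500"),
    reaction("T_atp_mc", c(ATP_m = -1, ATP_c = 1), reversible = TRUE,
             kind = "transport", compartment = "cytosol|mitochondrion",
             pathway = "transport", genes = "AT3G08580"),
    reaction("R_biomass",
             c(G6P_c = -1, R5P_p = -1, PYR_m = -1, ATP_c = -10,
               NADPH_c = -4, biomass = 1),
             compartment = "cytosol", pathway = "biomass"))

  net <- metabolic_network(mets, rx, provenance = "mini leaf fixture")
  net <- add_exchanges(net, c("CO2", "photon", "starch_p", "biomass"),
                       direction = c("both", "in", "in", "out"))
  net <- add_exchanges(net, "ATP_c", direction = "out")  # maintenance ATP
  attr(net, "species_roles") <- list(photon = "photon", co2 = "CO2",
                                     starch = "starch_p", biomass = "biomass",
                                     maint = "ATP_c")
  attr(net, "light_species") <- list(photon = "photon", nadph = "NADPH_p",
                                     atp = "ATP_p")
  attr(net, "biomass_mass") <- 430
  net
}

#' Diurnal phase hints for the mini leaf's genes
#'
#' Expected expression phases matching the fixture's physiology: genes of
#' photosynthesis, carbon fixation, hexose-phosphate synthesis and starch
#' synthesis peak in the light; genes of starch degradation, glycolysis,
#' pyruvate transport and the TCA cycle peak in the dark. Pass to
#' [make_transcripts()] as `phase_hints` for a transcript fixture whose
#' diurnal genes agree with the model's light/dark flux changes.
#'
#' @return named character vector gene id -> phase.
#' @export
mini_leaf_phase_hints <- function() {
  c(AT4G02770 = "light_up", AT1G31330 = "light_up",  # light reactions
    AT1G67090 = "light_up", AT5G38430 = "light_up",  # carbon fixation
    AT2G21330 = "light_up", AT1G43670 = "light_up",  # hexose-P synthesis
    AT5G48300 = "light_up",                          # starch synthesis
    AT1G10760 = "dark_up",                           # starch degradation
    AT5G46110 = "dark_up", AT5G54800 = "dark_up",    # sugar-P export
    AT5G08570 = "dark_up", AT5G56350 = "dark_up",    # glycolysis
    AT3G49160 = "dark_up",
    AT5G20090 = "dark_up",                           # pyruvate transport
    AT2G44350 = "dark_up", AT3G55410 = "dark_up")    # TCA cycle
}

#' Generate diurnal transcript profiles
#'
#' Genes are split into a diurnal cohort (amplitudes drawn from
#' N(`amp_diurnal`, `amp_sd`), truncated at zero; phase light_up or dark_up)
#' and a flat cohort (amplitudes from N(`amp_flat`, `amp_sd`), phase none).
#' A sinusoidal expression series over a 12 h light / 12 h dark cycle is
#' emitted alongside, peaking mid-light for light_up genes and mid-dark for
#' dark_up genes. The ground-truth diurnal label (amplitude above `cutoff`
#' with a phase) is attached as column `truth_diurnal`.
#'
#' @param seed integer seed.
#' @param network optional network whose gene ids seed the table; extra
#'   background genes are appended up to `n_genes`.
#' @param n_genes total number of genes.
#' @param frac_diurnal fraction assigned to the diurnal cohort.
#' @param amp_diurnal,amp_flat,amp_sd amplitude distribution parameters
#'   (log2 units).
#' @param cutoff amplitude cutoff defining the ground truth (default 0.8).
#' @param timepoints number of samples over the 24 h cycle.
#' @param phase_hints optional named character vector gene id -> phase
#'   (`"light_up"`/`"dark_up"`); hinted genes are forced into the diurnal
#'   cohort with the given phase (used to make fixture transcripts agree
#'   with the fixture's known flux physiology).
#' @return data.frame: gene_id, log2_amplitude, phase, truth_diurnal, and
#'   expression columns t_<hour>.
#' @export
make_transcripts <- function(seed, network = NULL, n_genes = 200,
                             frac_diurnal = 0.4, amp_diurnal = 1.5,
                             amp_flat = 0.3, amp_sd = 0.4, cutoff = 0.8,
                             timepoints = 12, phase_hints = NULL) {
  with_seed(seed, {
    genes <- character(0)
    if (!is.null(network))
      genes <- unique(unlist(lapply(network$reactions, function(r) r$genes)))
    if (length(genes) < n_genes)
      genes <- c(genes, sprintf("ATSYN%04d", seq_len(n_genes - length(genes))))
    genes <- genes[seq_len(n_genes)]
    n_di <- round(frac_diurnal * n_genes)
    di <- seq_len(n_genes) <= n_di   # deterministic assignment, genes shuffled
    genes <- sample(genes)
    amp <- ifelse(di, stats::rnorm(n_genes, amp_diurnal, amp_sd),
                  stats::rnorm(n_genes, amp_flat, amp_sd))
    amp <- pmax(amp, 0)
    phase <- ifelse(di, sample(c("light_up", "dark_up"), n_genes, TRUE), "none")
    if (!is.null(phase_hints)) {
      hit <- match(names(phase_hints), genes)
      ok <- !is.na(hit)
      phase[hit[ok]] <- unname(phase_hints[ok])
      amp[hit[ok]] <- pmax(amp[hit[ok]], amp_diurnal)  # force above cutoff
    }
    hours <- seq(0, 24 - 24 / timepoints, length.out = timepoints)
    base <- stats::rnorm(n_genes, 8, 1)
    series <- sapply(hours, function(h) {
      # light period 0-12 h; light_up genes peak at h = 6, dark_up at h = 18
      shift <- ifelse(phase == "light_up", 6, ifelse(phase == "dark_up", 18, 0))
      osc <- ifelse(phase == "none", 0,
                    amp / 2 * cos(2 * pi * (h - shift) / 24))
      base + osc
    })
    colnames(series) <- sprintf("t_%02d", round(hours))
    out <- data.frame(gene_id = genes, log2_amplitude = amp, phase = phase,
                      truth_diurnal = amp > cutoff & phase != "none",
                      stringsAsFactors = FALSE)
    cbind(out, series)
  })
}

#' Generate a measured fluxome from a flux vector
#'
#' Multiplicative log-normal noise on a supplied flux vector; the ground
#' truth is the input itself. Zero noise returns the input exactly.
#'
#' @param seed integer seed.
#' @param flux named numeric flux vector (C-mol basis).
#' @param noise_sd standard deviation of the log-normal factor (0 = exact).
#' @return data.frame: reaction_id, flux, unit.
#' @export
make_fluxome <- function(seed, flux, noise_sd = 0.1) {
  with_seed(seed, {
    f <- as.numeric(flux)
    if (noise_sd > 0) f <- f * exp(stats::rnorm(length(f), 0, noise_sd))
    data.frame(reaction_id = names(flux), flux = f, unit = "cmol_per_cmol",
               stringsAsFactors = FALSE)
  })
}
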