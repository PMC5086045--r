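# Physiological scenario configuration.
#
# A scenario opens/closes the exchange reactions (CO2, photons, starch),
# fixes the photophosphorylation ratio and the maintenance-ATP policy.
# Networks carry a `species_roles` attribute naming which metabolites play
# the photon / CO2 / starch / biomass / maintenance-ATP roles, plus a
# `light_species` attribute naming the photon/NADPH/ATP species of the
# plastidic light reaction, and a `biomass_mass` attribute (grams of biomass
# per unit flux of the biomass exchange).

#' Scenario configuration
#'
#' @param co2_uptake logical: CO2 exchange bidirectional (TRUE) or
#'   efflux-only (FALSE).
#' @param starch_degradation logical: starch influx open.
#' @param starch_accumulation logical: when starch influx is closed, keep the
#'   starch exchange as an efflux (daytime starch storage) instead of
#'   removing it; ignored when `starch_degradation = TRUE`.
#' @param light_influx logical: photon influx open.
#' @param electron_flow_ratio integer pair (non_cyclic, cyclic) summing
#'   to 14.
#' @param maintenance_atp `"free_efflux_required"` (irreversible ATP efflux
#'   that may carry any non-negative flux, excluding ATP-deficient modes
#'   while permitting apparent excess) or `"off"`.
#' @return object of class `ScenarioConfig`.
#' @export
scenario_config <- function(co2_uptake = TRUE, starch_degradation = FALSE,
                            light_influx = TRUE,
                            electron_flow_ratio = c(12, 2),
                            maintenance_atp = c("free_efflux_required", "off"),
                            starch_accumulation = FALSE) {
  maintenance_atp <- match.arg(maintenance_atp)
  r <- electron_flow_ratio
  if (length(r) != 2 || any(r < 0) || any(r != round(r)) || sum(r) != 14)
    stop("electron_flow_ratio must be two non-negative integers summing to 14")
  if (!co2_uptake && !starch_degradation)
    stop("at least one carbon source (CO2 or starch) must be open when biomass is demanded")
  structure(list(co2_uptake = co2_uptake,
                 starch_degradation = starch_degradation,
                 starch_accumulation = isTRUE(starch_accumulation) &&
                   !starch_degradation,
                 light_influx = light_influx,
                 electron_flow_ratio = r,
                 maintenance_atp = maintenance_atp),
            class = "ScenarioConfig")
}

#' Canonical Table-1 style scenarios
#' @param which `"autotrophy_light"`, `"autotrophy_dark"`,
#'   `"heterotrophy_light"` or `"heterotrophy_dark"`.
#' @param electron_flow_ratio passed through to [scenario_config()].
#' @export
leaf_scenario <- function(which = c("autotrophy_light", "autotrophy_dark",
                                    "heterotrophy_light", "heterotrophy_dark"),
                          electron_flow_ratio = c(12, 2)) {
  which <- match.arg(which)
  switch(which,
    autotrophy_light  = scenario_config(TRUE,  FALSE, TRUE,  electron_flow_ratio,
                                        starch_accumulation = TRUE),
    autotrophy_dark   = scenario_config(TRUE,  FALSE, FALSE, electron_flow_ratio),
    heterotrophy_light = scenario_config(FALSE, TRUE, TRUE,  electron_flow_ratio),
    heterotrophy_dark = scenario_config(FALSE, TRUE,  FALSE, electron_flow_ratio))
}

#' Photophosphorylation stoichiometry parameters
#'
#' Defaults encode non-cyclic electron flow as 8 photons -> 2 NADPH + 2 ATP
#' and cyclic flow as 2 photons -> 1 ATP. One non-cyclic ratio unit is 2/3
#' photon yielding 1/6 NADPH + 1/6 ATP; one cyclic unit is 1 photon yielding
#' 1/2 ATP, so the 14-unit ratio grid reproduces the 8+2-photon base case at
#' 12:2 with ATP:NADPH = 1.5.
#'
#' @param photons_per_noncyclic_unit,nadph_per_noncyclic_unit,
#'   atp_per_noncyclic_unit,photons_per_cyclic_atp positive rationals.
#' @return object of class `LightStoichiometry`.
#' @export
light_stoichiometry <- function(photons_per_noncyclic_unit = 2 / 3,
                                nadph_per_noncyclic_unit = 1 / 6,
                                atp_per_noncyclic_unit = 1 / 6,
                                photons_per_cyclic_atp = 2) {
  vals <- c(photons_per_noncyclic_unit, nadph_per_noncyclic_unit,
            atp_per_noncyclic_unit, photons_per_cyclic_atp)
  if (any(vals <= 0)) stop("light stoichiometry parameters must be positive")
  structure(list(photons_per_noncyclic_unit = photons_per_noncyclic_unit,
                 nadph_per_noncyclic_unit = nadph_per_noncyclic_unit,
                 atp_per_noncyclic_unit = atp_per_noncyclic_unit,
                 photons_per_cyclic_atp = photons_per_cyclic_atp),
            class = "LightStoichiometry")
}

#' Build the lumped plastidic light reaction for an electron-flow ratio
#'
#' @param stoich a [light_stoichiometry()].
#' @param ratio integer pair (non_cyclic, cyclic) summing to 14.
#' @param photon_id,nadph_id,atp_id metabolite ids.
#' @return a single lumped [reaction()] consuming photons and producing
#'   NADPH/ATP in the proportions implied by the ratio; coefficients scaled
#'   to integers where possible.
#' @export
build_light_reactions <- function(stoich, ratio, photon_id = "photon",
                                  nadph_id = "NADPH_p", atp_id = "ATP_p") {
  nc <- ratio[1]; cy <- ratio[2]
  if (any(ratio < 0) || sum(ratio) != 14) stop("invalid electron-flow ratio")
  photons <- nc * stoich$photons_per_noncyclic_unit + cy * 1
  nadph <- nc * stoich$nadph_per_noncyclic_unit
  atp <- nc * stoich$atp_per_noncyclic_unit + cy / stoich$photons_per_cyclic_atp
  st <- c(-photons, nadph, atp)
  names(st) <- c(photon_id, nadph_id, atp_id)
  # scale to integers (clears the 1/6-unit denominators at defaults)
  r <- rat_from_decimal(st)
  l <- Reduce(rat_lcm, c(1, r$den))
  st <- stats::setNames(r$num * (l / r$den), names(st))
  st <- st[st != 0]
  reaction(sprintf("R_light_%d_%d", nc, cy), st, reversible = FALSE,
           kind = "internal", compartment = "plastid", pathway = "light")
}

#' Apply a scenario to a network
#'
#' Opens/closes exchanges per configuration and replaces the light
#' reaction(s) according to the electron-flow ratio. Applying a scenario
#' always starts from the stored base network, so re-application is
#' idempotent and toggling restores the base configuration.
#'
#' @param network a `MetabolicNetwork` with the five leaf exchanges attached
#'   and `species_roles`/`light_species` attributes.
#' @param config a [scenario_config()].
#' @param stoich a [light_stoichiometry()].
#' @return configured `MetabolicNetwork` (attribute `scenario` holds config).
#' @export
apply_scenario <- function(network, config,
                           stoich = light_stoichiometry()) {
  base <- attr(network, "scenario_base")
  if (is.null(base)) base <- network
  roles <- attr(base, "species_roles")
  if (is.null(roles)) stop("apply_scenario: network lacks a species_roles attribute")
  net <- base

  # photon influx
  if (!config$light_influx) net <- remove_exchanges(net, roles$photon)
  # starch: influx (degradation), efflux (daytime accumulation), or closed
  if (!config$starch_degradation) {
    if (isTRUE(config$starch_accumulation) && !is.na(roles$starch[1])) {
      idx <- which(vapply(net$reactions, function(r)
        r$kind == "exchange" && roles$starch %in% r$mets, TRUE))
      for (i in idx) {
        net$reactions[[i]]$reversible <- FALSE
        net$reactions[[i]]$num <- -abs(net$reactions[[i]]$num)  # efflux
      }
    } else net <- remove_exchanges(net, roles$starch)
  }
  # CO2: bidirectional when uptake allowed, efflux-only otherwise
  if (!config$co2_uptake) {
    idx <- which(vapply(net$reactions, function(r)
      r$kind == "exchange" && roles$co2 %in% r$mets, TRUE))
    for (i in idx) {
      net$reactions[[i]]$reversible <- FALSE
      # efflux convention: coefficient -1 on the species
      net$reactions[[i]]$num <- -abs(net$reactions[[i]]$num)
    }
  }
  # maintenance ATP policy
  if (config$maintenance_atp == "off" && !is.null(roles$maint))
    net <- remove_exchanges(net, roles$maint)
  # light reaction per electron-flow ratio
  ls <- attr(base, "light_species")
  if (!is.null(ls)) {
    keep <- vapply(net$reactions, function(r) r$pathway != "light", TRUE)
    genes <- unique(unlist(lapply(net$reactions[!keep], function(r) r$genes)))
    net$reactions <- net$reactions[keep]
    if (config$light_influx) {
      lr <- build_light_reactions(stoich, config$electron_flow_ratio,
                                  photon_id = ls$photon, nadph_id = ls$nadph,
                                  atp_id = ls$atp)
      lr$genes <- as.character(genes)
      net$reactions <- c(net$reactions, list(lr))
    }
  }
  attr(net, "species_roles") <- roles
  attr(net, "light_species") <- ls
  attr(net, "biomass_mass") <- attr(base, "biomass_mass")
  attr(net, "scenario_base") <- base
  attr(net, "scenario") <- config
  net
}

# exchange columns importing carbon (substrate uptake definition used by the
# LP and by mode normalization); returns data.frame(id, species, carbon,
# direction) for carbon-bearing exchange reactions
#' @noRd
substrate_exchanges <- function(network) {
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  roles <- attr(network, "species_roles")
  out <- do.call(rbind, lapply(network$reactions, function(r) {
    if (r$kind != "exchange") return(NULL)
    m <- r$mets[1]
    if (carbons[m] <= 0) return(NULL)
    if (!is.null(roles) && identical(m, roles$biomass)) return(NULL)
    can_in <- r$reversible || r$num[1] > 0
    if (!can_in) return(NULL)
    data.frame(id = r$id, species = m, carbon = carbons[m],
               stringsAsFactors = FALSE)
  }))
  out
}

#' Maximum biomass yield by linear programming
#'
#' Independent oracle for the theoretical maximum growth yield: maximize the
#' biomass efflux per unit of substrate carbon uptake subject to S v = 0 and
#' reaction sign constraints. Equals the maximum over all EFM yields.
#'
#' @param network scenario-configured `MetabolicNetwork`.
#' @return list(yield = g biomass per C-mol substrate, flux = named vector on
#'   the original reaction basis, feasible = logical).
#' @export
max_biomass_yield_lp <- function(network) {
  roles <- attr(network, "species_roles")
  if (is.null(roles)) stop("network lacks species_roles")
  mass <- attr(network, "biomass_mass")
  if (is.null(mass)) stop("network lacks a biomass_mass attribute")
  sp <- split_reversible(network)
  S <- as.matrix(build_matrix(sp$network))
  n <- ncol(S)
  ids <- reaction_ids(sp$network)
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  # substrate C-mol uptake row: positive-coefficient exchange columns on
  # carbon sources
  uptake <- numeric(n)
  for (j in seq_along(sp$network$reactions)) {
    r <- sp$network$reactions[[j]]
    if (r$kind != "exchange") next
    m <- r$mets[1]
    if (carbons[m] <= 0 || identical(m, roles$biomass)) next
    coef <- r$num[1] / r$den[1]
    if (coef > 0) uptake[j] <- coef * carbons[m]
  }
  bio_col <- match(paste0("EX_", roles$biomass), ids)
  if (is.na(bio_col)) stop("no biomass exchange reaction found")
  if (all(uptake == 0)) return(list(yield = 0, flux = NULL, feasible = FALSE))
  obj <- numeric(n); obj[bio_col] <- 1
  Aeq <- rbind(S, uptake)
  beq <- c(numeric(nrow(S)), 1)
  res <- lp_max_eq(obj, Aeq, beq)
  if (res$status != "optimal")
    return(list(yield = 0, flux = NULL, feasible = FALSE))
  v <- res$x
  # fold split fluxes back
  flux <- stats::setNames(numeric(length(network$reactions)),
                          reaction_ids(network))
  for (k in seq_len(nrow(sp$fold))) {
    flux[sp$fold$orig[k]] <- flux[sp$fold$orig[k]] +
      sp$fold$dir[k] * v[match(sp$fold$col[k], ids)]
  }
  list(yield = res$fval * mass, flux = flux, feasible = TRUE)
}

#' Scan photophosphorylation plasticity over electron-flow ratios
#'
#' For each (non-cyclic : cyclic) ratio, applies the light scenario,
#' enumerates EFMs, records the maximum biomass yield and the top-percentile
#' mean flux vector, then classifies each reaction's absolute-flux trend
#' across the scan as flat, rising at low cyclic contribution, or rising at
#' high cyclic contribution.
#'
#' @param network base network (with roles/light attributes).
#' @param ratios list of ratio pairs; default all 15 from 14:0 to 0:14.
#' @param config base scenario (light scenario; its ratio is overridden).
#' @param percentile top fraction for the optimal flux average.
#' @param futile_k transport-cycling threshold passed to [filter_futile()].
#' @param trend_factor fold-change over the mid-scan median that marks a
#'   rising trend.
#' @return list(table = data.frame(non_cyclic, cyclic, atp_nadph, max_yield,
#'   n_modes), flux = matrix (reactions x ratios) of top-percentile means,
#'   trends = named character vector).
#' @export
scan_electron_flow <- function(network, ratios = NULL,
                               config = leaf_scenario("autotrophy_light"),
                               percentile = 0.01, futile_k = Inf,
                               trend_factor = 1.5) {
  if (is.null(ratios))
    ratios <- lapply(0:14, function(cy) c(14 - cy, cy))
  stoich <- light_stoichiometry()
  tab <- NULL
  fluxes <- NULL
  for (r in ratios) {
    cfg <- config
    cfg$electron_flow_ratio <- r
    net <- apply_scenario(network, cfg, stoich = stoich)
    atp_nadph <- if (r[1] > 0)
      (r[1] * stoich$atp_per_noncyclic_unit +
         r[2] / stoich$photons_per_cyclic_atp) /
        (r[1] * stoich$nadph_per_noncyclic_unit) else Inf
    ms <- enumerate_efms(net, scenario_id = sprintf("ratio_%d_%d", r[1], r[2]))
    norm <- normalize_modes(ms, network = net)
    yl <- mode_yields(norm, network = net)
    kept <- filter_futile(norm, k = futile_k, network = net)$kept
    max_y <- if (nrow(yl) && any(yl$biomass_yield > 0, na.rm = TRUE))
      max(yl$biomass_yield, na.rm = TRUE) else 0
    fv <- stats::setNames(rep(NA_real_, length(ms$reaction_ids)),
                          ms$reaction_ids)
    if (nrow(kept$modes) > 0 && max_y > 0) {
      tp <- top_percentile_mean(kept, p = percentile, network = net)
      fv[names(tp$mean)] <- tp$mean
    }
    tab <- rbind(tab, data.frame(non_cyclic = r[1], cyclic = r[2],
                                 atp_nadph = atp_nadph, max_yield = max_y,
                                 n_modes = nrow(ms$modes)))
    fluxes <- cbind(fluxes, fv)
  }
  colnames(fluxes) <- sprintf("%d:%d", tab$non_cyclic, tab$cyclic)
  # trend classification over ratios with any feasible flux
  feas <- which(tab$max_yield > 0)
  trends <- stats::setNames(rep("flat", nrow(fluxes)), rownames(fluxes))
  if (length(feas) >= 3) {
    mid <- feas[tab$cyclic[feas] >= 3 & tab$cyclic[feas] <= 10]
    if (length(mid) < 2) mid <- feas[-c(1, length(feas))]
    for (i in seq_len(nrow(fluxes))) {
      f <- abs(fluxes[i, feas])
      if (all(is.na(f)) || max(f, na.rm = TRUE) == 0) next
      m <- stats::median(abs(fluxes[i, mid]), na.rm = TRUE)
      lo <- abs(fluxes[i, feas[1]])   # lowest cyclic contribution
      hi <- abs(fluxes[i, feas[length(feas)]])  # highest feasible cyclic
      base <- max(m, 1e-9)
      if (!is.na(hi) && hi > trend_factor * base) trends[i] <- "rises_high_cyclic"
      else if (!is.na(lo) && lo > trend_factor * base) trends[i] <- "rises_low_cyclic"
    }
  }
  list(table = tab, flux = fluxes, trends = trends)
}
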