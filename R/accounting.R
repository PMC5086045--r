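# Provenance accounting: decompose a steady-state flux vector into the
# pathway and compartment shares that supply anabolic precursors, redox/ATP,
# and release CO2. Only producing half-fluxes enter the shares (a reversible
# reaction contributes by the sign of its realized flux); fractions over the
# sources of one target sum to one.

# producing contributions of each reaction to a species group under flux v:
# data.frame(reaction, pathway, compartment, production)
#' @noRd
producers_of <- function(flux, network, species_ids) {
  out <- do.call(rbind, lapply(seq_along(network$reactions), function(j) {
    r <- network$reactions[[j]]
    v <- flux[[r$id]]
    if (is.null(v) || is.na(v) || v == 0) return(NULL)
    hit <- r$mets %in% species_ids
    if (!any(hit)) return(NULL)
    # net production over the species group, so intra-group transport
    # (e.g. moving ATP between compartments) is not counted as a source
    prod <- sum((r$num[hit] / r$den[hit]) * v)
    if (prod <= 1e-12) return(NULL)
    data.frame(reaction = r$id, pathway = r$pathway,
               compartment = r$compartment, production = prod,
               stringsAsFactors = FALSE)
  }))
  out
}

#' @noRd
share_table <- function(prod, target, total = NULL) {
  if (is.null(prod) || !nrow(prod)) return(NULL)
  if (is.null(total)) total <- sum(prod$production)
  by_pw <- stats::aggregate(production ~ pathway, prod, sum)
  by_cp <- stats::aggregate(production ~ compartment, prod, sum)
  rbind(
    data.frame(target = target, by = "pathway", source = by_pw$pathway,
               fraction = by_pw$production / total, stringsAsFactors = FALSE),
    data.frame(target = target, by = "compartment", source = by_cp$compartment,
               fraction = by_cp$production / total, stringsAsFactors = FALSE))
}

#' Pathway contributions to anabolic precursor supply
#'
#' For each biomass precursor, every producing reaction (positive signed flux
#' times stoichiometric coefficient) is binned by its pathway label and by
#' its compartment; fractions are production divided by total production of
#' that precursor.
#'
#' @param flux named flux vector (a steady-state vector, e.g. a
#'   top-percentile mean).
#' @param network matching `MetabolicNetwork`.
#' @param precursors precursor metabolite ids; default: carbon-bearing
#'   species consumed by the biomass reaction.
#' @return long-format data.frame: target, by (pathway/compartment), source,
#'   fraction.
#' @export
precursor_contributions <- function(flux, network, precursors = NULL) {
  if (is.null(precursors)) {
    bio <- Filter(function(r) r$pathway == "biomass", network$reactions)
    if (!length(bio)) stop("no biomass reaction (pathway 'biomass') found")
    carbons <- stats::setNames(network$metabolites$carbon_atoms,
                               network$metabolites$id)
    b <- bio[[1]]
    precursors <- b$mets[b$num < 0 & carbons[b$mets] > 0]
    bio_flux <- flux[[b$id]]
  } else bio_flux <- NA_real_
  flux <- as.list(flux)
  out <- NULL
  for (m in precursors) {
    prod <- producers_of(flux, network, m)
    if (is.null(prod)) {
      if (!is.na(bio_flux) && bio_flux > 1e-9)
        stop("precursor '", m, "' has biomass demand but zero production")
      next
    }
    # exclude the biomass sink itself from sources (it only consumes)
    out <- rbind(out, share_table(prod, m))
  }
  out
}

#' Redox and ATP supply accounting
#'
#' Producing fluxes of each cofactor group (NADPH, NADH, ATP; all
#' compartmental species pooled by id prefix) binned by pathway and by
#' compartment, expressed per total demand (total consumption flux) of the
#' group.
#'
#' @param flux named flux vector.
#' @param network matching network.
#' @param groups named list of species-id vectors; default: ids matching
#'   `^NADPH`, `^NADH`, `^ATP`.
#' @return long-format data.frame: target, by, source, fraction.
#' @export
energy_accounting <- function(flux, network, groups = NULL) {
  ids <- network$metabolites$id
  if (is.null(groups)) {
    groups <- list(NADPH = grep("^NADPH", ids, value = TRUE),
                   NADH = grep("^NADH", ids, value = TRUE),
                   ATP = grep("^ATP", ids, value = TRUE))
  }
  flux <- as.list(flux)
  out <- NULL
  for (g in names(groups)) {
    sp <- groups[[g]]
    if (!length(sp)) next
    prod <- producers_of(flux, network, sp)
    if (is.null(prod)) next
    # demand = total consumption of the group (equals production at steady
    # state when the group is closed)
    demand <- sum(vapply(network$reactions, function(r) {
      v <- flux[[r$id]]
      if (is.null(v) || is.na(v) || v == 0) return(0)
      hit <- r$mets %in% sp
      if (!any(hit)) return(0)
      max(-sum((r$num[hit] / r$den[hit]) * v), 0)   # net group consumption
    }, 0))
    out <- rbind(out, share_table(prod, g, total = demand))
  }
  out
}

#' CO2 origin and net-release accounting
#'
#' CO2-producing reaction fluxes binned by pathway and compartment, plus the
#' net CO2 release as a percentage of substrate carbon uptake. On any single
#' mode this complements the carbon efficiency: release percent equals 100
#' minus carbon efficiency.
#'
#' @param flux named flux vector (substrate-normalized).
#' @param network matching network (supplies `species_roles`).
#' @return list(shares = long-format data.frame over producing reactions
#'   excluding the exchange, net_release_percent, substrate_cmol).
#' @export
co2_accounting <- function(flux, network) {
  roles <- attr(network, "species_roles")
  if (is.null(roles)) stop("co2_accounting: network lacks species_roles")
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  fl <- as.list(flux)
  prod <- producers_of(fl, network, roles$co2)
  if (!is.null(prod)) prod <- prod[!grepl("^EX_", prod$reaction), , drop = FALSE]
  shares <- share_table(prod, "CO2")
  # substrate C-mol uptake and net CO2 efflux from the exchange columns
  sub_cmol <- 0; co2_out <- 0
  for (r in network$reactions) {
    if (r$kind != "exchange") next
    v <- fl[[r$id]]
    if (is.null(v) || is.na(v)) next
    m <- r$mets[1]
    coef <- r$num[1] / r$den[1]
    d <- coef * v * carbons[m]   # carbon added to the system by this column
    if (identical(m, roles$co2)) {
      if (d < 0) co2_out <- co2_out - d else sub_cmol <- sub_cmol + d
    } else if (carbons[m] > 0 && !identical(m, roles$biomass) && d > 0) {
      sub_cmol <- sub_cmol + d
    }
  }
  list(shares = shares,
       net_release_percent = if (sub_cmol > 0)
         unname(co2_out / sub_cmol * 100) else NA_real_,
       substrate_cmol = unname(sub_cmol))
}
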