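# Mode-level analytics: substrate normalization, biomass yields and carbon
# efficiency, futile-mode filtering, top-percentile flux averaging,
# quantum-requirement analysis and condition comparison.

#' Carbon atoms transferred by each reaction
#'
#' Total carbon on the producing side of every reaction (equal to the
#' consuming side for carbon-balanced reactions). Multiplying a mol-basis
#' flux vector by this converts it to C-mol fluxes.
#'
#' @param network a `MetabolicNetwork`.
#' @return named numeric vector over the network's reaction ids.
#' @export
carbon_transfer <- function(network) {
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  vapply(network$reactions, function(r) {
    coef <- r$num / r$den
    sum(pmax(coef, 0) * carbons[r$mets])
  }, 0)
}

# uptake fluxes of a mode through an exchange reaction (positive = into the
# system), given the exchange column's stored coefficient sign convention
#' @noRd
exchange_uptake <- function(modes, network, species) {
  ids <- reaction_ids(network)
  j <- which(vapply(network$reactions, function(r)
    r$kind == "exchange" && species %in% r$mets, TRUE))
  if (!length(j)) return(rep(0, nrow(modes)))
  r <- network$reactions[[j[1]]]
  coef <- r$num[1] / r$den[1]
  modes[, j[1]] * coef   # coef > 0: positive flux imports; coef < 0: exports
}

#' Normalize modes to their substrate uptake
#'
#' Light (CO2-consuming) modes are scaled to 100 mol CO2 uptake; dark
#' (starch-consuming) modes to 50 mol starch (C12 dimer units), i.e. 100
#' C-mol and 600 C-mol of substrate carbon respectively. The per-mode
#' substrate C-mol is recorded so yields are always per C-mol regardless of
#' basis. Modes without substrate uptake are flagged and excluded from yield
#' statistics.
#'
#' @param modeset a `ModeSet`.
#' @param network the scenario-configured network the modes were enumerated
#'   on (provides `species_roles`).
#' @param co2_basis,starch_basis normalization targets (mol).
#' @return object of class `NormalizedModes`: list(modes = numeric matrix,
#'   reaction_ids, reversible, basis, substrate_cmol, excluded, scenario_id).
#' @export
normalize_modes <- function(modeset, network, co2_basis = 100,
                            starch_basis = 50) {
  if (inherits(modeset, "NormalizedModes")) return(modeset)  # idempotent
  roles <- attr(network, "species_roles")
  if (is.null(roles)) stop("normalize_modes: network lacks species_roles")
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  M <- modeset$modes * 1.0
  nm <- nrow(M)
  basis <- rep("none", nm)
  sub_cmol <- rep(NA_real_, nm)
  if (nm) {
    st_up <- exchange_uptake(M, network, roles$starch)
    co_up <- exchange_uptake(M, network, roles$co2)
    for (i in seq_len(nm)) {
      if (!is.na(roles$starch[1]) && st_up[i] > 1e-12) {
        s <- starch_basis / st_up[i]
        M[i, ] <- M[i, ] * s
        basis[i] <- "starch"
        sub_cmol[i] <- starch_basis * carbons[roles$starch] +
          max(co_up[i] * s, 0) * carbons[roles$co2]
      } else if (co_up[i] > 1e-12) {
        s <- co2_basis / co_up[i]
        M[i, ] <- M[i, ] * s
        basis[i] <- "co2"
        sub_cmol[i] <- co2_basis * carbons[roles$co2]
      }
    }
  }
  structure(list(modes = M, reaction_ids = modeset$reaction_ids,
                 reversible = modeset$reversible, basis = basis,
                 substrate_cmol = sub_cmol, excluded = basis == "none",
                 scenario_id = modeset$scenario_id),
            class = "NormalizedModes")
}

#' C-mol flux matrix of normalized modes
#'
#' Mol fluxes times the per-reaction carbon transfer, on the substrate
#' normalization basis.
#' @param norm a `NormalizedModes`.
#' @param network matching network.
#' @export
cmol_fluxes <- function(norm, network) {
  ct <- carbon_transfer(network)
  sweep(norm$modes, 2, ct, `*`)
}

#' Biomass yield and carbon efficiency per mode
#'
#' @param norm a `NormalizedModes`.
#' @param network scenario-configured network (supplies `biomass_mass` in
#'   grams per unit biomass flux and the biomass carbon content).
#' @return data.frame: mode, basis, biomass_yield (g per C-mol substrate),
#'   carbon_efficiency (percent), quantum_requirement (mol photons per mol
#'   CO2; NA when photons or CO2 uptake are absent).
#' @export
mode_yields <- function(norm, network) {
  roles <- attr(network, "species_roles")
  mass <- attr(network, "biomass_mass")
  if (is.null(mass)) stop("mode_yields: network lacks biomass_mass")
  carbons <- stats::setNames(network$metabolites$carbon_atoms,
                             network$metabolites$id)
  bio <- exchange_uptake(norm$modes, network, roles$biomass)
  bio <- -bio  # efflux is negative uptake
  photon <- if (!is.null(roles$photon))
    exchange_uptake(norm$modes, network, roles$photon) else rep(0, nrow(norm$modes))
  co2_up <- exchange_uptake(norm$modes, network, roles$co2)
  qr <- ifelse(photon > 1e-12 & co2_up > 1e-12, photon / co2_up, NA_real_)
  yield <- ifelse(norm$excluded, NA_real_, bio * mass / norm$substrate_cmol)
  eff <- ifelse(norm$excluded, NA_real_,
                bio * carbons[roles$biomass] / norm$substrate_cmol * 100)
  data.frame(mode = seq_len(nrow(norm$modes)), basis = norm$basis,
             biomass_yield = yield, carbon_efficiency = eff,
             quantum_requirement = qr)
}

#' Filter energetically futile modes
#'
#' Removes modes whose total absolute inter-compartmental transport flux (in
#' C-mol) exceeds `k` times the substrate C-mol uptake — the signature of
#' massive substrate cycling across organelle membranes to dissipate energy.
#' `k = Inf` keeps everything. The removed set is returned for audit.
#'
#' @param norm a `NormalizedModes`.
#' @param k cycling threshold (default 5).
#' @param network matching network.
#' @return list(kept, removed (both `NormalizedModes`), k, transport_ratio).
#' @export
filter_futile <- function(norm, k = 5, network) {
  ct <- carbon_transfer(network)
  is_tr <- vapply(network$reactions, function(r) r$kind == "transport", TRUE)
  trans_cmol <- abs(norm$modes[, is_tr, drop = FALSE]) %*% ct[is_tr]
  ratio <- as.numeric(trans_cmol) / ifelse(is.na(norm$substrate_cmol), Inf,
                                           norm$substrate_cmol)
  ratio[is.na(norm$substrate_cmol)] <- 0  # no-substrate modes judged elsewhere
  keep <- ratio <= k
  subset_norm <- function(x, idx) {
    structure(list(modes = x$modes[idx, , drop = FALSE],
                   reaction_ids = x$reaction_ids, reversible = x$reversible,
                   basis = x$basis[idx], substrate_cmol = x$substrate_cmol[idx],
                   excluded = x$excluded[idx], scenario_id = x$scenario_id),
              class = "NormalizedModes")
  }
  list(kept = subset_norm(norm, keep), removed = subset_norm(norm, !keep),
       k = k, transport_ratio = ratio)
}

#' Mean flux of the top biomass-producing modes
#'
#' Ranks modes by biomass yield (descending), takes the top `ceiling(p * N)`
#' of the biomass-producing modes (ties at the cut included), and returns the
#' per-reaction mean and standard deviation of the normalized mol fluxes.
#'
#' @param norm a `NormalizedModes` (futile-filtered first, by convention).
#' @param p top fraction (default 0.01).
#' @param network matching network.
#' @param min_n lower bound on the number of top modes (useful on small
#'   fixtures where 1 percent rounds to a single mode but downstream
#'   statistics need replication); capped at the number of producing modes.
#' @return list(mean, sd (named vectors), indices, n, yield_threshold).
#' @export
top_percentile_mean <- function(norm, p = 0.01, network, min_n = 1) {
  yl <- mode_yields(norm, network)
  ok <- which(!is.na(yl$biomass_yield) & yl$biomass_yield > 0)
  if (!length(ok)) stop("top_percentile_mean: no biomass-producing modes")
  n_top <- min(length(ok), max(min_n, ceiling(p * length(ok))))
  ys <- sort(yl$biomass_yield[ok], decreasing = TRUE)
  thr <- ys[n_top]
  idx <- ok[yl$biomass_yield[ok] >= thr]
  M <- norm$modes[idx, , drop = FALSE]
  list(mean = stats::setNames(colMeans(M), norm$reaction_ids),
       sd = stats::setNames(apply(M, 2, stats::sd), norm$reaction_ids),
       indices = idx, n = length(idx), yield_threshold = thr)
}

#' Quantum requirement analysis
#'
#' Per-mode photon requirement (mol photons per mol net CO2 fixed), a
#' histogram over requirements, and the optimal band spanned by the top
#' `p` biomass-producing modes. `correct_quantum_yield()` converts a measured
#' incident-light quantum yield to the photosynthetically active basis,
#' assuming 47 percent of incident photons fall outside the active range.
#'
#' @param norm a `NormalizedModes` from a light scenario (futile-filtered).
#' @param network matching network.
#' @param p top fraction defining the optimal band.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list(requirement per mode (NA when CO2 uptake absent), histogram,
#'   optimal_band = c(lo, hi), quantum_yield_band = reciprocal band).
#' @export
quantum_analysis <- function(norm, network, p = 0.01, breaks = 30) {
  yl <- mode_yields(norm, network)
  req <- yl$quantum_requirement
  ok <- which(!is.na(req) & !is.na(yl$biomass_yield) & yl$biomass_yield > 0)
  if (!length(ok)) stop("quantum_analysis: no photon-consuming biomass modes")
  n_top <- ceiling(p * length(ok))
  thr <- sort(yl$biomass_yield[ok], decreasing = TRUE)[n_top]
  top <- ok[yl$biomass_yield[ok] >= thr]
  band <- range(req[top])
  h <- graphics::hist(req[!is.na(req)], breaks = breaks, plot = FALSE)
  list(requirement = req, histogram = h, optimal_band = band,
       quantum_yield_band = rev(1 / band))
}

#' @rdname quantum_analysis
#' @param measured_yield quantum yield on the incident-photon basis.
#' @param active_fraction fraction of incident photons that are
#'   photosynthetically active (default 0.53).
#' @export
correct_quantum_yield <- function(measured_yield, active_fraction = 0.53) {
  measured_yield / active_fraction
}

# Welch t-test p-value robust to zero-variance samples
#' @noRd
welch_p <- function(a, b) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
    return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Compare per-reaction fluxes between two conditions
#'
#' Welch two-sample t-tests across two samples of top-percentile modes (rows
#' = modes, columns = reactions, C-mol normalized). Verdicts relative to
#' condition A: `reversed` when the mean fluxes have strictly opposite signs
#' (p < `p_cutoff`; sign change suffices, no log2 rule), `increased` /
#' `decreased` when |mean A| is above/below |mean B| with p < `p_cutoff` and
#' |log2 ratio| > `log2_cutoff` (on/off switches count as changed),
#' `unchanged` otherwise.
#'
#' @param topA,topB numeric matrices with identical column names.
#' @param p_cutoff significance level (default 0.05).
#' @param log2_cutoff absolute log2 ratio threshold (default 0.5).
#' @param zero_tol fluxes below this are treated as zero.
#' @return data.frame of ComparisonRecords: reaction, mean_a, mean_b,
#'   verdict, p_value, log2_ratio (NA for sign changes and zeros).
#' @export
compare_conditions <- function(topA, topB, p_cutoff = 0.05,
                               log2_cutoff = 0.5, zero_tol = 1e-9) {
  if (!identical(colnames(topA), colnames(topB)))
    stop("compare_conditions: reaction indexes differ")
  if (nrow(topA) < 2 || nrow(topB) < 2)
    stop("compare_conditions: need at least 2 modes per sample")
  out <- do.call(rbind, lapply(colnames(topA), function(j) {
    a <- topA[, j]; b <- topB[, j]
    ma <- mean(a); mb <- mean(b)
    p <- welch_p(a, b)
    za <- abs(ma) < zero_tol; zb <- abs(mb) < zero_tol
    l2 <- NA_real_
    verdict <- "unchanged"
    if (!za && !zb && sign(ma) != sign(mb)) {
      if (p < p_cutoff) verdict <- "reversed"
    } else if (za && zb) {
      verdict <- "unchanged"
    } else if (za || zb) {
      if (p < p_cutoff) verdict <- if (zb) "increased" else "decreased"
    } else {
      l2 <- log2(abs(ma) / abs(mb))
      if (p < p_cutoff && abs(l2) > log2_cutoff)
        verdict <- if (l2 > 0) "increased" else "decreased"
    }
    data.frame(reaction = j, mean_a = ma, mean_b = mb, verdict = verdict,
               p_value = p, log2_ratio = l2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
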