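#' Closed pathway vocabulary for reaction annotation
#'
#' Pathway labels used to bin fluxes in the accounting module. The vocabulary
#' is closed so that contribution tables partition cleanly.
#' @export
leaf_pathways <- function() {
  c("CBB", "EMP-cytosol", "EMP-plastid", "gluconeogenesis", "oxPPP", "PPP",
    "TCA", "oxphos", "light", "starch", "photorespiration", "transport",
    "shuttle", "anaplerosis", "biomass", "maintenance", "exchange", "other")
}

.compartments <- c("cytosol", "plastid", "mitochondrion", "peroxisome", "external")

#' Create a reaction
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed). Decimal coefficients are rationalized exactly
#'   (denominator cap 1e6).
#' @param reversible logical.
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`.
#' @param compartment single compartment label, or `"a|b"` pair for transport.
#' @param genes character vector of associated gene ids.
#' @param pathway label from [leaf_pathways()].
#' @return object of class `Reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE,
                     kind = c("internal", "transport", "exchange"),
                     compartment = "", genes = character(), pathway = "other") {
  kind <- match.arg(kind)
  if (!length(stoich)) stop("reaction '", id, "': empty stoichiometry")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a named vector")
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  if (!pathway %in% leaf_pathways())
    stop("reaction '", id, "': pathway '", pathway,
         "' not in the closed vocabulary (see leaf_pathways())")
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stop("reaction '", id, "': all-zero stoichiometry")
  r <- rat_from_decimal(unname(stoich))
  structure(list(id = as.character(id), mets = names(stoich),
                 num = r$num, den = r$den,
                 reversible = isTRUE(reversible), kind = kind,
                 compartment = compartment, genes = as.character(genes),
                 pathway = pathway),
            class = "Reaction")
}

#' @export
print.Reaction <- function(x, ...) {
  coef <- x$num / x$den
  lhs <- x$mets[coef < 0]; lc <- -coef[coef < 0]
  rhs <- x$mets[coef > 0]; rc <- coef[coef > 0]
  fmt <- function(c, m) paste(ifelse(c == 1, m, paste(c, m)), collapse = " + ")
  arrow <- if (x$reversible) "<->" else "->"
  cat(sprintf("%s [%s/%s]: %s %s %s\n", x$id, x$kind, x$pathway,
              fmt(lc, lhs), arrow, fmt(rc, rhs)))
  invisible(x)
}

#' Define metabolites for a network
#'
#' @param id,name,compartment,carbon_atoms,is_balanced vectors recycled to a
#'   common length. `is_balanced = FALSE` flags species (biomass, maintenance
#'   ATP, inorganic phosphate, photons, starch) that require an external
#'   exchange reaction to close their balance; they remain rows of the
#'   stoichiometric matrix unless their compartment is `"external"`.
#' @return data.frame of metabolites.
#' @export
metabolites <- function(id, name = id, compartment = "cytosol",
                        carbon_atoms = 0L, is_balanced = TRUE) {
  df <- data.frame(id = as.character(id), name = name,
                   compartment = compartment,
                   carbon_atoms = as.numeric(carbon_atoms),
                   is_balanced = is_balanced,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate metabolite ids")
  if (any(df$carbon_atoms < 0)) stop("carbon_atoms must be >= 0")
  df
}

#' Assemble a compartmented metabolic network
#'
#' @param mets data.frame from [metabolites()].
#' @param reactions list of [reaction()] objects.
#' @param provenance free-text metadata.
#' @return object of class `MetabolicNetwork`.
#' @export
metabolic_network <- function(mets, reactions, provenance = "") {
  if (!length(reactions)) stop("network needs at least one reaction")
  ids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  for (r in reactions) {
    missing <- setdiff(r$mets, mets$id)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  net <- structure(list(metabolites = mets, reactions = reactions,
                        provenance = provenance),
                   class = "MetabolicNetwork")
  net
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  kinds <- table(vapply(x$reactions, function(r) r$kind, ""))
  cat("MetabolicNetwork:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("  irreversible:", sum(!vapply(x$reactions, function(r) r$reversible, TRUE)),
      "| reversible:", sum(vapply(x$reactions, function(r) r$reversible, TRUE)), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @noRd
reaction_ids <- function(network) vapply(network$reactions, function(r) r$id, "")

#' @noRd
reversibility <- function(network) vapply(network$reactions, function(r) r$reversible, TRUE)

# metabolite rows entering S: everything not in the external compartment
#' @noRd
matrix_rows <- function(network) {
  network$metabolites$id[network$metabolites$compartment != "external"]
}

#' Build the exact stoichiometric matrix
#'
#' Rows are non-external metabolites in insertion order, columns reactions in
#' insertion order; entries are exact rationals. The steady-state system is
#' `S %*% v = 0`.
#'
#' @param network a `MetabolicNetwork`.
#' @return a rational matrix (class `rmat`); use `as.matrix()` for numerics.
#' @export
build_matrix <- function(network) {
  rows <- matrix_rows(network)
  rxn <- reaction_ids(network)
  num <- matrix(0, length(rows), length(rxn), dimnames = list(rows, rxn))
  den <- matrix(1, length(rows), length(rxn), dimnames = list(rows, rxn))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    keep <- r$mets %in% rows
    num[r$mets[keep], j] <- r$num[keep]
    den[r$mets[keep], j] <- r$den[keep]
  }
  rmat(num, den)
}

# default exchange directions for the leaf species (photon influx only,
# CO2 bidirectional, biomass / maintenance ATP efflux only)
#' @noRd
default_exchange_direction <- function(id) {
  if (grepl("photon", id, ignore.case = TRUE)) return("in")
  if (grepl("co2", id, ignore.case = TRUE)) return("both")
  if (grepl("biomass", id, ignore.case = TRUE)) return("out")
  if (grepl("atp|maint", id, ignore.case = TRUE)) return("out")
  if (grepl("starch", id, ignore.case = TRUE)) return("in")
  "both"
}

#' Attach external exchange reactions for unbalanced species
#'
#' One exchange column per species id. Directions follow the leaf defaults
#' (photon influx only; CO2 bidirectional; biomass and maintenance-ATP efflux
#' only; starch influx) when `direction = "auto"`.
#'
#' @param network a `MetabolicNetwork`.
#' @param unbalanced_ids metabolite ids needing exchanges.
#' @param direction `"auto"`, or a vector of `"in"`, `"out"`, `"both"`.
#' @return the network with exchange reactions appended (ids `EX_<species>`).
#' @export
add_exchanges <- function(network, unbalanced_ids, direction = "auto") {
  if (length(direction) == 1) direction <- rep(direction, length(unbalanced_ids))
  existing <- exchange_species(network)
  for (k in seq_along(unbalanced_ids)) {
    id <- unbalanced_ids[k]
    if (!id %in% network$metabolites$id)
      stop("add_exchanges: unknown metabolite '", id, "'")
    if (id %in% existing)
      stop("add_exchanges: exchange for '", id, "' already present")
    dir <- direction[k]
    if (dir == "auto") dir <- default_exchange_direction(id)
    coef <- if (dir == "in") 1 else -1
    rx <- reaction(paste0("EX_", id), stats::setNames(coef, id),
                   reversible = (dir == "both"), kind = "exchange",
                   compartment = "external", pathway = "exchange")
    network$reactions <- c(network$reactions, list(rx))
  }
  network
}

# species already touched by an exchange reaction
#' @noRd
exchange_species <- function(network) {
  unlist(lapply(network$reactions,
                function(r) if (r$kind == "exchange") r$mets else character(0)))
}

#' Remove exchange reactions for given species
#' @param network a `MetabolicNetwork`.
#' @param ids species whose exchange columns are removed (default: all).
#' @export
remove_exchanges <- function(network, ids = NULL) {
  keep <- vapply(network$reactions, function(r) {
    !(r$kind == "exchange" && (is.null(ids) || any(r$mets %in% ids)))
  }, TRUE)
  network$reactions <- network$reactions[keep]
  network
}

#' Carbon balance report
#'
#' Advisory per-reaction carbon accounting: sum of coefficient times
#' carbon_atoms. Exchange reactions, reactions touching unbalanced species
#' (biomass, photons, starch stores) and cofactor-only reactions sit on a
#' skip-list because they are intentionally unbalanced or carbon-free.
#'
#' @param network a `MetabolicNetwork`.
#' @return data.frame with columns reaction, imbalance, skipped, flagged.
#' @export
check_carbon_balance <- function(network) {
  carbons <- stats::setNames(network$metabolites$carbon_atoms, network$metabolites$id)
  unbal <- network$metabolites$id[!network$metabolites$is_balanced]
  out <- do.call(rbind, lapply(network$reactions, function(r) {
    imb <- sum(r$num / r$den * carbons[r$mets])
    skip <- r$kind == "exchange" || any(r$mets %in% unbal) ||
      all(carbons[r$mets] == 0)
    data.frame(reaction = r$id, imbalance = imb, skipped = skip,
               flagged = !skip && abs(imb) > 1e-9, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- condensation ------------------------------------------------------

#' Condense a network by lumping linear chains and parallel duplicates
#'
#' (i) A balanced internal metabolite with exactly one producing and one
#' consuming reaction (orientation-compatible, neither an exchange) is
#' eliminated by composing the two reactions into one. (ii) Reactions with
#' exactly proportional stoichiometry (positive ratio) and equal
#' reversibility are merged. Iterated to a fixed point. Exchange reactions
#' are never merged so scenario toggling stays well-defined.
#'
#' The returned lumping map sends each condensed reaction to its constituent
#' original reactions with exact rational flux factors, so condensed flux
#' modes expand to original-network modes.
#'
#' @param network a `MetabolicNetwork` (exchanges attached).
#' @return list(network = condensed `MetabolicNetwork`, map = named list of
#'   data.frames with columns orig, num, den).
#' @export
condense <- function(network) {
  rxns <- network$reactions
  # map: per current reaction, constituents with rational factors
  map <- lapply(rxns, function(r) data.frame(orig = r$id, num = 1, den = 1,
                                             stringsAsFactors = FALSE))
  names(map) <- vapply(rxns, function(r) r$id, "")
  mets <- network$metabolites

  coef_of <- function(r, m) {
    i <- match(m, r$mets)
    if (is.na(i)) c(0, 1) else c(r$num[i], r$den[i])
  }

  scale_map <- function(mp, fn, fd) {
    pr <- rat_mul(mp$num, mp$den, rep(fn, nrow(mp)), rep(fd, nrow(mp)))
    mp$num <- pr$num; mp$den <- pr$den
    mp
  }

  repeat {
    changed <- FALSE

    ## (i) chain elimination
    internal_rows <- mets$id[mets$compartment != "external"]
    for (m in internal_rows) {
      touch <- which(vapply(rxns, function(r) m %in% r$mets, TRUE))
      if (length(touch) != 2) next
      rA <- rxns[[touch[1]]]; rB <- rxns[[touch[2]]]
      if (rA$kind == "exchange" || rB$kind == "exchange") next
      sA <- sign(coef_of(rA, m)[1]); sB <- sign(coef_of(rB, m)[1])
      # choose producer P (coef > 0 in operating direction) and consumer C,
      # flipping a reversible reaction when needed
      flipP <- FALSE; flipC <- FALSE
      if (sA > 0 && sB < 0) { iP <- 1; iC <- 2 }
      else if (sA < 0 && sB > 0) { iP <- 2; iC <- 1 }
      else if (sA > 0 && sB > 0) {
        if (rB$reversible) { iP <- 1; iC <- 2; flipC <- TRUE }
        else if (rA$reversible) { iP <- 2; iC <- 1; flipC <- TRUE }
        else next
      } else {  # both consume
        if (rA$reversible) { iP <- 1; iC <- 2; flipP <- TRUE }
        else if (rB$reversible) { iP <- 2; iC <- 1; flipP <- TRUE }
        else next
      }
      P <- rxns[[touch[iP]]]; C <- rxns[[touch[iC]]]
      if (flipP) P$num <- -P$num
      if (flipC) C$num <- -C$num
      p <- coef_of(P, m)  # > 0
      cc <- coef_of(C, m) # < 0
      # merged = P * |c| + C * p   (eliminates m, both multipliers > 0)
      a_n <- -cc[1]; a_d <- cc[2]   # factor on P
      b_n <- p[1];   b_d <- p[2]    # factor on C
      all_mets <- union(P$mets, C$mets)
      nn <- numeric(length(all_mets)); dd <- rep(1, length(all_mets))
      for (i in seq_along(all_mets)) {
        p1 <- coef_of(P, all_mets[i]); p2 <- coef_of(C, all_mets[i])
        t1 <- rat_mul(p1[1], p1[2], a_n, a_d)
        t2 <- rat_mul(p2[1], p2[2], b_n, b_d)
        s <- rat_add(t1$num, t1$den, t2$num, t2$den)
        nn[i] <- s$num; dd[i] <- s$den
      }
      keep <- nn != 0
      if (!any(keep)) next  # complete cancellation: skip degenerate merge
      merged <- structure(list(
        id = paste(P$id, C$id, sep = "+"),
        mets = all_mets[keep], num = nn[keep], den = dd[keep],
        reversible = P$reversible && C$reversible,
        kind = if (P$kind == "transport" || C$kind == "transport") "transport" else "internal",
        compartment = if (identical(P$compartment, C$compartment))
          P$compartment else paste(P$compartment, C$compartment, sep = "|"),
        genes = union(P$genes, C$genes),
        pathway = P$pathway),
        class = "Reaction")
      # original flux of P = (sign) * |c|/cd * v_merged; likewise for C
      mP <- scale_map(map[[touch[iP]]], if (flipP) -a_n else a_n, a_d)
      mC <- scale_map(map[[touch[iC]]], if (flipC) -b_n else b_n, b_d)
      newmap <- rbind(mP, mC)
      idx <- sort(touch)
      rxns[[idx[1]]] <- merged
      rxns <- rxns[-idx[2]]
      map[[idx[1]]] <- newmap
      map <- map[-idx[2]]
      names(map)[idx[1]] <- merged$id
      mets <- mets[mets$id != m, , drop = FALSE]
      changed <- TRUE
      break
    }
    if (changed) next

    ## (ii) parallel proportional columns
    n <- length(rxns)
    done <- FALSE
    for (i in seq_len(max(0, n - 1))) {
      for (j in seq(i + 1, n)) {
        ri <- rxns[[i]]; rj <- rxns[[j]]
        if (ri$kind == "exchange" || rj$kind == "exchange") next
        if (ri$reversible != rj$reversible) next
        if (!setequal(ri$mets, rj$mets)) next
        ord <- match(ri$mets, rj$mets)
        # ratio = rj/ri on first metabolite; must be constant and positive
        q1 <- rat_mul(rj$num[ord[1]], rj$den[ord[1]], ri$den[1], ri$num[1])
        if (q1$num / q1$den <= 0) next
        ok <- TRUE
        for (k in seq_along(ri$mets)) {
          qk <- rat_mul(rj$num[ord[k]], rj$den[ord[k]], ri$den[k], ri$num[k])
          if (qk$num != q1$num || qk$den != q1$den) { ok <- FALSE; break }
        }
        if (!ok) next
        # merge j into i; original rj flux = ratio^{-1} * v ... representative
        # expansion puts all flux on the first constituent, others get 0.
        mj <- map[[j]]
        mj$num <- rep(0, nrow(mj)); mj$den <- rep(1, nrow(mj))
        map[[i]] <- rbind(map[[i]], mj)
        rxns[[i]]$id <- paste(ri$id, rj$id, sep = "|")
        names(map)[i] <- rxns[[i]]$id
        rxns <- rxns[-j]
        map <- map[-j]
        changed <- TRUE; done <- TRUE
        break
      }
      if (done) break
    }
    if (!changed) break
  }

  net <- metabolic_network(mets, rxns,
                           provenance = paste0(network$provenance,
                                               " [condensed]"))
  list(network = net, map = map)
}

#' Expand condensed-network flux modes to the original reaction basis
#'
#' @param modes numeric matrix (modes x condensed reactions) with column
#'   names matching the condensed reaction ids.
#' @param map lumping map from [condense()].
#' @param original the pre-condensation `MetabolicNetwork`.
#' @return numeric matrix (modes x original reactions), rows re-scaled to
#'   coprime integers when integral.
#' @export
expand_modes <- function(modes, map, original) {
  orig_ids <- reaction_ids(original)
  nm <- nrow(modes)
  onum <- matrix(0, nm, length(orig_ids), dimnames = list(NULL, orig_ids))
  oden <- matrix(1, nm, length(orig_ids), dimnames = list(NULL, orig_ids))
  for (cid in colnames(modes)) {
    mp <- map[[cid]]
    if (is.null(mp)) stop("expand_modes: no map entry for '", cid, "'")
    for (k in seq_len(nrow(mp))) {
      j <- mp$orig[k]
      # contribution = mode coefficient (integer) * factor num/den
      t1 <- rat_mul(modes[, cid], rep(1, nm),
                    rep(mp$num[k], nm), rep(mp$den[k], nm))
      s <- rat_add(onum[, j], oden[, j], t1$num, t1$den)
      onum[, j] <- s$num; oden[, j] <- s$den
    }
  }
  out <- matrix(0, nm, length(orig_ids), dimnames = list(NULL, orig_ids))
  for (i in seq_len(nm)) {
    l <- Reduce(rat_lcm, c(1, oden[i, ]))
    out[i, ] <- int_coprime(rat_guard(onum[i, ] * (l / oden[i, ])))
  }
  out
}
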