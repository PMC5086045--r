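# Elementary flux mode enumeration.
#
# The enumerator follows the nullspace variant of the double description
# method: start from an exact integer kernel basis of S carrying an identity
# block on the free coordinates (so the initial ray set generates exactly the
# kernel vectors with non-negative free coordinates), then impose the
# remaining non-negativity constraints one at a time, combining adjacent
# positive/negative ray pairs. Adjacency uses the restricted-support subset
# test over the constraints processed so far; a final exact rank test
# certifies elementarity of every returned mode. All arithmetic is integer
# (gcd-reduced after every combination).

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' @param network a `MetabolicNetwork`.
#' @return list(network = expanded all-irreversible network,
#'   fold = data.frame(col id, orig id, dir +1/-1) recombining split columns).
#' @export
split_reversible <- function(network) {
  rxns <- list()
  fold <- data.frame(col = character(0), orig = character(0), dir = numeric(0),
                     stringsAsFactors = FALSE)
  for (r in network$reactions) {
    f <- r; f$reversible <- FALSE
    rxns <- c(rxns, list(f))
    fold <- rbind(fold, data.frame(col = r$id, orig = r$id, dir = 1))
    if (r$reversible) {
      b <- r
      b$id <- paste0(r$id, "__rev")
      b$num <- -b$num
      b$reversible <- FALSE
      rxns <- c(rxns, list(b))
      fold <- rbind(fold, data.frame(col = b$id, orig = r$id, dir = -1))
    }
  }
  net <- metabolic_network(network$metabolites, rxns, network$provenance)
  list(network = net, fold = fold)
}

# canonical form of a mode vector: coprime integers; if the support touches
# any irreversible reaction the orientation is already fixed, otherwise the
# first nonzero entry is made positive
#' @noRd
canonical_mode <- function(v, reversible) {
  v <- int_coprime(v)
  supp <- which(v != 0)
  if (!length(supp)) return(v)
  if (all(reversible[supp])) {
    if (v[supp[1]] < 0) v <- -v
  }
  v
}

#' Enumerate all elementary flux modes
#'
#' @param network a `MetabolicNetwork` with exchanges configured for one
#'   scenario (condense first for large models).
#' @param max_candidates abort (with partial statistics attached to the
#'   error condition) if the working ray set exceeds this size.
#' @param scenario_id optional label stored on the result.
#' @return object of class `ModeSet`: list(modes = integer-valued matrix
#'   (modes x reactions, canonical coprime rows), reaction_ids, reversible,
#'   scenario_id, stats).
#' @export
enumerate_efms <- function(network, max_candidates = 1e7, scenario_id = NULL) {
  sp <- split_reversible(network)
  S <- build_matrix(sp$network)
  Si <- rmat_int_rows(S)$M
  n <- ncol(Si)
  ker <- rmat_kernel_int(rmat(matrix(Si, nrow(Si), n)))
  d <- ncol(ker$K)
  rids <- reaction_ids(network)
  rev <- reversibility(network)
  empty <- function(stats) {
    structure(list(modes = matrix(0, 0, length(rids),
                                  dimnames = list(NULL, rids)),
                   reaction_ids = rids, reversible = rev,
                   scenario_id = scenario_id, stats = stats),
              class = "ModeSet")
  }
  if (d == 0) return(empty(list(candidates = 0)))

  rays <- ker$K                      # n x d, identity block on free rows
  active <- ker$free                 # coordinates already constrained >= 0
  todo <- ker$pivots
  # fewest-nonzeros-first heuristic over the pending constraint rows
  nz <- vapply(todo, function(p) sum(rays[p, ] != 0), 0)
  todo <- todo[order(nz)]
  candidates <- 0

  for (p in todo) {
    w <- rays[p, ]
    pos <- which(w > 0); neg <- which(w < 0); zer <- which(w == 0)
    keep <- rays[, c(zer, pos), drop = FALSE]
    if (length(pos) && length(neg)) {
      supp <- rays[c(active, p), , drop = FALSE] != 0
      new <- list()
      for (i in pos) {
        si <- supp[, i]
        for (j in neg) {
          u <- si | supp[, j]
          # adjacency: no third ray whose restricted support is inside u
          others <- which(colSums(supp & !u) == 0)
          others <- setdiff(others, c(i, j))
          if (length(others)) next
          comb <- w[i] * rays[, j] - w[j] * rays[, i]
          rat_guard(comb)
          new[[length(new) + 1]] <- int_coprime(comb)
        }
      }
      if (length(new)) keep <- cbind(keep, do.call(cbind, new))
    }
    rays <- keep
    active <- c(active, p)
    candidates <- candidates + ncol(rays)
    if (ncol(rays) > max_candidates) {
      cond <- simpleError("enumerate_efms: candidate budget exceeded")
      cond$stats <- list(candidates = candidates, rays = ncol(rays),
                         processed = match(p, todo), total = length(todo))
      stop(cond)
    }
  }

  # fold split columns back to the original reaction basis
  split_ids <- reaction_ids(sp$network)
  folded <- matrix(0, length(rids), ncol(rays), dimnames = list(rids, NULL))
  for (k in seq_len(nrow(sp$fold))) {
    row <- match(sp$fold$col[k], split_ids)
    folded[sp$fold$orig[k], ] <- folded[sp$fold$orig[k], ] +
      sp$fold$dir[k] * rays[row, ]
  }
  nzcol <- colSums(folded != 0) > 0   # drop two-cycles (fold to zero)
  folded <- folded[, nzcol, drop = FALSE]
  modes <- t(apply(folded, 2, canonical_mode, reversible = rev))
  if (ncol(folded) == 0)
    modes <- matrix(0, 0, length(rids), dimnames = list(NULL, rids))
  colnames(modes) <- rids
  # deduplicate (+/- pairs of all-reversible-support modes fold to the same
  # canonical vector)
  key <- apply(modes, 1, paste, collapse = ",")
  modes <- modes[!duplicated(key), , drop = FALSE]
  # final exact elementarity certificate
  if (nrow(modes)) {
    ok <- vapply(seq_len(nrow(modes)),
                 function(i) is_elementary(modes[i, ], network), TRUE)
    modes <- modes[ok, , drop = FALSE]
  }
  # deterministic order: lexicographic by support pattern
  if (nrow(modes) > 1) {
    skey <- apply(modes != 0, 1, function(s) paste(as.integer(s), collapse = ""))
    modes <- modes[order(skey, apply(modes, 1, paste, collapse = ",")), ,
                   drop = FALSE]
  }
  structure(list(modes = modes, reaction_ids = rids, reversible = rev,
                 scenario_id = scenario_id,
                 stats = list(candidates = candidates)),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", nrow(x$modes), "elementary flux modes over",
      length(x$reaction_ids), "reactions\n")
  if (!is.null(x$scenario_id)) cat("  scenario:", x$scenario_id, "\n")
  invisible(x)
}

#' Exact rank-based elementarity test
#'
#' A steady-state, sign-feasible flux vector is elementary iff the rank of S
#' restricted to its support equals the support size minus one (its support
#' then carries a one-dimensional kernel, so no feasible vector has strictly
#' smaller support).
#'
#' @param v numeric flux vector over the network's reactions.
#' @param network a `MetabolicNetwork`.
#' @return logical.
#' @export
is_elementary <- function(v, network) {
  S <- build_matrix(network)
  rv <- rat_from_decimal(v)
  # exact steady-state check: S v = 0
  d <- rmat_dim(S)
  for (i in seq_len(d[1])) {
    acc_n <- 0; acc_d <- 1
    for (j in which(v != 0)) {
      t <- rat_mul(S$num[i, j], S$den[i, j], rv$num[j], rv$den[j])
      s <- rat_add(acc_n, acc_d, t$num, t$den)
      acc_n <- s$num; acc_d <- s$den
    }
    if (acc_n != 0) stop("is_elementary: vector is not a steady-state flux")
  }
  rev <- reversibility(network)
  if (any(v < 0 & !rev)) stop("is_elementary: negative flux through an irreversible reaction")
  supp <- which(v != 0)
  if (!length(supp)) return(FALSE)
  sub <- rmat(S$num[, supp, drop = FALSE], S$den[, supp, drop = FALSE])
  rmat_rank(sub) == length(supp) - 1L
}

#' Brute-force EFM oracle by support enumeration
#'
#' Independent of the double-description path: enumerates candidate support
#' sets up to size rank(S)+1, keeps those whose restricted stoichiometric
#' matrix has a one-dimensional kernel with a sign-feasible, zero-free
#' generator. Intended for small networks only.
#'
#' @param network a `MetabolicNetwork`.
#' @param max_reactions size guard (default 18).
#' @return a `ModeSet`.
#' @export
brute_force_efms <- function(network, max_reactions = 18) {
  rids <- reaction_ids(network)
  rev <- reversibility(network)
  n <- length(rids)
  if (n > max_reactions)
    stop("brute_force_efms: ", n, " reactions exceeds guard of ", max_reactions)
  S <- build_matrix(network)
  Si <- rmat_int_rows(S)$M
  r <- rmat_rank(S)
  modes <- list()
  for (size in seq_len(min(n, r + 1))) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      T <- combs[, ci]
      sub <- rmat(Si[, T, drop = FALSE])
      ker <- rmat_kernel_int(sub)
      if (ncol(ker$K) != 1) next
      g <- ker$K[, 1]
      if (any(g == 0)) next   # true support is smaller; found elsewhere
      irr <- !rev[T]
      if (any(irr)) {
        s <- sign(g[irr])
        if (length(unique(s)) > 1) next
        if (s[1] < 0) g <- -g
      }
      v <- numeric(n)
      v[T] <- g
      modes[[length(modes) + 1]] <- canonical_mode(v, rev)
    }
  }
  M <- if (length(modes)) do.call(rbind, modes)
       else matrix(0, 0, n)
  colnames(M) <- rids
  key <- apply(M, 1, paste, collapse = ",")
  M <- M[!duplicated(key), , drop = FALSE]
  if (nrow(M) > 1) {
    skey <- apply(M != 0, 1, function(s) paste(as.integer(s), collapse = ""))
    M <- M[order(skey, apply(M, 1, paste, collapse = ",")), , drop = FALSE]
  }
  structure(list(modes = M, reaction_ids = rids, reversible = rev,
                 scenario_id = NULL, stats = list(oracle = TRUE)),
            class = "ModeSet")
}

#' Compare two mode sets for exact equality
#' @param a,b `ModeSet` objects over the same reactions.
#' @return logical.
#' @export
modesets_equal <- function(a, b) {
  if (!identical(a$reaction_ids, b$reaction_ids)) return(FALSE)
  if (nrow(a$modes) != nrow(b$modes)) return(FALSE)
  ka <- sort(apply(a$modes, 1, paste, collapse = ","))
  kb <- sort(apply(b$modes, 1, paste, collapse = ","))
  identical(ka, kb)
}
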