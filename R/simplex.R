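# Dense two-phase simplex for the small flux LPs used as yield oracles.
# Bland's anti-cycling rule; problems here have at most a few dozen
# variables, so no effort is spent on sparsity.

# maximize c'x subject to A x = b, x >= 0  (b may have any sign)
# returns list(x, fval, status = "optimal" | "infeasible" | "unbounded")
#' @noRd
lp_max_eq <- function(cc, A, b, tol = 1e-9, max_iter = 10000) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  nart <- m
  width <- n + nart + 1
  rhs <- width

  # tableau: rows 1..m constraints, row m+1 cost; columns 1..n structural,
  # n+1..n+m artificial, last column RHS
  T <- matrix(0, m + 1, width)
  T[1:m, 1:n] <- A
  T[1:m, n + (1:m)] <- diag(m)
  T[1:m, rhs] <- b
  basis <- n + (1:m)

  pivot <- function(T, i, j) {
    T[i, ] <- T[i, ] / T[i, j]
    for (r in seq_len(nrow(T))) {
      if (r != i && T[r, j] != 0) T[r, ] <- T[r, ] - T[r, j] * T[i, ]
    }
    T
  }

  run <- function(T, basis, allowed) {
    iter <- 0
    repeat {
      iter <- iter + 1
      if (iter > max_iter) return(list(T = T, basis = basis, status = "maxiter"))
      z <- T[m + 1, allowed]
      ent <- allowed[z < -tol]
      if (!length(ent)) return(list(T = T, basis = basis, status = "optimal"))
      j <- min(ent)                               # Bland entering rule
      col <- T[1:m, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(T = T, basis = basis, status = "unbounded"))
      ratios <- T[pos, rhs] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]           # Bland leaving rule
      T <- pivot(T, i, j)
      basis[i] <- j
    }
  }

  # phase 1: minimize sum of artificials
  T[m + 1, ] <- -colSums(T[1:m, , drop = FALSE])
  T[m + 1, n + (1:m)] <- 0
  r1 <- run(T, basis, allowed = seq_len(n))
  if (r1$status != "optimal" || r1$T[m + 1, rhs] < -1e-7)
    return(list(x = NULL, fval = NA_real_, status = "infeasible"))
  T <- r1$T; basis <- r1$basis
  # drive leftover artificials out of the basis where a pivot exists
  for (i in which(basis > n)) {
    piv <- which(abs(T[i, 1:n]) > tol)
    if (length(piv)) {
      T <- pivot(T, i, piv[1])
      basis[i] <- piv[1]
    }
  }
  # phase 2: maximize c'x == minimize -c'x; artificials frozen at zero
  T[, n + (1:nart)] <- 0
  T[m + 1, ] <- 0
  T[m + 1, 1:n] <- -cc
  for (i in seq_len(m)) {
    bj <- basis[i]
    if (bj <= n && cc[bj] != 0) T[m + 1, ] <- T[m + 1, ] + cc[bj] * T[i, ]
  }
  r2 <- run(T, basis, allowed = seq_len(n))
  if (r2$status == "unbounded")
    return(list(x = NULL, fval = Inf, status = "unbounded"))
  if (r2$status != "optimal")
    return(list(x = NULL, fval = NA_real_, status = r2$status))
  x <- numeric(n)
  ok <- r2$basis <= n
  x[r2$basis[ok]] <- r2$T[seq_len(m), rhs][ok]
  list(x = x, fval = sum(cc * x), status = "optimal")
}
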