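# Exact rational arithmetic on parallel numerator/denominator vectors.
#
# Numerators and denominators are stored as doubles holding exact integers
# (exact up to 2^53). Every operation reduces by the gcd and checks the
# magnitude guard, so stoichiometric algebra (matrix builds, row reduction,
# kernel bases, elementarity rank tests) incurs no floating-point rounding.

.RAT_MAX <- 2^52

#' @noRd
rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    nz <- b > 0
    r <- numeric(length(a))
    r[nz] <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b <- r
  }
  a
}

#' @noRd
rat_lcm <- function(a, b) {
  z <- a == 0 | b == 0
  g <- rat_gcd(a, b)
  out <- numeric(length(g))
  out[!z] <- abs(a[!z] / g[!z] * b[!z])
  out[z] <- 0
  out
}

#' @noRd
rat_guard <- function(x) {
  if (any(abs(x) > .RAT_MAX)) {
    stop("exact integer arithmetic overflow (entry exceeds 2^52); ",
         "network coefficients too large for exact mode", call. = FALSE)
  }
  x
}

# reduce num/den to lowest terms, den > 0; returns list(num, den)
#' @noRd
rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational", call. = FALSE)
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

#' @noRd
rat_add <- function(n1, d1, n2, d2) {
  rat_reduce(rat_guard(n1 * d2 + n2 * d1), rat_guard(d1 * d2))
}

#' @noRd
rat_mul <- function(n1, d1, n2, d2) {
  # cross-reduce first to keep magnitudes small
  g1 <- rat_gcd(n1, d2); g1[g1 == 0] <- 1
  g2 <- rat_gcd(n2, d1); g2[g2 == 0] <- 1
  rat_reduce(rat_guard((n1 / g1) * (n2 / g2)),
             rat_guard((d1 / g2) * (d2 / g1)))
}

# Rationalize a decimal via continued fractions, denominator capped.
# Values that are already integral pass through exactly.
#' @noRd
rat_from_decimal <- function(x, max_den = 1e6) {
  n <- length(x)
  num <- numeric(n); den <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    if (!is.finite(xi)) stop("non-finite stoichiometric coefficient", call. = FALSE)
    if (xi == round(xi)) { num[i] <- xi; den[i] <- 1; next }
    # continued-fraction convergents
    p0 <- 1; q0 <- 0; p1 <- floor(xi); q1 <- 1
    frac <- xi - p1
    while (abs(p1 / q1 - xi) > 1e-12 && frac > 1e-12) {
      frac <- 1 / frac
      a <- floor(frac)
      frac <- frac - a
      p2 <- a * p1 + p0; q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    }
    if (abs(p1 / q1 - xi) > 1e-9) {
      warning("coefficient ", xi, " rationalized with denominator > ", max_den,
              " truncated to ", p1, "/", q1)
    }
    num[i] <- p1; den[i] <- q1
  }
  rat_reduce(num, den)
}

# ---- rational matrices -------------------------------------------------

# A rational matrix is list(num = matrix, den = matrix) with class "rmat".
#' @noRd
rmat <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  r <- rat_reduce(as.numeric(num), as.numeric(den))
  structure(list(num = matrix(r$num, nrow(num), ncol(num), dimnames = dimnames(num)),
                 den = matrix(r$den, nrow(num), ncol(num), dimnames = dimnames(num))),
            class = "rmat")
}

#' @noRd
rmat_dim <- function(x) dim(x$num)

#' @export
as.matrix.rmat <- function(x, ...) x$num / x$den

#' @export
print.rmat <- function(x, ...) {
  d <- rmat_dim(x)
  cat("rational matrix ", d[1], " x ", d[2], "\n", sep = "")
  m <- matrix(paste0(x$num, ifelse(x$den == 1, "", paste0("/", x$den))),
              d[1], d[2], dimnames = dimnames(x$num))
  print(m, quote = FALSE)
  invisible(x)
}

# Clear denominators row-wise: each row multiplied by the lcm of its
# denominators. Row scaling leaves the kernel (hence the EFM set) unchanged.
# Returns list(M = integer-valued numeric matrix, scale = per-row factor).
#' @noRd
rmat_int_rows <- function(x) {
  d <- rmat_dim(x)
  M <- matrix(0, d[1], d[2], dimnames = dimnames(x$num))
  scl <- numeric(d[1])
  for (i in seq_len(d[1])) {
    l <- 1
    for (j in seq_len(d[2])) l <- rat_lcm(l, x$den[i, j])
    if (l == 0) l <- 1
    scl[i] <- l
    M[i, ] <- rat_guard(x$num[i, ] * (l / x$den[i, ]))
  }
  list(M = M, scale = scl)
}

# Exact reduced row echelon form of a rational matrix.
# Returns list(num, den, pivots = pivot column indices).
#' @noRd
rref_rat <- function(x) {
  num <- x$num; den <- x$den
  m <- nrow(num); n <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    # find pivot: nonzero entry in this column at or below `row`
    cand <- which(num[row:m, col] != 0)
    if (!length(cand)) next
    pr <- row + cand[1] - 1L
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    # scale pivot row to make pivot 1
    pn <- num[row, col]; pd <- den[row, col]
    sc <- rat_mul(num[row, ], den[row, ], rep(pd, n), rep(pn, n))
    num[row, ] <- sc$num; den[row, ] <- sc$den
    # eliminate other rows
    for (r in seq_len(m)) {
      if (r == row || num[r, col] == 0) next
      f_n <- num[r, col]; f_d <- den[r, col]
      pr_ <- rat_mul(num[row, ], den[row, ], rep(-f_n, n), rep(f_d, n))
      su <- rat_add(num[r, ], den[r, ], pr_$num, pr_$den)
      num[r, ] <- su$num; den[r, ] <- su$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

#' @noRd
rmat_rank <- function(x) length(rref_rat(x)$pivots)

# Integer kernel basis of a rational matrix (columns = basis vectors),
# scaled to coprime integers, with an identity block on the free rows.
# Returns list(K = n x d matrix, free = free column indices of x,
#              pivots = pivot column indices).
#' @noRd
rmat_kernel_int <- function(x) {
  n <- ncol(x$num)
  rr <- rref_rat(x)
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  d <- length(free)
  K <- matrix(0, n, d)
  if (d == 0) return(list(K = K, free = free, pivots = piv))
  for (j in seq_len(d)) {
    fc <- free[j]
    # kernel vector: 1 at free col, -rref coefficient at each pivot col
    vn <- numeric(n); vd <- rep(1, n)
    vn[fc] <- 1
    if (length(piv)) {
      vn[piv] <- -rr$num[seq_along(piv), fc]
      vd[piv] <- rr$den[seq_along(piv), fc]
    }
    l <- 1
    for (i in seq_len(n)) l <- rat_lcm(l, vd[i])
    v <- rat_guard(vn * (l / vd))
    g <- Reduce(rat_gcd, abs(v[v != 0]))
    if (is.null(g) || g == 0) g <- 1
    K[, j] <- v / g
  }
  list(K = K, free = free, pivots = piv)
}

# gcd-reduce an integer-valued vector to coprime entries
#' @noRd
int_coprime <- function(v) {
  nz <- v[v != 0]
  if (!length(nz)) return(v)
  g <- Reduce(rat_gcd, abs(nz))
  if (g == 0) g <- 1
  v / g
}
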