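# Exact rational arithmetic layer (internal API, accessed via :::).

test_that("rational reduction and arithmetic are exact", {
  r <- leafefm:::rat_reduce(c(6, -4, 0), c(8, 2, 5))
  expect_equal(r$num, c(3, -2, 0))
  expect_equal(r$den, c(4, 1, 1))

  s <- leafefm:::rat_add(1, 3, 1, 6)     # 1/3 + 1/6 = 1/2
  expect_equal(s$num, 1); expect_equal(s$den, 2)

  p <- leafefm:::rat_mul(2, 3, 9, 4)     # 2/3 * 9/4 = 3/2
  expect_equal(p$num, 3); expect_equal(p$den, 2)
})

test_that("decimal rationalization recovers simple fractions exactly", {
  r <- leafefm:::rat_from_decimal(c(0.5, 1 / 3, -2.25, 3))
  expect_equal(r$num, c(1, 1, -9, 3))
  expect_equal(r$den, c(2, 3, 4, 1))
})

test_that("overflow guard rejects magnitudes beyond the exact-double range", {
  expect_error(leafefm:::rat_guard(2^53), "overflow")
})

test_that("rref, rank and integer kernel are exact on a rational matrix", {
  # S = [[1, 1/2, 0], [2, 1, 1]] has rank 2, kernel spanned by (1, -2, 0)
  S <- leafefm:::rmat(matrix(c(1, 2, 1, 1, 0, 1), 2, 3),
                      matrix(c(1, 1, 2, 1, 1, 1), 2, 3))
  expect_equal(leafefm:::rmat_rank(S), 2)
  ker <- leafefm:::rmat_kernel_int(S)
  expect_equal(ncol(ker$K), 1)
  v <- ker$K[, 1] / ker$K[which(ker$K[, 1] != 0)[1], 1]
  expect_equal(as.numeric(v), c(1, -2, 0))
  # kernel satisfies S v = 0 exactly
  expect_true(all(as.matrix(S) %*% ker$K == 0))
})

test_that("coprime integer scaling divides by the gcd, preserving sign", {
  # orientation is the job of canonical_mode, which knows reversibility
  expect_equal(leafefm:::int_coprime(c(-2, -4, -6)), c(-1, -2, -3))
  expect_equal(leafefm:::int_coprime(c(0, 10, 15)), c(0, 2, 3))
  expect_equal(leafefm:::canonical_mode(c(-2, -4, -6), rep(TRUE, 3)),
               c(1, 2, 3))
  expect_equal(leafefm:::canonical_mode(c(-2, -4, -6), c(TRUE, FALSE, TRUE)),
               c(-1, -2, -3))
})
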