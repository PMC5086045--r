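# EFM enumeration: double-description engine, brute-force oracle,
# elementarity, reversible handling.

test_that("the diamond network has exactly its two known EFMs", {
  net <- diamond_network()
  ms <- enumerate_efms(net)
  expect_s3_class(ms, "ModeSet")
  expect_equal(nrow(ms$modes), 2)
  expect_equal(colnames(ms$modes), c("EX_in", "R1", "R2", "R3", "EX_out"))
  keys <- canonical_rows(ms$modes)
  expect_equal(keys, canonical_rows(rbind(c(1, 1, 0, 1, 1),
                                          c(1, 0, 1, 0, 1))))
})

test_that("reversible reactions yield sign-fixed folded modes, no 2-cycles", {
  mets <- metabolites(c("A", "B"), carbon_atoms = 1)
  net <- metabolic_network(mets, list(
    reaction("EX_in", c(A = 1), kind = "exchange", pathway = "exchange"),
    reaction("R", c(A = -1, B = 1), reversible = TRUE, pathway = "other"),
    reaction("EX_out", c(B = -1), kind = "exchange", pathway = "exchange")))
  ms <- enumerate_efms(net)
  # single through-mode; the fwd/bwd two-cycle of R must not appear
  expect_equal(nrow(ms$modes), 1)
  expect_equal(as.numeric(ms$modes[1, ] / max(ms$modes[1, ])), c(1, 1, 1))
})

test_that("every enumerated mode is steady-state and elementary", {
  net <- make_toy_network(42)
  ms <- enumerate_efms(net)
  S <- as.matrix(build_matrix(net))
  for (i in seq_len(nrow(ms$modes))) {
    v <- ms$modes[i, ]
    expect_true(all(abs(S %*% v) == 0))
    expect_true(is_elementary(v, net))
  }
  # a sum of two distinct modes is not elementary
  if (nrow(ms$modes) >= 2) {
    w <- ms$modes[1, ] + ms$modes[2, ]
    expect_false(is_elementary(w, net))
  }
})

test_that("enumeration agrees with the brute-force oracle on seeded toys", {
  for (seed in c(1, 7, 19)) {
    net <- make_toy_network(seed, n_met = 5, n_rxn = 8)
    expect_true(modesets_equal(enumerate_efms(net), brute_force_efms(net)),
                info = paste("seed", seed))
  }
})

test_that("candidate budget aborts with a clear error", {
  net <- apply_scenario(make_mini_leaf(), leaf_scenario("autotrophy_light"))
  expect_error(enumerate_efms(net, max_candidates = 3), "budget")
})

test_that("brute force guards against intractable sizes", {
  net <- apply_scenario(make_mini_leaf(), leaf_scenario("autotrophy_light"))
  expect_error(brute_force_efms(net), "exceeds")
})

test_that("irreversibility constraints are honored", {
  net <- make_toy_network(3, rev_frac = 0)
  ms <- enumerate_efms(net)
  expect_true(all(ms$modes >= 0))
})
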