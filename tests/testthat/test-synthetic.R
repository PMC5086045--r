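# Deterministic fixture generators.

test_that("same seed gives byte-identical toy networks; different seeds differ", {
  a <- make_toy_network(5)
  b <- make_toy_network(5)
  expect_identical(as.matrix(build_matrix(a)), as.matrix(build_matrix(b)))
  c <- make_toy_network(6)
  expect_false(identical(as.matrix(build_matrix(a)), as.matrix(build_matrix(c))))
  # generator does not disturb the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(make_toy_network(5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("toy networks are oracle-enumerable and degenerate specs error", {
  net <- make_toy_network(8)
  expect_lte(length(net$reactions), 15 + 2)
  ms <- brute_force_efms(net)
  expect_gte(nrow(ms$modes), 1)
  expect_error(make_toy_network(1, n_rxn = 0), "at least one")
  expect_error(make_toy_network(1, n_met = 1), "at least two")
})

test_that("the mini leaf is a structurally sound three-compartment model", {
  net <- make_mini_leaf()
  expect_setequal(unique(net$metabolites$compartment),
                  c("plastid", "cytosol", "mitochondrion"))
  kinds <- table(vapply(net$reactions, function(r) r$kind, ""))
  expect_equal(unname(kinds["exchange"]), 5)
  expect_gte(unname(kinds["transport"]), 4)
  expect_equal(sum(check_carbon_balance(net)$flagged), 0)
  # biomass draws at least 3 carbon precursors from 3 compartments
  bio <- net$reactions[[match("R_biomass",
    vapply(net$reactions, function(r) r$id, ""))]]
  carbons <- stats::setNames(net$metabolites$carbon_atoms, net$metabolites$id)
  prec <- bio$mets[bio$num < 0 & carbons[bio$mets] > 0]
  expect_gte(length(prec), 3)
  expect_equal(attr(net, "biomass_mass"), 430)
})

test_that("transcript generator hits its diurnal fraction and phase hints", {
  tr <- make_transcripts(2, n_genes = 300, frac_diurnal = 0.4)
  expect_equal(nrow(tr), 300)
  expect_equal(sum(tr$phase != "none"), 120)   # exact cohort size
  hints <- c(ATSYN0001 = "light_up", ATSYN0002 = "dark_up")
  th <- make_transcripts(2, n_genes = 300, phase_hints = hints)
  expect_equal(unname(th$phase[match(names(hints), th$gene_id)]),
               unname(hints))
  expect_true(all(th$log2_amplitude[match(names(hints), th$gene_id)] > 0.8))
  # sinusoidal series: light_up genes peak mid-light
  g <- th[th$gene_id == "ATSYN0001", ]
  tcols <- grep("^t_", names(g), value = TRUE)
  expect_equal(tcols[which.max(as.numeric(g[1, tcols]))], "t_06")
})

test_that("fluxome generator is exact at zero noise and deterministic", {
  flux <- c(R1 = 2, R2 = 0.5, R3 = 0)
  f0 <- make_fluxome(1, flux, noise_sd = 0)
  expect_equal(stats::setNames(f0$flux, f0$reaction_id), flux)
  f1 <- make_fluxome(1, flux)
  f2 <- make_fluxome(1, flux)
  expect_identical(f1, f2)
  expect_false(identical(f1$flux, unname(flux)))
})
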