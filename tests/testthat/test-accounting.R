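# Precursor, energy and CO2 provenance accounting.

test_that("precursor shares partition to one over sources", {
  net <- apply_scenario(make_mini_leaf(), leaf_scenario("heterotrophy_dark"))
  nd <- normalize_modes(enumerate_efms(net), net)
  top <- top_percentile_mean(nd, p = 0.01, net, min_n = 5)
  pc <- precursor_contributions(top$mean, net)
  expect_true(all(c("target", "by", "source", "fraction") %in% names(pc)))
  sums <- stats::aggregate(fraction ~ target + by, pc, sum)
  expect_true(all(abs(sums$fraction - 1) < 1e-9))
  # biomass consumes G6P_c, R5P_p and PYR_m in the mini leaf
  expect_setequal(unique(pc$target), c("G6P_c", "R5P_p", "PYR_m"))
})

test_that("precursor demand without production is an error", {
  mets <- metabolites(c("A", "P"), carbon_atoms = c(1, 2))
  net <- metabolic_network(mets, list(
    reaction("EX_in", c(A = 1), kind = "exchange", pathway = "exchange"),
    reaction("R_bio", c(A = -1, P = -1), pathway = "biomass"),
    reaction("EX_A", c(A = -1), kind = "exchange", pathway = "exchange")))
  flux <- c(EX_in = 2, R_bio = 1, EX_A = 1)
  expect_error(precursor_contributions(flux, net), "zero production")
})

test_that("energy accounting pools cofactors by prefix against demand", {
  net <- apply_scenario(make_mini_leaf(), leaf_scenario("heterotrophy_dark"))
  nd <- normalize_modes(enumerate_efms(net), net)
  top <- top_percentile_mean(nd, p = 0.01, net, min_n = 5)
  ea <- energy_accounting(top$mean, net)
  expect_true(all(unique(ea$target) %in% c("NADPH", "NADH", "ATP")))
  expect_true(all(ea$fraction >= 0))
  # dark ATP comes mostly from oxidative phosphorylation
  atp <- ea[ea$target == "ATP" & ea$by == "pathway", ]
  expect_equal(atp$source[which.max(atp$fraction)], "oxphos")
})

test_that("CO2 release percent complements carbon efficiency on a mode", {
  net <- apply_scenario(make_mini_leaf(), leaf_scenario("heterotrophy_dark"))
  nd <- normalize_modes(enumerate_efms(net), net)
  yl <- mode_yields(nd, net)
  i <- which.max(yl$biomass_yield)
  flux <- stats::setNames(nd$modes[i, ], nd$reaction_ids)
  co2 <- co2_accounting(flux, net)
  expect_equal(co2$substrate_cmol, 600)
  expect_equal(co2$net_release_percent, 100 - yl$carbon_efficiency[i],
               tolerance = 1e-9)
  expect_true(all(abs(stats::aggregate(fraction ~ by, co2$shares,
                                       sum)$fraction - 1) < 1e-9))
})
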