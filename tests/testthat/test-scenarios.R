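# Scenario configuration, light stoichiometry, LP yield oracle, ratio scan.

test_that("scenario_config validates ratio and carbon sources", {
  expect_error(scenario_config(electron_flow_ratio = c(7, 6)), "summing to 14")
  expect_error(scenario_config(electron_flow_ratio = c(-1, 15)), "summing to 14")
  expect_error(scenario_config(co2_uptake = FALSE, starch_degradation = FALSE),
               "carbon source")
  cfg <- leaf_scenario("autotrophy_light")
  expect_true(cfg$co2_uptake && cfg$light_influx && cfg$starch_accumulation)
  dk <- leaf_scenario("heterotrophy_dark")
  expect_true(dk$starch_degradation && !dk$light_influx && !dk$co2_uptake)
})

test_that("the lumped light reaction reproduces the base stoichiometry", {
  lr <- build_light_reactions(light_stoichiometry(), c(12, 2))
  st <- stats::setNames(lr$num / lr$den, lr$mets)
  # 12:2 is the 8+2-photon base case: 10 photons -> 2 NADPH + 3 ATP
  expect_equal(unname(st["photon"]), -10)
  expect_equal(unname(st["NADPH_p"]), 2)
  expect_equal(unname(st["ATP_p"]), 3)
  expect_equal(-(st["ATP_p"] / st["NADPH_p"]) / -1, 1.5, ignore_attr = TRUE)
  # 0:14 is pure cyclic: photons make only ATP
  lr0 <- build_light_reactions(light_stoichiometry(), c(0, 14))
  expect_false("NADPH_p" %in% lr0$mets)
})

test_that("apply_scenario is idempotent and restores from the base", {
  net <- make_mini_leaf()
  light <- apply_scenario(net, leaf_scenario("autotrophy_light"))
  dark <- apply_scenario(light, leaf_scenario("heterotrophy_dark"))
  light2 <- apply_scenario(dark, leaf_scenario("autotrophy_light"))
  expect_equal(reaction_ids <- vapply(light$reactions, function(r) r$id, ""),
               vapply(light2$reactions, function(r) r$id, ""))
  # dark: no photon exchange, starch influx open, CO2 efflux-only
  ids_d <- vapply(dark$reactions, function(r) r$id, "")
  expect_false("EX_photon" %in% ids_d)
  expect_true("EX_starch_p" %in% ids_d)
  co2 <- dark$reactions[[match("EX_CO2", ids_d)]]
  expect_false(co2$reversible)
  expect_lt(co2$num[1], 0)
  # light: starch exchange flipped to efflux
  ids_l <- vapply(light$reactions, function(r) r$id, "")
  starch <- light$reactions[[match("EX_starch_p", ids_l)]]
  expect_false(starch$reversible)
  expect_lt(starch$num[1], 0)
})

test_that("LP maximum yield matches the best EFM on both main scenarios", {
  net <- make_mini_leaf()
  for (sc in c("autotrophy_light", "heterotrophy_dark")) {
    n2 <- apply_scenario(net, leaf_scenario(sc))
    lp <- max_biomass_yield_lp(n2)
    expect_true(lp$feasible)
    y <- mode_yields(normalize_modes(enumerate_efms(n2), n2), n2)
    expect_equal(lp$yield, max(y$biomass_yield, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("the internal simplex solves, detects infeasible and unbounded", {
  lp <- leafefm:::lp_max_eq(c(3, 2), rbind(c(1, 1), c(1, 0)), c(4, 2))
  expect_equal(lp$status, "optimal")
  expect_equal(lp$fval, 10)
  expect_equal(lp$x, c(2, 2))
  expect_equal(leafefm:::lp_max_eq(c(1), matrix(c(1, 1), 2, 1),
                                   c(1, 2))$status, "infeasible")
  expect_equal(leafefm:::lp_max_eq(c(1, 0), rbind(c(1, -1)),
                                   c(0))$status, "unbounded")
})

test_that("electron-flow scan covers 15 ratios with ATP:NADPH = 1.5 at 12:2", {
  net <- make_mini_leaf()
  sc <- scan_electron_flow(net, ratios = list(c(12, 2), c(0, 14)))
  expect_equal(nrow(sc$table), 2)
  expect_equal(sc$table$atp_nadph[1], 1.5)
  expect_equal(sc$table$max_yield[2], 0)
})
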