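# Network construction, stoichiometric matrix, exchanges, carbon balance,
# condensation and mode expansion.

test_that("reaction and network constructors validate their inputs", {
  expect_error(reaction("R", c(A = 0)), "all-zero")
  expect_error(reaction("R", c(1, -1)), "named")
  expect_error(reaction("R", c(A = -1, A = 1)), "duplicate")
  expect_error(reaction("R", c(A = -1, B = 1), pathway = "nope"),
               "closed vocabulary")
  mets <- metabolites(c("A", "B"), carbon_atoms = 1)
  expect_error(metabolic_network(mets, list(
    reaction("R1", c(A = -1, C = 1)))), "unknown metabolite")
  expect_error(metabolic_network(mets, list(
    reaction("R1", c(A = -1, B = 1)),
    reaction("R1", c(B = -1, A = 1)))), "duplicate reaction ids")
})

test_that("build_matrix is exact, ordered, and excludes external species", {
  net <- diamond_network()
  S <- as.matrix(build_matrix(net))
  expect_equal(rownames(S), c("A", "B", "C"))
  expect_equal(colnames(S), c("EX_in", "R1", "R2", "R3", "EX_out"))
  expect_equal(S["A", "R1"], -1)
  expect_equal(S["C", "EX_out"], -1)
  # rational entries stay exact
  mets <- metabolites(c("X", "Y"), carbon_atoms = 1)
  net2 <- metabolic_network(mets, list(reaction("R", c(X = -1 / 3, Y = 1 / 6))))
  S2 <- build_matrix(net2)
  expect_equal(S2$num["X", "R"], -1)
  expect_equal(S2$den["X", "R"], 3)
})

test_that("add_exchanges applies directional defaults and rejects duplicates", {
  mets <- rbind(metabolites(c("co2", "sucrose"), carbon_atoms = c(1, 12),
                            is_balanced = FALSE),
                metabolites("photon"), metabolites("biomass", carbon_atoms = 10,
                                                   is_balanced = FALSE))
  net <- metabolic_network(mets, list(
    reaction("R", c(co2 = -1, photon = -1, sucrose = 1 / 12, biomass = 0.1))))
  net <- add_exchanges(net, c("co2", "photon", "biomass"))
  ex <- Filter(function(r) r$kind == "exchange", net$reactions)
  names(ex) <- vapply(ex, function(r) r$id, "")
  expect_true(ex$EX_co2$reversible)               # bidirectional
  expect_false(ex$EX_photon$reversible)
  expect_gt(ex$EX_photon$num[1], 0)               # influx
  expect_lt(ex$EX_biomass$num[1], 0)              # efflux
  expect_error(add_exchanges(net, "co2"), "already present")
  expect_error(add_exchanges(net, "nope"), "unknown metabolite")
  expect_equal(length(remove_exchanges(net)$reactions), 1)
})

test_that("carbon balance report flags violations and skips unbalanced rows", {
  mets <- metabolites(c("A", "B"), carbon_atoms = c(2, 1))
  bad <- metabolic_network(mets, list(reaction("R", c(A = -1, B = 1))))
  rep <- check_carbon_balance(bad)
  expect_true(rep$flagged[rep$reaction == "R"])
  expect_equal(sum(check_carbon_balance(make_mini_leaf())$flagged), 0)
})

test_that("condense lumps chains exactly and expansion restores fluxes", {
  net <- chain_network()
  cd <- condense(net)
  expect_lt(length(cd$network$reactions), length(net$reactions))
  ms_c <- enumerate_efms(cd$network)
  ms_o <- enumerate_efms(net)
  ex <- expand_modes(ms_c$modes, cd$map, net)
  expect_equal(nrow(ex), nrow(ms_o$modes))
  expect_equal(canonical_rows(ex),
               canonical_rows(ms_o$modes[, colnames(ex), drop = FALSE]))
  # condensation never merges exchange columns
  ids_c <- vapply(cd$network$reactions, function(r) r$id, "")
  expect_true(all(c("EX_in", "EX_out") %in% ids_c))
})

test_that("proportional parallel reactions are merged", {
  mets <- metabolites(c("A", "B"), carbon_atoms = 1)
  net <- metabolic_network(mets, list(
    reaction("EX_in", c(A = 1), kind = "exchange", pathway = "exchange"),
    reaction("Ra", c(A = -1, B = 1), pathway = "other"),
    reaction("Rb", c(A = -2, B = 2), pathway = "other"),
    reaction("EX_out", c(B = -1), kind = "exchange", pathway = "exchange")))
  cd <- condense(net)
  ids <- vapply(cd$network$reactions, function(r) r$id, "")
  expect_equal(length(ids), 3)
  expect_true("Ra|Rb" %in% ids)
  # representative carries the flux, the dropped duplicate expands to zero
  mp <- cd$map[["Ra|Rb"]]
  expect_equal(mp$num[mp$orig == "Rb"], 0)
})
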