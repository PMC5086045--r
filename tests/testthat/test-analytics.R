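# Normalization, yields, futile filtering, top-percentile averaging,
# quantum analysis and condition comparison.

test_that("light modes normalize to 100 mol CO2, dark to 50 mol starch", {
  net <- make_mini_leaf()
  light <- apply_scenario(net, leaf_scenario("autotrophy_light"))
  nl <- normalize_modes(enumerate_efms(light), light)
  co2 <- leafefm:::exchange_uptake(nl$modes, light, "CO2")
  expect_true(all(abs(co2[nl$basis == "co2"] - 100) < 1e-9))
  expect_true(all(nl$substrate_cmol[nl$basis == "co2"] == 100))
  dark <- apply_scenario(net, leaf_scenario("heterotrophy_dark"))
  nd <- normalize_modes(enumerate_efms(dark), dark)
  st <- leafefm:::exchange_uptake(nd$modes, dark, "starch_p")
  expect_true(all(abs(st[nd$basis == "starch"] - 50) < 1e-9))
  expect_true(all(nd$substrate_cmol[nd$basis == "starch"] == 600))
  # idempotent
  expect_identical(normalize_modes(nl, light), nl)
})

test_that("yields and carbon efficiency follow their definitions", {
  net <- make_mini_leaf()
  light <- apply_scenario(net, leaf_scenario("autotrophy_light"))
  nl <- normalize_modes(enumerate_efms(light), light)
  yl <- mode_yields(nl, light)
  ok <- !is.na(yl$biomass_yield)
  # best light mode: all 100 C-mol into 14-carbon biomass weighing 430 g
  expect_equal(max(yl$biomass_yield[ok]), 430 * (100 / 14) / 100,
               tolerance = 1e-12)
  expect_equal(max(yl$carbon_efficiency[ok]), 100, tolerance = 1e-9)
  expect_true(all(yl$carbon_efficiency[ok] >= 0 &
                  yl$carbon_efficiency[ok] <= 100 + 1e-9))
})

test_that("futile filter: k = Inf is identity; cycling modes are removed", {
  net <- shuttle_network()
  clean <- shuttle_norm(rbind(c(100, 20, 20, 100, 100)))
  cyc <- shuttle_norm(rbind(c(100, 20, 20, 100, 100),
                            c(100, 400, 400, 100, 100)))
  id <- filter_futile(cyc, k = Inf, network = net)
  expect_equal(nrow(id$kept$modes), 2)
  def <- filter_futile(cyc, network = net)   # default k = 5
  expect_equal(nrow(def$kept$modes), 1)
  expect_equal(nrow(def$removed$modes), 1)
  expect_equal(def$transport_ratio, c(0.4, 8))
  expect_equal(filter_futile(clean, network = net)$transport_ratio, 0.4)
})

test_that("top-percentile mean takes ceiling(p*N), includes ties, honors min_n", {
  net <- make_mini_leaf()
  dark <- apply_scenario(net, leaf_scenario("heterotrophy_dark"))
  nd <- normalize_modes(enumerate_efms(dark), dark)
  tp1 <- top_percentile_mean(nd, p = 0.01, dark)
  expect_equal(tp1$n, 1)
  tp5 <- top_percentile_mean(nd, p = 0.01, dark, min_n = 5)
  expect_gte(tp5$n, 5)
  yl <- mode_yields(nd, dark)
  expect_true(all(yl$biomass_yield[tp5$indices] >= tp5$yield_threshold))
  tp50 <- top_percentile_mean(nd, p = 0.5, dark)
  expect_gte(tp50$n, tp5$n)
})

test_that("quantum analysis bands and yield correction", {
  net <- make_mini_leaf()
  light <- apply_scenario(net, leaf_scenario("autotrophy_light"))
  nl <- normalize_modes(enumerate_efms(light), light)
  qa <- quantum_analysis(nl, light)
  expect_true(qa$optimal_band[1] <= qa$optimal_band[2])
  expect_true(all(qa$requirement[!is.na(qa$requirement)] > 0))
  expect_equal(qa$quantum_yield_band, rev(1 / qa$optimal_band))
  expect_equal(correct_quantum_yield(0.053), 0.1)
  # permutation stability
  perm <- sample(nrow(nl$modes))
  np <- structure(list(modes = nl$modes[perm, , drop = FALSE],
                       reaction_ids = nl$reaction_ids,
                       reversible = nl$reversible, basis = nl$basis[perm],
                       substrate_cmol = nl$substrate_cmol[perm],
                       excluded = nl$excluded[perm],
                       scenario_id = nl$scenario_id),
                  class = "NormalizedModes")
  expect_equal(quantum_analysis(np, light)$optimal_band, qa$optimal_band)
})

test_that("compare_conditions verdicts follow the thresholds", {
  set.seed(1)
  n <- 10
  A <- cbind(up = rnorm(n, 10, 0.5), down = rnorm(n, 1, 0.1),
             rev = rnorm(n, 5, 0.3), same = rnorm(n, 4, 0.2),
             small = rnorm(n, 4, 0.2), onoff = rnorm(n, 2, 0.1))
  B <- cbind(up = rnorm(n, 2, 0.5), down = rnorm(n, 8, 0.4),
             rev = rnorm(n, -5, 0.3), same = rnorm(n, 4, 0.2),
             small = rnorm(n, 4 * 2^0.3, 0.01), onoff = rep(0, n))
  cmp <- compare_conditions(A, B)
  v <- stats::setNames(cmp$verdict, cmp$reaction)
  expect_equal(unname(v[c("up", "down", "rev", "same", "onoff")]),
               c("increased", "decreased", "reversed", "unchanged",
                 "increased"))
  expect_equal(unname(v["small"]), "unchanged")  # |log2| = 0.3 < 0.5
  expect_true(is.na(cmp$log2_ratio[cmp$reaction == "rev"]))
  expect_error(compare_conditions(A[, 1:2], B[, 2:1]), "differ")
  expect_error(compare_conditions(A[1, , drop = FALSE], B), "at least 2")
})

test_that("welch_p is robust to zero-variance samples", {
  expect_equal(leafefm:::welch_p(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(leafefm:::welch_p(c(1, 1, 1), c(2, 2, 2)), 0)
  p <- leafefm:::welch_p(c(1, 1, 1), c(2, 2.1, 1.9))
  expect_true(p > 0 && p < 0.05)
})
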