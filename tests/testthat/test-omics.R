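# Diurnal classification, gene mapping, concordance, fluxome overlay.

test_that("diurnal classification uses the amplitude cutoff and the phase", {
  prof <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     log2_amplitude = c(1.2, 0.8, 1.5, 0.79),
                     phase = c("light_up", "dark_up", "none", "dark_up"))
  cl <- classify_diurnal(prof)
  expect_equal(cl$diurnal, c(TRUE, FALSE, FALSE, FALSE))  # 0.8 is not > 0.8
  expect_equal(classify_diurnal(prof, cutoff = 0.5)$diurnal,
               c(TRUE, TRUE, FALSE, TRUE))
})

test_that("gene-to-reaction mapping preserves many-to-many relations", {
  net <- make_mini_leaf()
  prof <- data.frame(gene_id = c("AT5G08570", "AT5G56350", "AT1G67090"),
                     log2_amplitude = c(1, 1, 1),
                     phase = "dark_up")
  mp <- map_genes_to_reactions(net, prof)
  expect_equal(nrow(mp$R_glyc_c), 2)     # two of its three genes profiled
  expect_equal(nrow(mp$R_cbb), 1)
  expect_equal(nrow(mp$T_gap), 0)        # gene present but not profiled
})

test_that("concordance classes and direction agreement", {
  cmp <- data.frame(reaction = c("Ra", "Rb", "Rc", "Rd"),
                    mean_a = c(5, -2, 3, 1), mean_b = c(1, 2, 3, 1),
                    verdict = c("increased", "reversed", "unchanged",
                                "decreased"),
                    p_value = c(0.01, 0.01, 0.9, 0.01),
                    log2_ratio = c(2.3, NA, 0, -1))
  prof <- function(g, ph, d) data.frame(gene_id = g, log2_amplitude = 2,
                                        phase = ph, diurnal = d)
  mapped <- list(Ra = prof("g1", "light_up", TRUE),
                 Rb = prof("g2", "light_up", TRUE),
                 Rc = prof("g3", "dark_up", TRUE),
                 Rd = prof("g4", "none", FALSE))
  cc <- concordance(cmp, mapped)
  expect_equal(cc$class, c("both", "both", "transcript_only", "flux_only"))
  expect_equal(cc$directions_agree[1], TRUE)    # increased & light_up
  # reversed with negative light mean means dark-directed flux: disagrees
  expect_equal(cc$directions_agree[2], FALSE)
  expect_true(is.na(cc$directions_agree[3]))
})

test_that("fluxome overlay rescales to the 6 C-mol basis and correlates", {
  meas <- c(R1 = 3, R2 = 1.5, R3 = 0.6)
  pred100 <- c(R1 = 50, R2 = 25, R3 = 10, R4 = 7)
  ov <- fluxome_overlay(meas, pred100, predicted_cmol = 100)
  expect_equal(ov$pairs$predicted, c(3, 1.5, 0.6))
  expect_equal(ov$pairs$rel_deviation, c(0, 0, 0))
  expect_equal(ov$correlation, 1)
  expect_equal(ov$n_unmatched, 1)
  expect_error(fluxome_overlay(c(X = 1), pred100), "no shared")
})
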