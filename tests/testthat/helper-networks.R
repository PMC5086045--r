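# Small hand-built networks shared across test files.

# A -> B -> C and A -> C "diamond" with one inlet and one outlet.
# EFMs: {in, R1, R3, out} and {in, R2, out}.
diamond_network <- function() {
  mets <- metabolites(c("A", "B", "C"), carbon_atoms = 1)
  metabolic_network(mets, list(
    reaction("EX_in", c(A = 1), kind = "exchange", compartment = "external",
             pathway = "exchange"),
    reaction("R1", c(A = -1, B = 1), pathway = "other"),
    reaction("R2", c(A = -1, C = 1), pathway = "other"),
    reaction("R3", c(B = -1, C = 1), pathway = "other"),
    reaction("EX_out", c(C = -1), kind = "exchange", compartment = "external",
             pathway = "exchange")))
}

# linear chain with an inner 2-step segment that condensation should lump
chain_network <- function() {
  mets <- metabolites(c("A", "B", "C", "D"), carbon_atoms = 1)
  metabolic_network(mets, list(
    reaction("EX_in", c(A = 1), kind = "exchange", compartment = "external",
             pathway = "exchange"),
    reaction("R1", c(A = -1, B = 1), pathway = "other"),
    reaction("R2", c(B = -2, C = 1), pathway = "other"),
    reaction("R3", c(C = -1, D = 2), pathway = "other"),
    reaction("EX_out", c(D = -1), kind = "exchange", compartment = "external",
             pathway = "exchange")))
}

# network with a transport pair usable for futile-cycling constructions
shuttle_network <- function() {
  mets <- rbind(metabolites(c("S_c", "P_c"), compartment = "cytosol",
                            carbon_atoms = 1),
                metabolites("S_p", compartment = "plastid", carbon_atoms = 1))
  metabolic_network(mets, list(
    reaction("EX_S", c(S_c = 1), kind = "exchange", compartment = "external",
             pathway = "exchange"),
    reaction("T_in", c(S_c = -1, S_p = 1), kind = "transport",
             compartment = "cytosol|plastid", pathway = "transport"),
    reaction("T_out", c(S_p = -1, S_c = 1), kind = "transport",
             compartment = "plastid|cytosol", pathway = "transport"),
    reaction("R_conv", c(S_c = -1, P_c = 1), pathway = "other"),
    reaction("EX_P", c(P_c = -1), kind = "exchange", compartment = "external",
             pathway = "exchange")))
}

# hand-built NormalizedModes over shuttle_network columns
shuttle_norm <- function(modes) {
  structure(list(modes = modes,
                 reaction_ids = c("EX_S", "T_in", "T_out", "R_conv", "EX_P"),
                 reversible = rep(FALSE, 5),
                 basis = rep("co2", nrow(modes)),
                 substrate_cmol = rep(100, nrow(modes)),
                 excluded = rep(FALSE, nrow(modes)),
                 scenario_id = "test"),
            class = "NormalizedModes")
}

canonical_rows <- function(M) {
  keys <- apply(M, 1, function(v) {
    v <- v / v[which(v != 0)[1]]   # scale- and sign-normalize
    paste(sprintf("%.10g", v), collapse = ",")
  })
  sort(keys)
}
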