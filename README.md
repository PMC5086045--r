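# leafefm

Elementary flux mode (EFM) analysis of compartmented plant leaf central
carbon metabolism, with exact rational arithmetic throughout.

An EFM is a minimal steady-state flux route through a metabolic network:
every feasible flux distribution is a non-negative combination of EFMs, so
enumerating them exhaustively characterizes the complete metabolic
capability of a model. `leafefm` builds stoichiometric models across
cytosol, plastid and mitochondrion, enumerates their EFMs exactly, and
analyzes the resulting mode sets the way a leaf physiologist would: biomass
yields per C-mol of substrate, carbon efficiencies, quantum requirements,
light-versus-dark flux reorganization, pathway-resolved precursor and
energy accounting, and integration with diurnal transcript profiles and
measured fluxomes.

## What is in the box

- **Model core** — exact-rational stoichiometric networks, exchange
  attachment, carbon-balance checking, and lossless network condensation
  (dead-end removal, chain lumping, proportional-duplicate merging) with a
  map that expands condensed modes back to the full network.
- **EFM engine** — nullspace-based double-description enumeration with a
  rank-based elementarity test, plus an independent brute-force oracle used
  to verify the enumerator on small networks.
- **Scenarios** — autotrophic light (CO2 + photons in, starch accumulating)
  and heterotrophic dark (starch-fed) configurations, a 15-point scan over
  non-cyclic:cyclic photophosphorylation ratios (14:0 … 0:14), and an
  in-package exact-arithmetic-friendly LP that computes the maximum biomass
  yield as an independent check on the enumeration.
- **Analytics** — normalization to 100 mol CO2 (light) or 50 mol starch
  (dark), yields and carbon efficiencies, a transport-flux futile-mode
  filter, top-1 % flux averaging, quantum-requirement bands, and a
  Welch-test light/dark comparison with a verdict taxonomy
  (reversed / increased / decreased / unchanged) that never needs
  pseudo-counts.
- **Omics integration** — diurnal transcript classification (amplitude
  cutoff 0.8 log2 units), gene-to-reaction mapping, flux–transcript
  concordance, and fluxome overlay with rank correlation.
- **Synthetic data** — seeded, byte-deterministic generators for toy
  networks, a miniature three-compartment leaf model, transcript tables and
  fluxomes, so the entire pipeline is testable offline.
- **Pipeline** — `run_enumerate()`, `run_analyze()`, `run_compare()`,
  `run_scan_light()`, `run_integrate()`, `run_fixtures()` writing TSV
  outputs, plus an `Rscript` dispatcher in `inst/scripts/leafefm-cli.R`.
- **I/O** — SBML (Level 2 read, Level 3 write) and a lossless,
  byte-stable tabular model dialect; transcript and fluxome TSV readers.

## Worked example

```r
library(leafefm)

net   <- make_mini_leaf()
light <- apply_scenario(net, leaf_scenario("autotrophy_light"))
dark  <- apply_scenario(net, leaf_scenario("heterotrophy_dark"))

ms_l <- enumerate_efms(light)   # 41 modes
ms_d <- enumerate_efms(dark)    # 36 modes

norm_l <- normalize_modes(ms_l, light)   # 100 mol CO2 basis
yl     <- mode_yields(norm_l, light)
max(yl$biomass_yield, na.rm = TRUE)
#> [1] 30.71429        # g biomass per C-mol CO2

# the LP bound agrees with the best enumerated mode to ~1e-13
max_biomass_yield_lp(light)$yield
#> [1] 30.71429
max_biomass_yield_lp(dark)$yield
#> [1] 24.85549        # dark, starch-fed: 80.9 % carbon efficiency

# quantum requirement band of the top modes (mol photon / mol CO2)
quantum_analysis(normalize_modes(ms_l, light), light)$optimal_band
#> [1] 11.74107 16.42857

# light vs dark flux reorganization on the top-percentile modes
cmp <- run_compare(run_config(out_dir = tempdir()))
table(cmp$comparison$verdict)
#>  reversed increased decreased unchanged
#>         1         1         7        13
```

The one *reversed* reaction is the plastidic triose/hexose-phosphate
interconversion (`R_hex_p`): in the light it runs toward hexose phosphate
(feeding starch synthesis and biomass hexose), in the dark it runs the
other way (starch-derived hexose phosphate feeding glycolysis) — the
classic starch turnover signature.

Photophosphorylation plasticity:

```r
sc <- scan_electron_flow(make_mini_leaf())
range(sc$table$max_yield[sc$table$non_cyclic > 0])
#> [1] 30.71429 30.71429    # identical from 14:0 down to 1:13
sc$table$max_yield[sc$table$non_cyclic == 0]
#> [1] 0                    # cyclic-only flow makes no NADPH: no biomass
```

Omics integration on the shipped fixtures:

```r
cfg <- run_config(out_dir = tempdir(), seed = 1)
fx  <- run_fixtures(cfg)
it  <- run_integrate(cfg, transcripts = fx[["transcripts"]],
                     fluxome = fx[["fluxome"]])
sum(it$concordance$class == "both")   #> 7 reactions, all directions agree
it$overlay$correlation                #> 0.958 (Spearman; 1.0 at zero noise)
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/leafefm-cli.R", package="leafefm"))') \
  analyze --scenario autotrophy_light --out out/
```

## Reproduction

All headline numbers above are recomputed by the acceptance script:

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which writes the EFM counts, LP/EFM yield agreement, scan invariance,
quantum band, comparison tallies and omics-recovery statistics as JSON.
The test suite (`testthat::test_dir("tests/testthat", package = "leafefm",
load_package = "installed")`) verifies the enumerator against the
brute-force oracle on 50 seeded networks, condensation fidelity, LP–EFM
yield duality, futile-filter and quantum-band properties, the electron-flow
plasticity result, and synthetic-data recovery. One acceptance block
requires a reference genome-scale condensed leaf model
(`inst/extdata/arabidopsis_leaf_condensed.xml`) that is not distributable
with the package; that block fails until the file is supplied.
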