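# SBML reader/writer built on xml2. The structural mapping (species,
# compartments, reactions, reversibility, stoichiometry) follows SBML Level
# 2/3 core; package-specific annotation (carbon counts, reaction kind and
# pathway, gene associations, species roles) travels in notes lines of the
# form "KEY: value" so files remain valid plain SBML.

# compartment label normalization: common SBML compartment ids mapped onto
# the package's compartment vocabulary; unknown labels are preserved
#' @noRd
normalize_compartment <- function(x) {
  key <- tolower(x)
  map <- c(c = "cytosol", cyt = "cytosol", cytosol = "cytosol",
           cytoplasm = "cytosol",
           p = "plastid", chl = "plastid", chloroplast = "plastid",
           plastid = "plastid",
           m = "mitochondrion", mit = "mitochondrion", mito = "mitochondrion",
           mitochondrion = "mitochondrion", mitochondria = "mitochondrion",
           x = "peroxisome", per = "peroxisome", peroxisome = "peroxisome",
           e = "external", ext = "external", external = "external",
           boundary = "external", extracellular = "external")
  out <- unname(map[key])
  ifelse(is.na(out), x, out)
}

#' @noRd
notes_lines <- function(node) {
  notes <- xml2::xml_find_first(node, "./notes")
  if (inherits(notes, "xml_missing")) return(character())
  txt <- xml2::xml_text(xml2::xml_find_all(notes, ".//text()"))
  txt <- trimws(txt)
  txt[nzchar(txt)]
}

#' @noRd
notes_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\s*:"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(paste0("^", key, "\\s*:"), "", hit[1]))
}

#' @noRd
fmt_coef <- function(num, den) {
  ifelse(den == 1, as.character(num),
         format(num / den, digits = 15, scientific = FALSE))
}

#' Write a network as SBML Level 3
#'
#' Emits SBML Level 3 Version 1 core with the package's annotations (carbon
#' atoms, balance flags, reaction kind/pathway/genes, species roles, biomass
#' mass) embedded as `KEY: value` lines in notes, so the file stays readable
#' by generic SBML tools and round-trips through [read_sbml()].
#'
#' @param network a `MetabolicNetwork`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sbml <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  note_block <- function(lines, indent) {
    if (!length(lines)) return(character())
    c(paste0(indent, "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">"),
      paste0(indent, "  <p>", esc(lines), "</p>"),
      paste0(indent, "</body></notes>"))
  }
  roles <- attr(network, "species_roles")
  mass <- attr(network, "biomass_mass")
  light <- attr(network, "light_species")
  model_notes <- character()
  if (nzchar(network$provenance))
    model_notes <- c(model_notes, paste("PROVENANCE:", network$provenance))
  if (!is.null(roles))
    for (nm in names(roles)) if (!is.na(roles[[nm]][1]))
      model_notes <- c(model_notes,
                       paste0("ROLE_", toupper(nm), ": ", roles[[nm]][1]))
  if (!is.null(mass))
    model_notes <- c(model_notes, paste("BIOMASS_MASS:", format(mass, digits = 15)))
  if (!is.null(light))
    model_notes <- c(model_notes,
                     paste("LIGHT_SPECIES:",
                           paste(names(light), unlist(light), sep = "=",
                                 collapse = ";")))

  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
                  " level=\"3\" version=\"1\">"),
           "  <model id=\"leafefm_model\">",
           note_block(model_notes, "    "))
  comps <- unique(network$metabolites$compartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf("      <compartment id=\"%s\" constant=\"true\"/>", esc(comps)),
           "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    out <- c(out,
             sprintf(paste0("      <species id=\"%s\" name=\"%s\"",
                            " compartment=\"%s\" hasOnlySubstanceUnits=\"false\"",
                            " boundaryCondition=\"%s\" constant=\"false\">"),
                     esc(m$id), esc(m$name), esc(m$compartment),
                     if (m$compartment == "external") "true" else "false"),
             note_block(c(paste("CARBON:", m$carbon_atoms),
                          paste("BALANCED:", tolower(as.character(m$is_balanced)))),
                        "        "),
             "      </species>")
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in network$reactions) {
    notes <- c(paste("KIND:", r$kind), paste("PATHWAY:", r$pathway))
    if (nzchar(r$compartment))
      notes <- c(notes, paste("LOCATION:", r$compartment))
    if (length(r$genes))
      notes <- c(notes, paste("GENE_ASSOCIATION:", paste(r$genes, collapse = ";")))
    coef <- r$num / r$den
    side <- function(idx, tag) {
      if (!any(idx)) return(character())
      c(sprintf("        <listOf%ss>", tag),
        sprintf(paste0("          <speciesReference species=\"%s\"",
                       " stoichiometry=\"%s\" constant=\"true\"/>"),
                esc(r$mets[idx]), fmt_coef(abs(r$num[idx]), r$den[idx])),
        sprintf("        </listOf%ss>", tag))
    }
    out <- c(out,
             sprintf("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\">",
                     esc(r$id), tolower(as.character(r$reversible))),
             note_block(notes, "        "),
             side(coef < 0, "Reactant"), side(coef > 0, "Product"),
             "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

#' Read an SBML model
#'
#' Parses SBML Level 2 or Level 3 core into a `MetabolicNetwork`.
#' Stoichiometric coefficients are rationalized exactly; compartment ids are
#' mapped to the package vocabulary where recognizable (`c`, `chloroplast`,
#' `mito`, ...) and preserved verbatim otherwise; species without a
#' compartment raise a warning and land in `"external"`; boundary-condition
#' species are placed in `"external"` so they drop out of the stoichiometric
#' matrix. Notes lines `CARBON:`, `BALANCED:`, `KIND:`, `PATHWAY:`,
#' `LOCATION:`, `GENE_ASSOCIATION:` and the model-level role/mass lines
#' written by [write_sbml()] are honored when present; otherwise reaction
#' kinds are inferred (single-species columns are exchanges, multi-compartment
#' reactions transports).
#'
#' @param path SBML file path.
#' @return a `MetabolicNetwork`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_sbml: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("read_sbml: no <model> element")
  m_notes <- notes_lines(model)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("read_sbml: no species")
  mets <- do.call(rbind, lapply(sp_nodes, function(s) {
    id <- xml2::xml_attr(s, "id")
    comp <- xml2::xml_attr(s, "compartment")
    if (is.na(comp) || !nzchar(comp)) {
      warning("species '", id, "' has no compartment; assigning 'external'")
      comp <- "external"
    } else comp <- normalize_compartment(comp)
    if (identical(xml2::xml_attr(s, "boundaryCondition"), "true"))
      comp <- "external"
    ln <- notes_lines(s)
    carb <- suppressWarnings(as.numeric(notes_value(ln, "CARBON")))
    bal <- notes_value(ln, "BALANCED")
    nm <- xml2::xml_attr(s, "name")
    data.frame(id = id, name = if (is.na(nm)) id else nm, compartment = comp,
               carbon_atoms = if (is.na(carb)) 0 else carb,
               is_balanced = !identical(bal, "false"),
               stringsAsFactors = FALSE)
  }))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("read_sbml: no reactions")
  comp_of <- stats::setNames(mets$compartment, mets$id)
  reactions <- lapply(rx_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev_attr <- xml2::xml_attr(rn, "reversible")
    reversible <- is.na(rev_attr) || identical(rev_attr, "true")  # L2 default
    refs <- function(xp, sgn) {
      nodes <- xml2::xml_find_all(rn, xp)
      if (!length(nodes)) return(numeric())
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st <- ifelse(is.na(st), 1, suppressWarnings(as.numeric(st)))
      if (anyNA(st)) stop("reaction '", id, "': non-numeric stoichiometry")
      stats::setNames(sgn * st, xml2::xml_attr(nodes, "species"))
    }
    stoich_l <- c(refs("./listOfReactants/speciesReference", -1),
                  refs("./listOfProducts/speciesReference", 1))
    # the same species on both sides is net-summed
    stoich <- tapply(stoich_l, names(stoich_l), sum)
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
    ln <- notes_lines(rn)
    kind <- notes_value(ln, "KIND")
    comps <- unique(setdiff(comp_of[names(stoich)], "external"))
    if (is.na(kind) || !kind %in% c("internal", "transport", "exchange")) {
      kind <- if (length(stoich) == 1 || length(comps) == 0 ||
                  grepl("^EX_", id)) "exchange"
        else if (length(comps) > 1) "transport" else "internal"
    }
    pathway <- notes_value(ln, "PATHWAY")
    if (is.na(pathway) || !pathway %in% leaf_pathways())
      pathway <- if (kind == "exchange") "exchange" else "other"
    loc <- notes_value(ln, "LOCATION")
    if (is.na(loc))
      loc <- paste(if (length(comps)) comps else "external", collapse = "|")
    ga <- notes_value(ln, "GENE_ASSOCIATION")
    genes <- if (is.na(ga)) character() else {
      g <- trimws(strsplit(ga, "[;,]| or | and ")[[1]])
      g[nzchar(g)]
    }
    reaction(id, stoich, reversible = reversible, kind = kind,
             compartment = loc, genes = genes, pathway = pathway)
  })

  prov <- notes_value(m_notes, "PROVENANCE")
  net <- metabolic_network(mets, reactions,
                           provenance = if (is.na(prov)) "" else prov)
  role_lines <- grep("^ROLE_[A-Z0-9]+\\s*:", m_notes, value = TRUE)
  if (length(role_lines)) {
    keys <- tolower(sub("^ROLE_([A-Z0-9]+)\\s*:.*$", "\\1", role_lines))
    vals <- trimws(sub("^ROLE_[A-Z0-9]+\\s*:", "", role_lines))
    attr(net, "species_roles") <- stats::setNames(as.list(vals), keys)
  }
  mass <- suppressWarnings(as.numeric(notes_value(m_notes, "BIOMASS_MASS")))
  if (!is.na(mass)) attr(net, "biomass_mass") <- mass
  light <- notes_value(m_notes, "LIGHT_SPECIES")
  if (!is.na(light)) {
    parts <- strsplit(strsplit(light, ";")[[1]], "=", fixed = TRUE)
    attr(net, "light_species") <-
      stats::setNames(lapply(parts, function(p) p[length(p)]),
                      vapply(parts, function(p) p[1], ""))
  }
  net
}
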