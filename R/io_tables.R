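# Tab-separated model dialect and readers/writers for transcript and
# fluxome tables. The model dialect is a single TSV with [metabolites] and
# [reactions] sections; reactions carry human-readable equation strings
# ("2 A_c + B_p -> C_m") whose arrow encodes reversibility. Network
# attributes (species roles, biomass mass, light species) travel in `#@`
# header lines so the dialect round-trips losslessly.

#' @noRd
fmt_equation <- function(r) {
  coef <- r$num / r$den
  term <- function(num, den, met) {
    c <- ifelse(den == 1, as.character(num), paste0(num, "/", den))
    paste(ifelse(num == 1 & den == 1, met, paste(c, met)), collapse = " + ")
  }
  lhs <- coef < 0
  arrow <- if (r$reversible) "<->" else "->"
  paste(term(abs(r$num[lhs]), r$den[lhs], r$mets[lhs]), arrow,
        term(r$num[!lhs], r$den[!lhs], r$mets[!lhs]))
}

# parse one side of an equation ("2 A_c + 1/2 B_p") into a named vector
#' @noRd
parse_side <- function(txt, sgn, id) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(numeric())
  terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    toks <- strsplit(tm, "\\s+")[[1]]
    coef <- 1
    if (length(toks) == 2 && grepl("^[0-9.]+(/[0-9]+)?$", toks[1])) {
      if (grepl("/", toks[1], fixed = TRUE)) {
        ab <- as.numeric(strsplit(toks[1], "/", fixed = TRUE)[[1]])
        coef <- ab[1] / ab[2]
      } else coef <- as.numeric(toks[1])
      toks <- toks[-1]
    }
    if (length(toks) != 1)
      stop("reaction '", id, "': cannot parse equation term '", tm, "'")
    out[toks] <- (if (toks %in% names(out)) out[[toks]] else 0) + sgn * coef
  }
  out
}

#' @noRd
parse_equation <- function(eq, id) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("reaction '", id, "': equation needs exactly one arrow: '", eq, "'")
  stoich_l <- parse_side(sides[1], -1, id)
  stoich_r <- parse_side(sides[2], 1, id)
  stoich <- stoich_l
  for (m in names(stoich_r))
    stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) + stoich_r[[m]]
  list(stoich = stoich, reversible = rev)
}

#' Write a network in the tabular model dialect
#'
#' One TSV file with a `[metabolites]` section (id, name, compartment,
#' carbon_atoms, is_balanced) and a `[reactions]` section (id, equation,
#' kind, compartment, pathway, genes); the equation arrow (`->` / `<->`)
#' encodes reversibility, genes are semicolon-separated. Network attributes
#' are kept in `#@` header lines. Round-trips with [read_table()].
#'
#' @param network a `MetabolicNetwork`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(network, path) {
  hdr <- c("# leafefm tabular model v1")
  if (nzchar(network$provenance))
    hdr <- c(hdr, paste0("#@ provenance\t", network$provenance))
  roles <- attr(network, "species_roles")
  if (!is.null(roles))
    for (nm in names(roles)) if (!is.na(roles[[nm]][1]))
      hdr <- c(hdr, paste0("#@ role\t", nm, "\t", roles[[nm]][1]))
  light <- attr(network, "light_species")
  if (!is.null(light))
    for (nm in names(light))
      hdr <- c(hdr, paste0("#@ light\t", nm, "\t", light[[nm]]))
  mass <- attr(network, "biomass_mass")
  if (!is.null(mass))
    hdr <- c(hdr, paste0("#@ biomass_mass\t", format(mass, digits = 15)))

  m <- network$metabolites
  met_rows <- paste(m$id, m$name, m$compartment, m$carbon_atoms,
                    tolower(as.character(m$is_balanced)), sep = "\t")
  rxn_rows <- vapply(network$reactions, function(r) {
    paste(r$id, fmt_equation(r), r$kind, r$compartment, r$pathway,
          paste(r$genes, collapse = ";"), sep = "\t")
  }, "")
  writeLines(c(hdr,
               "[metabolites]",
               "id\tname\tcompartment\tcarbon_atoms\tis_balanced",
               met_rows,
               "[reactions]",
               "id\tequation\tkind\tcompartment\tpathway\tgenes",
               rxn_rows), path)
  invisible(path)
}

#' Read a tabular model
#'
#' Parses the dialect written by [write_table()] back into a
#' `MetabolicNetwork`, restoring attributes from the `#@` header lines.
#'
#' @param path input path.
#' @return a `MetabolicNetwork`.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  attrs <- strsplit(sub("^#@ ", "", grep("^#@ ", lines, value = TRUE)), "\t",
                    fixed = TRUE)
  lines <- lines[!grepl("^#", lines)]
  sec_m <- which(lines == "[metabolites]")
  sec_r <- which(lines == "[reactions]")
  if (length(sec_m) != 1 || length(sec_r) != 1 || sec_r < sec_m)
    stop("read_table: need one [metabolites] section followed by [reactions]")
  split_rows <- function(rows, ncol, what) {
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) < 2) stop("read_table: empty ", what, " section")
    cells <- strsplit(rows, "\t", fixed = TRUE)
    header <- cells[[1]]
    if (length(header) != ncol)
      stop("read_table: ", what, " header must have ", ncol, " columns")
    list(header = header, rows = cells[-1])
  }
  msec <- split_rows(lines[(sec_m + 1):(sec_r - 1)], 5, "metabolite")
  mdf <- do.call(rbind, lapply(msec$rows, function(x) {
    if (length(x) != 5) stop("read_table: malformed metabolite row: ",
                             paste(x, collapse = "\t"))
    data.frame(id = x[1], name = x[2], compartment = x[3],
               carbon_atoms = as.numeric(x[4]),
               is_balanced = !identical(x[5], "false"),
               stringsAsFactors = FALSE)
  }))
  rsec <- split_rows(lines[(sec_r + 1):length(lines)], 6, "reaction")
  reactions <- lapply(rsec$rows, function(x) {
    if (length(x) == 5) x <- c(x, "")  # strsplit drops a trailing empty field
    if (length(x) != 6) stop("read_table: malformed reaction row: ",
                             paste(x, collapse = "\t"))
    eq <- parse_equation(x[2], x[1])
    genes <- strsplit(x[6], ";", fixed = TRUE)[[1]]
    reaction(x[1], eq$stoich, reversible = eq$reversible, kind = x[3],
             compartment = x[4], genes = genes[nzchar(genes)], pathway = x[5])
  })
  prov <- Filter(function(a) a[1] == "provenance", attrs)
  net <- metabolic_network(mdf, reactions,
                           provenance = if (length(prov)) prov[[1]][2] else "")
  roles <- Filter(function(a) a[1] == "role", attrs)
  if (length(roles))
    attr(net, "species_roles") <-
      stats::setNames(lapply(roles, `[`, 3), vapply(roles, `[`, "", 2))
  light <- Filter(function(a) a[1] == "light", attrs)
  if (length(light))
    attr(net, "light_species") <-
      stats::setNames(lapply(light, `[`, 3), vapply(light, `[`, "", 2))
  mass <- Filter(function(a) a[1] == "biomass_mass", attrs)
  if (length(mass)) attr(net, "biomass_mass") <- as.numeric(mass[[1]][2])
  net
}

#' Read transcript profiles
#'
#' Reads a delimited table with mandatory columns `gene_id` and
#' `log2_amplitude`, optional `phase` (`light-up`/`dark-up`, also accepted
#' with underscores; anything else becomes `"none"`) and optional
#' per-timepoint columns. Rows with a non-numeric amplitude are skipped and
#' the skip count messaged and attached as the `n_skipped` attribute.
#'
#' @param path TSV/CSV path (separator sniffed from the header line).
#' @return data.frame of transcript profiles.
#' @export
read_transcripts <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("gene_id", "log2_amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_transcripts: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  amp <- suppressWarnings(as.numeric(df$log2_amplitude))
  bad <- is.na(amp) | !nzchar(trimws(df$gene_id))
  if (any(bad))
    message("read_transcripts: skipped ", sum(bad), " malformed row(s)")
  df <- df[!bad, , drop = FALSE]
  df$log2_amplitude <- amp[!bad]
  if (is.null(df$phase)) df$phase <- "none"
  df$phase <- gsub("-", "_", df$phase, fixed = TRUE)
  df$phase[!df$phase %in% c("light_up", "dark_up")] <- "none"
  rownames(df) <- NULL
  attr(df, "n_skipped") <- sum(bad)
  df
}

#' Write transcript profiles
#'
#' @param profiles data.frame (e.g. from [make_transcripts()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_transcripts <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a measured fluxome
#'
#' Reads a table with mandatory columns `reaction_id` and `flux` and an
#' optional `unit` column (`"cmol"`, the default, or `"mol"`). `mol` entries
#' are converted to C-mol by the reaction's carbon transfer (total carbon on
#' the producing side), which requires `network`. Malformed rows (non-numeric
#' flux, unknown reaction for a `mol` row) are skipped with a message.
#'
#' @param path TSV/CSV path.
#' @param network `MetabolicNetwork`; needed when any row uses `mol` units.
#' @return named numeric vector of C-mol fluxes, with `n_skipped` attribute.
#' @export
read_fluxome <- function(path, network = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("reaction_id", "flux"), names(df))
  if (length(miss))
    stop("read_fluxome: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  flux <- suppressWarnings(as.numeric(df$flux))
  unit <- if (is.null(df$unit)) rep("cmol", nrow(df)) else tolower(df$unit)
  unit[!nzchar(unit) | is.na(unit)] <- "cmol"
  bad <- is.na(flux)
  if (any(unit == "mol")) {
    if (is.null(network))
      stop("read_fluxome: 'mol' entries need a network for carbon conversion")
    ct <- stats::setNames(carbon_transfer(network), reaction_ids(network))
    conv <- ct[df$reaction_id]
    sel <- unit == "mol"
    bad <- bad | (sel & is.na(conv))
    flux[sel & !bad] <- flux[sel & !bad] * conv[sel & !bad]
  }
  if (any(bad))
    message("read_fluxome: skipped ", sum(bad), " malformed row(s)")
  out <- stats::setNames(flux[!bad], df$reaction_id[!bad])
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a measured fluxome
#'
#' @param flux named numeric vector of C-mol fluxes.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fluxome <- function(flux, path) {
  utils::write.table(data.frame(reaction_id = names(flux),
                                flux = as.numeric(flux), unit = "cmol"),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
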