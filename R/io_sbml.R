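# SBML Level 3 + FBC v2 model I/O.
#
# Purpose-written xml2-based reader/writer for the FBC subset used by
# constraint-based models: species (with fbc:chemicalFormula), flux bounds as
# global parameters referenced by fbc:lowerFluxBound/upperFluxBound, the
# active fbc objective, and gene-product associations (preserved as gene
# token sets; boolean GPR structure is out of scope).  SBML ids use the
# conventional "M_"/"R_" prefixes, stripped on read and re-added on write.

#' Load a metabolic model from file
#'
#' @param path file path.
#' @param dialect `"bigg-json"` or `"sbml-fbc"`; default guesses from the
#'   file extension.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, dialect = c("auto", "bigg-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else "bigg-json"
  }
  switch(dialect,
         "bigg-json" = .read_bigg_json(path),
         "sbml-fbc" = .read_sbml_fbc(path))
}

#' Write a metabolic model to file
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param dialect `"bigg-json"` or `"sbml-fbc"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "bigg-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else "bigg-json"
  }
  switch(dialect,
         "bigg-json" = .write_bigg_json(model, path),
         "sbml-fbc" = .write_sbml_fbc(model, path))
}

# attribute access tolerant of namespace prefixes
.attr1 <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0("(^|:)", name, "$"), names(at)))
  if (!length(hit)) NA_character_ else unname(at[hit[1L]])
}

.strip_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

.read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure: ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  sbml_model <- xml2::xml_find_first(doc, ".//model")
  if (is.na(sbml_model)) stop("no <model> element in ", path, call. = FALSE)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  sp <- sp[keep]
  mets <- data.frame(
    id = .strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  .strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    formula = vapply(sp, .attr1, "", "chemicalFormula"),
    charge = suppressWarnings(as.numeric(vapply(sp, .attr1, "", "charge"))),
    stringsAsFactors = FALSE)

  rx <- xml2::xml_find_all(sbml_model, ".//listOfReactions/reaction")
  nr <- length(rx)
  if (!nr) stop("no reactions in ", path, call. = FALSE)
  ids <- .strip_prefix(xml2::xml_attr(rx, "id"), "R_")
  lb <- ub <- numeric(nr)
  gene_rule <- character(nr)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(nr)) {
    node <- rx[[k]]
    lbp <- .attr1(node, "lowerFluxBound"); ubp <- .attr1(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[k] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    gps <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    if (length(gps)) {
      toks <- unique(vapply(gps, .attr1, "", "geneProduct"))
      gene_rule[k] <- paste(.strip_prefix(toks, "G_"), collapse = " or ")
    }
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sid <- .strip_prefix(xml2::xml_attr(refs, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      row <- match(sid, mets$id)
      ok <- !is.na(row) & coef != 0   # boundary species silently dropped
      i <- c(i, row[ok]); j <- c(j, rep.int(k, sum(ok))); x <- c(x, coef[ok])
    }
  }
  rxns <- data.frame(id = ids,
                     name = ifelse(is.na(xml2::xml_attr(rx, "name")), ids,
                                   xml2::xml_attr(rx, "name")),
                     lb = lb, ub = ub, gene_rule = gene_rule, subsystem = "",
                     stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrow(mets), nr))

  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass_id <- if (!is.na(fo)) {
    .strip_prefix(.attr1(fo, "reaction"), "R_")
  } else {
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) stop("no biomass reaction identifiable in ", path,
                           call. = FALSE)
    hit[1L]
  }
  metabolic_model(mets, rxns, S, biomass_id,
                  annotations = list(id = xml2::xml_attr(sbml_model, "id"),
                                     source = "sbml-fbc"))
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.write_sbml_fbc <- function(model, path) {
  # parameters: one per distinct bound value
  vals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  pid <- paste0("fb_", seq_along(vals))
  pmap <- stats::setNames(pid, sprintf("%.17g", vals))
  pref <- function(v) pmap[[sprintf("%.17g", v)]]

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', .xml_escape(model$annotations$id %||% "model"),
    '" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (cp in unique(model$mets$compartment)) {
    w('      <compartment id="', .xml_escape(cp), '" constant="true"/>')
  }
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (k in seq_len(nrow(model$mets))) {
    m <- model$mets[k, ]
    extra <- ""
    if (!is.na(m$formula)) {
      extra <- paste0(extra, ' fbc:chemicalFormula="', .xml_escape(m$formula), '"')
    }
    if (!is.na(m$charge)) {
      extra <- paste0(extra, ' fbc:charge="', as.integer(m$charge), '"')
    }
    w('      <species id="M_', .xml_escape(m$id), '" name="',
      .xml_escape(m$name), '" compartment="', .xml_escape(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"', extra, '/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (k in seq_along(vals)) {
    w('      <parameter id="', pid[k], '" value="',
      format(vals[k], digits = 17), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  S <- model$S
  for (k in seq_len(nrow(model$rxns))) {
    r <- model$rxns[k, ]
    w('      <reaction id="R_', .xml_escape(r$id), '" name="',
      .xml_escape(r$name), '" reversible="',
      if (r$lb < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', pref(r$lb),
      '" fbc:upperFluxBound="', pref(r$ub), '">')
    col <- S[, k]
    nz <- which(col != 0)
    subs <- nz[col[nz] < 0]; prods <- nz[col[nz] > 0]
    if (length(subs)) {
      w('        <listOfReactants>')
      for (s in subs) {
        w('          <speciesReference species="M_',
          .xml_escape(rownames(S)[s]), '" stoichiometry="',
          format(-col[s], digits = 17), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (s in prods) {
        w('          <speciesReference species="M_',
          .xml_escape(rownames(S)[s]), '" stoichiometry="',
          format(col[s], digits = 17), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    toks <- .gene_tokens(r$gene_rule)
    if (length(toks)) {
      w('        <fbc:geneProductAssociation>')
      if (length(toks) == 1L) {
        w('          <fbc:geneProductRef fbc:geneProduct="G_',
          .xml_escape(toks), '"/>')
      } else {
        w('          <fbc:or>')
        for (g in toks) {
          w('            <fbc:geneProductRef fbc:geneProduct="G_',
            .xml_escape(g), '"/>')
        }
        w('          </fbc:or>')
      }
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  w('          <fbc:fluxObjective fbc:reaction="R_',
    .xml_escape(model$biomass_id), '" fbc:coefficient="1"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  genes <- unique(unlist(lapply(model$rxns$gene_rule, .gene_tokens)))
  if (length(genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in genes) {
      w('      <fbc:geneProduct fbc:id="G_', .xml_escape(g),
        '" fbc:label="', .xml_escape(g), '"/>')
    }
    w('    </fbc:listOfGeneProducts>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
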