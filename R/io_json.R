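# BiGG-style JSON model I/O (the cobra JSON schema: metabolites, reactions
# with metabolite->coefficient maps, bounds, gene_reaction_rule,
# objective_coefficient).

.read_bigg_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("not a BiGG-style JSON model: ", path, call. = FALSE)
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, ""),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, ""),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "c", ""),
    formula = vapply(doc$metabolites, function(m) {
      f <- m$formula
      if (is.null(f) || length(f) != 1L || is.na(f)) NA_character_ else as.character(f)
    }, ""),
    charge = vapply(doc$metabolites, function(m) {
      ch <- m$charge
      if (is.null(ch) || length(ch) != 1L) NA_real_ else as.numeric(ch)
    }, 0),
    stringsAsFactors = FALSE)

  nr <- length(doc$reactions)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) r$id, ""),
    name = vapply(doc$reactions, function(r) r$name %||% r$id, ""),
    lb = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% -1000), 0),
    ub = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 1000), 0),
    gene_rule = vapply(doc$reactions, function(r) {
      as.character(r$gene_reaction_rule %||% "")
    }, ""),
    subsystem = vapply(doc$reactions, function(r) {
      s <- r$subsystem
      if (is.null(s) || length(s) != 1L || is.na(s)) "" else as.character(s)
    }, ""),
    stringsAsFactors = FALSE)

  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(nr)) {
    st <- doc$reactions[[k]]$metabolites
    if (is.null(st) || length(st) == 0L) {
      stop("reaction without stoichiometry: ", rxns$id[k], call. = FALSE)
    }
    row <- match(names(st), mets$id)
    if (anyNA(row)) {
      stop("reaction ", rxns$id[k], " references unknown metabolite(s)",
           call. = FALSE)
    }
    v <- vapply(st, as.numeric, 0)
    keep <- v != 0
    i <- c(i, row[keep]); j <- c(j, rep.int(k, sum(keep))); x <- c(x, v[keep])
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrow(mets), nr))

  objc <- vapply(doc$reactions, function(r) {
    as.numeric(r$objective_coefficient %||% 0)
  }, 0)
  biomass_id <- if (any(objc != 0)) {
    rxns$id[which(objc != 0)[1L]]
  } else {
    hit <- grep("biomass", rxns$id, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) {
      stop("no biomass reaction identifiable in ", path, call. = FALSE)
    }
    core <- grep("core", hit, ignore.case = TRUE, value = TRUE)
    if (length(core)) core[1L] else hit[1L]
  }
  metabolic_model(mets, rxns, S, biomass_id,
                  annotations = list(id = doc$id %||% NA_character_,
                                     source = "bigg-json"))
}

.write_bigg_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(k) {
    m <- model$mets[k, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  S <- model$S
  rxns <- lapply(seq_len(nrow(model$rxns)), function(k) {
    r <- model$rxns[k, ]
    col <- S[, k]
    nz <- which(col != 0)
    st <- as.list(col[nz])
    names(st) <- rownames(S)[nz]
    out <- list(id = r$id, name = r$name, metabolites = st,
                lower_bound = r$lb, upper_bound = r$ub,
                gene_reaction_rule = r$gene_rule,
                subsystem = r$subsystem)
    if (identical(r$id, model$biomass_id)) out$objective_coefficient <- 1
    out
  })
  genes <- unique(unlist(lapply(model$rxns$gene_rule, .gene_tokens)))
  doc <- list(
    id = model$annotations$id %||% "model",
    version = "1",
    metabolites = mets,
    reactions = rxns,
    genes = lapply(genes, function(g) list(id = g, name = g)),
    compartments = as.list(stats::setNames(
      unique(model$mets$compartment), unique(model$mets$compartment))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.gene_tokens <- function(rule) {
  if (!nzchar(rule)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
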