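# Metabolic-model data structures and organism preprocessing.
#
# A model is a light S3 list: a metabolite table, a reaction table, and a
# sparse stoichiometric matrix S (metabolites x reactions).  Flux sign
# convention: exchange flux negative = uptake; all user-facing uptake rates
# are magnitudes (mmol/gDW/h; the biomass reaction carries 1/h).

#' Construct a metabolic model
#'
#' @param mets data.frame with at least column `id`; optional `name`,
#'   `compartment`, `formula`, `charge`.
#' @param rxns data.frame with columns `id`, `lb`, `ub`; optional `name`,
#'   `gene_rule` (empty string = no gene association), `subsystem`.
#' @param S stoichiometric matrix, `nrow(mets)` x `nrow(rxns)` (coercible to
#'   sparse); rows/columns follow the table order.
#' @param biomass_id id of the biomass reaction.
#' @param exchange_ids character vector of exchange reaction ids, or `NULL`
#'   to auto-detect every reaction touching exactly one metabolite.
#' @param annotations free-form named list.
#'
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(mets, rxns, S, biomass_id,
                            exchange_ids = NULL, annotations = list()) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- "c"
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_real_
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$gene_rule)) rxns$gene_rule <- ""
  rxns$gene_rule[is.na(rxns$gene_rule)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- ""
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  rownames(mets) <- NULL; rownames(rxns) <- NULL

  S <- methods::as(methods::as(methods::as(S, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns)) {
    stop("S must be nrow(mets) x nrow(rxns)", call. = FALSE)
  }
  dimnames(S) <- list(mets$id, rxns$id)

  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids", call. = FALSE)
  if (any(rxns$lb > rxns$ub)) {
    stop("reaction lower bound exceeds upper bound: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(S@x)) || any(S@x == 0)) {
    S <- Matrix::drop0(S)
    if (any(!is.finite(S@x))) stop("non-finite stoichiometry", call. = FALSE)
  }
  if (any(Matrix::colSums(abs(S)) == 0)) {
    stop("reaction with empty stoichiometry: ",
         paste(rxns$id[Matrix::colSums(abs(S)) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (!biomass_id %in% rxns$id) {
    stop("biomass reaction '", biomass_id, "' not in model", call. = FALSE)
  }
  if (is.null(exchange_ids)) {
    exchange_ids <- rxns$id[Matrix::colSums(S != 0) == 1L]
    exchange_ids <- setdiff(exchange_ids, biomass_id)
  }
  structure(list(mets = mets, rxns = rxns, S = S,
                 biomass_id = biomass_id,
                 exchange_ids = exchange_ids,
                 annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ",
      nrow(x$rxns), " reactions, ", nrow(x$mets), " metabolites, ",
      length(x$exchange_ids), " exchanges; biomass: ", x$biomass_id, "\n",
      sep = "")
  invisible(x)
}

n_reactions <- function(model) nrow(model$rxns)
n_metabolites <- function(model) nrow(model$mets)
reaction_index <- function(model, ids) {
  idx <- match(ids, model$rxns$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
reaction_ids <- function(model) model$rxns$id

has_gene <- function(model) nzchar(model$rxns$gene_rule)

#' Describe a reaction to be added to a model
#'
#' @param id reaction id (must not collide with existing ids when added).
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed).
#' @param lb,ub flux bounds.
#' @param name display name.
#' @param gene_rule gene association string ("" = none).
#' @param subsystem subsystem label.
#' @return a `reaction_spec` list.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, name = id,
                     gene_rule = "", subsystem = "") {
  stopifnot(length(stoich) >= 1, !is.null(names(stoich)),
            all(nzchar(names(stoich))), all(is.finite(stoich)),
            all(stoich != 0), lb <= ub)
  structure(list(id = id, stoich = stoich, lb = lb, ub = ub, name = name,
                 gene_rule = gene_rule, subsystem = subsystem),
            class = "reaction_spec")
}

#' Bundle reactions (and exchanges) for pathway insertion
#'
#' @param reactions list of [reaction()] specs to add.
#' @param required_exchanges list of [reaction()] specs for exchange
#'   reactions added only if an exchange for the same metabolite is absent.
#' @param metabolites optional data.frame (`id`, `name`, `compartment`,
#'   `formula`) describing novel metabolites; unknown metabolites referenced
#'   by the reactions are otherwise created with NA formula.
#' @return a `pathway_spec` list.
#' @export
pathway_spec <- function(reactions = list(), required_exchanges = list(),
                         metabolites = NULL) {
  stopifnot(all(vapply(reactions, inherits, TRUE, "reaction_spec")),
            all(vapply(required_exchanges, inherits, TRUE, "reaction_spec")))
  structure(list(reactions = reactions,
                 required_exchanges = required_exchanges,
                 metabolites = metabolites),
            class = "pathway_spec")
}

# internal: append reaction specs (creating unseen metabolites)
.add_reaction_specs <- function(model, specs, new_mets = NULL) {
  if (length(specs) == 0L) return(model)
  ids <- vapply(specs, `[[`, "", "id")
  clash <- intersect(ids, model$rxns$id)
  if (length(clash)) {
    stop("reaction id(s) already present: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  mets <- model$mets
  wanted <- unique(unlist(lapply(specs, function(s) names(s$stoich))))
  missing <- setdiff(wanted, mets$id)
  if (length(missing)) {
    extra <- data.frame(id = missing, name = missing, compartment = "c",
                        formula = NA_character_, charge = NA_real_,
                        stringsAsFactors = FALSE)
    if (!is.null(new_mets)) {
      nm <- as.data.frame(new_mets, stringsAsFactors = FALSE)
      hit <- match(extra$id, nm$id)
      for (col in intersect(names(nm), c("name", "compartment", "formula", "charge"))) {
        extra[[col]][!is.na(hit)] <- nm[[col]][hit[!is.na(hit)]]
      }
    }
    mets <- rbind(mets, extra[names(mets)])
  }
  rxns <- rbind(model$rxns,
                data.frame(id = ids,
                           name = vapply(specs, `[[`, "", "name"),
                           lb = vapply(specs, `[[`, 0, "lb"),
                           ub = vapply(specs, `[[`, 0, "ub"),
                           gene_rule = vapply(specs, `[[`, "", "gene_rule"),
                           subsystem = vapply(specs, `[[`, "", "subsystem"),
                           stringsAsFactors = FALSE))
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    i <- c(i, match(names(s$stoich), mets$id))
    j <- c(j, rep.int(k, length(s$stoich)))
    x <- c(x, unname(s$stoich))
  }
  Snew <- Matrix::sparseMatrix(i = i, j = j, x = x,
                               dims = c(nrow(mets), length(specs)))
  S <- rbind(model$S,
             Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nrow(mets) - nrow(model$S),
                                           ncol(model$S))))
  S <- cbind(S, Snew)
  metabolic_model(mets, rxns, S, model$biomass_id,
                  exchange_ids = NULL, annotations = model$annotations)
}

#' Insert a heterologous pathway into a model
#'
#' Adds the reactions of a [pathway_spec()]; exchanges listed under
#' `required_exchanges` are added only when the model has no exchange for the
#' same metabolite yet.
#'
#' @param model a `metabolic_model`.
#' @param spec a [pathway_spec()].
#' @return the augmented model (the input is not modified).
#' @export
add_pathway <- function(model, spec) {
  stopifnot(inherits(model, "metabolic_model"), inherits(spec, "pathway_spec"))
  out <- .add_reaction_specs(model, spec$reactions, spec$metabolites)
  if (length(spec$required_exchanges)) {
    have <- unique(unlist(lapply(out$exchange_ids, function(ex) {
      rownames(out$S)[out$S[, ex] != 0]
    })))
    need <- Filter(function(s) !all(names(s$stoich) %in% have),
                   spec$required_exchanges)
    out <- .add_reaction_specs(out, need, spec$metabolites)
  }
  out
}

#' RuMP-cycle methanol assimilation pathway
#'
#' The three-reaction ribulose-monophosphate (RuMP) module used to make a
#' non-methylotroph methanol-positive: methanol dehydrogenase (MEDH,
#' NAD-dependent by default), 3-hexulose-6-phosphate synthase (HPS) and
#' 6-phospho-3-hexuloisomerase (PHI), plus a methanol exchange and diffusion
#' transport if the model lacks them.  Metabolite ids follow BiGG conventions
#' (`meoh_c`, `fald_c`, `ru5p__D_c`, `h6p_c`, `f6p_c`, ...).
#'
#' @param cofactor `"nad"` (default) or `"pqq"`; with `"pqq"` the
#'   dehydrogenase is written cofactor-free (electrons leave the modelled
#'   network), since PQQ chemistry is usually absent from the host model.
#' @return a [pathway_spec()].
#' @export
rump_pathway <- function(cofactor = c("nad", "pqq")) {
  cofactor <- match.arg(cofactor)
  medh_stoich <- if (cofactor == "nad") {
    c(meoh_c = -1, nad_c = -1, fald_c = 1, nadh_c = 1, h_c = 1)
  } else {
    c(meoh_c = -1, fald_c = 1)
  }
  pathway_spec(
    reactions = list(
      reaction("MEDH", medh_stoich, lb = 0, ub = 1000,
               name = "methanol dehydrogenase", gene_rule = "medh",
               subsystem = "Methanol assimilation"),
      reaction("HPS", c(fald_c = -1, ru5p__D_c = -1, h6p_c = 1),
               lb = 0, ub = 1000,
               name = "3-hexulose-6-phosphate synthase", gene_rule = "hps",
               subsystem = "Methanol assimilation"),
      reaction("PHI", c(h6p_c = -1, f6p_c = 1), lb = -1000, ub = 1000,
               name = "6-phospho-3-hexuloisomerase", gene_rule = "phi",
               subsystem = "Methanol assimilation"),
      reaction("MEOHt", c(meoh_e = -1, meoh_c = 1), lb = -1000, ub = 1000,
               name = "methanol diffusion", gene_rule = "",
               subsystem = "Transport")),
    required_exchanges = list(
      reaction("EX_meoh_e", c(meoh_e = -1), lb = 0, ub = 1000,
               name = "methanol exchange")),
    metabolites = data.frame(
      id = c("meoh_c", "meoh_e", "fald_c", "h6p_c"),
      name = c("methanol", "methanol", "formaldehyde",
               "D-arabino-3-hexulose-6-phosphate"),
      compartment = c("c", "e", "c", "c"),
      formula = c("CH4O", "CH4O", "CH2O", "C6H11O9P"),
      stringsAsFactors = FALSE))
}

# reactions whose CO2/HCO3-consuming direction is kept open during
# preprocessing (enzymes named: PEP carboxylase, carbamate kinase, isocitrate
# dehydrogenase, carbamoyl-phosphate synthase, pyruvate carboxylase,
# acetyl-CoA carboxylase, methylmalonate-semialdehyde dehydrogenase)
.carbon_fixation_whitelist <- c(
  "PPC", "PPCr", "CBMKr", "CBMK", "ICDHyr", "ICDHx", "ICDHy", "CBPS",
  "PC", "PYC", "ACCOAC", "MMSAD", "MMSAD3", "MSAD", "MMSDH")

.deactivate <- function(model, ids) {
  hit <- ids %in% model$rxns$id
  if (any(!hit)) {
    warning("preprocessing target(s) not in model (skipped): ",
            paste(ids[!hit], collapse = ", "), call. = FALSE)
  }
  idx <- match(ids[hit], model$rxns$id)
  model$rxns$lb[idx] <- 0
  model$rxns$ub[idx] <- 0
  model
}

# block only the CO2/HCO3-consuming direction of non-whitelisted internal
# reactions, leaving decarboxylations and CO2 transport/exchange untouched
.block_carbon_fixation <- function(model, whitelist) {
  co2_rows <- grep("^(co2|hco3)(_|\\[)", model$mets$id)
  if (!length(co2_rows)) return(model)
  sub <- model$S[co2_rows, , drop = FALSE]
  touches <- which(Matrix::colSums(sub != 0) > 0)
  for (j in touches) {
    id <- model$rxns$id[j]
    if (id %in% whitelist || id %in% model$exchange_ids) next
    # skip pure transport: same base species on both sides
    met_idx <- which(model$S[, j] != 0)
    bases <- sub("(_|\\[)[a-z0-9]+\\]?$", "", model$mets$id[met_idx])
    if (anyDuplicated(bases)) next
    coef <- sum(model$S[co2_rows, j])
    if (coef < 0 && model$rxns$ub[j] > 0) model$rxns$ub[j] <- 0
    if (coef > 0 && model$rxns$lb[j] < 0) model$rxns$lb[j] <- 0
  }
  model
}

#' Organism-specific model preprocessing
#'
#' Prepares a genome-scale model for aerobic strain design.  The `ecoli`
#' profile deactivates the anaerobic formate lyases `PFL` and `OBTFL` and the
#' unrealistic `DRPA` and `PAI2T`; the `cglutamicum` profile adds a xylose
#' transport reaction (plus xylose exchange if absent).  Both profiles then
#' block the CO2/HCO3-fixing direction of internal carbon-fixation reactions
#' outside a whitelist of physiologically genuine carboxylases.  Missing
#' targets are warnings, never errors, so one profile works across model
#' versions.
#'
#' @param model a `metabolic_model`.
#' @param profile `"ecoli"`, `"cglutamicum"` or `"none"`.
#' @param fixation_whitelist reaction ids whose carbon-fixing direction stays
#'   open.
#' @return the preprocessed model.
#' @export
apply_preprocessing <- function(model,
                                profile = c("none", "ecoli", "cglutamicum"),
                                fixation_whitelist = .carbon_fixation_whitelist) {
  profile <- match.arg(profile)
  if (profile == "none") return(model)
  if (profile == "ecoli") {
    model <- .deactivate(model, c("PFL", "OBTFL", "DRPA", "PAI2T"))
  } else {
    if (!"XYLt" %in% model$rxns$id) {
      spec <- pathway_spec(
        reactions = list(
          reaction("XYLt", c(xyl__D_e = -1, xyl__D_c = 1),
                   lb = -1000, ub = 1000, name = "xylose transport",
                   gene_rule = "", subsystem = "Transport")),
        required_exchanges = list(
          reaction("EX_xyl__D_e", c(xyl__D_e = -1), lb = 0, ub = 1000,
                   name = "xylose exchange")),
        metabolites = data.frame(
          id = c("xyl__D_e", "xyl__D_c"),
          name = c("D-xylose", "D-xylose"),
          compartment = c("e", "c"),
          formula = c("C5H10O5", "C5H10O5"),
          stringsAsFactors = FALSE))
      model <- add_pathway(model, spec)
    }
  }
  .block_carbon_fixation(model, fixation_whitelist)
}

# --- formulas and media ------------------------------------------------------

.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085,
  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Mo = 95.95,
  Cd = 112.41, I = 126.9, W = 183.84, Hg = 200.59)

# parse "C6H12O6" -> named counts; NA for missing/unparseable (R-groups etc.)
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  toks <- regmatches(formula,
                     gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) return(NULL)
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct[ct == ""] <- "1"
  stats::setNames(as.numeric(ct), el)
}

molar_mass <- function(formula) {
  cnt <- parse_formula(formula)
  if (is.null(cnt)) return(NA_real_)
  w <- .atomic_weights[names(cnt)]
  if (anyNA(w)) return(NA_real_)
  sum(w * cnt)
}

contains_carbon <- function(formula) {
  cnt <- parse_formula(formula)
  if (is.null(cnt)) return(NA)
  "C" %in% names(cnt)
}

# exchanges whose metabolite carries carbon (unknown formula counts as
# carbon: closing an unidentified substrate is the safe default)
carbon_exchanges <- function(model) {
  Filter(function(ex) {
    met <- rownames(model$S)[model$S[, ex] != 0]
    cc <- contains_carbon(model$mets$formula[match(met, model$mets$id)])
    is.na(cc) || cc
  }, model$exchange_ids)
}

#' Set the growth medium
#'
#' Opens the listed exchange reactions for uptake (lower bound = minus the
#' given maximal uptake rate), closes every other carbon-source exchange, and
#' leaves non-carbon medium components (O2, ions, ...) untouched.  Exchanges
#' listed in `base_medium` are also left untouched regardless of carbon
#' content.  Idempotent for a fixed mapping.
#'
#' @param model a `metabolic_model`.
#' @param uptakes named numeric vector, exchange id -> maximal uptake rate
#'   (magnitude, mmol/gDW/h); an empty vector closes all carbon sources.
#' @param base_medium character vector of exchange ids held at their current
#'   bounds.
#' @return the model with adjusted exchange bounds.
#' @export
set_medium <- function(model, uptakes = numeric(0), base_medium = character(0)) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(uptakes)) {
    if (is.null(names(uptakes)) || !all(nzchar(names(uptakes)))) {
      stop("'uptakes' must be a named vector of exchange ids", call. = FALSE)
    }
    bad <- setdiff(names(uptakes), model$exchange_ids)
    if (length(bad)) {
      stop("not an exchange reaction: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(uptakes < 0)) stop("uptake rates are magnitudes (>= 0)", call. = FALSE)
  }
  close_ids <- setdiff(setdiff(carbon_exchanges(model), names(uptakes)),
                       base_medium)
  idx <- match(close_ids, model$rxns$id)
  model$rxns$lb[idx] <- pmax(model$rxns$lb[idx], 0)
  if (length(uptakes)) {
    idx <- match(names(uptakes), model$rxns$id)
    model$rxns$lb[idx] <- -unname(uptakes)
    model$rxns$ub[idx] <- pmax(model$rxns$ub[idx], 0)
  }
  model
}
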