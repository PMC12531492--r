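# Evaluation layer: ALE starting-strain requirements, SADF, UC/Co,
# minimal-uptake growth curves, and biomass-precursor producibility.

#' Design configuration
#'
#' Bundles the substrate identities and thresholds shared by the metric and
#' MILP layers.
#'
#' @param uc_exchange exchange id of the unadapted carbon source (UC).
#' @param cosub_exchange exchange id of the cosubstrate.
#' @param variant `"A"` (growth requires both substrates) or `"B"` (growth on
#'   the UC alone is preserved).
#' @param K maximal number of knockouts (>= 0).
#' @param uptake_bound substrate uptake bound (mmol/gDW/h; default 10).
#' @param req1_fraction requirement-1 growth fraction of the reference
#'   UC-only growth; default 0.1 for variant A (upper bound: at most 10 % of
#'   reference growth on the UC alone) and 0.5 for variant B (lower bound:
#'   at least 50 % retained).
#' @param req2_fraction requirement-2 upper fraction of reference
#'   cosubstrate growth allowed on cosubstrate alone (default 0.1).
#' @param ucco_growth growth floor (1/h) for the UC/Co ratio (default 0.1).
#' @param uc_recovery_bound UC uptake bound for the minimal-uptake problem
#'   (default 1000).
#' @param base_medium exchange ids held open regardless of carbon content.
#' @param tol absolute comparison tolerance for requirement flags.
#' @param producibility_min demand flux above which a precursor counts as
#'   producible (default 1e-4).
#' @return a `design_config` list.
#' @export
design_config <- function(uc_exchange, cosub_exchange, variant = c("A", "B"),
                          K = 5, uptake_bound = 10,
                          req1_fraction = NULL, req2_fraction = 0.1,
                          ucco_growth = 0.1, uc_recovery_bound = 1000,
                          base_medium = character(0), tol = 1e-6,
                          producibility_min = 1e-4) {
  variant <- match.arg(variant)
  if (is.null(req1_fraction)) {
    req1_fraction <- if (variant == "A") 0.1 else 0.5
  }
  stopifnot(K >= 0, uptake_bound > 0, uc_recovery_bound > 0,
            req1_fraction > 0, req1_fraction <= 1,
            req2_fraction > 0, req2_fraction <= 1,
            ucco_growth > 0)
  structure(list(uc_exchange = uc_exchange, cosub_exchange = cosub_exchange,
                 variant = variant, K = as.integer(K),
                 uptake_bound = uptake_bound,
                 req1_fraction = req1_fraction, req2_fraction = req2_fraction,
                 ucco_growth = ucco_growth,
                 uc_recovery_bound = uc_recovery_bound,
                 base_medium = base_medium, tol = tol,
                 producibility_min = producibility_min),
            class = "design_config")
}

# the four media of the design problem
design_medium <- function(model, config,
                          which = c("uc", "cosub", "both", "recover")) {
  which <- match.arg(which)
  up <- switch(which,
    uc = stats::setNames(config$uptake_bound, config$uc_exchange),
    cosub = stats::setNames(config$uptake_bound, config$cosub_exchange),
    both = stats::setNames(rep(config$uptake_bound, 2),
                           c(config$uc_exchange, config$cosub_exchange)),
    recover = stats::setNames(c(config$uc_recovery_bound, config$uptake_bound),
                              c(config$uc_exchange, config$cosub_exchange)))
  set_medium(model, up, base_medium = config$base_medium)
}

#' Reference (pre-deletion) growth rates
#'
#' @param model augmented, preprocessed `metabolic_model`.
#' @param config a [design_config()].
#' @return list with `v0bio_uc` and `v0bio_cosub` (1/h).
#' @export
reference_state <- function(model, config) {
  v0u <- solve_fba(design_medium(model, config, "uc"))
  v0c <- solve_fba(design_medium(model, config, "cosub"))
  if (v0u$status != "optimal" || v0c$status != "optimal") {
    stop("reference FBA failed (", v0u$status, "/", v0c$status, ")",
         call. = FALSE)
  }
  list(v0bio_uc = max(0, v0u$objective_value),
       v0bio_cosub = max(0, v0c$objective_value))
}

#' Check the three ALE starting-strain requirements
#'
#' Requirement 1 (growth on the UC alone): variant A demands at most
#' `req1_fraction` (default 10 %) of the reference UC-only growth; variant B
#' demands at least `req1_fraction` (default 50 %) retained.  Requirement 2
#' (dependence): growth on the cosubstrate alone at most `req2_fraction`
#' (default 10 %) of the reference cosubstrate growth.  Requirement 3
#' (recovery): growth with both substrates at least the reference
#' cosubstrate growth.
#'
#' @param model augmented, preprocessed `metabolic_model`.
#' @param knockouts character vector of reaction ids.
#' @param config a [design_config()].
#' @param reference optional precomputed [reference_state()].
#' @return a `requirement_report`: growth rates `v1bio`, `v2bio`, `v3bio`,
#'   pass flags, and the reference state.
#' @export
check_requirements <- function(model, knockouts, config, reference = NULL) {
  if (is.null(reference)) reference <- reference_state(model, config)
  if (reference$v0bio_cosub <= config$tol) {
    stop("reference strain does not grow on the cosubstrate; ",
         "check medium and cosub_exchange", call. = FALSE)
  }
  g <- function(which) {
    fs <- solve_fba(design_medium(model, config, which), knockouts = knockouts)
    if (fs$status != "optimal") {
      stop("inner FBA (", which, " medium) not optimal: ", fs$status,
           call. = FALSE)
    }
    max(0, fs$objective_value)
  }
  v1 <- g("uc"); v2 <- g("cosub"); v3 <- g("both")
  tol <- config$tol
  req1 <- if (config$variant == "A") {
    v1 <= config$req1_fraction * reference$v0bio_uc + tol
  } else {
    v1 >= config$req1_fraction * reference$v0bio_uc - tol
  }
  req2 <- v2 <= config$req2_fraction * reference$v0bio_cosub + tol
  req3 <- v3 >= reference$v0bio_cosub - tol
  structure(list(v1bio = v1, v2bio = v2, v3bio = v3,
                 req1_pass = req1, req2_pass = req2, req3_pass = req3,
                 variant = config$variant, reference = reference,
                 knockouts = sort(knockouts)),
            class = "requirement_report")
}

#' @export
print.requirement_report <- function(x, ...) {
  flag <- function(p) if (p) "pass" else "FAIL"
  cat("<requirement_report> variant ", x$variant, ", knockouts {",
      paste(x$knockouts, collapse = ", "), "}\n",
      "  v1bio (UC only)    = ", format(x$v1bio), "  [", flag(x$req1_pass), "]\n",
      "  v2bio (cosub only) = ", format(x$v2bio), "  [", flag(x$req2_pass), "]\n",
      "  v3bio (both)       = ", format(x$v3bio), "  [", flag(x$req3_pass), "]\n",
      sep = "")
  invisible(x)
}

#' Minimal UC uptake needed to reach a growth target
#'
#' With the cosubstrate open at `uptake_bound` and the UC at
#' `uc_recovery_bound`, minimises the UC uptake subject to growth at least
#' `growth_target`.  Returns 0 when the target is achievable without the UC
#' and `NA` (with `attr(,"status") == "infeasible"`) when the target is
#' unreachable even with the UC.
#'
#' @param model a `metabolic_model`.
#' @param knockouts reaction ids knocked out.
#' @param growth_target growth rate (1/h).
#' @param config a [design_config()].
#' @return uptake magnitude (mmol/gDW/h), or `NA` when infeasible.
#' @export
minimal_uc_uptake <- function(model, knockouts, growth_target, config) {
  m <- design_medium(model, config, "recover")
  uc <- config$uc_exchange
  # forbid UC secretion so that maximising the exchange flux minimises uptake
  ov <- list(c(-config$uc_recovery_bound, 0))
  names(ov) <- uc
  fs <- solve_fba(m, objective_id = uc, sense = "max", knockouts = knockouts,
                  bound_overrides = ov,
                  extra_constraints = list(list(
                    coefs = stats::setNames(1, model$biomass_id),
                    lb = growth_target, ub = Inf)))
  if (fs$status != "optimal") {
    out <- NA_real_
    attr(out, "status") <- "infeasible"
    return(out)
  }
  max(0, -fs$objective_value)
}

#' Substrate assimilation driving force (SADF)
#'
#' The growth gained per unit UC uptake,
#' `(v0bio_cosub - v2bio) / vUC` (gDW/mmol), where `v2bio` is the knockout
#' strain's maximal growth on the cosubstrate alone (direct FBA) and `vUC`
#' the minimal UC uptake restoring growth to the reference cosubstrate level
#' ([minimal_uc_uptake()]).  `NA` with an explanatory attribute when the
#' growth target is unreachable or no UC is required (no coupling).
#'
#' @inheritParams check_requirements
#' @return SADF (gDW/mmol) or `NA`.
#' @export
sadf <- function(model, knockouts, config, reference = NULL) {
  if (is.null(reference)) reference <- reference_state(model, config)
  v2 <- solve_fba(design_medium(model, config, "cosub"), knockouts = knockouts)
  if (v2$status != "optimal") {
    stop("cosubstrate-only FBA not optimal: ", v2$status, call. = FALSE)
  }
  v2bio <- max(0, v2$objective_value)
  vuc <- minimal_uc_uptake(model, knockouts, reference$v0bio_cosub, config)
  if (is.na(vuc)) {
    out <- NA_real_; attr(out, "status") <- "target_unreachable"
    return(out)
  }
  if (vuc <= config$tol) {
    out <- NA_real_; attr(out, "status") <- "no_coupling"
    return(out)
  }
  (reference$v0bio_cosub - v2bio) / vuc
}

#' Parsimonious UC-to-cosubstrate uptake ratio (UC/Co)
#'
#' Step 1 minimises the UC uptake subject to growth at least `ucco_growth`
#' (default 0.1 1/h); step 2 fixes the UC uptake at that minimum and
#' minimises the cosubstrate uptake.  The ratio of the two minima is UC/Co.
#' A zero step-2 denominator (cosubstrate not needed) yields `Inf`, flagged
#' via `attr(,"status") == "infinite_coupling"`.
#'
#' @inheritParams check_requirements
#' @return dimensionless ratio (>= 0), possibly `Inf` or `NA` (infeasible).
#' @export
ucco_ratio <- function(model, knockouts, config) {
  uc_min <- minimal_uc_uptake(model, knockouts, config$ucco_growth, config)
  if (is.na(uc_min)) {
    out <- NA_real_; attr(out, "status") <- "infeasible"
    return(out)
  }
  m <- design_medium(model, config, "recover")
  ov <- list(c(-uc_min, -uc_min), c(-config$uptake_bound, 0))
  names(ov) <- c(config$uc_exchange, config$cosub_exchange)
  fs <- solve_fba(m, objective_id = config$cosub_exchange, sense = "max",
                  knockouts = knockouts, bound_overrides = ov,
                  extra_constraints = list(list(
                    coefs = stats::setNames(1, model$biomass_id),
                    lb = config$ucco_growth, ub = Inf)))
  if (fs$status != "optimal") {
    out <- NA_real_; attr(out, "status") <- "infeasible"
    return(out)
  }
  cosub_min <- max(0, -fs$objective_value)
  if (cosub_min <= config$tol) {
    out <- Inf; attr(out, "status") <- "infinite_coupling"
    return(out)
  }
  uc_min / cosub_min
}

#' Minimal-UC-uptake growth curves
#'
#' For each cosubstrate uptake level and each growth target, the minimal UC
#' uptake sustaining that growth (NA where infeasible).  Each
#' fixed-cosubstrate curve is non-decreasing and piecewise linear in growth.
#'
#' @param model a `metabolic_model`.
#' @param knockouts reaction ids knocked out.
#' @param cosub_uptakes numeric vector of cosubstrate uptake bounds.
#' @param growth_grid numeric vector of growth targets (1/h).
#' @param config a [design_config()].
#' @return data.frame with columns `cosub_uptake`, `growth`, `uc_min`.
#' @export
growth_uc_curve <- function(model, knockouts, cosub_uptakes, growth_grid,
                            config) {
  stopifnot(length(cosub_uptakes) >= 0, length(growth_grid) >= 0,
            all(cosub_uptakes >= 0), all(growth_grid >= 0))
  rows <- list()
  m <- design_medium(model, config, "recover")
  cosub_ub <- m$rxns$ub[reaction_index(m, config$cosub_exchange)]
  for (cu in cosub_uptakes) {
    for (g in growth_grid) {
      if (g == 0) {
        uc <- 0
      } else {
        ovr <- list(c(-config$uc_recovery_bound, 0), c(-cu, cosub_ub))
        names(ovr) <- c(config$uc_exchange, config$cosub_exchange)
        fs <- solve_fba(m, objective_id = config$uc_exchange, sense = "max",
                        knockouts = knockouts, bound_overrides = ovr,
                        extra_constraints = list(list(
                          coefs = stats::setNames(1, model$biomass_id),
                          lb = g, ub = Inf)))
        uc <- if (fs$status == "optimal") max(0, -fs$objective_value) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(cosub_uptake = cu, growth = g,
                                              uc_min = uc)
    }
  }
  if (!length(rows)) {
    return(data.frame(cosub_uptake = numeric(0), growth = numeric(0),
                      uc_min = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Biomass-precursor producibility from the cosubstrate alone
#'
#' For every metabolite consumed by the biomass reaction, opens only the
#' cosubstrate, adds a unit demand for that metabolite, and tests whether a
#' positive demand flux (at least `producibility_min`) is feasible under the
#' knockouts.  Mass fractions are coefficient x molar mass over the summed
#' substrate side; when formulas are missing the report falls back to a
#' coefficient-weight basis with a warning.  The coupling fraction is the
#' summed mass fraction of non-producible precursors; the coupling class is
#' `"full"` when no precursor is producible, `"minimal"` when the coupling
#' fraction is at most 0.10, and `"intermediate"` otherwise.
#'
#' @inheritParams check_requirements
#' @param groups optional named list mapping group label -> metabolite ids,
#'   a presentation-layer aggregation added to the report.
#' @return a `producibility_report`: per-precursor data.frame `precursors`,
#'   `coupling_fraction`, `coupling_class`, `mass_basis`.
#' @export
precursor_producibility <- function(model, knockouts, config, groups = NULL) {
  bidx <- reaction_index(model, model$biomass_id)
  coefs <- model$S[, bidx]
  prec <- which(coefs < 0)
  if (!length(prec)) stop("biomass reaction has no substrate-side precursor",
                          call. = FALSE)
  met_ids <- rownames(model$S)[prec]
  weights <- -coefs[prec]
  mm <- vapply(model$mets$formula[match(met_ids, model$mets$id)],
               molar_mass, 0, USE.NAMES = FALSE)
  basis <- "mass"
  if (anyNA(mm)) {
    warning("missing/unparseable formula for ",
            sum(is.na(mm)), " biomass precursor(s); ",
            "mass fractions reported on a coefficient-weight basis",
            call. = FALSE)
    basis <- "coefficient"
    mm <- rep(1, length(mm))
  }
  mass <- weights * mm
  frac <- mass / sum(mass)

  base <- design_medium(model, config, "cosub")
  producible <- logical(length(prec))
  for (k in seq_along(prec)) {
    dm_id <- paste0(".DM_", met_ids[k])
    m2 <- .add_reaction_specs(base, list(
      reaction(dm_id, stats::setNames(-1, met_ids[k]), lb = 0, ub = 1000,
               name = paste("demand", met_ids[k]))))
    fs <- solve_fba(m2, objective_id = dm_id, sense = "max",
                    knockouts = knockouts)
    producible[k] <- fs$status == "optimal" &&
      fs$objective_value >= config$producibility_min
  }
  coupling_fraction <- sum(frac[!producible])
  coupling_class <- if (!any(producible)) {
    "full"
  } else if (coupling_fraction <= 0.10) "minimal" else "intermediate"

  df <- data.frame(metabolite = met_ids, coefficient = weights,
                   mass_fraction = frac, producible = producible,
                   stringsAsFactors = FALSE)
  group_df <- NULL
  if (!is.null(groups)) {
    group_df <- do.call(rbind, lapply(names(groups), function(g) {
      sel <- df$metabolite %in% groups[[g]]
      data.frame(group = g,
                 mass_fraction = sum(df$mass_fraction[sel]),
                 producible = all(df$producible[sel]) && any(sel),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(precursors = df, groups = group_df,
                 coupling_fraction = coupling_fraction,
                 coupling_class = coupling_class, mass_basis = basis,
                 knockouts = sort(knockouts)),
            class = "producibility_report")
}

#' @export
print.producibility_report <- function(x, ...) {
  cat("<producibility_report> ", nrow(x$precursors), " precursors, ",
      sum(!x$precursors$producible), " not producible from cosubstrate; ",
      "coupling fraction ", format(round(x$coupling_fraction, 4)),
      " (", x$coupling_class, " coupling, ", x$mass_basis, " basis)\n",
      sep = "")
  invisible(x)
}

#' Score a knockout strategy
#'
#' Convenience wrapper assembling the requirement report, SADF, UC/Co,
#' minimal UC uptake at the reference growth target and the producibility
#' report into one record.
#'
#' @inheritParams check_requirements
#' @param producibility logical; include the producibility analysis.
#' @return a `strategy_score`.
#' @export
strategy_score <- function(model, knockouts, config, reference = NULL,
                           producibility = TRUE) {
  if (is.null(reference)) reference <- reference_state(model, config)
  req <- check_requirements(model, knockouts, config, reference)
  s <- sadf(model, knockouts, config, reference)
  u <- ucco_ratio(model, knockouts, config)
  vuc <- minimal_uc_uptake(model, knockouts, reference$v0bio_cosub, config)
  prod <- if (producibility) {
    precursor_producibility(model, knockouts, config)
  } else NULL
  structure(list(knockouts = sort(knockouts),
                 sadf = as.numeric(s), sadf_status = attr(s, "status"),
                 ucco = as.numeric(u), ucco_status = attr(u, "status"),
                 v_uc_min = as.numeric(vuc),
                 requirements = req,
                 coupling_fraction = if (!is.null(prod)) prod$coupling_fraction else NA_real_,
                 coupling_class = if (!is.null(prod)) prod$coupling_class else NA_character_,
                 producibility = prod),
            class = "strategy_score")
}

#' @export
print.strategy_score <- function(x, ...) {
  cat("<strategy_score> {", paste(x$knockouts, collapse = ", "), "}: ",
      "SADF = ", format(x$sadf), ", UC/Co = ", format(x$ucco),
      if (!is.na(x$coupling_class)) paste0(", coupling: ", x$coupling_class),
      "\n", sep = "")
  invisible(x)
}
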