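# Candidate-knockout prefiltering: shrink the binary search space before
# MILP construction without discarding genuine design targets.

#' Prefilter candidate knockout reactions
#'
#' Applies, in the given order: `scaffold` (drop all exchange reactions and
#' the biomass reaction), `substrate` (drop every reaction touching the
#' extracellular species of the two substrate exchanges, i.e. their
#' exchange/transport machinery), `orphan` (drop gene-unassociated
#' reactions), `blocked` (drop reactions whose flux range is (0, 0) with
#' both substrates open — structurally unable to carry flux), `exclusion`
#' (drop reactions whose subsystem is on the user-supplied peripheral-
#' pathway list), and optionally `essential` (drop reactions whose single
#' deletion already makes requirement 3 structurally impossible).  Every
#' removal is recorded.
#'
#' @param model augmented, preprocessed `metabolic_model`.
#' @param config a [design_config()].
#' @param filters ordered subset of
#'   `c("scaffold", "substrate", "orphan", "blocked", "exclusion",
#'   "essential")`.
#' @param exclusion_subsystems character vector of subsystem labels treated
#'   as peripheral (empty by default).
#' @return a `filter_trace`: `initial_count`, named list `removed`,
#'   `final_candidates`.
#' @export
candidate_knockouts <- function(model, config,
                                filters = c("scaffold", "substrate",
                                            "orphan", "blocked", "exclusion"),
                                exclusion_subsystems = character(0)) {
  allowed <- c("scaffold", "substrate", "orphan", "blocked", "exclusion",
               "essential")
  stopifnot(all(filters %in% allowed))
  pool <- model$rxns$id
  initial <- length(pool)
  removed <- list()

  drop <- function(ids, name) {
    ids <- intersect(pool, ids)
    removed[[name]] <<- sort(ids)
    pool <<- setdiff(pool, ids)
  }
  for (f in filters) {
    switch(f,
      scaffold = drop(c(model$exchange_ids, model$biomass_id), "scaffold"),
      substrate = {
        subs_mets <- unique(unlist(lapply(
          c(config$uc_exchange, config$cosub_exchange), function(ex) {
            rownames(model$S)[model$S[, ex] != 0]
          })))
        touches <- model$rxns$id[Matrix::colSums(
          model$S[subs_mets, , drop = FALSE] != 0) > 0]
        drop(touches, "substrate")
      },
      orphan = drop(model$rxns$id[!has_gene(model)], "orphan"),
      blocked = {
        if (length(pool)) {
          fva <- flux_variability(design_medium(model, config, "both"), pool)
          drop(fva$id[abs(fva$min) < 1e-6 & abs(fva$max) < 1e-6], "blocked")
        } else drop(character(0), "blocked")
      },
      exclusion = drop(
        model$rxns$id[model$rxns$subsystem %in% exclusion_subsystems],
        "exclusion"),
      essential = {
        ref <- reference_state(model, config)
        both <- design_medium(model, config, "both")
        lethal <- Filter(function(id) {
          fs <- solve_fba(both, knockouts = id)
          fs$status != "optimal" ||
            fs$objective_value < ref$v0bio_cosub - config$tol
        }, pool)
        drop(unlist(lethal), "essential")
      })
  }
  structure(list(initial_count = initial, removed = removed,
                 final_candidates = sort(pool), filters = filters),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace> ", x$initial_count, " reactions -> ",
      length(x$final_candidates), " candidates\n", sep = "")
  for (f in names(x$removed)) {
    cat("  -", f, ": removed", length(x$removed[[f]]), "\n")
  }
  invisible(x)
}

#' @export
format.filter_trace <- function(x, ...) {
  jsonlite::toJSON(list(initial_count = x$initial_count,
                        removed = x$removed,
                        final_candidates = x$final_candidates),
                   auto_unbox = TRUE, pretty = TRUE)
}
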