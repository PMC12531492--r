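# Flux balance analysis primitives.
#
# Objective values are the contract of every operation; flux vectors of
# degenerate optima are solver-dependent, so any operation that reports a
# flux distribution offers the parsimonious (total-flux-minimising)
# secondary objective and flags it in the result.

#' Flux balance analysis
#'
#' Solves `max/min v[objective_id]` subject to `S v = 0` and the model's flux
#' bounds, optionally with knockouts (bounds forced to zero), bound
#' overrides, and extra linear constraints.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction id to optimise (default: biomass).
#' @param sense `"max"` or `"min"`.
#' @param knockouts character vector of reaction ids forced to zero flux.
#' @param bound_overrides named list, reaction id -> `c(lb, ub)`.
#' @param extra_constraints list of `list(coefs = named numeric, lb=, ub=)`
#'   rows added to the LP.
#' @param pfba logical; if `TRUE`, a second LP fixes the optimal objective
#'   and minimises total absolute flux, making the reported flux vector
#'   reproducible under degeneracy.
#'
#' @return a `flux_state`: list with `fluxes` (named), `objective_value`,
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"`, ...), `residual`
#'   (max |S v|) and `parsimonious` flag.
#' @export
solve_fba <- function(model, objective_id = model$biomass_id,
                      sense = c("max", "min"), knockouts = NULL,
                      bound_overrides = NULL, extra_constraints = NULL,
                      pfba = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  sense <- match.arg(sense)
  n <- n_reactions(model)
  oidx <- reaction_index(model, objective_id)
  bounds <- .effective_bounds(model, knockouts, bound_overrides)
  obj <- numeric(n); obj[oidx] <- 1

  A <- model$S
  row_lb <- rep(0, nrow(A)); row_ub <- rep(0, nrow(A))
  if (length(extra_constraints)) {
    for (ec in extra_constraints) {
      r <- Matrix::sparseMatrix(
        i = rep.int(1L, length(ec$coefs)),
        j = reaction_index(model, names(ec$coefs)),
        x = unname(ec$coefs), dims = c(1L, n))
      A <- rbind(A, r)
      row_lb <- c(row_lb, ec$lb %||% -Inf)
      row_ub <- c(row_ub, ec$ub %||% Inf)
    }
  }
  res <- hs_solve(obj, A, row_lb, row_ub, bounds$lb, bounds$ub,
                  maximize = (sense == "max"))
  fluxes <- NULL; residual <- NA_real_
  if (!is.null(res$x)) {
    fluxes <- stats::setNames(res$x, model$rxns$id)
    residual <- max(abs(model$S %*% res$x))
  }
  parsimonious <- FALSE
  if (pfba && res$status == "optimal") {
    ps <- .pfba_refit(model, A, row_lb, row_ub, bounds, obj, sense,
                      res$objective)
    if (!is.null(ps)) {
      fluxes <- stats::setNames(ps, model$rxns$id)
      residual <- max(abs(model$S %*% ps))
      parsimonious <- TRUE
    }
  }
  structure(list(fluxes = fluxes, objective_value = res$objective,
                 status = res$status, residual = residual,
                 parsimonious = parsimonious, solver_message = res$message),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status,
      ", objective: ", format(x$objective_value),
      if (isTRUE(x$parsimonious)) " (parsimonious)", "\n", sep = "")
  invisible(x)
}

.effective_bounds <- function(model, knockouts = NULL, bound_overrides = NULL) {
  lb <- model$rxns$lb; ub <- model$rxns$ub
  if (length(bound_overrides)) {
    idx <- reaction_index(model, names(bound_overrides))
    for (k in seq_along(idx)) {
      lb[idx[k]] <- bound_overrides[[k]][1]
      ub[idx[k]] <- bound_overrides[[k]][2]
    }
  }
  if (length(knockouts)) {
    idx <- reaction_index(model, knockouts)
    lb[idx] <- 0; ub[idx] <- 0
  }
  list(lb = lb, ub = ub)
}

# minimise sum |v| with the first objective fixed at its optimum
.pfba_refit <- function(model, A, row_lb, row_ub, bounds, obj, sense, opt) {
  n <- length(obj)
  # variables: v (n), s (n) with s >= v, s >= -v
  A2 <- rbind(
    cbind(A, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(nrow(A), n))),
    cbind(Matrix::Diagonal(n, -1), Matrix::Diagonal(n, 1)),
    cbind(Matrix::Diagonal(n, 1), Matrix::Diagonal(n, 1)))
  tol <- 1e-9 * max(1, abs(opt))
  fix_lb <- row_lb; fix_ub <- row_ub
  row_lb2 <- c(fix_lb, rep(0, 2 * n))
  row_ub2 <- c(fix_ub, rep(Inf, 2 * n))
  lb2 <- c(bounds$lb, rep(0, n)); ub2 <- c(bounds$ub, rep(Inf, n))
  obj2 <- c(numeric(n), rep(1, n))
  # pin the primary objective via variable-bound tightening on the objective
  # reaction when it is a single flux, else via an extra row
  oidx <- which(obj != 0)
  A2 <- rbind(A2, cbind(
    Matrix::sparseMatrix(i = rep.int(1L, length(oidx)), j = oidx,
                         x = obj[oidx], dims = c(1L, n)),
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(1L, n))))
  row_lb2 <- c(row_lb2, opt - tol); row_ub2 <- c(row_ub2, opt + tol)
  res <- hs_solve(obj2, A2, row_lb2, row_ub2, lb2, ub2, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Maximal growth of the reference strain on a single substrate
#'
#' Opens only the given substrate exchange at the given uptake (all other
#' carbon exchanges closed) and maximises biomass.  Used for both the
#' reference growth on the unadapted carbon source and on the cosubstrate.
#'
#' @param model a `metabolic_model`.
#' @param substrate_exchange exchange reaction id.
#' @param uptake maximal uptake rate (magnitude).
#' @param base_medium passed to [set_medium()].
#' @return maximal growth rate (1/h).
#' @export
reference_growth <- function(model, substrate_exchange, uptake,
                             base_medium = character(0)) {
  m <- set_medium(model, stats::setNames(uptake, substrate_exchange),
                  base_medium = base_medium)
  fs <- solve_fba(m)
  if (fs$status != "optimal") {
    stop("reference FBA not optimal (", fs$status, ")", call. = FALSE)
  }
  fs$objective_value
}

#' Apply reaction knockouts
#'
#' Returns a copy of the model with the listed reactions' bounds forced to
#' zero; the input model is unmodified.
#'
#' @param model a `metabolic_model`.
#' @param knockouts character vector of reaction ids.
#' @return the knockout model.
#' @export
apply_knockouts <- function(model, knockouts) {
  if (!length(knockouts)) return(model)
  idx <- reaction_index(model, knockouts)
  model$rxns$lb[idx] <- 0
  model$rxns$ub[idx] <- 0
  model
}

#' Flux variability analysis
#'
#' Minimal and maximal flux of each listed reaction under the model's
#' current bounds with no growth requirement (the structural blocking test:
#' a reaction with range (0, 0) can never carry flux).
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to scan (default: all).
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$rxns$id
  idx <- reaction_index(model, reaction_ids)
  n <- n_reactions(model)
  bounds <- .effective_bounds(model)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    rmin <- hs_solve(obj, model$S, rep(0, nrow(model$S)), rep(0, nrow(model$S)),
                     bounds$lb, bounds$ub, maximize = FALSE)
    rmax <- hs_solve(obj, model$S, rep(0, nrow(model$S)), rep(0, nrow(model$S)),
                     bounds$lb, bounds$ub, maximize = TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal") {
      stop("FVA solve failed for ", reaction_ids[k], " (", rmin$status, "/",
           rmax$status, ")", call. = FALSE)
    }
    lo[k] <- rmin$objective; hi[k] <- rmax$objective
  }
  data.frame(id = reaction_ids, min = lo, max = hi, stringsAsFactors = FALSE)
}

#' Export a flux state as TSV
#'
#' @param flux_state a `flux_state` from [solve_fba()].
#' @param model the model it was solved on (for bounds).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(flux_state, model, path) {
  stopifnot(inherits(flux_state, "flux_state"), !is.null(flux_state$fluxes))
  df <- data.frame(id = model$rxns$id,
                   flux = unname(flux_state$fluxes[model$rxns$id]),
                   lb = model$rxns$lb, ub = model$rxns$ub,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
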