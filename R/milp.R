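# Single-level MILP reformulation of the bilevel knockout-design problem.
#
# The bilevel program has three inner FBA problems (growth on the UC alone,
# on the cosubstrate alone, on both) plus the minimal-UC-uptake problem, all
# sharing the knockout binaries y_j (y_j = 1: reaction j deleted).  It is
# collapsed to one MILP with the minimal sufficient certificate per inner
# problem:
#   * "inner max >= b" (variant B requirement 1; requirement 3): a primal
#     witness suffices;
#   * "inner max <= b" (variant A requirement 1; requirement 2): a
#     dual-feasibility witness with dual objective <= b (weak duality);
#   * requirement 2's value enters the objective, so it additionally gets a
#     strong-duality certificate (primal objective >= dual objective), which
#     pins v2bio at the true inner maximum;
#   * the minimal UC uptake vUC is handled by the Charnes-Cooper scaling
#     t = 1/vUC with normalisation -g.(t v4) = 1: maximising the objective
#     pushes t up against primal feasibility of the scaled witness, which is
#     exactly the primal minimality of vUC, so no dual block is needed.
# Products of binaries with continuous variables (y*t and y*dual) are
# linearised with big-M envelopes.  The objective max (v0c - v2bio)/vUC
# becomes the linear max v0c*t - c.(t v2).

#' Build the single-level design MILP
#'
#' @param model augmented, preprocessed `metabolic_model` with all bounds
#'   finite.
#' @param config a [design_config()].
#' @param candidates candidate knockout reaction ids; must exclude the
#'   biomass reaction and both substrate exchanges.
#' @param mode `"sadf"` (direct ratio maximisation via Charnes-Cooper,
#'   default) or `"feasibility"` (requirement-satisfaction only, minimising
#'   the knockout count; pair with [enumerate_designs()] and exact LP
#'   scoring).
#' @param M_dual big-M bound on the inner-problem dual variables.
#' @param eps_uc smallest representable minimal UC uptake; the scaling
#'   variable t lives in (1/uc_recovery_bound, 1/eps_uc].
#' @param fva_tighten logical; tighten all flux bounds to their
#'   flux-variability ranges under the widest medium before building (valid
#'   for every knockout pattern, and keeps every big-M constant small).
#' @return a `milp_formulation`.
#' @export
build_milp <- function(model, config, candidates,
                       mode = c("sadf", "feasibility"),
                       M_dual = 1000, eps_uc = 1e-3, fva_tighten = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "metabolic_model"), inherits(config, "design_config"))
  candidates <- sort(unique(candidates))
  bad <- setdiff(candidates, model$rxns$id)
  if (length(bad)) stop("unknown candidate(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  forbidden <- intersect(candidates, c(model$biomass_id, config$uc_exchange,
                                       config$cosub_exchange))
  if (length(forbidden)) {
    stop("candidates must exclude biomass and substrate exchanges: ",
         paste(forbidden, collapse = ", "), call. = FALSE)
  }
  if (!length(candidates) && config$K > 0) {
    stop("empty candidate list with K > 0", call. = FALSE)
  }
  reference <- reference_state(model, config)
  n <- n_reactions(model); m <- n_metabolites(model)
  nc <- length(candidates)
  cand_idx <- reaction_index(model, candidates)
  bio <- reaction_index(model, model$biomass_id)
  uc <- reaction_index(model, config$uc_exchange)

  bnd <- lapply(c(uc = "uc", cosub = "cosub", both = "both",
                  recover = "recover"),
                function(w) .effective_bounds(design_medium(model, config, w)))
  if (!all(vapply(bnd, function(b) all(is.finite(c(b$lb, b$ub))), TRUE))) {
    stop("MILP construction requires finite flux bounds", call. = FALSE)
  }
  if (fva_tighten) {
    # knockouts only shrink the flux cone, so wild-type ranges under the
    # widest medium are valid outer bounds in every inner problem
    fva <- flux_variability(design_medium(model, config, "recover"))
    margin <- 1e-5 + 1e-6 * pmax(abs(fva$min), abs(fva$max))
    for (w in names(bnd)) {
      bnd[[w]]$lb <- pmax(bnd[[w]]$lb, fva$min - margin)
      bnd[[w]]$ub <- pmin(bnd[[w]]$ub, fva$max + margin)
      # numerical guard: tightening must never invert a bound pair
      flip <- bnd[[w]]$lb > bnd[[w]]$ub
      if (any(flip)) {
        mid <- (bnd[[w]]$lb[flip] + bnd[[w]]$ub[flip]) / 2
        bnd[[w]]$lb[flip] <- mid; bnd[[w]]$ub[flip] <- mid
      }
    }
  }
  t_min <- 1 / config$uc_recovery_bound
  t_max <- 1 / eps_uc

  # ---- variable layout ------------------------------------------------------
  blocks <- if (mode == "sadf") {
    c(v1 = n, v3 = n, w2 = n, w4 = n, t = 1, tau = nc, y = nc,
      l2 = m, mu2 = n, nu2 = n, a2 = nc, b2 = nc)
  } else {
    c(v1 = n, v3 = n, y = nc, l2 = m, mu2 = n, nu2 = n, a2 = nc, b2 = nc)
  }
  if (config$variant == "A") {
    blocks <- c(blocks, c(l1 = m, mu1 = n, nu1 = n, a1 = nc, b1 = nc))
  }
  off <- cumsum(c(0, blocks))[seq_along(blocks)]
  names(off) <- names(blocks)
  nvar <- sum(blocks)
  V <- function(block, i = 1L) off[[block]] + i

  vlb <- rep(-Inf, nvar); vub <- rep(Inf, nvar)
  intg <- numeric(nvar)
  intg[V("y", seq_len(nc))] <- 1
  vlb[V("y", seq_len(nc))] <- 0; vub[V("y", seq_len(nc))] <- 1

  B <- .lp_builder(nvar)
  cvec <- numeric(n); cvec[bio] <- 1

  # primal block with knockout envelopes, bounds linear in y
  add_primal <- function(block, b) {
    B$add_matrix(model$S, V(block, seq_len(n)), rep(0, m), rep(0, m))
    vlb[V(block, seq_len(n))] <<- b$lb
    vub[V(block, seq_len(n))] <<- b$ub
    for (k in seq_len(nc)) {
      j <- cand_idx[k]
      if (b$lb[j] != 0) {
        B$add_row(c(V(block, j), V("y", k)), c(1, b$lb[j]), b$lb[j], Inf)
      }
      if (b$ub[j] != 0) {
        B$add_row(c(V(block, j), V("y", k)), c(1, b$ub[j]), -Inf, b$ub[j])
      }
    }
  }
  # scaled primal block: t*lb(1-y) <= w <= t*ub(1-y) via tau = t*y
  add_scaled_primal <- function(block, b) {
    B$add_matrix(model$S, V(block, seq_len(n)), rep(0, m), rep(0, m))
    for (j in seq_len(n)) {
      k <- match(j, cand_idx)
      if (b$lb[j] == 0) {
        vlb[V(block, j)] <<- 0
      } else if (is.na(k)) {
        B$add_row(c(V(block, j), V("t")), c(1, -b$lb[j]), 0, Inf)
      } else {
        B$add_row(c(V(block, j), V("t"), V("tau", k)),
                  c(1, -b$lb[j], b$lb[j]), 0, Inf)
      }
      if (b$ub[j] == 0) {
        vub[V(block, j)] <<- 0
      } else if (is.na(k)) {
        B$add_row(c(V(block, j), V("t")), c(1, -b$ub[j]), -Inf, 0)
      } else {
        B$add_row(c(V(block, j), V("t"), V("tau", k)),
                  c(1, -b$ub[j], b$ub[j]), -Inf, 0)
      }
    }
  }
  # dual block for an inner maximisation with bounds b: feasibility
  # S' l + mu - nu = c * t_coef (t_coef = 0 -> plain c), dual objective row
  # with the knockout products linearised, bounded above by rhs
  add_dual <- function(lbl, mubl, nubl, abl, bbl, b, rhs_row_ub, Mbig,
                       t_scaled = FALSE) {
    St <- Matrix::t(model$S)
    for (j in seq_len(n)) {
      row <- St[j, ]
      nzi <- which(row != 0)
      cols <- c(V(lbl, nzi), V(mubl, j), V(nubl, j))
      vals <- c(row[nzi], 1, -1)
      if (t_scaled && cvec[j] != 0) {
        cols <- c(cols, V("t")); vals <- c(vals, -cvec[j])
        B$add_row(cols, vals, 0, 0)
      } else {
        B$add_row(cols, vals, cvec[j], cvec[j])
      }
    }
    cap <- if (t_scaled) Mbig * t_max else Mbig
    vlb[V(mubl, seq_len(n))] <<- 0; vub[V(mubl, seq_len(n))] <<- cap
    vlb[V(nubl, seq_len(n))] <<- 0; vub[V(nubl, seq_len(n))] <<- cap
    vlb[V(abl, seq_len(nc))] <<- 0; vub[V(abl, seq_len(nc))] <<- cap
    vlb[V(bbl, seq_len(nc))] <<- 0; vub[V(bbl, seq_len(nc))] <<- cap
    if (t_scaled) {
      # scaled duals obey mu <= M*t (the unscaled dual bound times t), and
      # the products a = mu*y use t-proportional envelopes via tau = t*y —
      # every big constant stays of the order of M*t at the optimum, which
      # keeps the certificate immune to integrality-tolerance leakage
      for (j in seq_len(n)) {
        B$add_row(c(V(mubl, j), V("t")), c(1, -Mbig), -Inf, 0)
        B$add_row(c(V(nubl, j), V("t")), c(1, -Mbig), -Inf, 0)
      }
      for (k in seq_len(nc)) {
        j <- cand_idx[k]
        B$add_row(c(V(abl, k), V("tau", k)), c(1, -Mbig), -Inf, 0)
        B$add_row(c(V(abl, k), V(mubl, j)), c(1, -1), -Inf, 0)
        B$add_row(c(V(abl, k), V(mubl, j), V("t"), V("tau", k)),
                  c(1, -1, Mbig, -Mbig), 0, Inf)
        B$add_row(c(V(bbl, k), V("tau", k)), c(1, -Mbig), -Inf, 0)
        B$add_row(c(V(bbl, k), V(nubl, j)), c(1, -1), -Inf, 0)
        B$add_row(c(V(bbl, k), V(nubl, j), V("t"), V("tau", k)),
                  c(1, -1, Mbig, -Mbig), 0, Inf)
      }
    } else {
      # plain big-M product envelopes a = mu*y, b = nu*y
      for (k in seq_len(nc)) {
        j <- cand_idx[k]
        B$add_row(c(V(abl, k), V("y", k)), c(1, -Mbig), -Inf, 0)
        B$add_row(c(V(abl, k), V(mubl, j)), c(1, -1), -Inf, 0)
        B$add_row(c(V(abl, k), V(mubl, j), V("y", k)),
                  c(1, -1, -Mbig), -Mbig, Inf)
        B$add_row(c(V(bbl, k), V("y", k)), c(1, -Mbig), -Inf, 0)
        B$add_row(c(V(bbl, k), V(nubl, j)), c(1, -1), -Inf, 0)
        B$add_row(c(V(bbl, k), V(nubl, j), V("y", k)),
                  c(1, -1, -Mbig), -Mbig, Inf)
      }
    }
    # dual objective = sum_j (ub_j mu_j - lb_j nu_j)
    #                - sum_{j in C} (ub_j a_j - lb_j b_j)
    dual_cols <- c(V(mubl, seq_len(n)), V(nubl, seq_len(n)),
                   V(abl, seq_len(nc)), V(bbl, seq_len(nc)))
    dual_vals <- c(b$ub, -b$lb, -b$ub[cand_idx], b$lb[cand_idx])
    list(cols = dual_cols, vals = dual_vals, rhs_ub = rhs_row_ub)
  }

  f1 <- config$req1_fraction; f2 <- config$req2_fraction
  v0u <- reference$v0bio_uc; v0c <- reference$v0bio_cosub

  # requirement 1
  add_primal("v1", bnd$uc)
  if (config$variant == "B") {
    B$add_row(V("v1", bio), 1, f1 * v0u, Inf)
  } else {
    d1 <- add_dual("l1", "mu1", "nu1", "a1", "b1", bnd$uc,
                   rhs_row_ub = f1 * v0u, Mbig = M_dual)
    B$add_row(d1$cols, d1$vals, -Inf, d1$rhs_ub)
  }
  # requirement 3
  add_primal("v3", bnd$both)
  B$add_row(V("v3", bio), 1, v0c, Inf)

  if (mode == "sadf") {
    vlb[V("t")] <- t_min; vub[V("t")] <- t_max
    vlb[V("tau", seq_len(nc))] <- 0; vub[V("tau", seq_len(nc))] <- t_max
    # tau = t*y envelopes
    for (k in seq_len(nc)) {
      B$add_row(c(V("tau", k), V("y", k)), c(1, -t_max), -Inf, 0)
      B$add_row(c(V("tau", k), V("y", k)), c(1, -t_min), 0, Inf)
      B$add_row(c(V("tau", k), V("t"), V("y", k)), c(1, -1, -t_max),
                -t_max, Inf)
      B$add_row(c(V("tau", k), V("t"), V("y", k)), c(1, -1, -t_min),
                -Inf, -t_min)
    }
    # requirement 2, scaled: primal + weak-duality bound + strong duality
    add_scaled_primal("w2", bnd$cosub)
    B$add_row(c(V("w2", bio), V("t")), c(1, -f2 * v0c), -Inf, 0)
    d2 <- add_dual("l2", "mu2", "nu2", "a2", "b2", bnd$cosub,
                   rhs_row_ub = NA, Mbig = M_dual, t_scaled = TRUE)
    # strong duality: c.w2 - dualobj >= 0
    B$add_row(c(V("w2", bio), d2$cols), c(1, -d2$vals), 0, Inf)
    # minimal-uptake problem, scaled, with Charnes-Cooper normalisation
    add_scaled_primal("w4", bnd$recover)
    vlb[V("w4", uc)] <- -1; vub[V("w4", uc)] <- -1
    B$add_row(c(V("w4", bio), V("t")), c(1, -v0c), 0, Inf)
    obj <- numeric(nvar)
    obj[V("t")] <- v0c
    obj[V("w2", bio)] <- -1
    maximize <- TRUE
  } else {
    # feasibility mode: unscaled weak-duality certificate for requirement 2
    d2 <- add_dual("l2", "mu2", "nu2", "a2", "b2", bnd$cosub,
                   rhs_row_ub = f2 * v0c, Mbig = M_dual)
    B$add_row(d2$cols, d2$vals, -Inf, d2$rhs_ub)
    obj <- numeric(nvar)
    obj[V("y", seq_len(nc))] <- 1
    maximize <- FALSE
  }
  # knockout budget
  B$add_row(V("y", seq_len(nc)), rep(1, nc), -Inf, config$K)

  built <- B$build()
  structure(list(model = model, config = config, candidates = candidates,
                 reference = reference, mode = mode,
                 A = built$A, row_lb = built$row_lb, row_ub = built$row_ub,
                 var_lb = vlb, var_ub = vub, obj = obj,
                 integrality = intg, maximize = maximize,
                 offsets = off, blocks = blocks, nvar = nvar,
                 M_dual = M_dual, eps_uc = eps_uc,
                 t_min = t_min, t_max = t_max,
                 cuts = list()),
            class = "milp_formulation")
}

#' @export
print.milp_formulation <- function(x, ...) {
  cat("<milp_formulation> mode ", x$mode, ", variant ", x$config$variant,
      ": ", x$nvar, " variables (", length(x$candidates),
      " binaries), ", nrow(x$A), " rows, ", length(x$cuts),
      " integer cut(s)\n", sep = "")
  invisible(x)
}

#' Add an integer cut excluding a knockout set
#'
#' The default cut `sum(y_j, j in S) <= |S| - 1` excludes the found set and
#' every superset from later solves; with `exclude_supersets = FALSE` the
#' exact no-good cut (excluding only the exact set) is used instead.
#'
#' @param formulation a `milp_formulation`.
#' @param knockouts the knockout set to exclude (subset of candidates).
#' @param exclude_supersets logical (default TRUE).
#' @return the formulation with the cut appended.
#' @export
add_integer_cut <- function(formulation, knockouts, exclude_supersets = TRUE) {
  stopifnot(all(knockouts %in% formulation$candidates), length(knockouts) >= 1)
  formulation$cuts <- c(formulation$cuts,
                        list(list(set = sort(knockouts),
                                  supersets = exclude_supersets)))
  formulation
}

.cut_rows <- function(formulation) {
  nc <- length(formulation$candidates)
  y_off <- formulation$offsets[["y"]]
  rows <- lapply(formulation$cuts, function(cut) {
    inset <- formulation$candidates %in% cut$set
    if (cut$supersets) {
      cols <- y_off + which(inset)
      vals <- rep(1, sum(inset))
    } else {
      cols <- y_off + seq_len(nc)
      vals <- ifelse(inset, 1, -1)
    }
    i <- rep.int(1L, length(cols))
    list(mat = Matrix::sparseMatrix(i = i, j = cols, x = vals,
                                    dims = c(1L, formulation$nvar)),
         ub = length(cut$set) - 1)
  })
  rows
}

#' Solve the design MILP
#'
#' Solves the formulation (with any integer cuts applied) and post-verifies
#' the incumbent knockout set through the direct-FBA metrics layer: a
#' solution is `verified` when it passes all three requirements and (in
#' `"sadf"` mode) its MILP objective agrees with [sadf()] within 1e-3
#' relative.  When a continuous variable sits within 1e-3 of its big-M bound
#' the run is flagged and automatically re-solved with a tenfold larger M.
#'
#' @param formulation a `milp_formulation` from [build_milp()].
#' @param time_limit seconds, or `NULL`.
#' @return a `design_solution`: `knockouts`, `objective_sadf`,
#'   `milp_status`, `verified`, `sadf_check` (the direct-FBA SADF),
#'   `bigM_flag`.
#' @export
solve_design <- function(formulation, time_limit = NULL) {
  # Two safety nets around the raw MILP solve:
  #  * big-M proximity: a continuous variable at its big-M cap means the
  #    certificate may be truncated -> rebuild with tenfold M;
  #  * certificate erosion: if the incumbent's claimed objective exceeds its
  #    exact direct-FBA score, the relaxation leaked through a numerically
  #    marginal binary -> exclude exactly that knockout pattern and re-solve.
  # The claimed value never understates the exact score of its own pattern,
  # so eliminating corrupted incumbents preserves global optimality.
  sol <- NULL
  for (attempt in 1:10) {
    sol <- .solve_milp_once(formulation, time_limit)
    if (isTRUE(sol$bigM_flag)) {
      cuts <- formulation$cuts
      formulation <- build_milp(formulation$model, formulation$config,
                                formulation$candidates,
                                mode = formulation$mode,
                                M_dual = formulation$M_dual * 10,
                                eps_uc = formulation$eps_uc)
      formulation$cuts <- cuts
      next
    }
    refine <- formulation$mode == "sadf" &&
      sol$milp_status == "optimal" && !sol$verified &&
      length(sol$knockouts) > 0 &&
      (!is.finite(sol$sadf_check) ||
         sol$objective_sadf > sol$sadf_check +
           1e-3 * max(1, abs(sol$sadf_check)))
    if (!refine) return(sol)
    formulation <- add_integer_cut(formulation, sol$knockouts,
                                   exclude_supersets = FALSE)
  }
  sol
}

.solve_milp_once <- function(formulation, time_limit = NULL) {
  f <- formulation
  A <- f$A; rlb <- f$row_lb; rub <- f$row_ub
  for (cr in .cut_rows(f)) {
    A <- rbind(A, cr$mat); rlb <- c(rlb, -Inf); rub <- c(rub, cr$ub)
  }
  res <- hs_solve(f$obj, A, rlb, rub, f$var_lb, f$var_ub,
                  integrality = f$integrality, maximize = f$maximize,
                  time_limit = time_limit, mip_rel_gap = 1e-4)
  empty <- function(status) {
    structure(list(knockouts = character(0), objective_sadf = NA_real_,
                   milp_status = status, verified = FALSE,
                   sadf_check = NA_real_, bigM_flag = FALSE,
                   requirements = NULL),
              class = "design_solution")
  }
  if (is.null(res$x)) return(empty(res$status))
  nc <- length(f$candidates)
  yval <- res$x[f$offsets[["y"]] + seq_len(nc)]
  knockouts <- f$candidates[yval > 0.5]

  bigM_flag <- FALSE
  if (f$mode == "sadf") {
    Mds <- f$M_dual * f$t_max
    duals <- res$x[c(f$offsets[["mu2"]] + seq_len(f$blocks[["mu2"]]),
                     f$offsets[["nu2"]] + seq_len(f$blocks[["nu2"]]))]
    tval <- res$x[f$offsets[["t"]] + 1L]
    if (any(duals > Mds * (1 - 1e-3)) || tval > f$t_max * (1 - 1e-3)) {
      bigM_flag <- TRUE
    }
    if (f$config$variant == "A") {
      duals1 <- res$x[c(f$offsets[["mu1"]] + seq_len(f$blocks[["mu1"]]),
                        f$offsets[["nu1"]] + seq_len(f$blocks[["nu1"]]))]
      if (any(duals1 > f$M_dual * (1 - 1e-3))) bigM_flag <- TRUE
    }
  }

  rep <- check_requirements(f$model, knockouts, f$config, f$reference)
  s_direct <- sadf(f$model, knockouts, f$config, f$reference)
  objective_sadf <- if (f$mode == "sadf") res$objective else as.numeric(s_direct)
  agree <- is.finite(objective_sadf) && is.finite(s_direct) &&
    abs(objective_sadf - s_direct) <= 1e-3 * max(1, abs(s_direct))
  verified <- rep$req1_pass && rep$req2_pass && rep$req3_pass && agree
  structure(list(knockouts = knockouts, objective_sadf = objective_sadf,
                 milp_status = res$status, verified = verified,
                 sadf_check = as.numeric(s_direct), bigM_flag = bigM_flag,
                 requirements = rep),
            class = "design_solution")
}

#' @export
print.design_solution <- function(x, ...) {
  cat("<design_solution> {", paste(x$knockouts, collapse = ", "), "}: ",
      "SADF = ", format(x$objective_sadf), " (", x$milp_status,
      if (x$verified) ", verified" else ", NOT verified", ")\n", sep = "")
  invisible(x)
}

#' Enumerate alternative knockout designs with integer cuts
#'
#' Iteratively solves the MILP, after each solution appending an integer cut
#' over that solution's knockout set, until `max_solutions` designs have
#' been found or the problem becomes infeasible.  Returned sets are pairwise
#' distinct; with the default cut no returned set is a superset of an
#' earlier one.  Objectives are not guaranteed monotone (near-optimal
#' alternatives are admitted).
#'
#' @param formulation a `milp_formulation`.
#' @param max_solutions maximal number of designs (>= 0).
#' @param time_limit per-solve limit in seconds, or `NULL`.
#' @param exclude_supersets cut style, see [add_integer_cut()].
#' @return list of `design_solution` objects.
#' @export
enumerate_designs <- function(formulation, max_solutions, time_limit = NULL,
                              exclude_supersets = TRUE) {
  stopifnot(max_solutions >= 0)
  out <- list()
  while (length(out) < max_solutions) {
    sol <- solve_design(formulation, time_limit)
    if (!sol$milp_status %in% c("optimal", "limit") ||
        is.null(sol$knockouts)) break
    if (sol$milp_status == "limit" && !length(sol$knockouts)) break
    out[[length(out) + 1L]] <- sol
    if (!length(sol$knockouts)) break  # nothing left to cut
    formulation <- add_integer_cut(formulation, sol$knockouts,
                                   exclude_supersets = exclude_supersets)
  }
  out
}
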