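# Parametric toy networks with closed-form answers, and the exhaustive
# brute-force design oracle used to verify the MILP.
#
# The core toy couples a fraction phi of biomass to the unadapted carbon
# source M: cosubstrate A feeds precursor P directly (rP) and precursor Q
# either directly (rQ1, the deletion target) or through a 1:1 condensation
# with M (rQ2: A + M -> 2 Q, the RuMP-like motif).  Biomass consumes
# (1-phi) P + phi Q per unit growth, and the uptake-to-growth yield is 1, so
# after deleting rQ1:
#   v2bio = 0 (no leak)           vUC(target g) = phi g / 2
#   SADF  = 2 / phi               UC/Co = phi / (2 - phi)
# All metabolites carry formula "C" (one carbon, equal molar mass), so
# biomass mass fractions equal stoichiometric coefficients and the coupling
# fraction after the deletion is exactly phi.

#' Specify a toy network
#'
#' @param phi UC-dependent biomass mass fraction, in (0, 1].
#' @param uptake_bound substrate uptake bound (default 10).
#' @param include_uc_only_route add `rMA: M -> A`, letting the UC substitute
#'   for the cosubstrate so that growth on the UC alone is possible and
#'   variant B is exercisable.
#' @param include_leak_route add an inefficient cosubstrate route to Q
#'   (`rQL: c_leak A -> Q`), making requirement 2 nontrivial.
#' @param c_leak stoichiometric cost of the leak route; requirement 2 holds
#'   after deleting `rQ1` iff `c_leak >= (1/req2_fraction - (1-phi))/phi`.
#' @param q_route `"single"` (rQ1: A -> Q), `"serial"` (two-step route
#'   rQ1a: A -> QI, rQ1b: QI -> Q, giving two equal-score singleton
#'   deletions) or `"parallel"` (duplicated rQ1a/rQ1b, both must go).
#' @param decoys number of blocked or gene-orphan decoy reactions, generated
#'   reproducibly from `seed`.
#' @param seed integer seed for decoy generation.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(phi, uptake_bound = 10, include_uc_only_route = FALSE,
                     include_leak_route = FALSE, c_leak = NULL,
                     q_route = c("single", "serial", "parallel"),
                     decoys = 0, seed = 1L) {
  q_route <- match.arg(q_route)
  stopifnot(phi > 0, phi <= 1, uptake_bound > 0, decoys >= 0)
  if (include_leak_route && is.null(c_leak)) {
    # just past the requirement-2 boundary at the default 10% threshold
    c_leak <- (10 - (1 - phi)) / phi + 1
  }
  if (include_leak_route) stopifnot(c_leak > 1)
  structure(list(phi = phi, uptake_bound = uptake_bound,
                 include_uc_only_route = include_uc_only_route,
                 include_leak_route = include_leak_route,
                 c_leak = c_leak, q_route = q_route,
                 decoys = as.integer(decoys), seed = as.integer(seed)),
            class = "toy_spec")
}

# closed forms for the generated family (unit yield, uptake bound a):
#   no leak:  v2bio = 0,  vUC(g) = phi g / 2
#   leak:     v2bio = a / (1 - phi + phi c),
#             vUC(a) = phi a (c - 1) / (2 c - 1)   [leak used up to A budget]
.toy_answer_key <- function(spec) {
  a <- spec$uptake_bound; phi <- spec$phi
  if (spec$include_leak_route) {
    c <- spec$c_leak
    v2 <- a / (1 - phi + phi * c)
    vuc <- phi * a * (c - 1) / (2 * c - 1)
    sadf <- (a - v2) / vuc
    # at the 0.1 growth floor the A budget is slack, so the leak covers Q
    # entirely: no UC is needed and the parsimonious ratio is zero
    ucco <- 0
    req2_pass <- v2 <= 0.1 * a + 1e-9
  } else {
    v2 <- 0
    vuc <- phi * a / 2
    sadf <- 2 / phi
    ucco <- phi / (2 - phi)
    req2_pass <- TRUE
  }
  best <- switch(spec$q_route,
                 single = list("rQ1"),
                 serial = list("rQ1a", "rQ1b"),
                 parallel = list(c("rQ1a", "rQ1b")))
  list(expected_best_knockouts = best,
       expected_sadf = sadf,
       expected_ucco = ucco,
       expected_v0_cosub = a,
       expected_v2bio = v2,
       expected_vuc = vuc,
       # with a leak route Q stays producible from the cosubstrate (growth is
       # impaired, not structurally blocked), so no precursor is coupled
       expected_coupling_fraction = if (spec$include_leak_route) 0 else phi,
       expected_req2_pass_after_cut = req2_pass)
}

#' Generate a toy model with its analytic answer key
#'
#' @param spec a [toy_spec()].
#' @return list with elements `model` (a `metabolic_model`), `key` (the
#'   analytically derived `toy_answer_key`) and `config` (a matching
#'   [design_config()], variant B when the UC-only route is present, else A).
#' @export
make_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  mets <- data.frame(id = c("A", "M", "P", "Q"),
                     name = c("cosubstrate", "unadapted substrate",
                              "precursor P", "precursor Q"),
                     compartment = "c", formula = "C", charge = 0,
                     stringsAsFactors = FALSE)
  phi <- spec$phi
  biomass_stoich <- if (phi == 1) c(Q = -1) else c(P = -(1 - phi), Q = -phi)
  rx <- list(
    reaction("EX_A", c(A = -1), lb = -spec$uptake_bound, ub = 1000,
             name = "cosubstrate exchange"),
    reaction("EX_M", c(M = -1), lb = -spec$uptake_bound, ub = 1000,
             name = "UC exchange"),
    reaction("rP", c(A = -1, P = 1), lb = 0, ub = 1000, gene_rule = "gP"),
    reaction("rQ2", c(A = -1, M = -1, Q = 2), lb = 0, ub = 1000,
             gene_rule = "gQ2"),
    reaction("biomass", biomass_stoich, lb = 0, ub = 1000, name = "biomass"))
  rx <- c(rx, switch(spec$q_route,
    single = list(reaction("rQ1", c(A = -1, Q = 1), gene_rule = "gQ1")),
    serial = list(reaction("rQ1a", c(A = -1, QI = 1), gene_rule = "gQ1a"),
                  reaction("rQ1b", c(QI = -1, Q = 1), gene_rule = "gQ1b")),
    parallel = list(reaction("rQ1a", c(A = -1, Q = 1), gene_rule = "gQ1a"),
                    reaction("rQ1b", c(A = -1, Q = 1), gene_rule = "gQ1b"))))
  if (spec$include_uc_only_route) {
    rx <- c(rx, list(reaction("rMA", c(M = -1, A = 1), gene_rule = "gMA")))
  }
  if (spec$include_leak_route) {
    rx <- c(rx, list(reaction("rQL", c(A = -spec$c_leak, Q = 1),
                              gene_rule = "gQL")))
  }
  if (spec$decoys > 0) {
    rng <- .toy_rng(spec$seed)
    for (k in seq_len(spec$decoys)) {
      coef <- round(1 + 2 * rng(), 2)
      orphan <- rng() < 0.5
      rx <- c(rx, list(reaction(
        sprintf("rDEC%d", k),
        stats::setNames(c(-coef, 1), c("A", sprintf("DEAD%d", k))),
        lb = 0, ub = 1000,
        gene_rule = if (orphan) "" else sprintf("gDEC%d", k),
        subsystem = "decoy")))
    }
  }
  extra_mets <- setdiff(unique(unlist(lapply(rx, function(r) names(r$stoich)))),
                        mets$id)
  if (length(extra_mets)) {
    mets <- rbind(mets, data.frame(id = extra_mets, name = extra_mets,
                                   compartment = "c", formula = "C",
                                   charge = 0, stringsAsFactors = FALSE))
  }
  rxns <- data.frame(id = vapply(rx, `[[`, "", "id"),
                     name = vapply(rx, `[[`, "", "name"),
                     lb = vapply(rx, `[[`, 0, "lb"),
                     ub = vapply(rx, `[[`, 0, "ub"),
                     gene_rule = vapply(rx, `[[`, "", "gene_rule"),
                     subsystem = vapply(rx, `[[`, "", "subsystem"),
                     stringsAsFactors = FALSE)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rx)) {
    i <- c(i, match(names(rx[[k]]$stoich), mets$id))
    j <- c(j, rep.int(k, length(rx[[k]]$stoich)))
    x <- c(x, unname(rx[[k]]$stoich))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(mets), nrow(rxns)))
  model <- metabolic_model(mets, rxns, S, biomass_id = "biomass",
                           annotations = list(
                             id = sprintf("toy_phi_%g", phi),
                             source = "synthetic"))

  key <- .toy_answer_key(spec)
  config <- design_config(
    uc_exchange = "EX_M", cosub_exchange = "EX_A",
    variant = if (spec$include_uc_only_route) "B" else "A",
    K = 2, uptake_bound = spec$uptake_bound)
  # the generator's analytic pass/fail claim for requirement 2 must hold
  if (spec$include_leak_route && !key$expected_req2_pass_after_cut) {
    stop("toy_spec leak cost too low: requirement 2 would fail for the ",
         "intended design; raise c_leak", call. = FALSE)
  }
  list(model = model, key = key, config = config, spec = spec)
}

# small deterministic generator (decoys must not disturb the global RNG)
.toy_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Exhaustive brute-force design oracle
#'
#' Evaluates every knockout subset of the candidates up to size `K` with
#' direct FBA ([check_requirements()]); subsets passing all three
#' requirements are scored by [sadf()] and [ucco_ratio()] and returned
#' sorted by SADF (descending), ties broken by fewer knockouts then
#' lexicographic ids.  Structurally blocked candidates are collapsed before
#' evaluation (deleting a blocked reaction never changes any flux solution),
#' which keeps the enumeration tractable.
#'
#' @param model a `metabolic_model`.
#' @param config a [design_config()].
#' @param candidates character vector of candidate reaction ids.
#' @param K maximal subset size (default `config$K`).
#' @param guard maximal number of subsets (error above; default 1e5).
#' @return data.frame with columns `knockouts` (comma-joined), `n_knockouts`,
#'   `sadf`, `ucco`, plus attribute `"n_evaluated"`.
#' @export
brute_force_designs <- function(model, config, candidates, K = config$K,
                                guard = 1e5) {
  stopifnot(K >= 0)
  candidates <- sort(unique(candidates))
  n <- length(candidates)
  total <- sum(vapply(0:min(K, n), function(k) choose(n, k), 0))
  if (total > guard) {
    stop("subset count ", format(total), " exceeds guard ", guard,
         call. = FALSE)
  }
  reference <- reference_state(model, config)
  fva <- flux_variability(design_medium(model, config, "both"), candidates)
  blocked <- fva$id[abs(fva$min) < 1e-6 & abs(fva$max) < 1e-6]

  cache <- new.env(parent = emptyenv())
  evaluate <- function(ko) {
    eff <- setdiff(ko, blocked)
    keyname <- paste0("k:", paste(eff, collapse = "|"))
    if (!is.null(cache[[keyname]])) return(cache[[keyname]])
    # cheap short-circuit order: requirement 2 prunes most subsets
    v2 <- solve_fba(design_medium(model, config, "cosub"), knockouts = eff)
    out <- NULL
    if (v2$status == "optimal" &&
        max(0, v2$objective_value) <=
          config$req2_fraction * reference$v0bio_cosub + config$tol) {
      rep <- check_requirements(model, eff, config, reference)
      if (rep$req1_pass && rep$req2_pass && rep$req3_pass) {
        s <- sadf(model, eff, config, reference)
        u <- ucco_ratio(model, eff, config)
        out <- list(sadf = as.numeric(s), ucco = as.numeric(u))
      }
    }
    if (is.null(out)) out <- list(sadf = NA_real_, ucco = NA_real_)
    cache[[keyname]] <- out
    out
  }

  res <- list()
  n_eval <- 0L
  for (k in 0:min(K, n)) {
    sets <- if (k == 0) list(character(0)) else {
      cm <- utils::combn(candidates, k)
      lapply(seq_len(ncol(cm)), function(j) cm[, j])
    }
    for (ko in sets) {
      n_eval <- n_eval + 1L
      sc <- evaluate(ko)
      if (!is.na(sc$sadf)) {
        res[[length(res) + 1L]] <- data.frame(
          knockouts = paste(ko, collapse = ","),
          n_knockouts = length(ko), sadf = sc$sadf, ucco = sc$ucco,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(knockouts = character(0), n_knockouts = integer(0),
               sadf = numeric(0), ucco = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$sadf, out$n_knockouts, out$knockouts), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- n_eval
  out
}
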