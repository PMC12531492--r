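# single-level MILP: construction, optimisation, enumeration

test_that("formulation structure matches the design dimensions", {
  toy <- make_toy(toy_spec(0.5, decoys = 2, seed = 4))
  cand <- toy_candidates(toy)
  fm <- build_milp(toy$model, toy$config, cand)
  expect_s3_class(fm, "milp_formulation")
  expect_equal(sum(fm$integrality > 0), length(cand))
  # four flux blocks of model width
  n <- nrow(toy$model$rxns)
  expect_equal(unname(fm$blocks[c("v1", "v3", "w2", "w4")]), rep(n, 4))
  expect_equal(fm$nvar, ncol(fm$A))
  # candidate preconditions
  expect_error(build_milp(toy$model, toy$config, c(cand, "biomass")),
               "biomass")
  expect_error(build_milp(toy$model, toy$config, c(cand, "EX_M")),
               "exclude")
  expect_error(build_milp(toy$model, toy$config, character(0)), "empty")
})

test_that("the MILP recovers the known optimum and is verified", {
  toy <- make_toy(toy_spec(0.1, decoys = 2, seed = 9))
  fm <- build_milp(toy$model, toy$config, toy_candidates(toy))
  sol <- solve_design(fm)
  expect_identical(sol$milp_status, "optimal")
  expect_identical(sol$knockouts, "rQ1")
  expect_equal(sol$objective_sadf, 20, tolerance = 1e-5)
  expect_true(sol$verified)
  expect_false(sol$bigM_flag)
  # the implied metric agrees with the direct-FBA scoring route
  expect_equal(sol$objective_sadf, sol$sadf_check, tolerance = 1e-6)
})

test_that("zero knockout budget is infeasible (requirement 2 cannot hold)", {
  toy <- make_toy(toy_spec(0.5))
  cfg <- toy$config; cfg$K <- 0L
  sol <- solve_design(build_milp(toy$model, cfg, toy_candidates(toy)))
  expect_identical(sol$milp_status, "infeasible")
  expect_length(sol$knockouts, 0)
})

test_that("blocked decoys never enter the optimal minimal support", {
  toy <- make_toy(toy_spec(0.25, decoys = 4, seed = 13))
  fm <- build_milp(toy$model, toy$config, toy_candidates(toy),
                   mode = "feasibility")
  sol <- solve_design(fm)
  expect_true(sol$verified)
  expect_false(any(grepl("^rDEC", sol$knockouts)))
})

test_that("variant B designs preserve growth on the UC alone", {
  toy <- make_toy(toy_spec(0.25, include_uc_only_route = TRUE))
  sol <- solve_design(build_milp(toy$model, toy$config, toy_candidates(toy)))
  expect_true(sol$verified)
  expect_equal(sol$objective_sadf, 8, tolerance = 1e-5)
  rep <- check_requirements(toy$model, sol$knockouts, toy$config)
  expect_gte(rep$v1bio, 0.5 * rep$reference$v0bio_uc - 1e-6)
})

test_that("the optimum is non-decreasing in the knockout budget K", {
  toy <- make_toy(toy_spec(0.25, q_route = "parallel", include_leak_route = TRUE))
  cand <- toy_candidates(toy)
  opts <- vapply(0:3, function(k) {
    cfg <- toy$config; cfg$K <- k
    sol <- solve_design(build_milp(toy$model, cfg, cand))
    if (sol$milp_status == "optimal") sol$objective_sadf else -Inf
  }, 0)
  expect_identical(opts[1], -Inf)       # K = 0 infeasible
  expect_true(is.finite(opts[4]))
  # once feasible, stays feasible, and the optimum never degrades
  feas <- which(is.finite(opts))
  expect_identical(feas, min(feas):4)
  expect_true(all(diff(opts[feas]) >= -1e-6))
})

test_that("feasibility-mode enumeration plus LP scoring agrees with the ratio MILP", {
  for (spec in list(toy_spec(0.5, include_leak_route = TRUE, seed = 2),
                    toy_spec(0.1, q_route = "serial", decoys = 1, seed = 3))) {
    toy <- make_toy(spec)
    cand <- toy_candidates(toy)
    direct <- solve_design(build_milp(toy$model, toy$config, cand))
    fm <- build_milp(toy$model, toy$config, cand, mode = "feasibility")
    # exact no-good cuts: the pool must cover supersets of earlier designs,
    # whose SADF can dominate
    pool <- enumerate_designs(fm, max_solutions = 50,
                              exclude_supersets = FALSE)
    expect_gt(length(pool), 0)
    best <- max(vapply(pool, function(s) s$sadf_check, 0), na.rm = TRUE)
    expect_equal(direct$objective_sadf, best, tolerance = 1e-5)
  }
})

test_that("integer-cut enumeration returns distinct non-superset solutions", {
  toy <- make_toy(toy_spec(0.5, q_route = "serial"))
  fm <- build_milp(toy$model, toy$config, toy_candidates(toy))
  expect_length(enumerate_designs(fm, max_solutions = 0), 0)
  sols <- enumerate_designs(fm, max_solutions = 6)
  sets <- lapply(sols, `[[`, "knockouts")
  keys <- vapply(sets, paste, "", collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  # both equal-score singleton alternatives surface in the first two rounds
  expect_setequal(unlist(sets[1:2]), c("rQ1a", "rQ1b"))
  expect_equal(sols[[1]]$objective_sadf, sols[[2]]$objective_sadf,
               tolerance = 1e-6)
  # no returned set is a superset of an earlier (cut) set
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    expect_false(all(sets[[j]] %in% sets[[i]]))
  }
  # every enumerated solution re-passes the requirements by direct FBA
  for (s in sols) {
    rep <- check_requirements(toy$model, s$knockouts, toy$config)
    expect_true(rep$req1_pass && rep$req2_pass && rep$req3_pass)
  }
})

test_that("the exact no-good cut admits supersets the default cut prunes", {
  toy <- make_toy(toy_spec(0.5, q_route = "serial", decoys = 0))
  cfg <- toy$config; cfg$K <- 2L
  fm <- build_milp(toy$model, cfg, toy_candidates(toy), mode = "feasibility")
  strict <- enumerate_designs(fm, max_solutions = 20, exclude_supersets = TRUE)
  loose <- enumerate_designs(fm, max_solutions = 20, exclude_supersets = FALSE)
  expect_gte(length(loose), length(strict))
  strict_sets <- lapply(strict, `[[`, "knockouts")
  for (i in seq_along(strict_sets)) for (j in seq_len(i - 1L)) {
    expect_false(all(strict_sets[[j]] %in% strict_sets[[i]]))
  }
})
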