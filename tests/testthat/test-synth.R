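# toy generator: analytic answer keys, and the brute-force oracle

test_that("generated toys match their analytic answer keys", {
  specs <- list(
    toy_spec(1), toy_spec(0.5), toy_spec(0.05),
    toy_spec(0.5, decoys = 3, seed = 11),
    toy_spec(0.25, include_uc_only_route = TRUE),
    toy_spec(0.5, include_leak_route = TRUE),
    toy_spec(0.2, include_leak_route = TRUE, c_leak = 60))
  for (spec in specs) {
    toy <- make_toy(spec)
    ko <- toy$key$expected_best_knockouts[[1]]
    ref <- reference_state(toy$model, toy$config)
    expect_equal(ref$v0bio_cosub, toy$key$expected_v0_cosub, tolerance = 1e-8)
    expect_equal(as.numeric(sadf(toy$model, ko, toy$config, ref)),
                 toy$key$expected_sadf, tolerance = 1e-6)
    expect_equal(as.numeric(ucco_ratio(toy$model, ko, toy$config)),
                 toy$key$expected_ucco, tolerance = 1e-6)
    expect_equal(minimal_uc_uptake(toy$model, ko, ref$v0bio_cosub, toy$config),
                 toy$key$expected_vuc, tolerance = 1e-6)
    v2 <- solve_fba(set_medium(toy$model,
                               setNames(toy$config$uptake_bound, "EX_A")),
                    knockouts = ko)
    expect_equal(max(0, v2$objective_value), toy$key$expected_v2bio,
                 tolerance = 1e-6)
    pp <- precursor_producibility(toy$model, ko, toy$config)
    expect_equal(pp$coupling_fraction, toy$key$expected_coupling_fraction,
                 tolerance = 1e-9)
  }
})

test_that("decoy reactions are reproducible and inert", {
  a <- make_toy(toy_spec(0.5, decoys = 3, seed = 5))
  b <- make_toy(toy_spec(0.5, decoys = 3, seed = 5))
  c <- make_toy(toy_spec(0.5, decoys = 3, seed = 6))
  expect_identical(a$model$rxns, b$model$rxns)
  expect_false(identical(as.matrix(a$model$S), as.matrix(c$model$S)))
  expect_equal(nrow(a$model$rxns), nrow(make_toy(toy_spec(0.5))$model$rxns) + 3)
  # the oracle answer is unchanged by decoys
  expect_equal(as.numeric(sadf(a$model, "rQ1", a$config)), 4, tolerance = 1e-6)
})

test_that("the generator rejects leak costs that break its analytic claim", {
  # c_leak below the requirement-2 boundary (9 + phi)/phi must be refused
  expect_error(make_toy(toy_spec(0.5, include_leak_route = TRUE, c_leak = 5)),
               "requirement 2")
  # the analytic pass claim holds by direct FBA at the default cost
  toy <- make_toy(toy_spec(0.5, include_leak_route = TRUE))
  rep <- check_requirements(toy$model, "rQ1", toy$config)
  expect_true(rep$req2_pass)
  expect_gt(rep$v2bio, 0)  # the leak really leaks
})

test_that("brute force finds the known optimum and respects K", {
  toy <- make_toy(toy_spec(0.1, decoys = 2, seed = 2))
  bf <- brute_force_designs(toy$model, toy$config, toy_candidates(toy), K = 2)
  expect_gt(nrow(bf), 0)
  expect_identical(bf$knockouts[1], "rQ1")
  expect_equal(bf$sadf[1], 20, tolerance = 1e-6)
  # every reported design passes all requirements by construction
  expect_true(all(bf$sadf > 0))
  # K = 0: the empty set fails requirement 2, so no passers
  bf0 <- brute_force_designs(toy$model, toy$config, toy_candidates(toy), K = 0)
  expect_equal(nrow(bf0), 0)
  # guard on combinatorial explosion
  expect_error(
    brute_force_designs(toy$model, toy$config, toy_candidates(toy), K = 2,
                        guard = 3), "guard")
})

test_that("parallel duplicated routes need both deletions", {
  toy <- make_toy(toy_spec(0.25, q_route = "parallel"))
  cand <- toy_candidates(toy)
  bf1 <- brute_force_designs(toy$model, toy$config, cand, K = 1)
  expect_equal(nrow(bf1), 0)
  bf2 <- brute_force_designs(toy$model, toy$config, cand, K = 2)
  expect_identical(bf2$knockouts[1], "rQ1a,rQ1b")
  expect_equal(bf2$sadf[1], 8, tolerance = 1e-6)
})

test_that("serial two-step routes admit two equal-score singleton cuts", {
  toy <- make_toy(toy_spec(0.5, q_route = "serial"))
  bf <- brute_force_designs(toy$model, toy$config, toy_candidates(toy), K = 1)
  expect_setequal(bf$knockouts, c("rQ1a", "rQ1b"))
  expect_equal(bf$sadf, c(4, 4), tolerance = 1e-6)
})
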