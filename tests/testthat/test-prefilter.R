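# candidate prefiltering: trace bookkeeping and soundness

test_that("filters remove scaffold, orphan, blocked and excluded reactions", {
  toy <- make_toy(toy_spec(0.5, decoys = 4, seed = 21))
  trace <- candidate_knockouts(
    toy$model, toy$config,
    filters = c("scaffold", "orphan", "blocked", "exclusion"),
    exclusion_subsystems = "decoy")
  expect_s3_class(trace, "filter_trace")
  # exchanges and biomass never become candidates
  expect_setequal(trace$removed$scaffold, c("EX_A", "EX_M", "biomass"))
  expect_false(any(c("EX_A", "EX_M", "biomass") %in% trace$final_candidates))
  # gene-orphan decoys fall to the orphan filter, dead-ended ones to blocked,
  # and the 'decoy' subsystem sweep takes any remainder: none survive
  expect_false(any(grepl("^rDEC", trace$final_candidates)))
  # dead-end side reactions are blocked under the union medium
  all_dec <- grep("^rDEC", toy$model$rxns$id, value = TRUE)
  caught <- unique(unlist(trace$removed[c("orphan", "blocked", "exclusion")]))
  expect_true(all(all_dec %in% caught))
})

test_that("trace counts are additive and runs are deterministic", {
  toy <- make_toy(toy_spec(0.25, decoys = 3, seed = 8))
  t1 <- candidate_knockouts(toy$model, toy$config)
  t2 <- candidate_knockouts(toy$model, toy$config)
  expect_identical(t1, t2)
  removed_all <- unique(unlist(t1$removed))
  expect_setequal(c(removed_all, t1$final_candidates), toy$model$rxns$id)
  expect_equal(length(t1$final_candidates),
               t1$initial_count - length(removed_all))
})

test_that("filtering is sound: the oracle optimum survives", {
  for (spec in list(toy_spec(0.1, decoys = 2, seed = 31),
                    toy_spec(0.5, q_route = "serial", decoys = 3, seed = 32),
                    toy_spec(0.25, include_leak_route = TRUE, seed = 33))) {
    toy <- make_toy(spec)
    trace <- candidate_knockouts(
      toy$model, toy$config,
      filters = c("scaffold", "orphan", "blocked", "exclusion"),
      exclusion_subsystems = "decoy")
    bf <- brute_force_designs(toy$model, toy$config, toy_candidates(toy),
                              K = 2)
    best <- strsplit(bf$knockouts[1], ",")[[1]]
    expect_true(all(best %in% trace$final_candidates))
  }
})

test_that("the essential screen drops deletions that wreck requirement 3", {
  toy <- make_toy(toy_spec(0.5))
  trace <- candidate_knockouts(toy$model, toy$config,
                               filters = c("scaffold", "essential"))
  # deleting rP (or the biomass route) makes recovery growth impossible
  expect_true("rP" %in% trace$removed$essential)
  expect_false("rP" %in% trace$final_candidates)
  # the intended coupling deletion survives (growth recovers through rQ2)
  expect_true("rQ1" %in% trace$final_candidates)
})
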