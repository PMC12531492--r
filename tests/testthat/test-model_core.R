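# model construction, pathway insertion, preprocessing, media

test_that("model construction validates structure and detects exchanges", {
  toy <- make_toy(toy_spec(0.25, decoys = 1))
  m <- toy$model
  expect_s3_class(m, "metabolic_model")
  expect_setequal(m$exchange_ids, c("EX_A", "EX_M"))
  expect_false(m$biomass_id %in% m$exchange_ids)
  # every metabolite referenced by some reaction is in the table
  expect_true(all(Matrix::rowSums(m$S != 0) >= 1))
  # invalid inputs are rejected
  expect_error(reaction("bad", c(A = 0)), "stoich")
  expect_error(
    metabolic_model(m$mets, m$rxns, m$S, biomass_id = "nope"),
    "biomass")
  bad <- m$rxns; bad$lb[2] <- 5; bad$ub[2] <- -5
  expect_error(metabolic_model(m$mets, bad, m$S, m$biomass_id), "bound")
})

test_that("add_pathway inserts the RuMP module and is identity for empty specs", {
  base <- mini_ecoli()
  aug <- add_pathway(base, rump_pathway())
  # MEDH + HPS + PHI + transport, plus the methanol exchange (absent before)
  expect_equal(nrow(aug$rxns), nrow(base$rxns) + 5L)
  expect_true(all(c("MEDH", "HPS", "PHI", "MEOHt", "EX_meoh_e") %in%
                    aug$rxns$id))
  expect_true("EX_meoh_e" %in% aug$exchange_ids)
  # structurally well-formed: no dangling metabolite references
  expect_true(all(rownames(aug$S)[Matrix::rowSums(aug$S != 0) > 0] %in%
                    aug$mets$id))
  # methanol-only medium supports growth through the inserted pathway
  g <- reference_growth(aug, "EX_meoh_e", 10)
  expect_gt(g, 0)
  # identity and collision cases
  expect_identical(add_pathway(base, pathway_spec())$rxns, base$rxns)
  expect_error(add_pathway(aug, rump_pathway()), "already present")
  # an exchange already present is not duplicated
  aug2 <- add_pathway(aug, pathway_spec(required_exchanges = list(
    reaction("EX_meoh_e2", c(meoh_e = -1), lb = 0, ub = 1000))))
  expect_false("EX_meoh_e2" %in% aug2$rxns$id)
})

test_that("preprocessing profiles deactivate target reactions and fixation", {
  base <- mini_ecoli()
  expect_warning(pp <- apply_preprocessing(base, "ecoli"), "OBTFL")
  idx <- match("PFL", pp$rxns$id)
  expect_identical(c(pp$rxns$lb[idx], pp$rxns$ub[idx]), c(0, 0))
  # CFIX consumes CO2 in its forward direction and is not whitelisted:
  # the fixing direction is blocked, the reverse stays open
  cfx <- match("CFIX", pp$rxns$id)
  expect_identical(pp$rxns$ub[cfx], 0)
  expect_lt(pp$rxns$lb[cfx], 0)
  # CO2 exchange is untouched
  ex <- match("EX_co2_c", pp$rxns$id)
  expect_identical(pp$rxns$lb[ex], -1000)
  # none profile is the identity
  expect_identical(apply_preprocessing(base, "none"), base)
  # the C. glutamicum profile gains one xylose transport reaction
  suppressWarnings(cg <- apply_preprocessing(base, "cglutamicum"))
  expect_true(all(c("XYLt", "EX_xyl__D_e") %in% cg$rxns$id))
})

test_that("set_medium opens listed uptakes, closes other carbon, is idempotent", {
  m <- mini_ecoli()
  m <- add_pathway(m, rump_pathway())
  med <- set_medium(m, c(EX_meoh_e = 10))
  expect_equal(med$rxns$lb[match("EX_meoh_e", med$rxns$id)], -10)
  expect_equal(med$rxns$lb[match("EX_glc__D_e", med$rxns$id)], 0)
  # O2 (non-carbon) untouched
  expect_equal(med$rxns$lb[match("EX_o2_e", med$rxns$id)], -1000)
  expect_identical(set_medium(med, c(EX_meoh_e = 10)), med)
  # empty mapping closes all carbon: no growth
  closed <- set_medium(m)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-9)
  expect_error(set_medium(m, c(NOPE = 5)), "not an exchange")
  expect_error(set_medium(m, c(GLYC = 5)), "not an exchange")
})

test_that("formula parsing and molar masses match hand-computed values", {
  expect_equal(adaptuc:::molar_mass("C6H12O6"),
               6 * 12.011 + 12 * 1.008 + 6 * 15.999, tolerance = 1e-12)
  expect_equal(adaptuc:::molar_mass("CO2"), 12.011 + 2 * 15.999)
  expect_true(is.na(adaptuc:::molar_mass("C10H12R2")))   # R-group
  expect_true(adaptuc:::contains_carbon("CH4O"))
  # Ca is calcium, not carbon
  expect_false(adaptuc:::contains_carbon("CaCl2"))
  expect_false(adaptuc:::contains_carbon("H2O"))
})
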