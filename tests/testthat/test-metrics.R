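# requirement checks, SADF, UC/Co, curves, producibility

test_that("requirement reports match hand LP solutions per variant", {
  toy <- make_toy(toy_spec(0.1))
  ref <- reference_state(toy$model, toy$config)
  expect_equal(ref$v0bio_uc, 0)
  expect_equal(ref$v0bio_cosub, 10)

  rep <- check_requirements(toy$model, "rQ1", toy$config, ref)
  expect_equal(rep$v1bio, 0); expect_equal(rep$v2bio, 0)
  expect_gte(rep$v3bio, 10 - 1e-8)
  expect_true(rep$req1_pass && rep$req2_pass && rep$req3_pass)

  # the reference strain trivially violates the dependence requirement
  rep0 <- check_requirements(toy$model, character(0), toy$config, ref)
  expect_false(rep0$req2_pass)
  expect_true(rep0$req1_pass && rep0$req3_pass)

  # removing the P route kills requirement 3
  repP <- check_requirements(toy$model, "rP", toy$config, ref)
  expect_false(repP$req3_pass)

  # variant B demands retained growth on the UC alone
  tb <- make_toy(toy_spec(0.25, include_uc_only_route = TRUE))
  rb <- check_requirements(tb$model, "rQ1", tb$config)
  expect_true(rb$req1_pass)
  rb2 <- check_requirements(tb$model, c("rQ1", "rMA"), tb$config)
  expect_false(rb2$req1_pass)  # UC route cut: no growth on the UC alone
})

test_that("minimal UC uptake matches the closed form and edge cases", {
  toy <- make_toy(toy_spec(0.1))
  expect_equal(minimal_uc_uptake(toy$model, "rQ1", 10, toy$config), 0.5,
               tolerance = 1e-8)   # phi * g / 2
  expect_equal(minimal_uc_uptake(toy$model, character(0), 10, toy$config), 0,
               tolerance = 1e-9)   # cosubstrate suffices for the reference
  out <- minimal_uc_uptake(toy$model, "rQ1", 1e6, toy$config)
  expect_true(is.na(out))
  expect_identical(attr(out, "status"), "infeasible")
})

test_that("SADF and UC/Co report degenerate cases distinctly", {
  toy <- make_toy(toy_spec(0.5))
  # no coupling without a knockout: SADF undefined, not zero
  s0 <- sadf(toy$model, character(0), toy$config)
  expect_true(is.na(s0))
  expect_identical(attr(s0, "status"), "no_coupling")
  # requirement-passing strategies have finite positive metrics
  s <- sadf(toy$model, "rQ1", toy$config)
  u <- ucco_ratio(toy$model, "rQ1", toy$config)
  v <- minimal_uc_uptake(toy$model, "rQ1", 10, toy$config)
  expect_gt(s, 0); expect_gt(u, 0); expect_gt(v, 0)
})

test_that("growth/UC curves are monotone with the analytic slope", {
  toy <- make_toy(toy_spec(0.4))
  growth <- seq(0, 10, by = 2.5)
  curve <- growth_uc_curve(toy$model, "rQ1", cosub_uptakes = 10,
                           growth_grid = growth, config = toy$config)
  expect_equal(nrow(curve), length(growth))
  expect_equal(curve$uc_min[curve$growth == 0], 0)
  expect_true(all(diff(curve$uc_min) >= -1e-8))
  # slope d(UC)/d(growth) = phi/2 everywhere on this toy
  slopes <- diff(curve$uc_min) / diff(curve$growth)
  expect_equal(slopes, rep(0.4 / 2, length(slopes)), tolerance = 1e-7)
  # curve at the reference growth target equals minimal_uc_uptake there
  expect_equal(curve$uc_min[curve$growth == 10],
               minimal_uc_uptake(toy$model, "rQ1", 10, toy$config),
               tolerance = 1e-8)
  # empty grids give an empty table
  empty <- growth_uc_curve(toy$model, "rQ1", numeric(0), numeric(0),
                           toy$config)
  expect_equal(nrow(empty), 0)
  # variant-B toy grows from the UC alone: finite positive curve at cosub 0
  tb <- make_toy(toy_spec(0.25, include_uc_only_route = TRUE))
  cb <- growth_uc_curve(tb$model, "rQ1", cosub_uptakes = 0,
                        growth_grid = c(1, 2), config = tb$config)
  expect_true(all(is.finite(cb$uc_min) & cb$uc_min > 0))
})

test_that("precursor producibility yields the coupling fraction phi", {
  toy <- make_toy(toy_spec(0.3))
  pp <- precursor_producibility(toy$model, "rQ1", toy$config)
  expect_identical(pp$mass_basis, "mass")
  expect_false(pp$precursors$producible[pp$precursors$metabolite == "Q"])
  expect_true(pp$precursors$producible[pp$precursors$metabolite == "P"])
  expect_equal(pp$coupling_fraction, 0.3, tolerance = 1e-9)
  expect_identical(pp$coupling_class, "intermediate")
  # no knockout: everything producible, zero coupling
  pp0 <- precursor_producibility(toy$model, character(0), toy$config)
  expect_true(all(pp0$precursors$producible))
  expect_identical(pp0$coupling_class, "minimal")
  # phi = 1: single precursor, nothing producible -> full coupling
  t1 <- make_toy(toy_spec(1))
  pp1 <- precursor_producibility(t1$model, "rQ1", t1$config)
  expect_identical(pp1$coupling_class, "full")
  expect_equal(pp1$coupling_fraction, 1)
  # minimal-coupling boundary: phi = 0.1 classes as minimal
  tm <- make_toy(toy_spec(0.1))
  expect_identical(
    precursor_producibility(tm$model, "rQ1", tm$config)$coupling_class,
    "minimal")
  # grouping is a presentation-layer aggregation
  ppg <- precursor_producibility(toy$model, "rQ1", toy$config,
                                 groups = list(all = c("P", "Q")))
  expect_equal(ppg$groups$mass_fraction, 1, tolerance = 1e-9)
  expect_false(ppg$groups$producible)
})

test_that("missing formulas fall back to coefficient weights with a warning", {
  toy <- make_toy(toy_spec(0.3))
  toy$model$mets$formula[] <- NA_character_
  expect_warning(
    pp <- precursor_producibility(toy$model, "rQ1", toy$config),
    "coefficient-weight")
  expect_identical(pp$mass_basis, "coefficient")
  # unit coefficients: fraction still equals phi
  expect_equal(pp$coupling_fraction, 0.3, tolerance = 1e-9)
})

test_that("strategy_score assembles a coherent record", {
  toy <- make_toy(toy_spec(0.2))
  sc <- strategy_score(toy$model, "rQ1", toy$config)
  expect_equal(sc$sadf, 2 / 0.2, tolerance = 1e-6)
  expect_equal(sc$ucco, 0.2 / (2 - 0.2), tolerance = 1e-6)
  expect_equal(sc$coupling_fraction, 0.2, tolerance = 1e-9)
  expect_true(sc$requirements$req1_pass && sc$requirements$req2_pass &&
                sc$requirements$req3_pass)
})
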