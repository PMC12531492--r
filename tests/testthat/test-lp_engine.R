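# FBA primitives: optimality, feasibility reporting, knockouts, FVA

test_that("FBA reproduces hand-solved toy optima and honours mass balance", {
  for (phi in c(1, 0.5, 0.1)) {
    toy <- make_toy(toy_spec(phi))
    fs <- solve_fba(set_medium(toy$model, c(EX_A = 10)))
    expect_identical(fs$status, "optimal")
    # unit uptake-to-growth yield: growth equals the uptake bound
    expect_equal(fs$objective_value, 10, tolerance = 1e-8)
    expect_lte(fs$residual, 1e-6)
    expect_true(all(fs$fluxes >= toy$model$rxns$lb - 1e-9 &
                      fs$fluxes <= toy$model$rxns$ub + 1e-9))
  }
})

test_that("degenerate and infeasible cases are reported faithfully", {
  toy <- make_toy(toy_spec(0.5))
  # all exchanges closed: zero flux is optimal
  closed <- set_medium(toy$model)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-12)
  expect_identical(solve_fba(closed)$status, "optimal")
  # contradictory injected bounds
  ov <- list(rP = c(5, 5), EX_A = c(0, 0))
  fs <- solve_fba(toy$model, bound_overrides = ov)
  expect_identical(fs$status, "infeasible")
})

test_that("knockouts zero out reactions without touching the input model", {
  toy <- make_toy(toy_spec(0.5))
  m0 <- toy$model
  m1 <- apply_knockouts(m0, "rQ1")
  expect_equal(m1$rxns$ub[match("rQ1", m1$rxns$id)], 0)
  expect_equal(m0$rxns$ub[match("rQ1", m0$rxns$id)], 1000)  # untouched
  expect_identical(apply_knockouts(m0, character(0)), m0)
  # Q only reachable through M after the deletion: no growth on A alone
  g <- solve_fba(set_medium(m0, c(EX_A = 10)), knockouts = "rQ1")
  expect_equal(g$objective_value, 0, tolerance = 1e-9)
  # deleting biomass kills growth in every medium
  for (med in list(c(EX_A = 10), c(EX_M = 10), c(EX_A = 10, EX_M = 10))) {
    g <- solve_fba(set_medium(m0, med), knockouts = "biomass")
    expect_equal(g$objective_value, 0, tolerance = 1e-12)
  }
  expect_error(apply_knockouts(m0, "nope"), "unknown reaction")
})

test_that("knockout-set growth is sub-additive (union dominated by parts)", {
  toy <- make_toy(toy_spec(0.3, include_leak_route = TRUE, q_route = "serial"))
  med <- set_medium(toy$model, c(EX_A = 10, EX_M = 10))
  g <- function(ko) solve_fba(med, knockouts = ko)$objective_value
  sets <- list(c("rQ1a"), c("rQL"), c("rP"), c("rQ1b", "rQL"))
  for (a in sets) for (b in sets) {
    expect_lte(g(union(a, b)), min(g(a), g(b)) + 1e-7)
  }
})

test_that("reference growth is monotone non-decreasing in uptake", {
  toy <- make_toy(toy_spec(0.25))
  g <- vapply(c(0, 1, 5, 10, 20), function(u) {
    reference_growth(toy$model, "EX_A", u)
  }, 0)
  expect_equal(g[1], 0, tolerance = 1e-9)
  expect_true(all(diff(g) >= -1e-8))
  # substrate with no route to biomass supports no growth
  expect_equal(reference_growth(toy$model, "EX_M", 10), 0, tolerance = 1e-9)
})

test_that("flux variability flags structurally blocked reactions", {
  toy <- make_toy(toy_spec(0.5, decoys = 2, seed = 3))
  m <- set_medium(toy$model, c(EX_A = 10, EX_M = 10))
  fva <- flux_variability(m, c("rDEC1", "rDEC2", "rP", "EX_M"))
  dec <- fva[fva$id %in% c("rDEC1", "rDEC2"), ]
  expect_true(all(abs(dec$min) < 1e-9 & abs(dec$max) < 1e-9))
  # max rP: all growth routed through the P side; with Q made by the 1:1
  # condensation, growth = 10/(1 - phi/2) and rP = (1 - phi)*growth
  expect_equal(fva$max[fva$id == "rP"], 10 * (1 - 0.5) / (1 - 0.5 / 2),
               tolerance = 1e-8)
  # a closed exchange cannot run in the uptake direction
  closed <- set_medium(toy$model, c(EX_A = 10))
  fva2 <- flux_variability(closed, "EX_M")
  expect_gte(fva2$min, 0)
})

test_that("parsimonious refit keeps the objective and trims total flux", {
  toy <- make_toy(toy_spec(0.5, include_leak_route = TRUE))
  med <- set_medium(toy$model, c(EX_A = 10, EX_M = 10))
  plain <- solve_fba(med)
  pfba <- solve_fba(med, pfba = TRUE)
  expect_true(pfba$parsimonious)
  expect_equal(pfba$objective_value, plain$objective_value, tolerance = 1e-6)
  expect_lte(sum(abs(pfba$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
  # TSV export round-trips the flux table
  path <- tempfile(fileext = ".tsv")
  write_flux_tsv(pfba, med, path)
  tab <- read.delim(path)
  expect_identical(tab$id, med$rxns$id)
  expect_equal(tab$flux, unname(pfba$fluxes))
})
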