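# Shared fixtures: toy networks are generated in code, never stored.

toy_candidates <- function(toy) {
  setdiff(reaction_ids(toy$model),
          c(toy$model$biomass_id, toy$config$uc_exchange,
            toy$config$cosub_exchange))
}

# a small glycolysis-flavoured network with BiGG-style ids, enough structure
# for pathway insertion and preprocessing tests
mini_ecoli <- function() {
  mets <- data.frame(
    id = c("glc__D_e", "glc__D_c", "f6p_c", "ru5p__D_c", "co2_c", "o2_e",
           "pyr_c", "nad_c", "nadh_c", "h_c", "for_c"),
    compartment = c("e", "c", "c", "c", "c", "e", "c", "c", "c", "c", "c"),
    formula = c("C6H12O6", "C6H12O6", "C6H11O9P", "C5H9O8P", "CO2", "O2",
                "C3H3O3", "C21H26N7O14P2", "C21H27N7O14P2", "H", "CHO2"),
    stringsAsFactors = FALSE)
  rx <- list(
    reaction("EX_glc__D_e", c(glc__D_e = -1), lb = -10, ub = 1000),
    reaction("EX_o2_e", c(o2_e = -1), lb = -1000, ub = 1000),
    reaction("GLCt", c(glc__D_e = -1, glc__D_c = 1), lb = -1000, ub = 1000,
             gene_rule = "ptsG"),
    reaction("HEX", c(glc__D_c = -1, f6p_c = 1), gene_rule = "pgi"),
    reaction("PPP", c(f6p_c = -5, ru5p__D_c = 6), gene_rule = "zwf",
             subsystem = "Pentose Phosphate Pathway"),
    reaction("GLYC", c(f6p_c = -1, pyr_c = 2, nad_c = -2, nadh_c = 2, h_c = 2),
             gene_rule = "gapA"),
    reaction("PFL", c(pyr_c = -1, for_c = 1), gene_rule = "pflB"),
    reaction("RESP", c(nadh_c = -1, nad_c = 1, h_c = -1), gene_rule = "nuo"),
    reaction("CFIX", c(co2_c = -1, pyr_c = -1, f6p_c = 0.5), lb = -1000,
             gene_rule = "fix"),
    reaction("EX_co2_c", c(co2_c = -1), lb = -1000, ub = 1000),
    reaction("BIOMASS_mini", c(pyr_c = -1, ru5p__D_c = -0.1)))
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
  metabolic_model(mets, rxns, S, biomass_id = "BIOMASS_mini")
}

expect_model_equal <- function(a, b) {
  expect_identical(a$rxns$id, b$rxns$id)
  expect_identical(a$mets$id, b$mets$id)
  expect_equal(a$rxns$lb, b$rxns$lb)
  expect_equal(a$rxns$ub, b$rxns$ub)
  expect_equal(as.matrix(a$S), as.matrix(b$S), ignore_attr = TRUE)
  expect_identical(a$biomass_id, b$biomass_id)
}
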