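#!/usr/bin/env Rscript
# C. glutamicum case study on iCW773: keeping the rpi (ribose-5-phosphate
# isomerase) deletion but swapping the xylose cosubstrate for a decoupling
# one (succinate, acetate, pyruvate, ...) should raise SADF about 5.2-fold
# and cut UC/Co by about 91 %.
#
# iCW773 is not hosted on BiGG; supply a local BiGG-style JSON export:
#   Rscript scripts/reproduce_cglutamicum.R --model path/to/iCW773.json

suppressPackageStartupMessages(library(adaptuc))

reproduce_cglutamicum <- function(model_path,
                                  rpi_id = "RPI",
                                  xylose_exchange = "EX_xyl__D_e",
                                  alt_exchanges = c("EX_succ_e", "EX_ac_e",
                                                    "EX_pyr_e", "EX_glu__L_e",
                                                    "EX_fru_e", "EX_glyc_e",
                                                    "EX_rib__D_e")) {
  model <- load_model(model_path, dialect = "bigg-json")
  model <- add_pathway(model, rump_pathway())
  model <- apply_preprocessing(model, "cglutamicum")

  score <- function(cosub) {
    cfg <- design_config("EX_meoh_e", cosub, variant = "A", K = 5)
    sc <- strategy_score(model, rpi_id, cfg, producibility = FALSE)
    c(sadf = sc$sadf, ucco = sc$ucco)
  }
  base <- score(xylose_exchange)
  alts <- do.call(rbind, lapply(intersect(alt_exchanges, model$rxns$id), score))
  best <- alts[which.max(alts[, "sadf"]), ]
  list(xylose = base, best_alternative = best,
       sadf_ratio = unname(best["sadf"] / base["sadf"]),
       ucco_reduction = unname(1 - best["ucco"] / base["ucco"]))
}

if (sys.nframe() == 0L) {
  args <- commandArgs(trailingOnly = TRUE)
  if (length(args) < 2 || args[[1]] != "--model") {
    stop("usage: Rscript scripts/reproduce_cglutamicum.R --model iCW773.json")
  }
  res <- reproduce_cglutamicum(args[[2]])
  cat(sprintf("xylose + delta-rpi:        SADF %6.2f  UC/Co %7.4f\n",
              res$xylose["sadf"], res$xylose["ucco"]))
  cat(sprintf("best alt cosubstrate:      SADF %6.2f  UC/Co %7.4f\n",
              res$best_alternative["sadf"], res$best_alternative["ucco"]))
  cat(sprintf("SADF improvement: %.1f-fold;  UC/Co reduction: %.0f %%\n",
              res$sadf_ratio, 100 * res$ucco_reduction))
}
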