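#!/usr/bin/env Rscript
# Reproduce the E. coli methylotrophy case study numbers on iML1515:
#   gluconate cosubstrate, delta FBA / RPE / F6PA  -> SADF ~24.9, UC/Co ~0.001
#   pyruvate  cosubstrate, delta FBA / F6PA        -> SADF ~11.9, UC/Co ~0.027
# plus the producibility analysis of the gluconate strategy (the cell-
# envelope precursor group, ~5.48 wt% of biomass, is the only one not
# producible from gluconate alone).
#
# Requires the iML1515 BiGG JSON (~6 MB), downloaded on demand:
#   Rscript scripts/reproduce_ecoli.R [--model path/to/iML1515.json]

suppressPackageStartupMessages(library(adaptuc))

args <- commandArgs(trailingOnly = TRUE)
model_path <- if (length(args) >= 2 && args[[1]] == "--model") args[[2]] else NULL
if (is.null(model_path)) {
  model_path <- file.path(Sys.getenv("HOME"), ".cache", "adaptuc",
                          "iML1515.json")
  if (!file.exists(model_path)) {
    dir.create(dirname(model_path), showWarnings = FALSE, recursive = TRUE)
    message("downloading iML1515 from the BiGG model repository ...")
    utils::download.file("http://bigg.ucsd.edu/static/models/iML1515.json",
                         model_path, quiet = TRUE)
  }
}

model <- load_model(model_path, dialect = "bigg-json")
message("iML1515: ", nrow(model$rxns), " reactions")
model <- add_pathway(model, rump_pathway())
model <- apply_preprocessing(model, "ecoli")

evaluate <- function(cosub_exchange, variant, knockouts) {
  cfg <- design_config("EX_meoh_e", cosub_exchange, variant = variant, K = 5)
  sc <- strategy_score(model, knockouts, cfg, producibility = FALSE)
  cat(sprintf("%-12s  %-18s  SADF %6.2f   UC/Co %7.4f\n",
              sub("^EX_", "", cosub_exchange),
              paste(knockouts, collapse = "+"), sc$sadf, sc$ucco))
  sc
}

cat("\n-- fixed-strategy evaluation --------------------------------------\n")
sc1 <- evaluate("EX_glcn_e", "A", c("FBA", "RPE", "F6PA"))
sc2 <- evaluate("EX_pyr_e", "B", c("FBA", "F6PA"))

cat("\n-- producibility, gluconate strategy ------------------------------\n")
cfg <- design_config("EX_meoh_e", "EX_glcn_e", variant = "A", K = 5)
pp <- precursor_producibility(model, c("FBA", "RPE", "F6PA"), cfg)
nonprod <- pp$precursors[!pp$precursors$producible, ]
cat("non-producible precursors from gluconate alone:\n")
print(nonprod[, c("metabolite", "mass_fraction")], row.names = FALSE)
cat(sprintf("coupled biomass mass fraction: %.2f %% (%s coupling)\n",
            100 * pp$coupling_fraction, pp$coupling_class))
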