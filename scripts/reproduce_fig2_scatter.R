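#!/usr/bin/env Rscript
# Full design-space scatter for methylotrophic E. coli: enumerate knockout
# designs (K <= 5) on iML1515 + RuMP for ten cosubstrates and tabulate
# SADF against UC/Co for every verified design.  Long-running (hours at
# genome scale); intended for a networked workstation, not the test suite.
#
#   Rscript scripts/reproduce_fig2_scatter.R [--model iML1515.json]
#                                            [--out scatter.tsv]
#                                            [--max-per-cosub 12]

suppressPackageStartupMessages(library(adaptuc))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(model = NULL, out = "scatter.tsv", max_per_cosub = 12L)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[[i]])
  opt[[gsub("-", "_", key)]] <- args[[i + 1L]]
  i <- i + 2L
}
if (is.null(opt$model)) {
  opt$model <- file.path(Sys.getenv("HOME"), ".cache", "adaptuc",
                         "iML1515.json")
  if (!file.exists(opt$model)) {
    dir.create(dirname(opt$model), showWarnings = FALSE, recursive = TRUE)
    utils::download.file("http://bigg.ucsd.edu/static/models/iML1515.json",
                         opt$model, quiet = TRUE)
  }
}

cosubs <- c(succinate = "EX_succ_e", fructose = "EX_fru_e",
            glucose = "EX_glc__D_e", acetate = "EX_ac_e",
            glutamate = "EX_glu__L_e", glycerol = "EX_glyc_e",
            glycerate = "EX_glyc__R_e", pyruvate = "EX_pyr_e",
            xylulose = "EX_xylu__L_e", ribose = "EX_rib__D_e")

model <- load_model(opt$model, dialect = "bigg-json")
model <- add_pathway(model, rump_pathway())
model <- apply_preprocessing(model, "ecoli")

rows <- list()
for (nm in names(cosubs)) {
  ex <- cosubs[[nm]]
  if (!ex %in% model$rxns$id) { message("skipping ", nm, ": no ", ex); next }
  for (variant in c("A", "B")) {
    cfg <- design_config("EX_meoh_e", ex, variant = variant, K = 5)
    trace <- candidate_knockouts(model, cfg)
    message(nm, " (", variant, "): ", length(trace$final_candidates),
            " candidates")
    fm <- build_milp(model, cfg, trace$final_candidates)
    sols <- enumerate_designs(fm, max_solutions = as.integer(opt$max_per_cosub),
                              time_limit = 600)
    for (s in Filter(function(s) s$verified, sols)) {
      u <- ucco_ratio(model, s$knockouts, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        cosubstrate = nm, variant = variant,
        knockouts = paste(s$knockouts, collapse = ","),
        sadf = s$objective_sadf, ucco = as.numeric(u),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      utils::write.table(do.call(rbind, rows), opt$out, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
}
message("wrote ", length(rows), " designs to ", opt$out)
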