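#!/usr/bin/env Rscript
# The 13 phenotypes: semantic clusters + rule-based Cluster-1 split +
# geometric Cluster-0 periphery sectors; Table-3/4-style report.

source("analysis/00_config.R")
per <- data.table::fread(file.path(RESULTS_DIR, "periods.csv"))
pnights <- data.table::fread(file.path(RESULTS_DIR, "period_nights.csv"))
emb <- data.table::fread(file.path(RESULTS_DIR, "landscape_embedding.csv"))
params <- jsonlite::read_json(file.path(RESULTS_DIR, "landscape_params.json"))

stopifnot(identical(per$period_id, emb$period_id))
fake_landscape <- structure(
  list(embedding = as.matrix(emb[, .(x, y)]), cluster = emb$dbscan_id,
       was_noise = emb$was_noise, params = params),
  class = "sleep_landscape")

lab <- assign_phenotypes(per, fake_landscape)
data.table::fwrite(lab, file.path(RESULTS_DIR, "periods_labelled.csv"))

rep <- phenotype_report(lab, pnights)
data.table::fwrite(rep, file.path(RESULTS_DIR, "phenotype_report.csv"))

message("periods per phenotype:")
print(table(lab$subcluster))
message(sprintf("insomnia-like share: %.1f%%; recommended share: %.1f%%",
                100 * mean(lab$is_insomnia_like), 100 * mean(lab$is_recommended)))
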