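#!/usr/bin/env Rscript
# Nightly features -> non-overlapping 3-6-night sleep periods with the
# 18-dimensional feature vector, under the exclusion criteria.

source("analysis/00_config.R")
nf <- data.table::fread(file.path(RESULTS_DIR, "night_features.csv"))
nf[, night_date := as.Date(night_date)]

out <- assemble_periods(nf)
data.table::fwrite(out$periods, file.path(RESULTS_DIR, "periods.csv"))
data.table::fwrite(out$nights, file.path(RESULTS_DIR, "period_nights.csv"))

message(sprintf("kept %d periods (%.2f per individual); dropped %d too-few-nights, %d non-wear",
                nrow(out$periods),
                nrow(out$periods) / length(unique(out$periods$individual_id)),
                out$dropped[["too_few_nights"]], out$dropped[["nonwear"]]))
message(sprintf("night counts: %s",
                paste(names(table(out$periods$n_nights)),
                      table(out$periods$n_nights), sep = "=", collapse = " ")))
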