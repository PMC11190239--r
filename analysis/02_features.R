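#!/usr/bin/env Rscript
# Nights -> windows -> nine nightly features, for the whole cohort.
#
# Individuals are processed in batches (the epoch-level data for the full
# cohort never needs to be in memory at once). Reports a Table-2-style
# population summary of the nightly features.

source("analysis/00_config.R")
cfg <- study_config()
truth <- generate_truth(cfg)

batches <- split(truth$individual_ids, ceiling(seq_along(truth$individual_ids) / 50))
nf <- data.table::rbindlist(lapply(batches, function(ids) {
  pop <- generate_population(cfg, truth, individuals = ids)
  compute_night_features(filter_nights(pop$nights))
}))
data.table::fwrite(nf, file.path(RESULTS_DIR, "night_features.csv"))

feat <- nf[, sleepscape:::NIGHT_FEATURES, with = FALSE]
summ <- data.table::data.table(
  feature = names(feat),
  mean = vapply(feat, mean, numeric(1)),
  sd = vapply(feat, stats::sd, numeric(1)))
# length features conditional on the window kind being present
summ[feature == "lw_length", `:=`(mean = mean(nf$lw_length[nf$lw_count > 0]),
                                  sd = stats::sd(nf$lw_length[nf$lw_count > 0]))]
summ[feature == "sw_length", `:=`(mean = mean(nf$sw_length[nf$sw_count > 0]),
                                  sd = stats::sd(nf$sw_length[nf$sw_count > 0]))]
data.table::fwrite(summ, file.path(RESULTS_DIR, "nightly_feature_summary.csv"))

message(sprintf("featurized %d nights; mean sleep percent %.3f, mean ST long %.2f h",
                nrow(nf), mean(nf$sleep_percent), mean(nf$st_long)))
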