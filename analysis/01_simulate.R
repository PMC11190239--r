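#!/usr/bin/env Rscript
# Simulate the synthetic study cohort and write the interchange files.
#
# The full cohort is regenerated deterministically by later scripts from
# the shared config; here we record the survey/symptom tables, the latent
# truth, and a small hypnogram CSV excerpt (10 individuals) in the
# long-format interchange dialect.

source("analysis/00_config.R")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config()
truth <- generate_truth(cfg)
labs <- truth_night_labels(truth)

message(sprintf("cohort: %d individuals x %d nights, %d archetypes",
                cfg$n_individuals, cfg$n_nights, length(cfg$archetypes)))
message(sprintf("missing nights: %.1f%% (configured %.0f%%)",
                100 * mean(labs$missing), 100 * cfg$missing_night_prob))
message(sprintf("chronic positives: %d; acute reports: %d",
                sum(truth$survey$response == "positive"), nrow(truth$symptoms)))

data.table::fwrite(truth$survey, file.path(RESULTS_DIR, "survey.csv"))
data.table::fwrite(truth$symptoms, file.path(RESULTS_DIR, "symptoms.csv"))
data.table::fwrite(labs, file.path(RESULTS_DIR, "latent_truth.csv"))

excerpt <- generate_population(cfg, truth,
                               individuals = truth$individual_ids[1:10])
files <- write_population_csv(excerpt, file.path(RESULTS_DIR, "excerpt"))
message("wrote interchange excerpt: ", paste(basename(files), collapse = ", "))
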