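#!/usr/bin/env Rscript
# Chronic and acute cohort comparisons: chi-square and information gain
# of the static (phenotype membership) vs dynamic (transition) models.

source("analysis/00_config.R")
lab <- data.table::fread(file.path(RESULTS_DIR, "periods_labelled.csv"))
lab[, start_date := as.Date(start_date)]
pairs <- data.table::fread(file.path(RESULTS_DIR, "transition_pairs.csv"))
pairs[, `:=`(from_start = as.Date(from_start), to_start = as.Date(to_start))]
survey <- data.table::fread(file.path(RESULTS_DIR, "survey.csv"))
symptoms <- data.table::fread(file.path(RESULTS_DIR, "symptoms.csv"))
symptoms[, report_date := as.Date(report_date)]

rows <- list()
for (eff in study_config()$condition_effects) {
  d <- cohort_design(eff$type, eff$condition)
  res <- static_vs_dynamic(lab, pairs, d, survey = survey,
                           symptoms = symptoms, pseudocount = 0.5)
  message(sprintf("%s (%s): chi2 %.1f (p=%.2e) static vs %.1f (p=%.2e) dynamic; IG %.4f -> %.4f bits (ratio %.2f)",
                  res$condition, res$mode,
                  res$chi_static$statistic, res$chi_static$p_value,
                  res$chi_dynamic$statistic, res$chi_dynamic$p_value,
                  res$ig_static, res$ig_dynamic, res$ig_ratio))
  rows[[eff$condition]] <- data.table::data.table(
    condition = res$condition, mode = res$mode,
    chi2_static = res$chi_static$statistic, p_static = res$chi_static$p_value,
    chi2_dynamic = res$chi_dynamic$statistic, p_dynamic = res$chi_dynamic$p_value,
    ig_static = res$ig_static, ig_dynamic = res$ig_dynamic,
    ig_ratio = res$ig_ratio)
}
data.table::fwrite(data.table::rbindlist(rows),
                   file.path(RESULTS_DIR, "health_comparison.csv"))
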