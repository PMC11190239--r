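#!/usr/bin/env Rscript
# Within-individual phenotype transitions and the CTP graph; grouped
# fractured-phenotype summaries with relative reductions.

source("analysis/00_config.R")
lab <- data.table::fread(file.path(RESULTS_DIR, "periods_labelled.csv"))
lab[, start_date := as.Date(start_date)]

pairs <- extract_transition_pairs(lab)
data.table::fwrite(pairs, file.path(RESULTS_DIR, "transition_pairs.csv"))
g <- build_ctp(pairs)
ctp <- data.table::as.data.table(g$ctp, keep.rownames = "from")
data.table::fwrite(ctp, file.path(RESULTS_DIR, "ctp_matrix.csv"))
cnt <- data.table::as.data.table(g$counts, keep.rownames = "from")
data.table::fwrite(cnt, file.path(RESULTS_DIR, "transition_counts.csv"))

message(sprintf("%d transition pairs over %d nodes; rows sum to one (max dev %.1e)",
                g$n_pairs, length(g$nodes),
                max(abs(rowSums(g$ctp[rowSums(g$counts) > 0, ]) - 1))))
if ("rec" %in% g$nodes)
  message(sprintf("P(stay recommended) = %.3f; P(return to recommended) = %.3f-%.3f",
                  g$ctp["rec", "rec"],
                  min(g$ctp[g$nodes != "rec", "rec"]),
                  max(g$ctp[g$nodes != "rec", "rec"])))

summ <- transition_summaries(g)
data.table::fwrite(summ, file.path(RESULTS_DIR, "transition_summaries.csv"))
for (i in seq_len(nrow(summ)))
  message(sprintf("  %s (%s-fractured): same %.3f, other %.3f (%.1f%% relative reduction)",
                  summ$from[i], summ$group[i], summ$p_same_group[i],
                  summ$p_other_group[i], summ$relative_reduction_pct[i]))
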