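# Shared study configuration for the analysis scripts.
#
# A synthetic cohort standing in for the proprietary wearable dataset:
# 200 individuals x 90 nights over all 13 phenotype archetypes, with
# realistic night-to-night variability (sd_scale = 1), 8% missing nights
# (matching the published 91.89% usable-night share), a chronic sleep-
# apnea-like effect that makes insomnia-like phenotypes stickier, and an
# acute flu-like effect that freezes dynamics for two weeks around the
# report.

library(sleepscape)

RESULTS_DIR <- "results/analysis"

study_config <- function(seed = 20200101 %% 100000) {
  arch <- c("rec", "0-A", "0-B", "0-C", "0-D", "0-E", "0-F",
            "1-a", "1-b", "1-c", "c2", "c3", "c4")
  K <- length(arch)
  # diagonal persistence plus strong pull back to recommended sleep, the
  # dominant pattern of the published transition heatmaps
  P <- matrix(0.02 / (K - 2), K, K)
  diag(P) <- 0.12
  P[, 1] <- 0.66
  P[1, 1] <- 0.78
  P <- P / rowSums(P)

  sticky <- P
  ins <- match(c("1-a", "1-b", "1-c", "c2", "c3", "c4"), arch)
  for (i in ins) {
    sticky[i, ] <- P[i, ] * 0.5
    sticky[i, i] <- sticky[i, i] + 0.5
  }
  sticky <- sticky / rowSums(sticky)

  frozen <- matrix(0.02 / (K - 1), K, K)
  diag(frozen) <- 0.98

  generator_config(
    archetypes = arch,
    transition_matrix = P,
    initial_distribution = stats::setNames(rep(1, K) / K, arch),
    n_individuals = 200L, n_nights = 90L,
    missing_night_prob = 0.08,
    condition_effects = list(
      condition_effect("sleep_apnea", "chronic", matrix = sticky,
                       prevalence = 0.10, no_answer_frac = 0.2),
      condition_effect("flu", "acute", matrix = frozen, n_affected = 50L)),
    sd_scale = 1, seed = seed)
}
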