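# Shared constants. Defined in one early-loading file because several
# modules use them at load time.

# Epochs are 30 s; all durations are hours as doubles.
EPOCH_SECONDS <- 30
EPOCHS_PER_HOUR <- 3600 / EPOCH_SECONDS

# The nine nightly sleep features, in frozen order (also the order of the
# first nine period-feature columns).
NIGHT_FEATURES <- c("sleep_percent", "st_long", "wt_long", "st_short",
                    "wt_short", "lw_count", "sw_count", "lw_length", "sw_length")

# The 18 period features: 9 means then 9 population SDs.
PERIOD_FEATURES <- c(paste0("mean_", NIGHT_FEATURES), paste0("sd_", NIGHT_FEATURES))

# The 13 phenotype labels, catalogue order.
PHENOTYPE_LEVELS <- c("rec", paste0("0-", LETTERS[1:6]),
                      "1-a", "1-b", "1-c", "2", "3", "4")
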