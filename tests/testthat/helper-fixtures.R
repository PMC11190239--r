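# Programmatic fixtures.

# Stage vector from a named run-length spec: stg(s = 960, w = 10, s = 120)
# gives sleep, wake, sleep runs (sleep epochs drawn as stage 1).
stg <- function(...) {
  runs <- c(...)
  unlist(lapply(seq_along(runs), function(i)
    rep(if (names(runs)[i] == "w") 0L else 1L, runs[i])), use.names = FALSE)
}

h2e <- function(h) as.integer(round(h * 120))

# One in-memory night row.
mk_night <- function(stages, id = "ind0001", date = as.Date("2020-01-01"),
                     onset_hour = 23, nonwear = 0) {
  data.table::data.table(
    individual_id = id, night_date = date,
    sleep_onset = as.POSIXct(paste(date - 1L, sprintf("%02d:00:00", onset_hour)),
                             tz = "UTC"),
    stages = list(stages), nonwear_hours = nonwear)
}

# Minimal night-feature rows for period-level tests (bypasses epochs).
mk_feature_night <- function(id, date, nonwear = 0, n_windows = 1L,
                             sleep_percent = 0.87, st_long = 7, wt_long = 1,
                             st_short = 0, wt_short = 0, lw_count = 1,
                             sw_count = 0, lw_length = 8, sw_length = 0) {
  data.table::data.table(
    individual_id = id, night_date = as.Date(date), nonwear_hours = nonwear,
    n_windows = n_windows, sleep_percent = sleep_percent, st_long = st_long,
    wt_long = wt_long, st_short = st_short, wt_short = wt_short,
    lw_count = lw_count, sw_count = sw_count, lw_length = lw_length,
    sw_length = sw_length)
}

# Period rows with composition flags, for classifier/dynamics tests.
mk_period <- function(id, start, any_multi_lw = FALSE, any_multi_sw = FALSE,
                      any_short_only = FALSE, any_long_short = FALSE,
                      all_short_only = FALSE, all_one_long = TRUE,
                      subcluster = NULL) {
  p <- data.table::data.table(
    individual_id = id, period_id = paste0(id, "#", start),
    start_date = as.Date(start), n_nights = 6L,
    any_multi_lw = any_multi_lw, any_multi_sw = any_multi_sw,
    any_short_only = any_short_only, any_long_short = any_long_short,
    all_short_only = all_short_only, all_one_long = all_one_long)
  if (!is.null(subcluster)) p$subcluster <- subcluster
  p
}

# Fake labelled periods from per-individual subcluster sequences.
mk_labelled_sequence <- function(sequences, start = as.Date("2020-01-01")) {
  data.table::rbindlist(lapply(names(sequences), function(id) {
    labs <- sequences[[id]]
    data.table::data.table(
      individual_id = id,
      period_id = paste0(id, "#", seq_along(labs)),
      start_date = start + 6L * (seq_along(labs) - 1L),
      subcluster = labs)
  }))
}

# High-level ground-truth cluster (0-4) per pipeline period, from the
# latent archetypes; valid when periods align with generator blocks
# (no missingness, nights from day one).
ARCHETYPE_CLUSTER <- c(rec = 0L, "0-A" = 0L, "0-B" = 0L, "0-C" = 0L,
                       "0-D" = 0L, "0-E" = 0L, "0-F" = 0L,
                       "1-a" = 1L, "1-b" = 1L, "1-c" = 1L,
                       c2 = 2L, c3 = 3L, c4 = 4L)

truth_high_level <- function(res) {
  labels <- truth_night_labels(res$truth)
  cfg <- res$truth$config
  blocks <- labels[, .(archetype = archetype[1]), by = .(individual_id, block_index)]
  blocks[, start_date := cfg$start_date + 6L * (block_index - 1L)]
  per <- data.table::as.data.table(res$periods)
  m <- blocks[per, on = c("individual_id", "start_date")]
  ARCHETYPE_CLUSTER[m$archetype]
}

random_stage_string <- function(n, p_sleep = NULL) {
  if (is.null(p_sleep)) p_sleep <- stats::runif(1, 0.2, 0.9)
  ifelse(stats::runif(n) < p_sleep, 1L, 0L)
}
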