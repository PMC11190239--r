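# Sleep periods: non-overlapping 3-6-night blocks and their 18 features.
#
# Candidate periods tile each individual's calendar in blocks of 6
# consecutive days, anchored at the first recorded night; gaps do not
# re-anchor, so period identity is deterministic. A block is kept if,
# after removing nights with no sleep windows, it still has >= 3 nights
# and no contiguous 3-day section accumulates >= 5 h of non-wear.

#' Tile nights into candidate 6-day blocks
#'
#' @param night_features data.table from [compute_night_features()] (one
#'   row per retained night; must contain `individual_id`, `night_date`).
#' @return The input with `period_id`, `block_start` and `day_slot`
#'   (0-5 offset within the block) added.
#' @export
build_candidate_periods <- function(night_features) {
  nf <- as.data.table(night_features)
  setorder(nf, individual_id, night_date)
  nf[, `:=`(
    block_index = {
      off <- as.integer(night_date - min(night_date))
      off %/% 6L
    },
    block_start = {
      off <- as.integer(night_date - min(night_date))
      min(night_date) + 6L * (off %/% 6L)
    }
  ), by = individual_id]
  nf[, day_slot := as.integer(night_date - block_start)]
  nf[, period_id := paste0(individual_id, "#", format(block_start))]
  nf[, block_index := NULL]
  nf[]
}

#' Apply the period exclusion criteria to one candidate block
#'
#' @param block data.table of one candidate period's nights (needs
#'   `n_windows`, `nonwear_hours`, `day_slot`).
#' @param max_nonwear_h Non-wear threshold per 3-day section (hours).
#' @param min_nights Minimum retained nights.
#' @return List: `keep` (logical), `reason` (NA or why dropped), `nights`
#'   (the block with zero-window nights removed).
#' @export
apply_exclusion_criteria <- function(block, max_nonwear_h = 5, min_nights = 3L) {
  block <- as.data.table(block)
  block <- block[block$n_windows > 0L, ]  # erroneous nights: no sleep windows
  if (nrow(block) < min_nights)
    return(list(keep = FALSE, reason = "too_few_nights", nights = block))
  nw <- numeric(6)
  nw[block$day_slot + 1L] <- block$nonwear_hours
  sections <- vapply(1:4, function(s) sum(nw[s:(s + 2L)]), numeric(1))
  if (any(sections >= max_nonwear_h))
    return(list(keep = FALSE, reason = "nonwear", nights = block))
  list(keep = TRUE, reason = NA_character_, nights = block)
}

#' 18-dimensional period feature vector
#'
#' Mean then population SD (divide by n) of each of the 9 zero-filled
#' nightly features over the block's nights, in the frozen order
#' `PERIOD_FEATURES` (9 means, then 9 SDs).
#'
#' @param block data.table of a kept period's nights.
#' @return Named numeric vector of length 18.
#' @export
period_features <- function(block) {
  x <- as.matrix(as.data.table(block)[, NIGHT_FEATURES, with = FALSE])
  m <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, m)^2))
  stats::setNames(c(m, sds), PERIOD_FEATURES)
}

#' Assemble sleep periods from nightly features
#'
#' Tiles candidate blocks, applies the exclusion criteria, and computes
#' the 18 period features plus the night-composition flags used by the
#' rule-based phenotype classifier.
#'
#' @param night_features data.table from [compute_night_features()].
#' @param max_nonwear_h,min_nights Exclusion thresholds.
#' @return List with `periods` (one row per kept period: key columns, the
#'   18 features, composition flags) and `nights` (retained nights with
#'   their `period_id`), plus a drop-reason tally in `dropped`.
#' @export
assemble_periods <- function(night_features, max_nonwear_h = 5, min_nights = 3L) {
  nf <- build_candidate_periods(night_features)
  keep_rows <- list(); rows <- list(); reasons <- character()
  for (blk in split(nf, by = "period_id", sorted = TRUE)) {
    res <- apply_exclusion_criteria(blk, max_nonwear_h, min_nights)
    if (!res$keep) { reasons <- c(reasons, res$reason); next }
    b <- res$nights
    fv <- period_features(b)
    rows[[length(rows) + 1L]] <- data.table(
      individual_id = b$individual_id[1], period_id = b$period_id[1],
      start_date = b$block_start[1], n_nights = nrow(b),
      t(fv),
      any_multi_lw = any(b$lw_count > 1),
      any_multi_sw = any(b$sw_count > 1),
      any_short_only = any(b$lw_count == 0 & b$sw_count >= 1),
      any_long_short = any(b$lw_count >= 1 & b$sw_count >= 1),
      all_short_only = all(b$lw_count == 0 & b$sw_count >= 1),
      all_one_long = all(b$lw_count == 1 & b$sw_count == 0))
    keep_rows[[length(keep_rows) + 1L]] <- b
  }
  periods <- if (length(rows)) rbindlist(rows) else NULL
  nights <- if (length(keep_rows)) rbindlist(keep_rows) else NULL
  list(periods = periods, nights = nights,
       dropped = table(factor(reasons, levels = c("too_few_nights", "nonwear"))))
}
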