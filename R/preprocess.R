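# Night filtering, sleep-window construction, and nightly features.
#
# A night is a 30-s stage series between device-predicted sleep onset and
# wake onset. Stage 0 is wake; stages 1-3 (light/deep/REM) are collapsed
# to sleep. Windows are built by four ordered rules:
#   (a) wake runs  < 10 min -> sleep        (suppress spurious wake)
#   (b) sleep runs < 10 min -> wake         (suppress spurious sleep)
#   (c) sleep segments separated by < 60 min of contiguous wake merge into
#       one window; separations of >= 60 min split windows
#   (d) windows shorter than 3 h are "short", the rest "long"
# Sleep/wake time within each window is computed from the ORIGINAL
# (pre-smoothing) stage labels over the window's span.

#' Assign a night to a calendar day
#'
#' A night belongs to the calendar date of the midnight nearest its sleep
#' onset (i.e. onsets within 12 h before or after a midnight). Onsets at
#' exactly noon break toward the later date.
#'
#' @param onset POSIXct sleep onset (UTC).
#' @return Date vector.
#' @export
night_day <- function(onset) {
  as.Date(floor((as.numeric(onset) + 43200) / 86400), origin = "1970-01-01")
}

#' Filter artifact nights
#'
#' Removes nights that are empty or contain only wake predictions, and
#' nights shorter than 30 minutes that fall on the same calendar day (per
#' [night_day()]) as a longer night of the same individual (short
#' device-predicted "nights" overlapping a real night are artifactual).
#'
#' @param nights data.table with columns `individual_id`, `sleep_onset`
#'   (POSIXct) and `stages` (list of integer vectors).
#' @return The filtered data.table (possibly zero rows).
#' @export
filter_nights <- function(nights) {
  nights <- as.data.table(nights)
  if (!nrow(nights)) return(nights)
  n_epochs <- vapply(nights$stages, length, integer(1))
  any_sleep <- vapply(nights$stages, function(s) any(s != 0L), logical(1))
  nights <- nights[n_epochs > 0L & any_sleep]
  if (!nrow(nights)) return(nights)
  dur_h <- vapply(nights$stages, length, integer(1)) / EPOCHS_PER_HOUR
  day <- night_day(nights$sleep_onset)
  keep <- rep(TRUE, nrow(nights))
  grp <- split(seq_len(nrow(nights)), list(nights$individual_id, as.character(day)),
               drop = TRUE)
  for (idx in grp) {
    if (length(idx) < 2) next
    d <- dur_h[idx]
    keep[idx[d < 0.5 & d < max(d)]] <- FALSE
  }
  nights[keep]
}

#' Build long/short sleep windows from one night's stage series
#'
#' Applies the four window-construction rules in order (see file header).
#' Durations come from half-open epoch intervals; a window spanning epochs
#' `[s, e]` has length `(e - s + 1) * 30 s`.
#'
#' @param stages Integer stage vector (0 = wake, 1-3 = sleep).
#' @param smooth_min Rule (a)/(b) run-length threshold, minutes.
#' @param gap_min Rule (c) wake-gap threshold, minutes.
#' @param gap_rule `"lt"` (default): segments merge only when the gap is
#'   strictly below `gap_min`, so a gap of exactly 60 min splits.
#'   `"le"`: a gap of exactly `gap_min` still merges.
#' @param short_h Rule (d) short/long boundary, hours.
#' @return data.table with one row per window: `start_epoch`, `end_epoch`
#'   (1-based, inclusive), `length_h`, `sleep_time_h`, `wake_time_h`,
#'   `kind` ("long"/"short"). Zero rows if smoothing leaves no sleep.
#' @export
build_windows <- function(stages, smooth_min = 10, gap_min = 60,
                          gap_rule = c("lt", "le"), short_h = 3) {
  gap_rule <- match.arg(gap_rule)
  n <- length(stages)
  if (!n) return(empty_windows())
  smooth_e <- as.integer(round(smooth_min * 60 / EPOCH_SECONDS))
  gap_e <- as.integer(round(gap_min * 60 / EPOCH_SECONDS))

  wake <- stages == 0L
  # (a) short wake runs -> sleep (all runs at once, ends included)
  r <- rle(wake)
  r$values[r$values & r$lengths < smooth_e] <- FALSE
  wake <- inverse.rle(r)
  # (b) short sleep runs -> wake, on the updated series
  r <- rle(wake)
  r$values[!r$values & r$lengths < smooth_e] <- TRUE
  wake <- inverse.rle(r)

  r <- rle(wake)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(!r$values)  # sleep segments
  if (!length(seg)) return(empty_windows())

  # (c) merge segments across short wake gaps
  win_start <- starts[seg[1]]; win_end <- ends[seg[1]]
  out_s <- integer(); out_e <- integer()
  if (length(seg) > 1) for (k in seg[-1]) {
    gap <- starts[k] - win_end - 1L
    merges <- if (gap_rule == "lt") gap < gap_e else gap <= gap_e
    if (merges) {
      win_end <- ends[k]
    } else {
      out_s <- c(out_s, win_start); out_e <- c(out_e, win_end)
      win_start <- starts[k]; win_end <- ends[k]
    }
  }
  out_s <- c(out_s, win_start); out_e <- c(out_e, win_end)

  len_h <- epochs_to_hours(out_e - out_s + 1L)
  sleep_h <- vapply(seq_along(out_s), function(i)
    epochs_to_hours(sum(stages[out_s[i]:out_e[i]] != 0L)), numeric(1))
  data.table(start_epoch = out_s, end_epoch = out_e, length_h = len_h,
             sleep_time_h = sleep_h, wake_time_h = len_h - sleep_h,
             kind = ifelse(len_h < short_h, "short", "long"))
}

empty_windows <- function() {
  data.table(start_epoch = integer(), end_epoch = integer(),
             length_h = numeric(), sleep_time_h = numeric(),
             wake_time_h = numeric(), kind = character())
}

#' The nine nightly sleep features
#'
#' Feature order (frozen; also the first nine period-feature columns):
#' sleep_percent, st_long, wt_long, st_short, wt_short, lw_count,
#' sw_count, lw_length, sw_length. Sleep/wake times are hours SUMMED over
#' windows of a kind; lengths are MEAN window spans; features of an absent
#' window kind are zero-filled. Sleep percent is total sleep time across
#' all windows divided by the sleep-onset to wake-onset span.
#'
#' @param windows Output of [build_windows()] for the night.
#' @param span_h Hours from sleep onset to wake onset (the night span).
#' @return Named numeric vector of the 9 features.
#' @export
nightly_features <- function(windows, span_h) {
  if (span_h <= 0) stopf("night span must be positive (wake onset after sleep onset)")
  lw <- windows[windows$kind == "long", ]
  sw <- windows[windows$kind == "short", ]
  c(sleep_percent = sum(windows$sleep_time_h) / span_h,
    st_long = sum(lw$sleep_time_h), wt_long = sum(lw$wake_time_h),
    st_short = sum(sw$sleep_time_h), wt_short = sum(sw$wake_time_h),
    lw_count = nrow(lw), sw_count = nrow(sw),
    lw_length = if (nrow(lw)) mean(lw$length_h) else 0,
    sw_length = if (nrow(sw)) mean(sw$length_h) else 0)
}

#' Nightly features for a whole nights table
#'
#' Runs [build_windows()] and [nightly_features()] on every night. Nights
#' are expected to have passed [filter_nights()].
#'
#' @param nights data.table with `individual_id`, `night_date`, `stages`
#'   (list-column) and `nonwear_hours`; extra columns are carried through.
#' @param ... Passed to [build_windows()].
#' @return data.table: input columns minus `stages`, plus the 9 features
#'   and `n_windows`.
#' @export
compute_night_features <- function(nights, ...) {
  nights <- as.data.table(nights)
  feats <- matrix(0, nrow(nights), length(NIGHT_FEATURES),
                  dimnames = list(NULL, NIGHT_FEATURES))
  n_windows <- integer(nrow(nights))
  for (i in seq_len(nrow(nights))) {
    st <- nights$stages[[i]]
    w <- build_windows(st, ...)
    n_windows[i] <- nrow(w)
    if (nrow(w))
      feats[i, ] <- nightly_features(w, epochs_to_hours(length(st)))
  }
  out <- nights[, setdiff(names(nights), "stages"), with = FALSE]
  cbind(out, as.data.table(feats), data.table(n_windows = n_windows))
}
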