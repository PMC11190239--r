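# Phenotype archetypes: the generative night-architecture profiles behind
# the synthetic population. One archetype per sleep phenotype; parameter
# defaults are calibrated to the published per-subcluster feature profiles
# of the large wearable cohort this pipeline emulates (recommended
# monophasic sleep, six peripheral monophasic variants, three fragmented
# Cluster-1 variants, and the long+short, long+long and very-short-sleep
# phenotypes).

#' Built-in phenotype archetype catalogue
#'
#' Each archetype describes how the generator composes a night for that
#' phenotype: a mixture over night structures (`one_long`, `long_short`,
#' `long_long`, `short_only1`, `short_only2`) plus window-length and
#' sleep-percentage targets (mean and SD, hours / fraction). `signature`
#' names night structures that are forced at the start of every 6-night
#' block so that an sd-0 block carries the phenotype's defining structure
#' deterministically.
#'
#' @return Named list of archetype definitions (class `phenotype_archetype`).
#' @export
#' @examples
#' names(sleep_archetypes())
#' sleep_archetypes()[["rec"]]$lw_length_h
sleep_archetypes <- function() {
  mono <- function(name, sp, sp_sd, lw, lw_sd) {
    phenotype_archetype(
      name = name,
      night_types = c(one_long = 1),
      sleep_percent = c(sp, sp_sd),
      lw_length_h = c(lw, lw_sd),
      sw_length_h = c(NA_real_, NA_real_)
    )
  }
  out <- list(
    # central + peripheral monophasic phenotypes: one long window per night
    rec     = mono("rec", 0.870, 0.045, 8.087, 0.842),
    `0-A` = mono("0-A", 0.919, 0.017, 7.702, 0.406),
    `0-B` = mono("0-B", 0.876, 0.016, 7.479, 0.347),
    `0-C` = mono("0-C", 0.921, 0.017, 9.037, 0.436),
    `0-D` = mono("0-D", 0.872, 0.022, 9.745, 0.484),
    `0-E` = mono("0-E", 0.844, 0.031, 7.565, 0.657),
    `0-F` = mono("0-F", 0.789, 0.046, 8.845, 0.921),
    `1-a` = phenotype_archetype(
      name = "1-a",
      night_types = c(one_long = 0.8, short_only1 = 0.2),
      signature = "short_only1",
      sleep_percent = c(0.784, 0.073),
      lw_length_h = c(6.384, 1.034),
      sw_length_h = c(0.196, 0.233)
    ),
    `1-b` = phenotype_archetype(
      name = "1-b",
      night_types = c(one_long = 0.75, short_only2 = 0.25),
      signature = "short_only2",
      sleep_percent = c(0.700, 0.105),
      lw_length_h = c(4.606, 1.184),
      sw_length_h = c(0.405, 0.422)
    ),
    `1-c` = phenotype_archetype(
      name = "1-c",
      night_types = c(one_long = 0.70, long_long = 0.14, short_only1 = 0.16),
      signature = c("long_long", "short_only1"),
      sleep_percent = c(0.769, 0.064),
      lw_length_h = c(7.412, 1.236),
      sw_length_h = c(0.411, 0.311)
    ),
    c2 = phenotype_archetype(
      name = "c2",
      night_types = c(one_long = 0.8, long_short = 0.2),
      signature = "long_short",
      sleep_percent = c(0.821, 0.053),
      lw_length_h = c(7.757, 1.045),
      sw_length_h = c(0.331, 0.212)
    ),
    c3 = phenotype_archetype(
      name = "c3",
      night_types = c(one_long = 0.81, long_long = 0.19),
      signature = "long_long",
      sleep_percent = c(0.824, 0.051),
      lw_length_h = c(8.250, 0.978),
      sw_length_h = c(NA_real_, NA_real_)
    ),
    c4 = phenotype_archetype(
      name = "c4",
      night_types = c(short_only1 = 1),
      signature = "short_only1",
      sleep_percent = c(0.552, 0.167),
      lw_length_h = c(NA_real_, NA_real_),
      sw_length_h = c(0.510, 0.286)
    )
  )
  out
}

#' Construct a phenotype archetype
#'
#' @param name Archetype name (the phenotype it generates).
#' @param night_types Named probability vector over night structures
#'   (`one_long`, `long_short`, `long_long`, `short_only1`, `short_only2`).
#' @param sleep_percent,lw_length_h,sw_length_h Length-2 numeric vectors
#'   `c(mean, sd)`; sleep percent is the fraction of the sleep-onset to
#'   wake-onset span spent asleep, lengths are hours. Lengths may be `NA`
#'   for window kinds the archetype never emits.
#' @param signature Night structures forced at the start of each 6-night
#'   block (character, possibly empty).
#' @return An object of class `phenotype_archetype`.
#' @export
phenotype_archetype <- function(name, night_types, sleep_percent,
                                lw_length_h, sw_length_h,
                                signature = character()) {
  known <- c("one_long", "long_short", "long_long", "short_only1", "short_only2")
  if (!length(night_types) || is.null(names(night_types)) ||
      !all(names(night_types) %in% known))
    stopf("night_types must be a named probability vector over %s",
          paste(known, collapse = ", "))
  if (any(night_types < 0) || abs(sum(night_types) - 1) > 1e-9)
    stopf("night_types probabilities must be non-negative and sum to 1")
  if (!all(signature %in% names(night_types)))
    stopf("signature night types must appear in night_types")
  chk <- function(x, what, lo, hi) {
    if (length(x) != 2) stopf("%s must be c(mean, sd)", what)
    if (!is.na(x[1]) && (x[1] <= lo || x[1] > hi))
      stopf("%s mean %.3f outside (%s, %s]", what, x[1], lo, hi)
    if (!is.na(x[2]) && x[2] < 0) stopf("%s sd must be >= 0", what)
  }
  chk(sleep_percent, "sleep_percent", 0, 1)
  chk(lw_length_h, "lw_length_h", 0, Inf)
  chk(sw_length_h, "sw_length_h", 0, Inf)
  structure(
    list(name = name, night_types = night_types, signature = signature,
         sleep_percent = sleep_percent, lw_length_h = lw_length_h,
         sw_length_h = sw_length_h),
    class = "phenotype_archetype"
  )
}

#' @export
print.phenotype_archetype <- function(x, ...) {
  cat(sprintf("<phenotype_archetype '%s'>\n", x$name))
  cat("  night types:",
      paste(sprintf("%s=%.2f", names(x$night_types), x$night_types), collapse = ", "),
      "\n")
  cat(sprintf("  sleep%%: %.3f (%.3f)  LW len: %.3f (%.3f) h  SW len: %.3f (%.3f) h\n",
              x$sleep_percent[1], x$sleep_percent[2],
              x$lw_length_h[1], x$lw_length_h[2],
              x$sw_length_h[1], x$sw_length_h[2]))
  invisible(x)
}
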