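# File interfaces: long-format hypnogram CSV (one row per 30-s epoch)
# with a companion nights table, survey/symptom CSVs, and a JSON-lines
# truth file. These are the exchange formats of the pipeline; in-memory
# work uses the compact list-column representation.

#' Write a population to CSV files
#'
#' Writes `<prefix>_hypnogram.csv` (individual_id, night_date,
#' epoch_index 0-based, epoch_start_utc, stage_code),
#' `<prefix>_nights.csv` (individual_id, night_date, sleep_onset_utc,
#' wake_onset_utc, nonwear_hours), `<prefix>_survey.csv`,
#' `<prefix>_symptoms.csv`, and `<prefix>_truth.jsonl` (config header
#' line, then one line per individual with the latent block states).
#'
#' @param population A `sleep_population`.
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the named vector of files written.
#' @export
write_population_csv <- function(population, prefix) {
  stopifnot(inherits(population, "sleep_population"))
  nights <- population$nights
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- c(hypnogram = paste0(prefix, "_hypnogram.csv"),
             nights = paste0(prefix, "_nights.csv"),
             survey = paste0(prefix, "_survey.csv"),
             symptoms = paste0(prefix, "_symptoms.csv"),
             truth = paste0(prefix, "_truth.jsonl"))
  hyp <- nights[, {
    n <- length(stages[[1]])
    list(epoch_index = 0:(n - 1L),
         epoch_start_utc = format(sleep_onset + EPOCH_SECONDS * (0:(n - 1L)),
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         stage_code = stages[[1]])
  }, by = .(individual_id, night_date)]
  fwrite(hyp, files["hypnogram"])
  ntab <- nights[, .(individual_id, night_date,
                     sleep_onset_utc = format(sleep_onset, "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC"),
                     wake_onset_utc = format(
                       sleep_onset + EPOCH_SECONDS *
                         vapply(stages, length, integer(1)),
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                     nonwear_hours)]
  fwrite(ntab, files["nights"])
  fwrite(population$survey, files["survey"])
  fwrite(population$symptoms, files["symptoms"])

  truth <- population$truth
  con <- file(files["truth"], "w")
  on.exit(close(con))
  cfg <- truth$config
  writeLines(jsonlite::toJSON(list(
    type = "config", archetypes = names(cfg$archetypes),
    transition_matrix = cfg$transition_matrix,
    initial_distribution = cfg$initial_distribution,
    n_individuals = cfg$n_individuals, n_nights = cfg$n_nights,
    missing_night_prob = cfg$missing_night_prob, sd_scale = cfg$sd_scale,
    start_date = as.character(cfg$start_date), seed = cfg$seed),
    auto_unbox = TRUE, digits = NA), con)
  for (id in truth$individual_ids)
    writeLines(jsonlite::toJSON(list(
      type = "individual", individual_id = id,
      block_states = truth$block_states[[id]],
      missing_nights = which(truth$missing[[id]])),
      auto_unbox = TRUE), con)
  invisible(files)
}

#' Read a hypnogram + nights CSV pair into a nights table
#'
#' Inverse of the hypnogram/nights part of [write_population_csv()].
#'
#' @param hypnogram_csv,nights_csv File paths.
#' @return data.table with individual_id, night_date, sleep_onset
#'   (POSIXct UTC), stages (list-column), nonwear_hours.
#' @export
read_population_csv <- function(hypnogram_csv, nights_csv) {
  hyp <- fread(hypnogram_csv)
  ntab <- fread(nights_csv)
  st <- hyp[order(epoch_index),
            .(stages = list(as.integer(stage_code))),
            by = .(individual_id, night_date)]
  out <- ntab[, .(individual_id, night_date = as.Date(night_date),
                  sleep_onset = as.POSIXct(sleep_onset_utc, tz = "UTC",
                                           format = "%Y-%m-%dT%H:%M:%SZ"),
                  nonwear_hours)]
  st[, night_date := as.Date(night_date)]
  out[st, on = c("individual_id", "night_date"), stages := i.stages]
  out[]
}
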