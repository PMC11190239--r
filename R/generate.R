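# Synthetic hypnogram generator.
#
# Emits populations of per-night 30-s stage series with a known latent
# phenotype process: each individual follows a Markov chain over phenotype
# archetypes that steps once per 6-night block (the clustering unit
# downstream), so the planted transition matrix is directly estimable from
# period-level phenotype labels. Nights are built from explicit window
# plans (window kinds, lengths, wake gaps) so that the window-construction
# stage can be checked for exact plan recovery.

# Stage codes: 0 = wake, 1 = light NREM, 2 = deep NREM, 3 = REM. Only the
# wake / non-wake distinction matters downstream; non-wake epochs are
# spread over stages 1-3 with fixed proportions (cosmetic).
STAGE_PROPS <- c(light = 0.55, deep = 0.25, rem = 0.20)

# Structural constants for night plans, in epochs. Sleep runs inside a
# window are kept >= 10 min so they survive short-sleep-run suppression;
# interior wake bouts are kept < 55 min so they never split a window; gaps
# between windows are > 60 min so they always split.
MIN_SLEEP_RUN <- 20L   # 10 min
MAX_WAKE_BOUT <- 110L  # 55 min
MIN_GAP       <- 126L  # 63 min
MIN_TRAIL     <- 20L   # trailing wake below this is dropped (would be smoothed)

#' Generator configuration
#'
#' @param archetypes Character vector of archetype names (see
#'   [sleep_archetypes()]) or a named list of `phenotype_archetype` objects.
#' @param transition_matrix K x K row-stochastic matrix: latent phenotype
#'   dynamics, one step per 6-night block. Default: heavily diagonal with
#'   uniform off-diagonal leakage.
#' @param initial_distribution Length-K simplex vector (default uniform).
#' @param n_individuals,n_nights Population size and nights per individual.
#' @param missing_night_prob Per-night probability that no data is recorded.
#' @param nonwear_mean_h Mean of the exponential per-night non-wear hours
#'   (truncated at 8 h).
#' @param condition_effects List of [condition_effect()] specs.
#' @param sd_scale Multiplier on all archetype SDs; 0 gives deterministic
#'   "pure" archetype nights (used for calibration and recovery tests).
#' @param start_date First calendar night (Date).
#' @param onset_jitter_sd_h SD (hours) of the sleep-onset jitter around
#'   23:00 local; truncated at +/- 3 h so each night stays anchored to its
#'   calendar day.
#' @param seed Integer master seed.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(archetypes = c("rec", "1-a", "c2", "c3", "c4"),
                             transition_matrix = NULL,
                             initial_distribution = NULL,
                             n_individuals = 50L,
                             n_nights = 30L,
                             missing_night_prob = 0.08,
                             nonwear_mean_h = 0.4,
                             condition_effects = list(),
                             sd_scale = 1,
                             start_date = as.Date("2020-01-01"),
                             onset_jitter_sd_h = 0.75,
                             seed = 1L) {
  cat_all <- sleep_archetypes()
  if (is.character(archetypes)) {
    missing_a <- setdiff(archetypes, names(cat_all))
    if (length(missing_a))
      stopf("unknown archetypes: %s", paste(missing_a, collapse = ", "))
    archetypes <- cat_all[archetypes]
  }
  K <- length(archetypes)
  if (!K) stopf("need at least one archetype")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(if (K > 1) 0.2 / (K - 1) else 0, K, K)
    diag(transition_matrix) <- if (K > 1) 0.8 else 1
  }
  assert_prob_matrix(transition_matrix)
  if (nrow(transition_matrix) != K)
    stopf("transition_matrix must be %d x %d to match the archetypes", K, K)
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / K, K)
  if (length(initial_distribution) != K || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9)
    stopf("initial_distribution must be a length-%d simplex vector", K)
  if (!is_count(n_individuals) || !is_count(n_nights) ||
      n_individuals < 1 || n_nights < 1)
    stopf("n_individuals and n_nights must be positive counts")
  if (missing_night_prob < 0 || missing_night_prob >= 1)
    stopf("missing_night_prob must be in [0, 1)")
  for (eff in condition_effects) {
    if (!inherits(eff, "condition_effect"))
      stopf("condition_effects must be built with condition_effect()")
    if (!is.null(eff$matrix)) {
      assert_prob_matrix(eff$matrix)
      if (nrow(eff$matrix) != K)
        stopf("condition '%s': effect matrix must be %d x %d", eff$condition, K, K)
    }
  }
  structure(
    list(archetypes = archetypes, transition_matrix = transition_matrix,
         initial_distribution = initial_distribution,
         n_individuals = as.integer(n_individuals),
         n_nights = as.integer(n_nights),
         missing_night_prob = missing_night_prob,
         nonwear_mean_h = nonwear_mean_h,
         condition_effects = condition_effects,
         sd_scale = sd_scale, start_date = as.Date(start_date),
         onset_jitter_sd_h = onset_jitter_sd_h, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Condition effect specification
#'
#' Describes how a health condition perturbs the latent phenotype dynamics:
#' chronic conditions replace the transition matrix for positive
#' individuals on all nights; acute conditions replace it only for blocks
#' starting inside the `during_window` around the (single) report date.
#'
#' @param condition Condition name (e.g. `"diabetes"`, `"flu"`).
#' @param type `"chronic"` or `"acute"`.
#' @param matrix K x K replacement transition matrix (row-stochastic).
#' @param prevalence Chronic: fraction of individuals positive.
#' @param no_answer_frac Chronic: fraction of individuals who leave the
#'   survey question unanswered.
#' @param n_affected Acute: number of individuals with a report.
#' @param during_window Acute: inclusive day offsets around the report date
#'   in which the perturbed dynamics apply (default `c(-14, 14)`).
#' @param report_dates Acute, optional: explicit named vector/list of
#'   report dates keyed by individual id; drawn at random when `NULL`.
#' @return A `condition_effect` object.
#' @export
condition_effect <- function(condition, type = c("chronic", "acute"),
                             matrix = NULL, prevalence = 0.1,
                             no_answer_frac = 0.2, n_affected = 10L,
                             during_window = c(-14L, 14L),
                             report_dates = NULL) {
  type <- match.arg(type)
  structure(
    list(condition = condition, type = type, matrix = matrix,
         prevalence = prevalence, no_answer_frac = no_answer_frac,
         n_affected = as.integer(n_affected),
         during_window = as.integer(during_window),
         report_dates = report_dates),
    class = "condition_effect"
  )
}

# ---- latent truth ----------------------------------------------------------

simulate_chain <- function(n, P, init) {
  K <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(K, 1L, prob = init)
  if (n > 1) for (t in 2:n) s[t] <- sample.int(K, 1L, prob = P[s[t - 1L], ])
  s
}

#' Generate the latent truth of a synthetic population
#'
#' Simulates each individual's block-level phenotype chain under the base
#' transition matrix, assigns chronic/acute condition membership, and then
#' applies the configured condition effects via [apply_condition_effects()].
#'
#' @param config A [generator_config()].
#' @return A `synthetic_truth` list: per-individual block states, per-night
#'   archetype labels and missingness, condition tables, and the matrices
#'   actually used.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_ind <- config$n_individuals
  n_nights <- config$n_nights
  n_blocks <- ceiling(n_nights / 6)
  ids <- sprintf("ind%04d", seq_len(n_ind))
  ind_seeds <- sample.int(.Machine$integer.max - 1L, n_ind)

  block_states <- vector("list", n_ind)
  missing <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    set.seed(ind_seeds[i])
    block_states[[i]] <- simulate_chain(n_blocks, config$transition_matrix,
                                        config$initial_distribution)
    missing[[i]] <- stats::runif(n_nights) < config$missing_night_prob
  }
  names(block_states) <- names(missing) <- ids

  # condition membership (who is affected), before effects are applied
  set.seed(config$seed + 1L)
  survey <- list(); symptoms <- list(); affected <- list()
  for (eff in config$condition_effects) {
    if (eff$type == "chronic") {
      n_pos <- round(eff$prevalence * n_ind)
      n_na <- round(eff$no_answer_frac * n_ind)
      shuffled <- sample(ids)
      pos <- shuffled[seq_len(n_pos)]
      na_ids <- shuffled[n_pos + seq_len(min(n_na, n_ind - n_pos))]
      resp <- ifelse(ids %in% pos, "positive",
                     ifelse(ids %in% na_ids, "no_answer", "negative"))
      survey[[eff$condition]] <- data.table(
        individual_id = ids, condition = eff$condition, response = resp)
      affected[[eff$condition]] <- pos
    } else {
      if (!is.null(eff$report_dates)) {
        rep_ids <- names(eff$report_dates)
        rep_dates <- as.Date(unlist(lapply(eff$report_dates, as.character)))
      } else {
        # report late enough that a >50-day-prior baseline exists
        lo <- 56L; hi <- max(lo, n_nights - 15L)
        rep_ids <- sample(ids, min(eff$n_affected, n_ind))
        rep_dates <- config$start_date +
          sample(lo:hi, length(rep_ids), replace = TRUE) - 1L
      }
      symptoms[[eff$condition]] <- data.table(
        individual_id = rep_ids, condition = eff$condition,
        report_date = rep_dates)
      affected[[eff$condition]] <- rep_ids
    }
  }
  survey <- if (length(survey)) rbindlist(survey) else
    data.table(individual_id = character(), condition = character(),
               response = character())
  symptoms <- if (length(symptoms)) rbindlist(symptoms) else
    data.table(individual_id = character(), condition = character(),
               report_date = as.Date(character()))

  truth <- structure(
    list(config = config, archetype_names = names(config$archetypes),
         individual_ids = ids, ind_seeds = ind_seeds,
         block_states = block_states, missing = missing,
         survey = survey, symptoms = symptoms, affected = affected,
         matrices_used = list(base = config$transition_matrix)),
    class = "synthetic_truth"
  )
  apply_condition_effects(truth, config$condition_effects)
}

#' Apply condition effects to a latent truth
#'
#' Re-simulates the block chains of affected individuals: chronic-positive
#' individuals use the perturbed matrix on all blocks; acutely affected
#' individuals use it only for blocks whose start date falls inside the
#' configured window around their report date.
#'
#' @param truth A `synthetic_truth` (from [generate_truth()]).
#' @param condition_effects List of [condition_effect()]s (empty list
#'   leaves the truth unchanged).
#' @return The updated `synthetic_truth`.
#' @export
apply_condition_effects <- function(truth, condition_effects = list()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(condition_effects)) return(truth)
  config <- truth$config
  n_blocks <- ceiling(config$n_nights / 6)
  block_start_dates <- config$start_date + 6L * (seq_len(n_blocks) - 1L)

  # reject overlapping acute reports (the cohort design requires a clean
  # 50-day pre-report window)
  sym <- truth$symptoms
  if (nrow(sym) > 1) {
    setorder(sym, individual_id, report_date)
    gaps <- sym[, diff(as.numeric(report_date)), by = individual_id]$V1
    if (length(gaps) && any(gaps < 50))
      stopf("acute reports for one individual within 50 days are not allowed")
  }

  # per-individual, per-block effective matrix; chronic replaces acute
  # replaces base, chronic taking precedence if an individual has both
  for (i in seq_along(truth$individual_ids)) {
    id <- truth$individual_ids[i]
    mats <- rep(list(config$transition_matrix), n_blocks)
    touched <- FALSE
    for (eff in condition_effects) {
      if (is.null(eff$matrix)) next
      if (!id %in% truth$affected[[eff$condition]]) next
      if (eff$type == "chronic") {
        mats <- rep(list(eff$matrix), n_blocks)
      } else {
        rd <- truth$symptoms[truth$symptoms$individual_id == id &
                             truth$symptoms$condition == eff$condition, ]$report_date
        for (r in as.list(rd)) {
          off <- as.numeric(block_start_dates - r)
          sel <- off >= eff$during_window[1] & off <= eff$during_window[2]
          mats[sel] <- list(eff$matrix)
        }
      }
      touched <- TRUE
      truth$matrices_used[[eff$condition]] <- eff$matrix
    }
    if (!touched) next
    set.seed(truth$ind_seeds[i])  # same stream as the base chain draw
    s <- integer(n_blocks)
    s[1] <- sample.int(length(truth$archetype_names), 1L,
                       prob = config$initial_distribution)
    if (n_blocks > 1) for (t in 2:n_blocks)
      s[t] <- sample.int(length(truth$archetype_names), 1L,
                         prob = mats[[t - 1L]][s[t - 1L], ])
    truth$block_states[[id]] <- s
  }
  truth
}

#' Per-night latent labels of a truth object
#'
#' @param truth A `synthetic_truth`.
#' @return data.table: individual_id, night_index, night_date, block_index,
#'   archetype, missing.
#' @export
truth_night_labels <- function(truth) {
  config <- truth$config
  n_nights <- config$n_nights
  block_of_night <- ((seq_len(n_nights) - 1L) %/% 6L) + 1L
  out <- lapply(truth$individual_ids, function(id) {
    st <- truth$block_states[[id]][block_of_night]
    data.table(individual_id = id, night_index = seq_len(n_nights),
               night_date = config$start_date + seq_len(n_nights) - 1L,
               block_index = block_of_night,
               archetype = truth$archetype_names[st],
               missing = truth$missing[[id]])
  })
  rbindlist(out)
}

#' Empirical switch frequency of the latent block chain
#'
#' Fraction of consecutive block-state pairs whose state differs, pooled
#' over individuals (optionally restricted to blocks starting inside /
#' outside a day-offset window around per-individual reference dates).
#'
#' @param truth A `synthetic_truth`.
#' @param window,ref_dates Optional inclusive day-offset window and a named
#'   vector of reference dates (by individual id); transitions are kept if
#'   the *origin* block start falls inside (`window`) the offsets.
#' @param invert Keep transitions outside the window instead.
#' @return Numeric switch frequency.
#' @export
latent_switch_frequency <- function(truth, window = NULL, ref_dates = NULL,
                                    invert = FALSE) {
  config <- truth$config
  n_blocks <- ceiling(config$n_nights / 6)
  starts <- config$start_date + 6L * (seq_len(n_blocks) - 1L)
  num <- 0L; den <- 0L
  for (id in truth$individual_ids) {
    s <- truth$block_states[[id]]
    if (length(s) < 2) next
    keep <- rep(TRUE, length(s) - 1L)
    if (!is.null(window) && !is.null(ref_dates) && id %in% names(ref_dates)) {
      off <- as.numeric(starts[-length(starts)] - as.Date(ref_dates[[id]]))
      inside <- off >= window[1] & off <= window[2]
      keep <- if (invert) !inside else inside
    } else if (!is.null(window) && !is.null(ref_dates)) {
      keep <- rep(invert, length(s) - 1L)
    }
    num <- num + sum(s[-1][keep] != s[-length(s)][keep])
    den <- den + sum(keep)
  }
  if (!den) return(NA_real_)
  num / den
}

# ---- night plans and epoch emission ---------------------------------------

draw_len <- function(mean_sd, sd_scale, lo, hi) {
  rnorm_trunc(1L, mean_sd[1], mean_sd[2] * sd_scale, lo, hi)
}

# A night plan: windows (kind, n epochs, wake epochs inside), gaps before
# each window (epochs of wake), and a trailing wake run.
plan_night <- function(archetype, night_type, sd_scale = 1) {
  sp <- rnorm_trunc(1L, archetype$sleep_percent[1],
                    archetype$sleep_percent[2] * sd_scale, 0.35, 0.99)
  gap_h <- stats::runif(1, MIN_GAP / EPOCHS_PER_HOUR, 1.6)
  win <- function(len_h, wake_frac = 0) {
    n <- max(hours_to_epochs(len_h), MIN_SLEEP_RUN + 1L)
    list(n = n, wake = max(0L, min(n - 2L * MIN_SLEEP_RUN,
                                   as.integer(round(wake_frac * n)))))
  }
  lw <- function() draw_len(archetype$lw_length_h, sd_scale, 3.05, 14)
  lw_half <- function() draw_len(archetype$lw_length_h / c(2, 2), sd_scale, 3.05, 9)
  sw <- function() draw_len(archetype$sw_length_h, sd_scale, 0.18, 2.9)

  windows <- list(); gaps <- integer(); trail <- 0L
  if (night_type == "one_long") {
    windows <- list(win(lw(), 1 - sp)); gaps <- 0L
  } else if (night_type == "long_short") {
    L <- lw(); S <- sw()
    span <- L + gap_h + S
    wake_long_h <- min(0.45 * L, max(0, L - (sp * span - S)))
    windows <- list(win(L, wake_long_h / L), win(S))
    gaps <- c(0L, hours_to_epochs(gap_h))
  } else if (night_type == "long_long") {
    L1 <- lw_half(); L2 <- lw_half()
    span <- L1 + gap_h + L2
    wake_h <- max(0, (L1 + L2) - sp * span)
    windows <- list(win(L1, (wake_h * L1 / (L1 + L2)) / L1),
                    win(L2, (wake_h * L2 / (L1 + L2)) / L2))
    gaps <- c(0L, hours_to_epochs(gap_h))
  } else if (night_type %in% c("short_only1", "short_only2")) {
    k <- if (night_type == "short_only2") 2L else 1L
    lens <- replicate(k, sw())
    windows <- lapply(lens, win)
    gaps <- c(0L, rep(hours_to_epochs(gap_h), k - 1L))
    sleep_h <- sum(lens)
    span_h <- sleep_h + (k - 1L) * gap_h
    trail <- hours_to_epochs(max(0, sleep_h / sp - span_h))
    if (trail < MIN_TRAIL) trail <- 0L
    trail <- min(trail, hours_to_epochs(4))
  } else stopf("unknown night type '%s'", night_type)

  kinds <- vapply(windows, function(w)
    if (epochs_to_hours(w$n) < 3) "short" else "long", character(1))
  list(type = night_type,
       windows = data.table(kind = kinds,
                            n_epochs = vapply(windows, `[[`, integer(1), "n"),
                            wake_epochs = vapply(windows, `[[`, integer(1), "wake"),
                            gap_before = gaps),
       trail = trail)
}

# Interior wake placement for one window: `w` wake epochs in bouts of
# 1..MAX_WAKE_BOUT epochs, separated (and flanked) by sleep runs of at
# least MIN_SLEEP_RUN epochs. Returns a logical vector (TRUE = sleep).
window_sleep_mask <- function(n, w) {
  if (w <= 0L || n < 2L * MIN_SLEEP_RUN + 1L) return(rep(TRUE, n))
  w <- min(w, n - 2L * MIN_SLEEP_RUN)
  m_hi <- (n - w) %/% MIN_SLEEP_RUN - 1L
  if (m_hi < 1L) return(rep(TRUE, n))
  m_lo <- as.integer(ceiling(w / MAX_WAKE_BOUT))
  if (m_lo > m_hi) { w <- MAX_WAKE_BOUT * m_hi; m_lo <- m_hi }
  m <- max(m_lo, min(m_hi, max(1L, as.integer(round(w / 8)))))
  bouts <- 1L + rand_composition(w - m, m)
  while (any(bouts > MAX_WAKE_BOUT)) {  # redistribute clipped excess
    over <- which.max(bouts); under <- which.min(bouts)
    move <- bouts[over] - MAX_WAKE_BOUT
    bouts[over] <- MAX_WAKE_BOUT
    bouts[under] <- bouts[under] + move
  }
  runs <- MIN_SLEEP_RUN + rand_composition(n - w - MIN_SLEEP_RUN * (m + 1L), m + 1L)
  mask <- logical(0)
  for (j in seq_len(m))
    mask <- c(mask, rep(TRUE, runs[j]), rep(FALSE, bouts[j]))
  c(mask, rep(TRUE, runs[m + 1L]))
}

emit_stages <- function(plan) {
  pieces <- list()
  for (j in seq_len(nrow(plan$windows))) {
    g <- plan$windows$gap_before[j]
    if (g > 0L) pieces[[length(pieces) + 1L]] <- rep(FALSE, g)
    pieces[[length(pieces) + 1L]] <-
      window_sleep_mask(plan$windows$n_epochs[j], plan$windows$wake_epochs[j])
  }
  if (plan$trail > 0L) pieces[[length(pieces) + 1L]] <- rep(FALSE, plan$trail)
  mask <- unlist(pieces, use.names = FALSE)
  stages <- integer(length(mask))
  ns <- sum(mask)
  stages[mask] <- sample(1:3, ns, replace = TRUE, prob = STAGE_PROPS)
  stages
}

#' Generate one night for an archetype
#'
#' Draws a night structure from the archetype's mixture (or uses
#' `night_type`), builds the window plan, and emits the 30-s stage series.
#' The plan is returned alongside the stages so window construction can be
#' checked for exact recovery.
#'
#' @param archetype A `phenotype_archetype`.
#' @param night_type Optional night structure override.
#' @param sd_scale Multiplier on archetype SDs (0 = deterministic targets).
#' @return List with `stages` (integer vector, 0 = wake), `plan` (window
#'   plan), and `archetype`.
#' @export
generate_night <- function(archetype, night_type = NULL, sd_scale = 1) {
  stopifnot(inherits(archetype, "phenotype_archetype"))
  if (is.null(night_type)) {
    nt <- archetype$night_types
    night_type <- names(nt)[sample.int(length(nt), 1L, prob = nt)]
  }
  needs_lw <- night_type %in% c("one_long", "long_short", "long_long")
  needs_sw <- night_type %in% c("long_short", "short_only1", "short_only2")
  if (needs_lw && is.na(archetype$lw_length_h[1]))
    stopf("archetype '%s' has no long-window length for night type '%s'",
          archetype$name, night_type)
  if (needs_sw && is.na(archetype$sw_length_h[1]))
    stopf("archetype '%s' has no short-window length for night type '%s'",
          archetype$name, night_type)
  plan <- plan_night(archetype, night_type, sd_scale)
  list(stages = emit_stages(plan), plan = plan, archetype = archetype$name)
}

# ---- population ------------------------------------------------------------

#' Generate a synthetic population of hypnograms
#'
#' Simulates the latent truth ([generate_truth()]), then emits one epoch
#' series per non-missing (individual, night). Output is byte-identical
#' for identical config (including seed).
#'
#' Each individual's nights are emitted under an individual-specific seed,
#' so generating a subset of individuals reproduces exactly the nights the
#' full run would give them (used for batch-wise processing of large
#' populations).
#'
#' @param config A [generator_config()].
#' @param truth Optional pre-built `synthetic_truth` (must match `config`).
#' @param individuals Optional character subset of individual ids to emit.
#' @return A `sleep_population` list: `nights` (data.table with
#'   individual_id, night_date, sleep_onset POSIXct UTC, stages
#'   list-column, nonwear_hours, plus the planned window counts), `survey`,
#'   `symptoms`, `truth`.
#' @export
generate_population <- function(config, truth = NULL, individuals = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(truth)) truth <- generate_truth(config)
  labels <- truth_night_labels(truth)
  arch <- config$archetypes
  which_ind <- if (is.null(individuals)) seq_along(truth$individual_ids) else
    match(individuals, truth$individual_ids)
  if (anyNA(which_ind)) stopf("unknown individual ids requested")

  res <- vector("list", length(which_ind))
  for (ii in seq_along(which_ind)) {
    i <- which_ind[ii]
    id <- truth$individual_ids[i]
    set.seed((truth$ind_seeds[i] + 1L) %% .Machine$integer.max)
    lab <- labels[labels$individual_id == id & !labels$missing, ]
    if (!nrow(lab)) next
    n <- nrow(lab)
    stages <- vector("list", n)
    planned_long <- integer(n); planned_short <- integer(n)
    night_in_block <- integer(n)
    # position of each recorded night inside its 6-night block, counted
    # over ALL calendar nights so signature forcing is missingness-stable
    pos_in_block <- ((lab$night_index - 1L) %% 6L) + 1L
    for (j in seq_len(n)) {
      a <- arch[[lab$archetype[j]]]
      sig <- a$signature
      type <- if (length(sig) >= pos_in_block[j]) sig[pos_in_block[j]] else NULL
      night <- generate_night(a, night_type = type, sd_scale = config$sd_scale)
      stages[[j]] <- night$stages
      planned_long[j] <- sum(night$plan$windows$kind == "long")
      planned_short[j] <- sum(night$plan$windows$kind == "short")
    }
    jit <- rnorm_trunc(n, 0, config$onset_jitter_sd_h, -3, 3)
    onset <- as.POSIXct(paste(lab$night_date - 1L, "23:00:00"), tz = "UTC") +
      round(jit * 3600)
    nw <- pmin(stats::rexp(n, 1 / config$nonwear_mean_h), 8)
    res[[ii]] <- data.table(
      individual_id = id, night_date = lab$night_date,
      sleep_onset = onset, stages = stages, nonwear_hours = nw,
      archetype = lab$archetype,
      planned_long = planned_long, planned_short = planned_short)
  }
  nights <- rbindlist(res[!vapply(res, is.null, logical(1))])
  structure(list(nights = nights, survey = truth$survey,
                 symptoms = truth$symptoms, truth = truth),
            class = "sleep_population")
}

#' @export
print.sleep_population <- function(x, ...) {
  cat(sprintf("<sleep_population: %d nights, %d individuals, %d archetypes>\n",
              nrow(x$nights), length(unique(x$nights$individual_id)),
              length(x$truth$archetype_names)))
  invisible(x)
}
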