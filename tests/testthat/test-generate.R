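# Synthetic-data generator: determinism, degenerate chains, latent
# dynamics calibration, plan round-trips, and condition effects.

test_that("identical config and seed give byte-identical populations", {
  cfg <- generator_config(n_individuals = 3, n_nights = 8, seed = 11)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$nights$stages, p2$nights$stages)
  expect_identical(p1$nights$nonwear_hours, p2$nights$nonwear_hours)
  expect_identical(p1$truth$block_states, p2$truth$block_states)
  expect_identical(p1$survey, p2$survey)
})

test_that("degenerate one-archetype chain labels every night rec", {
  cfg <- generator_config(archetypes = "rec",
                          transition_matrix = matrix(1, 1, 1),
                          initial_distribution = 1,
                          n_individuals = 2, n_nights = 5,
                          missing_night_prob = 0, seed = 4)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$nights), 10L)
  expect_true(all(pop$nights$archetype == "rec"))
})

test_that("identity transition matrix makes the initial state absorbing", {
  cfg <- generator_config(archetypes = c("rec", "1-a"),
                          transition_matrix = diag(2),
                          initial_distribution = c(0, 1),
                          n_individuals = 3, n_nights = 24,
                          missing_night_prob = 0, seed = 9)
  pop <- generate_population(cfg)
  expect_true(all(pop$nights$archetype == "1-a"))
})

test_that("a non-stochastic matrix is rejected at configuration", {
  expect_error(generator_config(archetypes = c("rec", "c2"),
                                transition_matrix = matrix(c(.5, .4, .2, .8), 2, 2)),
               "sum to 1")
})

test_that("latent switch frequency matches the planted symmetric chain", {
  P <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  cfg <- generator_config(archetypes = c("rec", "1-a"),
                          transition_matrix = P,
                          n_individuals = 200, n_nights = 50,
                          missing_night_prob = 0, seed = 21)
  truth <- generate_truth(cfg)
  f <- latent_switch_frequency(truth)
  expect_lt(abs(f - 0.3), 0.02)
})

test_that("a night type the archetype cannot produce raises a generation error", {
  arch <- sleep_archetypes()
  set.seed(1)
  expect_error(generate_night(arch[["c4"]], night_type = "one_long"),
               "no long-window length")
  expect_error(generate_night(arch[["c3"]], night_type = "short_only1"),
               "no short-window length")
})

test_that("sd-0 nights round-trip: window construction recovers every planned window", {
  cfg <- generator_config(archetypes = c("rec", "1-a", "1-b", "1-c", "c2", "c3", "c4"),
                          transition_matrix = diag(7),
                          n_individuals = 14, n_nights = 12,
                          missing_night_prob = 0, sd_scale = 0, seed = 31)
  pop <- generate_population(cfg)
  for (i in seq_len(nrow(pop$nights))) {
    w <- build_windows(pop$nights$stages[[i]])
    expect_identical(sum(w$kind == "long"), pop$nights$planned_long[i])
    expect_identical(sum(w$kind == "short"), pop$nights$planned_short[i])
  }
})

test_that("sd-0 rec nights are a single long window at the target length", {
  arch <- sleep_archetypes()[["rec"]]
  set.seed(5)
  night <- generate_night(arch, sd_scale = 0)
  w <- build_windows(night$stages)
  expect_equal(nrow(w), 1L)
  expect_equal(w$kind, "long")
  expect_equal(w$length_h, 8.087, tolerance = 0.01)
})

test_that("c4 nights yield only sub-3-h windows; c3 signature nights two long windows", {
  arch <- sleep_archetypes()
  set.seed(6)
  for (r in 1:10) {
    w4 <- build_windows(generate_night(arch[["c4"]])$stages)
    expect_true(all(w4$length_h < 3))
  }
  w3 <- build_windows(generate_night(arch[["c3"]], night_type = "long_long")$stages)
  expect_equal(sum(w3$kind == "long"), 2L)
  # the two long windows are separated by more than 60 min of wake
  expect_gt(w3$start_epoch[2] - w3$end_epoch[1] - 1L, 120L)
})

test_that("population nightly features calibrate to the cohort profile", {
  # stationary mixture dominated by recommended sleep, as in the emulated
  # cohort; tolerance is 3 nightly-feature SDs of the published profile
  cfg <- generator_config(
    archetypes = c("rec", "1-a", "1-b", "1-c", "c2", "c3", "c4"),
    initial_distribution = c(0.85, 0.05, 0.01, 0.01, 0.05, 0.02, 0.01),
    transition_matrix = {
      m <- matrix(0, 7, 7)
      for (i in 1:7) m[i, ] <- c(0.85, 0.05, 0.01, 0.01, 0.05, 0.02, 0.01)
      m
    },
    n_individuals = 120, n_nights = 30, missing_night_prob = 0, seed = 77)
  pop <- generate_population(cfg)
  nf <- compute_night_features(pop$nights)
  ref_mean <- c(sleep_percent = 0.859, st_long = 6.992, wt_long = 1.074,
                lw_count = 0.988, sw_count = 0.030)
  ref_sd <- c(sleep_percent = 0.089, st_long = 1.274, wt_long = 0.578,
              lw_count = 0.148, sw_count = 0.180)
  for (f in names(ref_mean))
    expect_lt(abs(mean(nf[[f]]) - ref_mean[[f]]), 3 * ref_sd[[f]])
  # conditional mean long-window length, as the profile tabulates it
  expect_lt(abs(mean(nf$lw_length[nf$lw_count > 0]) - 8.066), 3 * 1.416)
})

test_that("empty condition effects leave the truth unchanged", {
  cfg <- generator_config(n_individuals = 4, n_nights = 12, seed = 2)
  truth <- generate_truth(cfg)
  expect_identical(apply_condition_effects(truth, list()), truth)
})

test_that("a chronic identity-matrix effect freezes positive individuals", {
  eff <- condition_effect("apnea", "chronic", matrix = diag(3),
                          prevalence = 0.4, no_answer_frac = 0.2)
  cfg <- generator_config(archetypes = c("rec", "1-a", "1-b"),
                          transition_matrix = matrix(1 / 3, 3, 3),
                          n_individuals = 20, n_nights = 36,
                          condition_effects = list(eff), seed = 13)
  truth <- generate_truth(cfg)
  pos <- truth$survey[truth$survey$response == "positive", ]$individual_id
  neg <- truth$survey[truth$survey$response == "negative", ]$individual_id
  expect_true(all(vapply(pos, function(id)
    length(unique(truth$block_states[[id]])) == 1L, logical(1))))
  # uniform chains essentially never stay constant over 6 blocks
  expect_true(any(vapply(neg, function(id)
    length(unique(truth$block_states[[id]])) > 1L, logical(1))))
  # survey has all three response levels
  expect_setequal(unique(truth$survey$response),
                  c("positive", "negative", "no_answer"))
})

test_that("an acute self-transition boost lowers switching inside the window", {
  sticky <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  eff <- condition_effect("flu", "acute", matrix = sticky, n_affected = 60)
  cfg <- generator_config(archetypes = c("rec", "1-a"),
                          transition_matrix = matrix(0.5, 2, 2),
                          n_individuals = 60, n_nights = 120,
                          condition_effects = list(eff), seed = 17)
  truth <- generate_truth(cfg)
  reps <- stats::setNames(truth$symptoms$report_date, truth$symptoms$individual_id)
  f_in <- latent_switch_frequency(truth, window = c(-14, 14), ref_dates = reps)
  f_out <- latent_switch_frequency(truth, window = c(-14, 14), ref_dates = reps,
                                   invert = TRUE)
  expect_lt(f_in, f_out)
  expect_lt(f_in, 0.25)   # sticky matrix switches at 0.05
  expect_gt(f_out, 0.35)  # uniform matrix switches at 0.5
})

test_that("overlapping acute reports within 50 days are rejected", {
  eff <- condition_effect(
    "flu", "acute", matrix = diag(2),
    report_dates = list(ind0001 = as.Date(c("2020-03-01", "2020-03-20"))))
  cfg <- generator_config(archetypes = c("rec", "1-a"),
                          n_individuals = 2, n_nights = 100,
                          condition_effects = list(eff), seed = 3)
  expect_error(generate_truth(cfg), "within 50 days")
})

test_that("population CSV round-trips through the file interface", {
  cfg <- generator_config(n_individuals = 2, n_nights = 4, seed = 8)
  pop <- generate_population(cfg)
  prefix <- file.path(withr::local_tempdir(), "pop")
  files <- write_population_csv(pop, prefix)
  back <- read_population_csv(files[["hypnogram"]], files[["nights"]])
  data.table::setorder(back, individual_id, night_date)
  nights <- data.table::copy(pop$nights)
  data.table::setorder(nights, individual_id, night_date)
  expect_identical(back$stages, nights$stages)
  expect_equal(back$nonwear_hours, nights$nonwear_hours, tolerance = 1e-6)
  expect_equal(as.numeric(back$sleep_onset), as.numeric(nights$sleep_onset))
  truth_lines <- readLines(files[["truth"]])
  expect_equal(length(truth_lines), 1L + cfg$n_individuals)
})
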