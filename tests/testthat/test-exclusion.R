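make_pre <- function(ds, axes = "x") preprocess_dataset(ds, axes = axes)

test_that("participant rules flag frozen gaze, invariant responses, and off-AOI excess", {
  ds <- simulate_cascade_study(sim_config(4, 6, seed = 31))
  # participant 1: frozen estimator
  ds$gaze <- ds$gaze |>
    dplyr::mutate(x_px = ifelse(participant_id == 1, 640, x_px),
                  y_px = ifelse(participant_id == 1, 360, y_px))
  # participant 2: always answers left
  ds$trials$chosen_label[ds$trials$participant_id == 2] <- "left"
  pre <- make_pre(ds)
  fl <- flag_participants(pre)
  expect_equal(fl$rule[fl$participant_id == 1], "no_gaze_variation")
  expect_equal(fl$rule[fl$participant_id == 2], "no_response_variation")

  # off-AOI rule is strict: 60 of 100 outside -> flagged; exactly 50 -> kept
  toy <- list(
    gaze = tibble::tibble(
      participant_id = rep(1:2, each = 100), condition = "online",
      trial_id = rep(rep(1:2, each = 50), 2), phase = "decision",
      t_ms = rep(seq_len(100), 2), x_px = rep(c(400, 405), 100),
      y_px = 360, live_feed = FALSE,
      aoi = c(rep(c("left", NA), c(40, 60)), rep(c("left", NA), c(50, 50)))
    ),
    trials = tibble::tibble(participant_id = rep(1:2, each = 2),
                            condition = "online", trial_id = rep(1:2, 2)),
    paradigm = "cascade"
  )
  fl2 <- flag_participants(toy)
  expect_equal(fl2$rule[fl2$participant_id == 1], "off_aoi")
  expect_false(fl2$excluded[fl2$participant_id == 2])
})

test_that("missing-data rule flags participants with most trials absent", {
  ds <- simulate_vwp_study(sim_config(3, n_trials = 4, seed = 9))
  # participant 3 only finished the online block: drop the lab gaze
  ds$gaze <- ds$gaze |>
    dplyr::filter(!(participant_id == 3 & condition == "lab"))
  fl <- flag_participants(make_pre(ds, "xy"))
  expect_false(fl$excluded[fl$participant_id == 1])
  # exactly 50% missing is retained (strict rule); remove one more trial
  ds$gaze <- ds$gaze |>
    dplyr::filter(!(participant_id == 3 & trial_id == 1))
  fl2 <- flag_participants(make_pre(ds, "xy"))
  expect_equal(fl2$rule[fl2$participant_id == 3], "missing_data")
})

test_that("trial rules fire on midline deviation, dispersion, and response time", {
  ds <- simulate_cascade_study(clean_config(2, 4, seed = 12))
  pre <- make_pre(ds)
  # screen 1280 -> limit 320 px; push trial 1 of participant 1 to 330
  pre$trials$corrected_midline_x[1] <- pre$trials$true_midline_x[1] + 330
  pre$biases$sd_x[2] <- 321     # > 0.25 * 1280
  pre$trials$response_time_ms[3] <- 400   # < 0.5 s
  fl <- flag_trials(pre, study_mode = "two_aoi")
  expect_equal(fl$rule[1], "midline_deviation")
  expect_equal(fl$rule[2], "midline_sd")
  expect_equal(fl$rule[3], "response_time")
  expect_false(any(fl$excluded[-(1:3)]))

  # a deviation of exactly the limit is retained (strict >)
  pre$trials$corrected_midline_x[1] <- pre$trials$true_midline_x[1] + 320
  fl320 <- flag_trials(pre, study_mode = "two_aoi")
  expect_false(fl320$excluded[1])

  # RT = 31 s is out on the other side
  pre$trials$response_time_ms[4] <- 31000
  expect_equal(flag_trials(pre, study_mode = "two_aoi")$rule[4],
               "response_time")
})

test_that("four-AOI mode uses per-midline limits (25% height vertical, 37.5% width horizontal)", {
  ds <- simulate_vwp_study(clean_config(2, n_trials = 2, seed = 13))
  pre <- make_pre(ds, "xy")
  # vertical midline off by > 0.25 * 720 = 180
  pre$trials$corrected_midline_y[1] <- pre$trials$true_midline_y[1] + 185
  # horizontal midline off by > 0.375 * 1280 = 480
  pre$trials$corrected_midline_x[2] <- pre$trials$true_midline_x[2] + 485
  # both inside their limits
  pre$trials$corrected_midline_x[3] <- pre$trials$true_midline_x[3] + 470
  pre$trials$corrected_midline_y[3] <- pre$trials$true_midline_y[3] + 175
  fl <- flag_trials(pre, study_mode = "four_aoi")
  expect_equal(fl$rule[1], "midline_deviation")
  expect_equal(fl$rule[2], "midline_deviation")
  expect_false(fl$excluded[3])
})

test_that("missing bias estimates flag the trial instead of crashing", {
  ds <- simulate_cascade_study(clean_config(2, 2, seed = 2))
  # remove all fixation samples of one trial
  ds$gaze <- ds$gaze |>
    dplyr::filter(!(participant_id == 1 & trial_id == 1 &
                      phase == "fixation"))
  pre <- make_pre(ds)
  fl <- flag_trials(pre)
  expect_equal(fl$rule[fl$participant_id == 1 & fl$trial_id == 1],
               "no_bias_estimate")
})

test_that("sample filter reports off-AOI and live-feed fractions", {
  pre <- list(gaze = tibble::tibble(
    participant_id = 1, condition = "online", trial_id = 1,
    phase = "decision", t_ms = 1:100, x_px = 0, y_px = 0,
    live_feed = c(rep(TRUE, 5), rep(FALSE, 95)),
    aoi = c(rep("left", 88), rep(NA, 12))
  ))
  f <- filter_samples(pre)
  expect_equal(f$counts$n_off_aoi, 12)
  expect_equal(f$counts$frac_off_aoi, 0.12)
  expect_equal(f$counts$n_retained, 88)
  expect_equal(f$counts$n_live_feed, 0)     # live-feed drop disabled

  f2 <- filter_samples(pre, drop_live_feed = TRUE)
  expect_equal(f2$counts$n_live_feed, 5)
  expect_equal(f2$counts$n_retained, 83)

  # identity when everything is in an AOI
  pre$gaze$aoi <- "left"
  f3 <- filter_samples(pre)
  expect_equal(f3$counts$n_retained, 100)
})

test_that("sensitivity filters apply cumulatively in hierarchical order", {
  participants <- tibble::tibble(
    participant_id = 1:5,
    attention_failures = c(0, 2, 0, 0, 0),
    instruction_time_s = c(30, 30, 7.0, 30, 30),
    self_report_reliability = c(4, 4, 4, 1, 5)
  )
  base <- sensitivity_filter(participants, "base")
  expect_false(any(base$flags$excluded))

  att <- sensitivity_filter(participants, "+attention")
  expect_equal(att$flags$rule[2], "attention_checks")
  expect_false(att$flags$excluded[3])   # instruction rule not yet active

  ins <- sensitivity_filter(participants, "+instruction")
  expect_equal(ins$flags$rule[3], "instruction_screen")

  sr <- sensitivity_filter(participants, "+self_report")
  expect_equal(sr$flags$rule[4], "unreliable_data")
  # cumulative: earlier rules still apply at later levels
  expect_true(all(sr$flags$excluded[2:4]))
  expect_equal(sr$retention$n_retained, c(5L, 4L, 3L, 2L))

  # order stability: anyone excluded at level k stays excluded at k+1
  lv <- c("base", "+attention", "+instruction", "+self_report", "+live_feed")
  prev <- rep(FALSE, 5)
  for (l in lv) {
    f <- sensitivity_filter(participants, l)$flags$excluded
    expect_true(all(f[prev]))
    prev <- f
  }

  expect_error(
    sensitivity_filter(participants[, 1:2], "+instruction"),
    "instruction_time_s")
})

test_that("clean synthetic data passes every rule", {
  # enough trials that an all-same-choice run is vanishingly unlikely
  ds <- simulate_cascade_study(clean_config(4, 14, seed = 77))
  pre <- make_pre(ds)
  clean <- apply_exclusions(pre)
  expect_equal(clean$retention$excluded, c(0L, 0L, 0L))
  expect_equal(clean$retention$retained + clean$retention$excluded,
               clean$retention$total)
})

test_that("exclusion report counts are internally consistent", {
  ds <- simulate_cascade_study(sim_config(10, 8, seed = 19))
  clean <- apply_exclusions(make_pre(ds))
  r <- clean$retention
  expect_equal(r$retained + r$excluded, r$total)
  expect_equal(r$retained[1], sum(!clean$participant_flags$excluded))
  expect_equal(r$retained[2], sum(!clean$trial_flags$excluded))
  expect_equal(r$retained[3], nrow(clean$gaze))
  # every exclusion cites exactly one rule
  expect_true(all(!is.na(clean$participant_flags$rule[
    clean$participant_flags$excluded])))
  expect_true(all(is.na(clean$participant_flags$rule[
    !clean$participant_flags$excluded])))
})
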