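test_that("cascade proportion is the chosen-AOI count ratio in the pre-decision window", {
  # response at 2000 + 1000 ms; window [2900, 3000); 9 in-AOI samples, 7 chosen
  clean <- toy_cascade_clean(
    aoi_labels = c(rep("left", 7), rep("right", 2), "right"),
    t_ms = c(seq(2901, 2999, length.out = 9), 2500),
    chosen = "left"
  )
  tr <- cascade_proportion(clean)
  expect_equal(tr$prop, 7 / 9)
  expect_equal(tr$n_in_aoi, 9L)

  # all on the chosen face -> 1; equal split -> 0.5
  all_on <- toy_cascade_clean(rep("left", 4), c(2910, 2930, 2950, 2970))
  expect_equal(cascade_proportion(all_on)$prop, 1)
  split <- toy_cascade_clean(c("left", "right", "left", "right"),
                             c(2910, 2930, 2950, 2970))
  expect_equal(cascade_proportion(split)$prop, 0.5)

  # the response moment itself is excluded (right-open window)
  at_resp <- toy_cascade_clean(c("right", "left"), c(2950, 3000))
  expect_equal(cascade_proportion(at_resp)$n_in_aoi, 1L)
  expect_equal(cascade_proportion(at_resp)$prop, 0)

  # no in-AOI samples in the window -> missing result
  none <- toy_cascade_clean("left", 2500)
  expect_true(is.na(cascade_proportion(none)$prop))
  expect_equal(cascade_proportion(none)$n_in_aoi, 0L)
})

test_that("novelty proportion scores the test phase against the novel AOI", {
  ds <- simulate_novelty_study(clean_config(3, 4, seed = 44,
                                            preference = list(p_novel = 0)))
  clean <- apply_exclusions(preprocess_dataset(ds, axes = "x"))
  tr <- novelty_proportion(clean)
  expect_true(all(tr$prop == 0))   # never looks at the novel image

  ds1 <- simulate_novelty_study(clean_config(3, 4, seed = 44,
                                             preference = list(p_novel = 1)))
  clean1 <- apply_exclusions(preprocess_dataset(ds1, axes = "x"))
  expect_true(all(novelty_proportion(clean1)$prop == 1))
})

test_that("vwp role proportions are count ratios that sum to one", {
  ds <- simulate_vwp_study(clean_config(2, n_trials = 3, seed = 15))
  clean <- apply_exclusions(preprocess_dataset(ds, axes = "xy"))
  roles <- vwp_proportion(clean)
  sums <- roles |>
    dplyr::group_by(participant_id, condition, trial_id) |>
    dplyr::summarise(s = sum(prop), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_equal(nrow(roles |> dplyr::filter(role == "target")),
               nrow(clean$trials))

  # noiseless lab block with p_target = 1: all window samples on the target
  ds1 <- simulate_vwp_study(clean_config(2, n_trials = 2, seed = 16,
    preference = list(p_target_online = 1, p_target_lab = 1)))
  clean1 <- apply_exclusions(preprocess_dataset(ds1, axes = "xy"))
  t1 <- vwp_proportion(clean1) |> dplyr::filter(role == "target")
  expect_true(all(t1$prop == 1))
})

test_that("participant aggregation is an unweighted mean over retained trials", {
  tr <- tibble::tibble(
    participant_id = c(1, 1, 2, 3), condition = "online",
    trial_id = c(1, 2, 1, 1),
    prop = c(0.4, 0.6, 0.62, NA), n_in_aoi = c(10, 90, 5, 0)
  )
  expect_warning(agg <- aggregate_participants(tr), "no scored trial")
  expect_equal(agg$mean_prop[agg$participant_id == 1], 0.5)  # not 0.58
  expect_equal(agg$mean_prop[agg$participant_id == 2], 0.62)
  expect_false(3 %in% agg$participant_id)
})

test_that("time-course bins are contiguous and consistent with the scalar outcome", {
  # sustained full preference (ramp completed): deterministic chosen-looking
  ds <- simulate_cascade_study(clean_config(4, 6, seed = 23,
    preference = list(p_final = 1, ramp_ms = Inf)))
  clean <- apply_exclusions(preprocess_dataset(ds, axes = "x"))
  tc <- decision_locked_timecourse(clean, bin_ms = 100, span_ms = 1000)
  expect_true(all(diff(tc$bin_start_ms) == 100))
  expect_true(all(tc$mean_prop == 1))

  # a finite ramp rises toward the decision
  dsr <- simulate_cascade_study(clean_config(8, 10, seed = 24,
    preference = list(p_final = 1, ramp_ms = 1000)))
  cleanr <- apply_exclusions(preprocess_dataset(dsr, axes = "x"))
  tcr <- decision_locked_timecourse(cleanr, bin_ms = 100, span_ms = 1000)
  expect_gt(tcr$mean_prop[tcr$bin_start_ms == -100],
            tcr$mean_prop[tcr$bin_start_ms == -1000])
  expect_gt(tcr$mean_prop[tcr$bin_start_ms == -100], 0.9)

  # single fully-on-chosen trial -> every bin at 1
  one <- toy_cascade_clean(rep("left", 20), seq(2010, 2990, length.out = 20))
  tc1 <- decision_locked_timecourse(one, bin_ms = 100, span_ms = 1000)
  expect_true(all(tc1$mean_prop == 1))
})

test_that("stimulus-locked time-course sits at chance before onset and rises after", {
  ds <- simulate_vwp_study(clean_config(6, n_trials = 6, seed = 27,
    preference = list(p_target_online = 0.9, p_target_lab = 0.9)))
  clean <- apply_exclusions(preprocess_dataset(ds, axes = "xy"))
  tc <- stimulus_locked_timecourse(clean, bin_ms = 200,
                                   span_ms = c(-1000, 2000))
  pre_bins <- tc$mean_prop[tc$bin_end_ms <= 0]
  post_bins <- tc$mean_prop[tc$bin_start_ms >= 400]
  expect_lt(abs(mean(pre_bins) - 0.25), 0.05)
  expect_gt(mean(post_bins), 0.8)
})

test_that("paired condition comparison recovers direction and decomposition", {
  on <- tibble::tibble(participant_id = 1:20, condition = "online",
                       mean_prop = seq(0.4, 0.6, length.out = 20),
                       n_trials_retained = 10)
  lab <- dplyr::mutate(on, condition = "lab", mean_prop = mean_prop + 0.19)
  cmp <- compare_conditions(on, lab, chance = 0.25)
  # constant shift: numerator ratio has closed form, SDs are equal
  expect_equal(cmp$numerator_ratio,
               (mean(on$mean_prop) - 0.25) / (mean(lab$mean_prop) - 0.25))
  expect_equal(cmp$sd_ratio, 1)
  expect_equal(cmp$test$t, Inf)  # constant shift: infinite paired evidence
  expect_equal(cmp$test$p, 0)

  # identical conditions: degenerate stand-in, ratios 1
  same <- compare_conditions(on, dplyr::mutate(on, condition = "lab"),
                             chance = 0.25)
  expect_equal(same$test$t, 0)
  expect_equal(same$numerator_ratio, 1)
  expect_equal(same$sd_ratio, 1)

  expect_error(compare_conditions(on, lab[-1, ], chance = 0.25),
               "only one condition")
})
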