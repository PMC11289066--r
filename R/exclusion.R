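#' Exclusion criteria for the preregistered cascade of filters
#'
#' Collects every threshold used by the participant-, trial- and sample-level
#' exclusion rules, plus the non-preregistered sensitivity filters. Defaults
#' follow the preregistered analysis plan for webcam AOI studies:
#' participants are dropped for frozen gaze estimates (zero variation),
#' invariant responses, more than 50% of stimulus-phase samples outside all
#' AOIs, or more than 50% missing trials; trials are dropped when the
#' corrected midline strays too far from the true midline (25% of screen
#' width in two-AOI mode; in four-AOI mode 25% of screen height vertically or
#' 37.5% of screen width horizontally), when the fixation-sample dispersion
#' `sd_x` exceeds 25% of screen width, or when the response time falls
#' outside \[0.5 s, 30 s\]; samples are dropped when outside every corrected
#' AOI (and optionally when live-feed-flagged).
#'
#' All "more than" thresholds are strict (`>`): boundary cases are retained.
#'
#' @param max_offaoi_frac Participant rule: max tolerated fraction of
#'   stimulus-phase samples outside all AOIs.
#' @param max_missing_frac Participant rule: max tolerated fraction of trials
#'   with no gaze data.
#' @param midline_dev_frac_w Trial rule, two-AOI mode: max |corrected -
#'   true| midline deviation as a fraction of screen width.
#' @param midline_dev_frac_w_4aoi,midline_dev_frac_h_4aoi Trial rule,
#'   four-AOI mode: horizontal limit as a fraction of screen width and
#'   vertical limit as a fraction of screen height (exceeding either flags
#'   the trial).
#' @param midline_sd_frac Trial rule: max `sd_x` as a fraction of screen
#'   width.
#' @param rt_min_s,rt_max_s Trial rule (response paradigms): response-time
#'   bounds in seconds.
#' @param max_attention_failures Sensitivity rule: participants failing more
#'   than this many attention checks are dropped (strictly more than one,
#'   i.e. >= 2 failures, by default).
#' @param min_instruction_s Sensitivity rule: participants who clicked
#'   through the instruction screen faster than this are dropped.
#' @param unreliable_level Sensitivity rule: participants whose self-reported
#'   data reliability is at or below this level (1 = "unreliable, do not use
#'   my data") are dropped.
#' @return An `exclusion_criteria` list.
#' @export
exclusion_criteria <- function(max_offaoi_frac = 0.5,
                               max_missing_frac = 0.5,
                               midline_dev_frac_w = 0.25,
                               midline_dev_frac_w_4aoi = 0.375,
                               midline_dev_frac_h_4aoi = 0.25,
                               midline_sd_frac = 0.25,
                               rt_min_s = 0.5, rt_max_s = 30,
                               max_attention_failures = 1,
                               min_instruction_s = 7.5,
                               unreliable_level = 1) {
  stopifnot(
    max_offaoi_frac > 0, max_offaoi_frac <= 1,
    max_missing_frac > 0, max_missing_frac <= 1,
    midline_dev_frac_w > 0, midline_dev_frac_w <= 1,
    midline_dev_frac_w_4aoi > 0, midline_dev_frac_w_4aoi <= 1,
    midline_dev_frac_h_4aoi > 0, midline_dev_frac_h_4aoi <= 1,
    midline_sd_frac > 0, midline_sd_frac <= 1,
    rt_min_s < rt_max_s
  )
  structure(as.list(environment()), class = "exclusion_criteria")
}

#' Participant-level exclusion flags
#'
#' Applies the participant rules in their preregistered order and reports the
#' first rule each excluded participant triggers: (1) no variation in
#' estimated gaze across all trials (exactly zero SD in both x and y — the
#' frozen-estimator failure mode); (2) no variation in responses (all chosen
#' sides identical; response paradigms only); (3) more than 50% of
#' stimulus-phase samples outside all corrected AOIs; (4) more than 50% of
#' trials missing (no gaze data).
#'
#' @param pre A `gaze_preprocessed` object.
#' @param criteria An [exclusion_criteria()].
#' @return Tibble: `participant_id`, `excluded`, `rule` (`NA` if retained).
#' @export
flag_participants <- function(pre, criteria = exclusion_criteria()) {
  if (nrow(pre$gaze) == 0) stop("empty dataset")
  stim <- pre$gaze |> filter(phase != "fixation")

  gaze_var <- pre$gaze |>
    group_by(participant_id) |>
    summarise(zero_var = sd(x_px) == 0 && sd(y_px) == 0, .groups = "drop")

  resp_var <- if ("chosen_label" %in% names(pre$trials) &&
                  any(!is.na(pre$trials$chosen_label))) {
    pre$trials |>
      group_by(participant_id) |>
      summarise(no_resp = dplyr::n_distinct(chosen_label) == 1 &&
                  dplyr::n() > 1, .groups = "drop")
  } else {
    tibble(participant_id = unique(pre$trials$participant_id),
           no_resp = FALSE)
  }

  off <- stim |>
    group_by(participant_id) |>
    summarise(off_frac = mean(is.na(aoi)), .groups = "drop")

  expected <- pre$trials |> count(participant_id, name = "n_expected")
  observed <- pre$gaze |>
    distinct(participant_id, condition, trial_id) |>
    count(participant_id, name = "n_observed")
  missing <- expected |>
    left_join(observed, by = "participant_id") |>
    mutate(missing_frac = 1 - coalesce(n_observed, 0L) / n_expected)

  tibble(participant_id = sort(unique(pre$trials$participant_id))) |>
    left_join(gaze_var, by = "participant_id") |>
    left_join(resp_var, by = "participant_id") |>
    left_join(off, by = "participant_id") |>
    left_join(missing[, c("participant_id", "missing_frac")],
              by = "participant_id") |>
    mutate(
      rule = dplyr::case_when(
        coalesce(zero_var, TRUE) ~ "no_gaze_variation",
        coalesce(no_resp, FALSE) ~ "no_response_variation",
        coalesce(off_frac, 1) > criteria$max_offaoi_frac ~ "off_aoi",
        missing_frac > criteria$max_missing_frac ~ "missing_data",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(rule)
    ) |>
    select(participant_id, excluded, rule)
}

#' Trial-level exclusion flags
#'
#' Rules, in order of precedence: missing bias estimate; corrected-midline
#' deviation beyond the mode-specific screen-fraction limit (two-AOI: 25% of
#' screen width; four-AOI: 25% of screen height vertically or 37.5% of screen
#' width horizontally); fixation-sample dispersion `sd_x` above 25% of screen
#' width; response time outside the \[0.5 s, 30 s\] bounds (trials with a
#' recorded response time only).
#'
#' @param pre A `gaze_preprocessed` object.
#' @param criteria An [exclusion_criteria()].
#' @param study_mode `"two_aoi"` or `"four_aoi"`; defaults by paradigm.
#' @return Tibble: keys, `excluded`, `rule`.
#' @export
flag_trials <- function(pre, criteria = exclusion_criteria(),
                        study_mode = NULL) {
  if (is.null(study_mode))
    study_mode <- if (pre$paradigm == "vwp") "four_aoi" else "two_aoi"
  study_mode <- match.arg(study_mode, c("two_aoi", "four_aoi"))
  keys <- c("participant_id", "condition", "trial_id")

  tr <- pre$trials |>
    left_join(pre$biases, by = keys) |>
    mutate(
      dev_x = abs(corrected_midline_x - true_midline_x),
      dev_y = abs(corrected_midline_y - true_midline_y),
      midline_out = if (study_mode == "two_aoi") {
        dev_x > criteria$midline_dev_frac_w * screen_w
      } else {
        dev_x > criteria$midline_dev_frac_w_4aoi * screen_w |
          coalesce(dev_y > criteria$midline_dev_frac_h_4aoi * screen_h, FALSE)
      },
      sd_out = coalesce(sd_x, 0) > criteria$midline_sd_frac * screen_w,
      rt_out = if ("response_time_ms" %in% names(pre$trials)) {
        !is.na(response_time_ms) &
          (response_time_ms < criteria$rt_min_s * 1000 |
             response_time_ms > criteria$rt_max_s * 1000)
      } else FALSE,
      rule = dplyr::case_when(
        is.na(dx) ~ "no_bias_estimate",
        midline_out ~ "midline_deviation",
        sd_out ~ "midline_sd",
        rt_out ~ "response_time",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(rule)
    )
  tr[, c(keys, "excluded", "rule")]
}

#' Sample-level filter
#'
#' Drops stimulus-phase samples assigned to no AOI and, optionally, samples
#' carrying the live-feed flag (estimator lost the eyes). Fixation-phase
#' samples are not part of the analyzed stream and are dropped here too.
#'
#' @param pre A `gaze_preprocessed` object.
#' @param drop_live_feed Also drop live-feed-flagged samples?
#' @return List: `gaze` (retained samples) and `counts`, a one-row tibble
#'   with `n_stimulus`, `n_off_aoi`, `frac_off_aoi`, `n_live_feed`,
#'   `frac_live_feed`, `n_retained`.
#' @export
filter_samples <- function(pre, drop_live_feed = FALSE) {
  stim <- pre$gaze |> filter(phase != "fixation")
  off <- is.na(stim$aoi)
  live <- !off & stim$live_feed & drop_live_feed
  counts <- tibble(
    n_stimulus = nrow(stim),
    n_off_aoi = sum(off),
    frac_off_aoi = mean(off),
    n_live_feed = sum(live),
    frac_live_feed = if (nrow(stim)) mean(live) else 0,
    n_retained = sum(!off & !live)
  )
  list(gaze = stim[!off & !live, ], counts = counts)
}

#' Apply the full exclusion cascade
#'
#' Participant rules, then trial rules, then the sample filter, with an
#' auditable retention table at each stage.
#'
#' @param pre A `gaze_preprocessed` object.
#' @param criteria An [exclusion_criteria()].
#' @param study_mode See [flag_trials()].
#' @param drop_live_feed See [filter_samples()].
#' @param sensitivity_level One of `"base"`, `"+attention"`,
#'   `"+instruction"`, `"+self_report"`, `"+live_feed"`: cumulative
#'   sensitivity filters applied on top of the preregistered cascade (see
#'   [sensitivity_filter()]).
#' @return A `gaze_clean` list: `gaze` (retained, AOI-labeled samples),
#'   `trials` (retained trials), `participant_flags`, `trial_flags`,
#'   `sample_counts`, `retention` (stage-by-stage counts), plus the
#'   pass-through tables (`biases`, `truth`, `participants`, ...).
#' @export
apply_exclusions <- function(pre, criteria = exclusion_criteria(),
                             study_mode = NULL, drop_live_feed = FALSE,
                             sensitivity_level = "base") {
  keys <- c("participant_id", "condition", "trial_id")
  pflags <- flag_participants(pre, criteria)

  if (sensitivity_level != "base") {
    sens <- sensitivity_filter(pre$participants, sensitivity_level, criteria)
    extra <- sens$flags |> filter(excluded)
    pflags <- pflags |>
      mutate(
        rule = ifelse(!excluded & participant_id %in% extra$participant_id,
                      extra$rule[match(participant_id, extra$participant_id)],
                      rule),
        excluded = excluded | participant_id %in% extra$participant_id
      )
    drop_live_feed <- drop_live_feed || sensitivity_level == "+live_feed"
  }

  keep_p <- pflags$participant_id[!pflags$excluded]
  tflags <- flag_trials(pre, criteria, study_mode) |>
    filter(participant_id %in% keep_p)
  keep_t <- tflags |> filter(!excluded)

  pre_kept <- pre
  pre_kept$gaze <- pre$gaze |>
    semi_join(keep_t[, keys], by = keys)
  samp <- filter_samples(pre_kept, drop_live_feed)

  retention <- tibble(
    stage = c("participants", "trials", "samples"),
    total = c(nrow(pflags), nrow(tflags), samp$counts$n_stimulus),
    excluded = c(sum(pflags$excluded), sum(tflags$excluded),
                 samp$counts$n_stimulus - samp$counts$n_retained),
    retained = c(sum(!pflags$excluded), sum(!tflags$excluded),
                 samp$counts$n_retained)
  )

  structure(
    list(
      gaze = samp$gaze,
      trials = pre$trials |> semi_join(keep_t[, keys], by = keys),
      biases = pre$biases, truth = pre$truth,
      participants = pre$participants, calibration = pre$calibration,
      participant_flags = pflags, trial_flags = tflags,
      sample_counts = samp$counts, retention = retention,
      paradigm = pre$paradigm, config = pre$config
    ),
    class = "gaze_clean"
  )
}

#' Cumulative sensitivity filters on participant-level auxiliary data
#'
#' The non-preregistered sensitivity cascade, applied in hierarchical order:
#' `+attention` (more than `max_attention_failures` failed attention checks),
#' `+instruction` (instruction screen clicked through in under
#' `min_instruction_s` seconds), `+self_report` (self-rated data reliability
#' at the "unreliable" level), `+live_feed` (sample-level live-feed drop,
#' handled in [filter_samples()]). Each level includes all previous levels.
#'
#' @param participants Tibble with `participant_id` and the auxiliary columns
#'   a requested level needs: `attention_failures`, `instruction_time_s`,
#'   `self_report_reliability`.
#' @param level One of `"base"`, `"+attention"`, `"+instruction"`,
#'   `"+self_report"`, `"+live_feed"`.
#' @param criteria An [exclusion_criteria()].
#' @return List: `flags` (tibble `participant_id`, `excluded`, `rule`) and
#'   `retention` (per-level retained participant counts, cumulative).
#' @export
sensitivity_filter <- function(participants, level = "base",
                               criteria = exclusion_criteria()) {
  levels_all <- c("base", "+attention", "+instruction", "+self_report",
                  "+live_feed")
  level <- match.arg(level, levels_all)
  k <- match(level, levels_all)

  need <- character()
  if (k >= 2) need <- c(need, "attention_failures")
  if (k >= 3) need <- c(need, "instruction_time_s")
  if (k >= 4) need <- c(need, "self_report_reliability")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("sensitivity level '", level, "' requires missing field(s): ",
         paste(miss, collapse = ", "))

  flags <- tibble(participant_id = participants$participant_id,
                  rule = NA_character_)
  if (k >= 2)
    flags$rule[is.na(flags$rule) &
                 participants$attention_failures >
                   criteria$max_attention_failures] <- "attention_checks"
  if (k >= 3)
    flags$rule[is.na(flags$rule) &
                 participants$instruction_time_s <
                   criteria$min_instruction_s] <- "instruction_screen"
  if (k >= 4)
    flags$rule[is.na(flags$rule) &
                 participants$self_report_reliability <=
                   criteria$unreliable_level] <- "unreliable_data"
  flags$excluded <- !is.na(flags$rule)

  retention <- tibble(
    level = levels_all[seq_len(k)],
    n_retained = vapply(seq_len(k), function(j) {
      f <- sensitivity_rules_upto(participants, j, criteria)
      sum(!f)
    }, 0L)
  )
  list(flags = flags[, c("participant_id", "excluded", "rule")],
       retention = retention)
}

sensitivity_rules_upto <- function(participants, k, criteria) {
  excl <- rep(FALSE, nrow(participants))
  if (k >= 2)
    excl <- excl | participants$attention_failures >
      criteria$max_attention_failures
  if (k >= 3)
    excl <- excl | participants$instruction_time_s < criteria$min_instruction_s
  if (k >= 4)
    excl <- excl | participants$self_report_reliability <=
      criteria$unreliable_level
  excl
}
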