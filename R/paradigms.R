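#' Per-trial decision-locked viewing proportion (gaze cascade)
#'
#' For every retained trial, the proportion of in-AOI samples that fall on
#' the eventually chosen AOI inside the window
#' `[response - window_ms, response)` (right-open: the response moment itself
#' is excluded). The denominator is the number of in-AOI samples in the
#' window; trials without any are returned with a missing proportion.
#'
#' @param clean A `gaze_clean` object (cascade paradigm), or any list with
#'   AOI-labeled `gaze` and `trials` tables.
#' @param window_ms Window length before the response, ms.
#' @return Tibble: keys, `prop` (chosen-AOI proportion), `n_in_aoi`,
#'   `n_total`, `win_start_ms`, `win_end_ms`.
#' @export
cascade_proportion <- function(clean, window_ms = 100) {
  keys <- c("participant_id", "condition", "trial_id")
  tr <- clean$trials
  resp_abs <- tr$stim_onset_ms + tr$response_time_ms
  win <- tr[, keys]
  win$win_start_ms <- resp_abs - window_ms
  win$win_end_ms <- resp_abs
  win$chosen <- tr$chosen_label

  clean$gaze |>
    inner_join(win, by = keys) |>
    filter(t_ms >= win_start_ms, t_ms < win_end_ms) |>
    group_by(across(all_of(keys))) |>
    summarise(
      prop = mean(aoi == chosen),
      n_in_aoi = dplyr::n(),
      win_start_ms = first(win_start_ms),
      win_end_ms = first(win_end_ms),
      .groups = "drop"
    ) |>
    right_join(win[, c(keys, "win_start_ms", "win_end_ms")],
               by = c(keys, "win_start_ms", "win_end_ms")) |>
    mutate(n_in_aoi = coalesce(n_in_aoi, 0L), n_total = n_in_aoi) |>
    arrange(across(all_of(keys)))
}

#' Per-trial novelty preference proportion
#'
#' Proportion of in-AOI test-phase samples on the novel AOI.
#'
#' @param clean A `gaze_clean` object (novelty paradigm).
#' @return Tibble: keys, `prop`, `n_in_aoi`, `n_total`, window bounds.
#' @export
novelty_proportion <- function(clean) {
  keys <- c("participant_id", "condition", "trial_id")
  tr <- clean$trials
  win <- tr[, keys]
  win$win_start_ms <- tr$test_onset_ms
  win$win_end_ms <- tr$test_onset_ms + tr$test_dur_ms
  win$novel <- tr$novel_label

  clean$gaze |>
    filter(phase == "test") |>
    inner_join(win, by = keys) |>
    filter(t_ms >= win_start_ms, t_ms < win_end_ms) |>
    group_by(across(all_of(keys))) |>
    summarise(
      prop = mean(aoi == novel),
      n_in_aoi = dplyr::n(),
      win_start_ms = first(win_start_ms),
      win_end_ms = first(win_end_ms),
      .groups = "drop"
    ) |>
    right_join(win[, c(keys, "win_start_ms", "win_end_ms")],
               by = c(keys, "win_start_ms", "win_end_ms")) |>
    mutate(n_in_aoi = coalesce(n_in_aoi, 0L), n_total = n_in_aoi) |>
    arrange(across(all_of(keys)))
}

#' Per-trial, per-role viewing proportions (visual world paradigm)
#'
#' Proportions of in-AOI samples on the target AOI and on each distractor
#' AOI, inside the analysis window `[target_onset + start_offset_ms,
#' target_onset + start_offset_ms + window_ms)`. Within a trial the
#' proportions over roles sum to 1 (the denominator is the in-AOI sample
#' count of the window). The window placement is configurable because it is a
#' analysis convention: the default opens 200 ms after target-word onset
#' (saccade-programming latency) and spans 400 ms.
#'
#' @param clean A `gaze_clean` object (visual world paradigm).
#' @param start_offset_ms Offset of the window start after target-word
#'   onset, ms.
#' @param window_ms Window length, ms.
#' @return Long tibble: keys, `label`, `role` ("target"/"distractor"),
#'   `prop`, `n_in_aoi`, `n_total`.
#' @export
vwp_proportion <- function(clean, start_offset_ms = 200, window_ms = 400) {
  keys <- c("participant_id", "condition", "trial_id")
  tr <- clean$trials
  win <- tr[, keys]
  win$win_start_ms <- tr$target_onset_ms + start_offset_ms
  win$win_end_ms <- win$win_start_ms + window_ms
  win$target <- tr$target_label

  hits <- clean$gaze |>
    inner_join(win, by = keys) |>
    filter(t_ms >= win_start_ms, t_ms < win_end_ms)

  labels <- sort(unique(clean$gaze$aoi))
  totals <- hits |>
    group_by(across(all_of(keys))) |>
    summarise(n_in_aoi = dplyr::n(), target = first(target),
              .groups = "drop")
  counts <- hits |>
    count(across(all_of(keys)), aoi, name = "n_lab")

  tidyr::crossing(totals, tibble(label = labels)) |>
    left_join(counts, by = stats::setNames(c(keys, "aoi"), c(keys, "label"))) |>
    mutate(
      role = ifelse(label == target, "target", "distractor"),
      prop = coalesce(n_lab, 0L) / n_in_aoi,
      n_total = n_in_aoi
    ) |>
    select(all_of(keys), label, role, prop, n_in_aoi, n_total) |>
    arrange(across(all_of(keys)), label)
}

#' Decision-locked time-course of chosen-AOI looking
#'
#' Bins samples by time measured backward from the response moment and
#' returns the per-bin chosen-AOI proportion, averaged over trials within
#' participants first and then over participants, with the across-participant
#' SEM.
#'
#' @param clean A `gaze_clean` object (cascade paradigm).
#' @param bin_ms Bin width, ms.
#' @param span_ms Total span before the response, ms.
#' @return Tibble: `bin_start_ms`, `bin_end_ms` (relative to the response,
#'   negative), `mean_prop`, `sem`, `n_participants`.
#' @export
decision_locked_timecourse <- function(clean, bin_ms = 100, span_ms = 2000) {
  keys <- c("participant_id", "condition", "trial_id")
  tr <- clean$trials
  win <- tr[, keys]
  win$resp_abs <- tr$stim_onset_ms + tr$response_time_ms
  win$chosen <- tr$chosen_label

  timecourse_core(
    clean$gaze |>
      inner_join(win, by = keys) |>
      mutate(t_rel = t_ms - resp_abs, on_target = aoi == chosen) |>
      filter(t_rel >= -span_ms, t_rel < 0),
    bin_ms
  )
}

#' Stimulus-locked time-course of target looking
#'
#' As [decision_locked_timecourse()], but time runs forward from the
#' target-word onset and the tracked AOI is the target.
#'
#' @param clean A `gaze_clean` object (visual world paradigm).
#' @param bin_ms Bin width, ms.
#' @param span_ms Length-2 numeric: window around onset, ms (e.g.
#'   `c(-1000, 3000)`).
#' @return Tibble as in [decision_locked_timecourse()].
#' @export
stimulus_locked_timecourse <- function(clean, bin_ms = 100,
                                       span_ms = c(-1000, 3000)) {
  keys <- c("participant_id", "condition", "trial_id")
  tr <- clean$trials
  win <- tr[, keys]
  win$onset <- tr$target_onset_ms
  win$target <- tr$target_label

  timecourse_core(
    clean$gaze |>
      inner_join(win, by = keys) |>
      mutate(t_rel = t_ms - onset, on_target = aoi == target) |>
      filter(t_rel >= span_ms[1], t_rel < span_ms[2]),
    bin_ms
  )
}

timecourse_core <- function(samples, bin_ms) {
  if (nrow(samples) == 0)
    return(tibble(bin_start_ms = numeric(), bin_end_ms = numeric(),
                  mean_prop = numeric(), sem = numeric(),
                  n_participants = integer()))
  samples |>
    mutate(bin = floor(t_rel / bin_ms) * bin_ms) |>
    group_by(participant_id, condition, trial_id, bin) |>
    summarise(prop = mean(on_target), .groups = "drop") |>
    group_by(participant_id, condition, bin) |>
    summarise(prop = mean(prop), .groups = "drop") |>
    group_by(bin) |>
    summarise(
      mean_prop = mean(prop),
      sem = sd(prop) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    transmute(bin_start_ms = bin, bin_end_ms = bin + bin_ms,
              mean_prop, sem, n_participants)
}

#' Aggregate per-trial proportions to participant summaries
#'
#' Unweighted mean of trial proportions per participant (each retained trial
#' counts equally, regardless of its sample count). Trials with no in-AOI
#' window samples are dropped; participants with no remaining trial are
#' dropped with a warning.
#'
#' @param trial_results Tibble from [cascade_proportion()],
#'   [novelty_proportion()], or the target rows of [vwp_proportion()].
#' @return Tibble: `participant_id`, `condition`, `mean_prop`,
#'   `n_trials_retained`.
#' @export
aggregate_participants <- function(trial_results) {
  ok <- trial_results |> filter(!is.na(prop))
  dropped <- setdiff(unique(trial_results$participant_id),
                     unique(ok$participant_id))
  if (length(dropped))
    warning("dropping participant(s) with no scored trial: ",
            paste(dropped, collapse = ", "))
  ok |>
    group_by(participant_id, condition) |>
    summarise(mean_prop = mean(prop), n_trials_retained = dplyr::n(),
              .groups = "drop")
}

#' Paired comparison of online and lab condition summaries
#'
#' One-sided paired t test (lab greater than online) with JZS Bayes factor,
#' plus the effect-size decomposition: the ratio of the Cohen's-d numerators
#' (mean minus chance, online over lab) and the ratio of the across-
#' participant SDs (online over lab). A numerator ratio of 0.59 reads as "the
#' online effect mean is 41% smaller"; an SD ratio of 1.32 as "the online SD
#' is 32% larger".
#'
#' If the paired differences have zero variance the t statistic is
#' degenerate and no Bayes factor is defined; identical conditions return
#' t = 0, p = 0.5 (and unit ratios), while a constant shift returns an
#' infinite t in the shift's direction rather than erroring.
#'
#' @param online,lab [aggregate_participants()] tibbles for the two
#'   conditions of the same participants.
#' @param chance Chance-level proportion (0.25 for four AOIs).
#' @param scale Cauchy prior scale for the Bayes factor.
#' @return List: `test` (a `gaze_stat` from [paired_t()] or the degenerate
#'   stand-in), `numerator_ratio`, `sd_ratio`, `mean_online`, `mean_lab`,
#'   `n`.
#' @export
compare_conditions <- function(online, lab, chance = 0.25, scale = 0.707) {
  o <- online |> arrange(participant_id)
  l <- lab |> arrange(participant_id)
  unmatched <- c(setdiff(o$participant_id, l$participant_id),
                 setdiff(l$participant_id, o$participant_id))
  if (length(unmatched))
    stop("participants present in only one condition: ",
         paste(sort(unique(unmatched)), collapse = ", "))
  a <- l$mean_prop
  b <- o$mean_prop[match(l$participant_id, o$participant_id)]

  num_ratio <- (mean(b) - chance) / (mean(a) - chance)
  sd_ratio <- sd(b) / sd(a)

  test <- if (sd(a - b) <
              sqrt(.Machine$double.eps) * max(1, abs(mean(a - b)))) {
    ## degenerate paired differences: identical conditions give t = 0; a
    ## constant shift gives infinite evidence in the shift's direction
    m <- mean(a - b)
    if (abs(m) < sqrt(.Machine$double.eps)) m <- 0
    structure(list(t = if (m == 0) 0 else Inf * sign(m),
                   df = length(a) - 1L,
                   p = if (m == 0) 0.5 else if (m > 0) 0 else 1,
                   d = if (m == 0) 0 else Inf * sign(m),
                   d_ci_lower = NA_real_, bf10 = NA_real_, n = length(a),
                   alternative = "greater", mu0 = 0, mean = m,
                   sd = 0, degenerate = TRUE),
              class = "gaze_stat")
  } else {
    paired_t(a, b, alternative = "greater", scale = scale)
  }
  list(test = test, numerator_ratio = num_ratio, sd_ratio = sd_ratio,
       mean_online = mean(b), mean_lab = mean(a), n = length(a))
}
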