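#' Run the full analysis pipeline
#'
#' Chains simulate (or read) -> preprocess -> exclude -> analyze -> test for
#' one study design and returns an auditable run report. The run is fully
#' deterministic given the configuration (all randomness flows from
#' `config$sim$seed`).
#'
#' @param config A [pipeline_config()].
#' @return A `gaze_run_report` list: `study`, `paradigm`, `config`,
#'   `correction` (correction-magnitude summary), `retention` (cascade
#'   retention table), `sample_counts`, `participant_summary`,
#'   `trial_results`, `group` (the group-level `gaze_stat` against chance),
#'   `binomial_p` (one-sided sign test of participants above chance),
#'   `timecourse`, and for study 3 additionally `comparison`
#'   ([compare_conditions()] output) and `calibration` (per-condition mean
#'   scores and the score-effect correlation). `elapsed_s` records wall time
#'   and is excluded from written outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()["elapsed"]
  ds <- if (!is.null(config$input_dir)) read_gaze_dataset(config$input_dir)
    else switch(config$study,
                simulate_cascade_study(config$sim),
                simulate_novelty_study(config$sim),
                simulate_vwp_study(config$sim))

  pre <- preprocess_dataset(ds, axes = config$axes,
                            tail_fraction = config$tail_fraction)
  clean <- apply_exclusions(pre, config$criteria,
                            drop_live_feed = config$drop_live_feed,
                            sensitivity_level = config$sensitivity_level)

  chance <- if (config$study == 3) 0.25 else 0.5
  if (config$study == 1) {
    tr <- cascade_proportion(clean, window_ms = config$cascade_window_ms)
    timecourse <- decision_locked_timecourse(clean)
  } else if (config$study == 2) {
    tr <- novelty_proportion(clean)
    timecourse <- NULL
  } else {
    roles <- vwp_proportion(clean,
                            start_offset_ms = config$vwp_start_offset_ms,
                            window_ms = config$vwp_window_ms)
    tr <- roles |> filter(role == "target")
    timecourse <- stimulus_locked_timecourse(clean)
  }

  agg <- suppressWarnings(aggregate_participants(tr))
  agg_test <- if (config$study == 3) agg |> filter(condition == "online")
    else agg
  group <- one_sample_t(agg_test$mean_prop, mu0 = chance,
                        alternative = "greater")
  binomial_p <- binomial_test_one_sided(sum(agg_test$mean_prop > chance),
                                        nrow(agg_test), 0.5)

  ## the correction summary describes the webcam block (the lab block's
  ## bias is near zero by design)
  bias_online <- if (config$study == 3)
    pre$biases |> filter(condition == "online") else pre$biases
  report <- list(
    study = config$study, paradigm = ds$paradigm, config = config,
    correction = correction_summary(bias_online),
    retention = clean$retention,
    sample_counts = clean$sample_counts,
    participant_summary = agg,
    trial_results = tr,
    group = group,
    binomial_p = binomial_p,
    timecourse = timecourse
  )

  if (config$study == 3) {
    online <- agg |> filter(condition == "online")
    lab <- agg |> filter(condition == "lab")
    common <- intersect(online$participant_id, lab$participant_id)
    report$comparison <- compare_conditions(
      online |> filter(participant_id %in% common),
      lab |> filter(participant_id %in% common),
      chance = 0.25
    )
    if (!is.null(clean$calibration))
      report$calibration <- calibration_report(clean$calibration, online,
                                               ds$config, chance)
  }

  report$elapsed_s <- unname(proc.time()["elapsed"] - t0)
  class(report) <- "gaze_run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

## Per-participant calibration scores per condition, their summary, and the
## correlation between online calibration score and online effect size
## (participant mean proportion minus chance).
calibration_report <- function(calibration, online_summary, sim, chance) {
  center <- c(sim$screen_w / 2, sim$screen_h / 2)
  scores <- calibration |>
    group_by(participant_id, condition) |>
    group_modify(~ tibble(score = calibration_score(.x, center = center))) |>
    ungroup()
  summary <- scores |>
    group_by(condition) |>
    summarise(mean_score = mean(score, na.rm = TRUE),
              sd_score = sd(score, na.rm = TRUE), .groups = "drop")
  on <- scores |>
    filter(condition == "online") |>
    inner_join(online_summary, by = "participant_id")
  corr <- if (nrow(on) >= 3 && sd(on$score) > 0 && sd(on$mean_prop) > 0)
    pearson_r(on$score, on$mean_prop - chance) else NULL
  list(scores = scores, summary = summary, score_effect_correlation = corr)
}

#' @export
print.gaze_run_report <- function(x, ...) {
  cat(sprintf("<gaze_run_report> study %d (%s)\n", x$study, x$paradigm))
  cat("Retention:\n")
  print(as.data.frame(x$retention), row.names = FALSE)
  cat(sprintf("Off-AOI samples: %.1f%%\n",
              100 * x$sample_counts$frac_off_aoi))
  cat("Correction magnitudes (px):\n")
  print(as.data.frame(x$correction), row.names = FALSE)
  cat(sprintf("Group proportion: %.3f (chance %.2f)\n",
              mean(x$participant_summary$mean_prop[
                x$participant_summary$condition == "online"]),
              ifelse(x$study == 3, 0.25, 0.5)))
  print(x$group)
  if (!is.null(x$comparison)) {
    cat(sprintf("Lab %.3f vs online %.3f; numerator ratio %.2f, SD ratio %.2f\n",
                x$comparison$mean_lab, x$comparison$mean_online,
                x$comparison$numerator_ratio, x$comparison$sd_ratio))
    print(x$comparison$test)
  }
  if (!is.null(x$calibration)) {
    cat("Calibration scores:\n")
    print(as.data.frame(x$calibration$summary), row.names = FALSE)
    if (!is.null(x$calibration$score_effect_correlation))
      cat(sprintf("Score-effect correlation: r = %.3f, p = %.3f\n",
                  x$calibration$score_effect_correlation$r,
                  x$calibration$score_effect_correlation$p))
  }
  invisible(x)
}

## Machine-readable outputs (timestamps and wall time excluded so identical
## configs produce byte-identical files).
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wr(report$retention, "retention.csv")
  wr(report$participant_summary, "participant_summary.csv")
  wr(report$trial_results, "trial_results.csv")
  wr(report$correction, "correction_summary.csv")
  if (!is.null(report$timecourse)) wr(report$timecourse, "timecourse.csv")
  g <- report$group
  wr(tibble(statistic = c("t", "df", "p", "d", "d_ci_lower", "bf10", "n",
                          "binomial_p"),
            value = c(g$t, g$df, g$p, g$d, g$d_ci_lower, g$bf10, g$n,
                      report$binomial_p)),
     "group_stats.csv")
  log_path <- file.path(dir, "summary.txt")
  con <- file(log_path, open = "wt", encoding = "UTF-8")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(dir)
}

#' Time-course plot helper
#'
#' Minimal ggplot of a time-course table (mean proportion per bin with a SEM
#' ribbon). Requires ggplot2.
#'
#' @param timecourse Output of [decision_locked_timecourse()] or
#'   [stimulus_locked_timecourse()].
#' @param chance Chance level reference line.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse, chance = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_timecourse requires ggplot2")
  mid <- (timecourse$bin_start_ms + timecourse$bin_end_ms) / 2
  df <- tibble(t = mid, y = timecourse$mean_prop, s = timecourse$sem)
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = y - s, ymax = y + s),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = "Proportion on tracked AOI")
}
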