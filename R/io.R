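#' Write a gaze dataset as delimited text tables
#'
#' Writes `gaze.csv`, `trials.csv`, `aois.csv`, `truth.csv`,
#' `participants.csv` (and `calibration.csv` when present) plus a
#' `config.yaml` echo into `dir`. All tables are UTF-8, comma-separated with
#' a header row; the column schema is the one documented in
#' [read_gaze_table()] and the simulators.
#'
#' @param dataset A `gaze_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gaze_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wr(dataset$gaze, "gaze.csv")
  wr(dataset$trials, "trials.csv")
  wr(dataset$aois, "aois.csv")
  wr(dataset$truth, "truth.csv")
  wr(dataset$participants, "participants.csv")
  if (!is.null(dataset$calibration))
    wr(dataset$calibration, "calibration.csv")
  cfg <- dataset$config
  cfg$paradigm <- dataset$paradigm
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read and validate a gaze sample table
#'
#' Expected columns: `participant_id`, `trial_id`, `phase`, `t_ms`, `x_px`,
#' `y_px`, `live_feed` (an optional `condition` column defaults to
#' `"online"`). Rows with unparseable coordinates or timestamps are rejected
#' with their line numbers; non-monotone timestamps within a trial are an
#' error.
#'
#' @param path CSV file path.
#' @return Validated tibble of gaze samples.
#' @export
read_gaze_table <- function(path) {
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("participant_id", "trial_id", "phase", "t_ms", "x_px", "y_px",
                "live_feed")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("gaze table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"condition" %in% names(raw)) raw$condition <- "online"
  raw$t_ms <- suppressWarnings(as.numeric(raw$t_ms))
  raw$x_px <- suppressWarnings(as.numeric(raw$x_px))
  raw$y_px <- suppressWarnings(as.numeric(raw$y_px))
  raw$live_feed <- as.logical(raw$live_feed)
  bad <- which(is.na(raw$t_ms) | is.na(raw$x_px) | is.na(raw$y_px))
  if (length(bad)) {
    warning("rejecting ", length(bad), " malformed row(s) at line(s): ",
            paste(utils::head(bad + 1L, 20), collapse = ", "))
    raw <- raw[-bad, ]
  }
  g <- as_tibble(raw) |>
    select(participant_id, condition, trial_id, phase, t_ms, x_px, y_px,
           live_feed)
  mono <- g |>
    group_by(participant_id, condition, trial_id) |>
    summarise(ok = all(diff(t_ms) > 0), .groups = "drop")
  if (any(!mono$ok)) {
    bad_tr <- mono[!mono$ok, ]
    stop("non-monotone timestamps within trial(s): ",
         paste(sprintf("p%s/%s/t%s", bad_tr$participant_id,
                       bad_tr$condition, bad_tr$trial_id),
               collapse = ", "))
  }
  g
}

read_plain_table <- function(path, required) {
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"condition" %in% names(raw) && "condition" %in% required)
    raw$condition <- "online"
  as_tibble(raw)
}

#' Read a gaze dataset previously written by [write_gaze_dataset()]
#'
#' @param dir Directory holding the CSV tables and `config.yaml`.
#' @return A `gaze_dataset`.
#' @export
read_gaze_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  paradigm <- cfg$paradigm
  cfg$paradigm <- NULL
  calib_path <- file.path(dir, "calibration.csv")
  new_gaze_dataset(
    gaze = read_gaze_table(file.path(dir, "gaze.csv")),
    trials = read_plain_table(file.path(dir, "trials.csv"),
                              c("participant_id", "trial_id")),
    aois = read_plain_table(file.path(dir, "aois.csv"),
                            c("participant_id", "trial_id", "label",
                              "x_min", "x_max", "y_min", "y_max")),
    truth = read_plain_table(file.path(dir, "truth.csv"),
                             c("participant_id", "trial_id")),
    participants = read_plain_table(file.path(dir, "participants.csv"),
                                    "participant_id"),
    calibration = if (file.exists(calib_path))
      read_plain_table(calib_path, c("participant_id", "t_ms")) else NULL,
    paradigm = paradigm,
    config = structure(cfg, class = "sim_config")
  )
}

#' Pipeline configuration
#'
#' A single object governing an end-to-end run: which study design to
#' analyze, the simulation parameters (or an input directory of tables), the
#' preprocessing and exclusion settings, and the analysis windows.
#'
#' @param study 1 (cascade), 2 (novelty) or 3 (visual world, paired
#'   online/lab).
#' @param sim A [sim_config()]; its `seed` drives all randomness of the run.
#' @param input_dir Optional directory of tables written by
#'   [write_gaze_dataset()]; when given, data are read rather than simulated.
#' @param axes Correction axes; defaults to `"x"` for studies 1-2 and
#'   `"xy"` for study 3.
#' @param tail_fraction Fixation tail fraction for bias estimation.
#' @param criteria An [exclusion_criteria()].
#' @param sensitivity_level See [apply_exclusions()].
#' @param drop_live_feed Drop live-feed samples at the sample filter.
#' @param cascade_window_ms Pre-decision window (study 1).
#' @param vwp_start_offset_ms,vwp_window_ms Analysis window (study 3).
#' @param out_dir Optional output directory for the result tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study = 1, sim = NULL, input_dir = NULL,
                            axes = NULL, tail_fraction = 0.8,
                            criteria = exclusion_criteria(),
                            sensitivity_level = "base",
                            drop_live_feed = FALSE,
                            cascade_window_ms = 100,
                            vwp_start_offset_ms = 200, vwp_window_ms = 400,
                            out_dir = NULL) {
  stopifnot(study %in% 1:3)
  if (is.null(sim))
    sim <- switch(study, sim_config(n_trials = 18),
                  sim_config(n_trials = 10), sim_config(n_trials = 12))
  if (is.null(axes)) axes <- if (study == 3) "xy" else "x"
  structure(
    list(study = study, sim = sim, input_dir = input_dir, axes = axes,
         tail_fraction = tail_fraction, criteria = criteria,
         sensitivity_level = sensitivity_level,
         drop_live_feed = drop_live_feed,
         cascade_window_ms = cascade_window_ms,
         vwp_start_offset_ms = vwp_start_offset_ms,
         vwp_window_ms = vwp_window_ms, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim` key
#' holds [sim_config()] arguments; the `criteria` key holds
#' [exclusion_criteria()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  criteria <- if (!is.null(y$criteria)) do.call(exclusion_criteria, y$criteria)
    else exclusion_criteria()
  y$sim <- NULL
  y$criteria <- NULL
  do.call(pipeline_config, c(y, list(sim = sim, criteria = criteria)))
}
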