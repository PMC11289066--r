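#' Estimate per-trial measurement bias from the fixation period
#'
#' Webcam gaze estimates carry a roughly constant spatial offset within a
#' trial. It is estimated from the central fixation period at the start of
#' the trial: samples falling in the tailing `tail_fraction` of the fixation
#' window (by time, so the estimate is robust to irregular sampling) are kept
#' and the bias is their mean gaze position minus the fixation point, per
#' requested axis. The within-trial SD of the kept x values (`sd_x`) is also
#' returned; it feeds the corrected-midline dispersion exclusion rule.
#'
#' @param samples Tibble of fixation-phase gaze samples with `t_ms`, `x_px`,
#'   `y_px` (`t_ms` relative to trial start; the fixation window is
#'   `[0, layout$fixation_ms)`).
#' @param layout A `trial_layout` (see [cascade_layout()]).
#' @param tail_fraction Fraction of the fixation window (from its end) used;
#'   in (0, 1].
#' @param axes `"x"` for horizontal-only correction (two-AOI designs) or
#'   `"xy"` (four-AOI designs). In `"x"` mode `dy` is 0.
#' @param stat `"mean"` (default) or `"median"` of the kept samples.
#' @return A `bias_estimate` list: `dx`, `dy`, `n_samples_used`, `sd_x`. If no
#'   sample falls in the tail window the estimate is missing (`dx`/`dy` are
#'   `NA`, `n_samples_used` is 0) rather than an error.
#' @examples
#' lay <- cascade_layout()
#' s <- tibble::tibble(t_ms = seq(100, 1900, by = 200),
#'                     x_px = 640 + 50, y_px = 360)
#' estimate_trial_bias(s, lay)  # dx = +50
#' @export
estimate_trial_bias <- function(samples, layout, tail_fraction = 0.8,
                                axes = c("x", "xy"), stat = c("mean", "median")) {
  axes <- match.arg(axes)
  stat <- match.arg(stat)
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  cutoff <- (1 - tail_fraction) * layout$fixation_ms
  kept <- samples[samples$t_ms >= cutoff & samples$t_ms < layout$fixation_ms, ]
  if (nrow(kept) == 0) {
    return(structure(list(dx = NA_real_, dy = NA_real_, n_samples_used = 0L,
                          sd_x = NA_real_),
                     class = "bias_estimate"))
  }
  avg <- if (stat == "mean") mean else median
  dx <- avg(kept$x_px) - layout$fix_x
  dy <- if (axes == "xy") avg(kept$y_px) - layout$fix_y else 0
  structure(
    list(dx = dx, dy = dy, n_samples_used = nrow(kept),
         sd_x = if (nrow(kept) > 1) sd(kept$x_px) else 0),
    class = "bias_estimate"
  )
}

#' Shift AOI geometry by an estimated bias
#'
#' The estimated bias is added to the midline(s) and every AOI bound of the
#' trial; the gaze samples themselves are never modified. A missing bias
#' estimate yields the identity geometry with a warning and a `flagged`
#' attribute so the trial can be excluded downstream rather than crashing the
#' run.
#'
#' @param layout A `trial_layout`.
#' @param bias A `bias_estimate` from [estimate_trial_bias()].
#' @return A `corrected_geometry` list: `midline_x`, `midline_y`, `aois`
#'   (shifted rectangles), `applied_bias`, `flagged`.
#' @examples
#' lay <- cascade_layout()
#' b <- structure(list(dx = 50, dy = 0, n_samples_used = 10L, sd_x = 0),
#'                class = "bias_estimate")
#' correct_geometry(lay, b)$midline_x - lay$midline_x  # +50
#' @export
correct_geometry <- function(layout, bias) {
  missing_bias <- is.null(bias) || is.na(bias$dx)
  if (missing_bias) {
    warning("missing bias estimate: returning uncorrected geometry")
    dx <- 0
    dy <- 0
  } else {
    dx <- bias$dx
    dy <- if (is.na(bias$dy)) 0 else bias$dy
  }
  structure(
    list(
      midline_x = layout$midline_x + dx,
      midline_y = if (is.na(layout$midline_y)) NA_real_ else
        layout$midline_y + dy,
      aois = layout$aois |>
        mutate(x_min = x_min + dx, x_max = x_max + dx,
               y_min = y_min + dy, y_max = y_max + dy),
      applied_bias = if (missing_bias) NULL else bias,
      flagged = missing_bias
    ),
    class = "corrected_geometry"
  )
}

#' Assign gaze points to AOIs
#'
#' Hit-tests points against the (corrected) AOI rectangles. Rectangles are
#' half-open, `[x_min, x_max) x [y_min, y_max)`, so a point exactly on a
#' shared boundary belongs to at most one AOI and assignment is
#' deterministic. Points inside no AOI get `NA`.
#'
#' @param x,y Numeric vectors of gaze coordinates, px.
#' @param geometry A `corrected_geometry` (or a `trial_layout`; anything with
#'   an `aois` tibble).
#' @return Character vector of AOI labels, `NA` where the point is outside
#'   all AOIs.
#' @export
assign_aoi <- function(x, y, geometry) {
  a <- geometry$aois
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(a))) {
    hit <- x >= a$x_min[i] & x < a$x_max[i] &
      y >= a$y_min[i] & y < a$y_max[i]
    hit[is.na(hit)] <- FALSE
    out[hit & is.na(out)] <- a$label[i]
  }
  out
}

#' Summarize correction magnitudes over trials
#'
#' Mean, median, min and max of the absolute correction per axis — the
#' summary conventionally reported for post-hoc midline correction (e.g.
#' "corrected for 119 px to either direction on average").
#'
#' @param biases Tibble with columns `dx` and optionally `dy` (one row per
#'   trial), e.g. the `$biases` table of [preprocess_dataset()].
#' @return Tibble with one row per axis: `axis`, `mean_abs`, `median_abs`,
#'   `min_abs`, `max_abs`, `n`.
#' @export
correction_summary <- function(biases) {
  if (nrow(biases) == 0) stop("no bias estimates to summarize")
  one_axis <- function(v, axis) {
    v <- abs(v[!is.na(v)])
    if (length(v) == 0) return(NULL)
    tibble(axis = axis, mean_abs = mean(v), median_abs = median(v),
           min_abs = min(v), max_abs = max(v), n = length(v))
  }
  out <- one_axis(biases$dx, "x")
  if (!is.null(biases$dy) && any(!is.na(biases$dy) & biases$dy != 0))
    out <- bind_rows(out, one_axis(biases$dy, "y"))
  out
}

#' Calibration score: central gaze capture after calibration
#'
#' Fraction of gaze samples falling inside a central screen region during the
#' post-calibration fixation window — a simple per-participant data-quality
#' index. The region size is a convention, not a measurement; the default is
#' a square of 200 px half-width around the screen center.
#'
#' @param samples Tibble with `t_ms`, `x_px`, `y_px` from the
#'   post-calibration fixation.
#' @param center Length-2 numeric, region center (px).
#' @param half_width Half-width of the square region, px.
#' @param window_ms Only samples with `t_ms < window_ms` are scored.
#' @return Proportion in \[0, 1\], or `NA` if no sample falls in the window.
#' @export
calibration_score <- function(samples, center = c(640, 360),
                              half_width = 200, window_ms = 3000) {
  s <- samples[samples$t_ms < window_ms, ]
  if (nrow(s) == 0) return(NA_real_)
  mean(abs(s$x_px - center[1]) < half_width &
         abs(s$y_px - center[2]) < half_width)
}

#' Preprocess a gaze dataset: bias estimation, correction, AOI assignment
#'
#' Runs the per-trial bias estimation over the fixation phases, shifts every
#' trial's midline(s) and AOI bounds by its estimated bias, and assigns every
#' stimulus-phase gaze sample to a corrected AOI (or none). Gaze coordinates
#' are never altered; only the geometry moves.
#'
#' @param dataset A `gaze_dataset` (from a simulator or [read_gaze_dataset()]).
#' @param axes `"x"` (two-AOI designs) or `"xy"` (four-AOI designs).
#' @param tail_fraction Tail fraction of the fixation window used for bias
#'   estimation.
#' @param stat Bias statistic, `"mean"` or `"median"`.
#' @return A `gaze_preprocessed` list: the input tables plus
#'   * `biases`: per-trial `dx`, `dy`, `n_used`, `sd_x`;
#'   * `aois_corrected`: shifted AOI rectangles per trial;
#'   * `trials`: input trials with `corrected_midline_x`/`_y`;
#'   * `gaze`: input gaze with an `aoi` column (`NA` for fixation-phase
#'     samples and samples outside all corrected AOIs).
#' @export
preprocess_dataset <- function(dataset, axes = c("x", "xy"),
                               tail_fraction = 0.8,
                               stat = c("mean", "median")) {
  axes <- match.arg(axes)
  stat <- match.arg(stat)
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  keys <- c("participant_id", "condition", "trial_id")
  avg <- if (stat == "mean") mean else median

  trials <- dataset$trials
  fix <- dataset$gaze |>
    filter(phase == "fixation") |>
    left_join(trials[, c(keys, "fix_x", "fix_y", "fixation_ms")], by = keys) |>
    filter(t_ms >= (1 - tail_fraction) * fixation_ms, t_ms < fixation_ms)

  biases <- fix |>
    group_by(across(all_of(keys))) |>
    summarise(
      dx = avg(x_px) - first(fix_x),
      dy = if (axes == "xy") avg(y_px) - first(fix_y) else 0,
      n_used = dplyr::n(),
      sd_x = if (dplyr::n() > 1) sd(x_px) else 0,
      .groups = "drop"
    )
  ## trials with no usable fixation samples: missing estimate, flagged later
  biases <- trials[, keys] |>
    left_join(biases, by = keys)

  aois_corrected <- dataset$aois |>
    left_join(biases[, c(keys, "dx", "dy")], by = keys) |>
    mutate(
      x_min = x_min + coalesce(dx, 0), x_max = x_max + coalesce(dx, 0),
      y_min = y_min + coalesce(dy, 0), y_max = y_max + coalesce(dy, 0)
    ) |>
    select(-dx, -dy)

  trials <- trials |>
    left_join(biases[, c(keys, "dx", "dy")], by = keys) |>
    mutate(
      corrected_midline_x = true_midline_x + coalesce(dx, 0),
      corrected_midline_y = true_midline_y + coalesce(dy, 0)
    ) |>
    select(-dx, -dy)

  gaze <- assign_aois_table(dataset$gaze, aois_corrected, keys)

  structure(
    list(gaze = gaze, trials = trials, aois = dataset$aois,
         aois_corrected = aois_corrected, biases = biases,
         truth = dataset$truth, participants = dataset$participants,
         calibration = dataset$calibration, paradigm = dataset$paradigm,
         config = dataset$config, axes = axes),
    class = "gaze_preprocessed"
  )
}

## Vectorized AOI assignment of stimulus-phase samples against per-trial
## rectangles: one pass per AOI label (at most four).
assign_aois_table <- function(gaze, aois, keys) {
  gaze$aoi <- NA_character_
  stim <- gaze$phase != "fixation"
  for (lab in unique(aois$label)) {
    rect <- aois[aois$label == lab, ]
    m <- gaze |>
      left_join(rect, by = keys, suffix = c("", ".r"))
    hit <- stim &
      m$x_px >= m$x_min & m$x_px < m$x_max &
      m$y_px >= m$y_min & m$y_px < m$y_max
    hit[is.na(hit)] <- FALSE
    gaze$aoi[hit & is.na(gaze$aoi)] <- lab
  }
  gaze
}

#' @export
print.gaze_preprocessed <- function(x, ...) {
  cs <- correction_summary(x$biases)
  cat(sprintf("<gaze_preprocessed: %s> axes=%s, %d trials\n",
              x$paradigm, x$axes, nrow(x$trials)))
  print(cs)
  invisible(x)
}
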