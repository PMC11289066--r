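#' Simulation configuration for synthetic gaze data
#'
#' Bundles the parameters of the synthetic webcam gaze generator. The defaults
#' emulate webcam-grade estimated gaze: ~30 Hz sampling with +/-20% uniform
#' inter-sample jitter, large per-sample spatial noise, a per-trial
#' measurement bias composed of a participant-level and a trial-level Gaussian
#' component (defaults give a mean absolute horizontal bias of ~120 px), and a
#' small fraction of samples that land anywhere on the screen regardless of
#' the looking process. The paired "lab" condition of the visual-world
#' generator uses the `lab_*` fields (regular high-rate sampling, low noise,
#' near-zero bias).
#'
#' @param n_participants,n_trials Number of simulated participants and trials
#'   per participant (per block for the visual-world paradigm).
#' @param sampling_rate_hz Nominal webcam sampling rate, Hz.
#' @param jitter_frac Half-width of the multiplicative uniform jitter on
#'   inter-sample intervals (0.2 means intervals vary by +/-20%).
#' @param noise_sd_px SD of isotropic Gaussian per-sample noise, px.
#' @param bias_sd_participant_x,bias_sd_trial_x SDs of the participant- and
#'   trial-level horizontal bias components, px.
#' @param bias_sd_participant_y,bias_sd_trial_y Same for the vertical axis.
#'   Two-AOI paradigms keep these small (only the horizontal axis is
#'   corrected downstream); the four-AOI generator overrides them (see
#'   [simulate_vwp_study()]).
#' @param off_aoi_rate Probability that a sample is replaced by a uniform
#'   position on the screen, irrespective of the looking process.
#' @param live_feed_rate Probability that a sample carries the live-feed flag
#'   (eye-tracker lost the eyes).
#' @param screen_w,screen_h Screen size, px.
#' @param fixation_ms Duration of the central fixation cross, ms.
#' @param lab_sampling_rate_hz,lab_noise_sd_px,lab_off_aoi_rate,lab_bias_sd_px
#'   Lab-condition overrides (visual-world paradigm only).
#' @param preference Named list of paradigm-specific looking-process
#'   parameters; unset entries fall back to per-paradigm defaults:
#'   * cascade: `p_final` (0.62), `ramp_ms` (1000), `rt_meanlog`
#'     (`log(3000)`), `rt_sdlog` (0.45);
#'   * novelty: `p_novel` (0.57), `randomize_novel_side` (TRUE);
#'   * visual world: `p_target_online` (0.52), `p_target_lab` (0.71),
#'     `ramp_ms` (200).
#' @param seed Integer seed; every simulator call is fully reproducible given
#'   the same config.
#' @return A validated `sim_config` list.
#' @seealso [simulate_cascade_study()], [simulate_novelty_study()],
#'   [simulate_vwp_study()]
#' @export
sim_config <- function(n_participants = 25, n_trials = 18,
                       sampling_rate_hz = 30, jitter_frac = 0.2,
                       noise_sd_px = 40,
                       bias_sd_participant_x = 120, bias_sd_trial_x = 90,
                       bias_sd_participant_y = 25, bias_sd_trial_y = 20,
                       off_aoi_rate = 0.05, live_feed_rate = 0,
                       screen_w = 1280, screen_h = 720, fixation_ms = 2000,
                       lab_sampling_rate_hz = 250, lab_noise_sd_px = 5,
                       lab_off_aoi_rate = 0.01, lab_bias_sd_px = 2,
                       preference = list(), seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials = as.integer(n_trials),
    sampling_rate_hz = sampling_rate_hz, jitter_frac = jitter_frac,
    noise_sd_px = noise_sd_px,
    bias_sd_participant_x = bias_sd_participant_x,
    bias_sd_trial_x = bias_sd_trial_x,
    bias_sd_participant_y = bias_sd_participant_y,
    bias_sd_trial_y = bias_sd_trial_y,
    off_aoi_rate = off_aoi_rate, live_feed_rate = live_feed_rate,
    screen_w = screen_w, screen_h = screen_h, fixation_ms = fixation_ms,
    lab_sampling_rate_hz = lab_sampling_rate_hz,
    lab_noise_sd_px = lab_noise_sd_px,
    lab_off_aoi_rate = lab_off_aoi_rate, lab_bias_sd_px = lab_bias_sd_px,
    preference = preference, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_participants >= 1, cfg$n_trials >= 1,
    cfg$sampling_rate_hz > 0, cfg$jitter_frac >= 0, cfg$jitter_frac < 1,
    cfg$noise_sd_px >= 0,
    cfg$off_aoi_rate >= 0, cfg$off_aoi_rate <= 1,
    cfg$live_feed_rate >= 0, cfg$live_feed_rate <= 1,
    cfg$screen_w > 0, cfg$screen_h > 0, cfg$fixation_ms > 0
  )
  structure(cfg, class = "sim_config")
}

pref_par <- function(config, name, default) {
  v <- config$preference[[name]]
  if (is.null(v)) default else v
}

## Strictly increasing sample times in (0, total_ms], nominal rate with
## multiplicative uniform jitter on the inter-sample intervals.
draw_times <- function(total_ms, rate_hz, jitter_frac) {
  dt <- 1000 / rate_hz
  n_max <- ceiling(total_ms / (dt * max(1 - jitter_frac, 0.5))) + 2L
  if (jitter_frac == 0) {
    t <- seq(dt, by = dt, length.out = n_max)
  } else {
    t <- cumsum(dt * runif(n_max, 1 - jitter_frac, 1 + jitter_frac))
  }
  t[t <= total_ms]
}

## Shared measurement model: true target position -> estimated gaze sample.
perturb_gaze <- function(tx, ty, bias_x, bias_y, noise_sd, off_aoi_rate,
                         live_feed_rate, screen_w, screen_h) {
  n <- length(tx)
  x <- tx + bias_x + rnorm(n, 0, noise_sd)
  y <- ty + bias_y + rnorm(n, 0, noise_sd)
  if (off_aoi_rate > 0) {
    u <- runif(n) < off_aoi_rate
    x[u] <- runif(sum(u), 0, screen_w)
    y[u] <- runif(sum(u), 0, screen_h)
  }
  live <- if (live_feed_rate > 0) runif(n) < live_feed_rate else rep(FALSE, n)
  list(x = x, y = y, live_feed = live)
}

## Participant-level table: biases plus auxiliary fields used by the
## sensitivity filters (attention checks, instruction-screen time,
## self-reported data reliability on a 1-5 scale).
draw_participants <- function(config) {
  n <- config$n_participants
  tibble(
    participant_id = seq_len(n),
    pbias_x = rnorm(n, 0, config$bias_sd_participant_x),
    pbias_y = rnorm(n, 0, config$bias_sd_participant_y),
    attention_failures = rbinom(n, 3, 0.03),
    instruction_time_s = rlnorm(n, log(30), 0.4),
    self_report_reliability = sample(2:5, n, replace = TRUE,
                                     prob = c(0.02, 0.08, 0.3, 0.6))
  )
}

new_gaze_dataset <- function(gaze, trials, aois, truth, participants,
                             calibration = NULL, paradigm, config) {
  ds <- structure(
    list(gaze = gaze, trials = trials, aois = aois, truth = truth,
         participants = participants, calibration = calibration,
         paradigm = paradigm, config = config),
    class = "gaze_dataset"
  )
  ds
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat(sprintf(
    "<gaze_dataset: %s> %d participants, %d trials, %d gaze samples\n",
    x$paradigm, nrow(x$participants), nrow(x$trials), nrow(x$gaze)))
  invisible(x)
}

## Expand per-trial layout AOIs into the per-trial AOI table.
expand_aois <- function(trials, layout) {
  tidyr::crossing(
    trials[, c("participant_id", "condition", "trial_id")],
    layout$aois
  )
}

#' Simulate a gaze cascade (two-alternative preference) study
#'
#' Generates synthetic webcam gaze for a face-preference task: each trial is a
#' 2000-ms central fixation followed by a decision phase that ends at a
#' log-normally distributed response time with a recorded chosen side. During
#' the decision phase the probability of looking at the eventually chosen AOI
#' rises linearly from 0.5 (starting `ramp_ms` before the response) to
#' `p_final` at the moment of the response. Samples are the looked-at AOI
#' center (or the fixation cross) plus per-trial bias and Gaussian noise; a
#' fraction `off_aoi_rate` is replaced by uniform screen positions.
#'
#' @param config A [sim_config()]. Preference parameters: `p_final` in
#'   \[0.5, 1\], `ramp_ms`, `rt_meanlog`, `rt_sdlog` (response time in ms is
#'   log-normal).
#' @return A `gaze_dataset`: tibbles `gaze` (participant_id, condition,
#'   trial_id, phase, t_ms, x_px, y_px, live_feed), `trials` (layout scalars
#'   and per-trial metadata), `aois` (per-trial AOI rectangles), `truth`
#'   (injected bias and preference parameter), `participants` (biases and
#'   auxiliary fields).
#' @examples
#' ds <- simulate_cascade_study(sim_config(n_participants = 2, n_trials = 3))
#' ds$trials
#' @export
simulate_cascade_study <- function(config = sim_config()) {
  p_final <- pref_par(config, "p_final", 0.62)
  if (p_final < 0.5 || p_final > 1)
    stop("p_final must lie in [0.5, 1]")
  ramp_ms <- pref_par(config, "ramp_ms", 1000)
  rt_meanlog <- pref_par(config, "rt_meanlog", log(3000))
  rt_sdlog <- pref_par(config, "rt_sdlog", 0.45)
  layout <- cascade_layout(config$screen_w, config$screen_h,
                           fixation_ms = config$fixation_ms)

  withr::with_seed(config$seed, {
    participants <- draw_participants(config)
    trials <- tidyr::crossing(participants[, "participant_id"],
                              tibble(trial_id = seq_len(config$n_trials)))
    nt <- nrow(trials)
    trials <- trials |>
      mutate(
        condition = "online",
        paradigm = "cascade",
        bias_x = participants$pbias_x[participant_id] +
          rnorm(nt, 0, config$bias_sd_trial_x),
        bias_y = participants$pbias_y[participant_id] +
          rnorm(nt, 0, config$bias_sd_trial_y),
        chosen_label = sample(c("left", "right"), nt, replace = TRUE),
        response_time_ms = rlnorm(nt, rt_meanlog, rt_sdlog)
      )

    ## sample times per trial, then everything vectorized over samples
    fix_times <- lapply(rep(config$fixation_ms, nt), draw_times,
                        rate_hz = config$sampling_rate_hz,
                        jitter_frac = config$jitter_frac)
    dec_times <- lapply(trials$response_time_ms, draw_times,
                        rate_hz = config$sampling_rate_hz,
                        jitter_frac = config$jitter_frac)
    n_fix <- lengths(fix_times)
    n_dec <- lengths(dec_times)

    idx <- c(rep.int(seq_len(nt), n_fix), rep.int(seq_len(nt), n_dec))
    t_rel <- c(unlist(fix_times), unlist(dec_times))
    is_dec <- c(rep(FALSE, sum(n_fix)), rep(TRUE, sum(n_dec)))

    centers <- layout$aois |>
      mutate(cx = (x_min + x_max) / 2, cy = (y_min + y_max) / 2)
    cx <- stats::setNames(centers$cx, centers$label)
    cy <- stats::setNames(centers$cy, centers$label)

    tx <- rep(layout$fix_x, length(idx))
    ty <- rep(layout$fix_y, length(idx))
    rt_i <- trials$response_time_ms[idx]
    remaining <- rt_i - t_rel
    p_look <- p_final - (p_final - 0.5) * pmin(1, pmax(0, remaining / ramp_ms))
    chosen_i <- trials$chosen_label[idx]
    other_i <- ifelse(chosen_i == "left", "right", "left")
    look_chosen <- runif(length(idx)) < p_look
    lab_i <- ifelse(look_chosen, chosen_i, other_i)
    tx[is_dec] <- cx[lab_i[is_dec]]
    ty[is_dec] <- cy[lab_i[is_dec]]

    g <- perturb_gaze(tx, ty, trials$bias_x[idx], trials$bias_y[idx],
                      config$noise_sd_px, config$off_aoi_rate,
                      config$live_feed_rate, config$screen_w, config$screen_h)

    gaze <- tibble(
      participant_id = trials$participant_id[idx],
      condition = "online",
      trial_id = trials$trial_id[idx],
      phase = ifelse(is_dec, "decision", "fixation"),
      t_ms = t_rel + ifelse(is_dec, config$fixation_ms, 0),
      x_px = g$x, y_px = g$y, live_feed = g$live_feed
    ) |>
      arrange(participant_id, trial_id, t_ms)

    trials_out <- trials |>
      mutate(
        screen_w = config$screen_w, screen_h = config$screen_h,
        fix_x = layout$fix_x, fix_y = layout$fix_y,
        fixation_ms = config$fixation_ms,
        stim_onset_ms = config$fixation_ms,
        stim_dur_ms = response_time_ms,
        true_midline_x = layout$midline_x,
        true_midline_y = NA_real_
      ) |>
      select(participant_id, condition, trial_id, paradigm, screen_w,
             screen_h, fix_x, fix_y, fixation_ms, stim_onset_ms, stim_dur_ms,
             response_time_ms, chosen_label, true_midline_x, true_midline_y)

    truth <- trials |>
      transmute(participant_id, condition, trial_id, bias_x, bias_y,
                pref = p_final)

    new_gaze_dataset(gaze, trials_out, expand_aois(trials_out, layout), truth,
                     participants, paradigm = "cascade", config = config)
  })
}

#' Simulate a novelty-preference (visual paired-comparison) study
#'
#' Each trial: 2000-ms fixation, a 5000-ms familiarization phase with two
#' identical lateral images (gaze splits evenly), a 2000-ms blank gap (no
#' gaze emitted), and a 5000-ms test phase in which samples target the novel
#' AOI with probability `p_novel` before bias/noise. The side of the novel
#' image is randomized per trial, or alternates with trial parity when
#' `randomize_novel_side = FALSE`.
#'
#' @param config A [sim_config()]. Preference parameters: `p_novel` in
#'   \[0, 1\], `randomize_novel_side`.
#' @return A `gaze_dataset`; `trials` carries `novel_label`, `test_onset_ms`,
#'   `test_dur_ms`.
#' @export
simulate_novelty_study <- function(config = sim_config(n_trials = 10)) {
  p_novel <- pref_par(config, "p_novel", 0.57)
  if (p_novel < 0 || p_novel > 1) stop("p_novel must lie in [0, 1]")
  randomize <- isTRUE(pref_par(config, "randomize_novel_side", TRUE))
  fam_ms <- 5000
  gap_ms <- 2000
  test_ms <- 5000
  layout <- novelty_layout(config$screen_w, config$screen_h,
                           fixation_ms = config$fixation_ms)

  withr::with_seed(config$seed, {
    participants <- draw_participants(config)
    trials <- tidyr::crossing(participants[, "participant_id"],
                              tibble(trial_id = seq_len(config$n_trials)))
    nt <- nrow(trials)
    trials <- trials |>
      mutate(
        condition = "online",
        paradigm = "novelty",
        bias_x = participants$pbias_x[participant_id] +
          rnorm(nt, 0, config$bias_sd_trial_x),
        bias_y = participants$pbias_y[participant_id] +
          rnorm(nt, 0, config$bias_sd_trial_y),
        novel_label = if (randomize) {
          sample(c("left", "right"), nt, replace = TRUE)
        } else {
          ifelse(trial_id %% 2 == 1, "left", "right")
        }
      )

    test_onset <- config$fixation_ms + fam_ms + gap_ms
    phases <- list(
      fixation = c(0, config$fixation_ms),
      familiarization = c(config$fixation_ms, config$fixation_ms + fam_ms),
      test = c(test_onset, test_onset + test_ms)
    )

    times_one <- function() {
      lapply(seq_len(nt), function(i) {
        lapply(phases, function(ph) {
          draw_times(ph[2] - ph[1], config$sampling_rate_hz,
                     config$jitter_frac) + ph[1]
        })
      })
    }
    all_times <- times_one()
    flat <- lapply(names(phases), function(pn) {
      tl <- lapply(all_times, `[[`, pn)
      list(idx = rep.int(seq_len(nt), lengths(tl)), t = unlist(tl),
           phase = pn)
    })
    idx <- unlist(lapply(flat, `[[`, "idx"))
    t_ms <- unlist(lapply(flat, `[[`, "t"))
    phase <- rep(vapply(flat, `[[`, "", "phase"),
                 vapply(flat, function(f) length(f$t), 0L))

    centers <- layout$aois |>
      mutate(cx = (x_min + x_max) / 2, cy = (y_min + y_max) / 2)
    cx <- stats::setNames(centers$cx, centers$label)
    cy <- stats::setNames(centers$cy, centers$label)

    n <- length(idx)
    tx <- rep(layout$fix_x, n)
    ty <- rep(layout$fix_y, n)
    novel_i <- trials$novel_label[idx]
    familiar_i <- ifelse(novel_i == "left", "right", "left")
    ## familiarization: even split between the two identical images
    fam <- phase == "familiarization"
    side_fam <- ifelse(runif(n) < 0.5, "left", "right")
    tx[fam] <- cx[side_fam[fam]]
    ty[fam] <- cy[side_fam[fam]]
    ## test: novel AOI with probability p_novel
    tst <- phase == "test"
    side_tst <- ifelse(runif(n) < p_novel, novel_i, familiar_i)
    tx[tst] <- cx[side_tst[tst]]
    ty[tst] <- cy[side_tst[tst]]

    g <- perturb_gaze(tx, ty, trials$bias_x[idx], trials$bias_y[idx],
                      config$noise_sd_px, config$off_aoi_rate,
                      config$live_feed_rate, config$screen_w, config$screen_h)

    gaze <- tibble(
      participant_id = trials$participant_id[idx],
      condition = "online",
      trial_id = trials$trial_id[idx],
      phase = phase, t_ms = t_ms, x_px = g$x, y_px = g$y,
      live_feed = g$live_feed
    ) |>
      arrange(participant_id, trial_id, t_ms)

    trials_out <- trials |>
      mutate(
        screen_w = config$screen_w, screen_h = config$screen_h,
        fix_x = layout$fix_x, fix_y = layout$fix_y,
        fixation_ms = config$fixation_ms,
        stim_onset_ms = config$fixation_ms,
        stim_dur_ms = fam_ms + gap_ms + test_ms,
        test_onset_ms = test_onset, test_dur_ms = test_ms,
        true_midline_x = layout$midline_x,
        true_midline_y = NA_real_
      ) |>
      select(participant_id, condition, trial_id, paradigm, screen_w,
             screen_h, fix_x, fix_y, fixation_ms, stim_onset_ms, stim_dur_ms,
             test_onset_ms, test_dur_ms, novel_label, true_midline_x,
             true_midline_y)

    truth <- trials |>
      transmute(participant_id, condition, trial_id, bias_x, bias_y,
                pref = p_novel)

    new_gaze_dataset(gaze, trials_out, expand_aois(trials_out, layout), truth,
                     participants, paradigm = "novelty", config = config)
  })
}

#' Simulate a paired online/lab visual-world study
#'
#' Each participant completes an "online" block (webcam-grade noise, bias,
#' irregular ~30 Hz sampling) and a "lab" block (low noise, near-zero bias,
#' regular high-rate sampling). Each trial: 2000-ms fixation, then a 9000-ms
#' four-image display (one image per screen quadrant). Before the spoken
#' target word onset (5000 ms into the display: 1000-ms preview plus 4000 ms
#' of carrier sentence) gaze is uniform over the four AOIs; from onset the
#' probability of looking at the target quadrant ramps linearly from 0.25 to
#' `p_target` over `ramp_ms` and then holds.
#'
#' Because the vertical axis is corrected downstream in this four-AOI design,
#' the online block draws vertical bias at webcam scale
#' (participant/trial SDs 135/100 px) rather than the two-AOI default.
#'
#' A per-participant, per-block 3000-ms post-calibration central fixation
#' segment is emitted in `$calibration` for calibration scoring.
#'
#' @param config A [sim_config()] (use `n_trials` per block). Preference
#'   parameters: `p_target_online`, `p_target_lab` (both >= 0.25), `ramp_ms`.
#' @return A `gaze_dataset` whose tables carry `condition` ("online"/"lab");
#'   `trials` has `target_label` and `target_onset_ms` (relative to trial
#'   start).
#' @export
simulate_vwp_study <- function(config = sim_config(n_trials = 12)) {
  p_on <- pref_par(config, "p_target_online", 0.52)
  p_lab <- pref_par(config, "p_target_lab", 0.71)
  if (p_on < 0.25 || p_lab < 0.25 || p_on > 1 || p_lab > 1)
    stop("p_target must lie in [0.25, 1]")
  ramp_ms <- pref_par(config, "ramp_ms", 200)
  img_ms <- 9000
  onset_in_stim <- 5000   # 1000 ms preview + 4000 ms to target word
  calib_ms <- 3000
  layout <- vwp_layout(config$screen_w, config$screen_h,
                       fixation_ms = config$fixation_ms)
  labels <- layout$aois$label

  withr::with_seed(config$seed, {
    participants <- draw_participants(config) |>
      mutate(pbias_y = rnorm(config$n_participants, 0, 135))

    one_block <- function(cond) {
      is_lab <- cond == "lab"
      rate <- if (is_lab) config$lab_sampling_rate_hz else
        config$sampling_rate_hz
      jit <- if (is_lab) 0 else config$jitter_frac
      noise <- if (is_lab) config$lab_noise_sd_px else config$noise_sd_px
      offr <- if (is_lab) config$lab_off_aoi_rate else config$off_aoi_rate
      p_target <- if (is_lab) p_lab else p_on

      trials <- tidyr::crossing(participants[, "participant_id"],
                                tibble(trial_id = seq_len(config$n_trials)))
      nt <- nrow(trials)
      trials <- trials |>
        mutate(
          condition = cond,
          paradigm = "vwp",
          bias_x = if (is_lab) rnorm(nt, 0, config$lab_bias_sd_px) else
            participants$pbias_x[participant_id] +
              rnorm(nt, 0, config$bias_sd_trial_x),
          bias_y = if (is_lab) rnorm(nt, 0, config$lab_bias_sd_px) else
            participants$pbias_y[participant_id] + rnorm(nt, 0, 100),
          target_label = sample(labels, nt, replace = TRUE)
        )

      fix_times <- lapply(rep(config$fixation_ms, nt), draw_times,
                          rate_hz = rate, jitter_frac = jit)
      img_times <- lapply(rep(img_ms, nt), draw_times,
                          rate_hz = rate, jitter_frac = jit)
      n_fix <- lengths(fix_times)
      n_img <- lengths(img_times)
      idx <- c(rep.int(seq_len(nt), n_fix), rep.int(seq_len(nt), n_img))
      t_rel <- c(unlist(fix_times), unlist(img_times))
      is_img <- c(rep(FALSE, sum(n_fix)), rep(TRUE, sum(n_img)))

      centers <- layout$aois |>
        mutate(cx = (x_min + x_max) / 2, cy = (y_min + y_max) / 2)
      cx <- stats::setNames(centers$cx, centers$label)
      cy <- stats::setNames(centers$cy, centers$label)

      n <- length(idx)
      tx <- rep(layout$fix_x, n)
      ty <- rep(layout$fix_y, n)
      since_onset <- t_rel - onset_in_stim
      p_t <- 0.25 + (p_target - 0.25) *
        pmin(1, pmax(0, since_onset / ramp_ms))
      on_target <- runif(n) < p_t
      target_i <- trials$target_label[idx]
      ## distractor chosen uniformly among the three non-target labels:
      ## others[k, j] = index of the j-th non-target label when target is k
      others <- t(vapply(seq_along(labels),
                         function(k) setdiff(seq_along(labels), k),
                         integer(length(labels) - 1L)))
      r3 <- sample.int(3L, n, replace = TRUE)
      ti <- match(target_i, labels)
      dist_lab <- labels[others[cbind(ti, r3)]]
      look_lab <- ifelse(on_target, target_i, dist_lab)
      sel <- is_img
      tx[sel] <- cx[look_lab[sel]]
      ty[sel] <- cy[look_lab[sel]]

      g <- perturb_gaze(tx, ty, trials$bias_x[idx], trials$bias_y[idx],
                        noise, offr, config$live_feed_rate,
                        config$screen_w, config$screen_h)

      gaze <- tibble(
        participant_id = trials$participant_id[idx],
        condition = cond,
        trial_id = trials$trial_id[idx],
        phase = ifelse(is_img, "images", "fixation"),
        t_ms = t_rel + ifelse(is_img, config$fixation_ms, 0),
        x_px = g$x, y_px = g$y, live_feed = g$live_feed
      ) |>
        arrange(participant_id, trial_id, t_ms)

      trials_out <- trials |>
        mutate(
          screen_w = config$screen_w, screen_h = config$screen_h,
          fix_x = layout$fix_x, fix_y = layout$fix_y,
          fixation_ms = config$fixation_ms,
          stim_onset_ms = config$fixation_ms,
          stim_dur_ms = img_ms,
          target_onset_ms = config$fixation_ms + onset_in_stim,
          true_midline_x = layout$midline_x,
          true_midline_y = layout$midline_y
        ) |>
        select(participant_id, condition, trial_id, paradigm, screen_w,
               screen_h, fix_x, fix_y, fixation_ms, stim_onset_ms,
               stim_dur_ms, target_label, target_onset_ms, true_midline_x,
               true_midline_y)

      truth <- trials |>
        transmute(participant_id, condition, trial_id, bias_x, bias_y,
                  pref = p_target)

      ## post-calibration central fixation (for calibration scores)
      ct <- lapply(rep(calib_ms, config$n_participants), draw_times,
                   rate_hz = rate, jitter_frac = jit)
      cidx <- rep.int(seq_len(config$n_participants), lengths(ct))
      cb_x <- if (is_lab) rnorm(config$n_participants, 0,
                                config$lab_bias_sd_px) else
        participants$pbias_x
      cb_y <- if (is_lab) rnorm(config$n_participants, 0,
                                config$lab_bias_sd_px) else
        participants$pbias_y
      cg <- perturb_gaze(rep(layout$fix_x, length(cidx)),
                         rep(layout$fix_y, length(cidx)),
                         cb_x[cidx], cb_y[cidx], noise, offr, 0,
                         config$screen_w, config$screen_h)
      calib <- tibble(
        participant_id = cidx, condition = cond,
        t_ms = unlist(ct), x_px = cg$x, y_px = cg$y, live_feed = FALSE
      )

      list(gaze = gaze, trials = trials_out, truth = truth, calib = calib)
    }

    online <- one_block("online")
    lab <- one_block("lab")

    trials_all <- bind_rows(online$trials, lab$trials)
    new_gaze_dataset(
      gaze = bind_rows(online$gaze, lab$gaze),
      trials = trials_all,
      aois = expand_aois(trials_all, layout),
      truth = bind_rows(online$truth, lab$truth),
      participants = participants,
      calibration = bind_rows(online$calib, lab$calib),
      paradigm = "vwp", config = config
    )
  })
}

#' Sample an estimated-gaze stream along a known looking path
#'
#' The shared measurement engine exposed directly: given a step-function path
#' of true looking positions, draws sample times at the nominal rate with
#' multiplicative timing jitter and returns `path + bias + noise`, with a
#' fraction `off_aoi_rate` of samples replaced by uniform screen positions and
#' a fraction `live_feed_rate` flagged as lost.
#'
#' @param path Tibble/data frame with columns `t_ms`, `x`, `y`: the looking
#'   position from time `t_ms` onward (piecewise constant). Must start at or
#'   before 0 and cover the trial duration.
#' @param config A [sim_config()] (rate, jitter, noise, off-AOI and live-feed
#'   rates, screen size are used).
#' @param trial_bias Length-2 numeric `(dx, dy)` measurement bias, px.
#' @param duration_ms Trial duration; defaults to `max(path$t_ms)`.
#' @return Tibble with `t_ms`, `x_px`, `y_px`, `live_feed`.
#' @examples
#' path <- tibble::tibble(t_ms = c(0, 1000), x = c(640, 400), y = 360)
#' cfg <- sim_config(noise_sd_px = 0, off_aoi_rate = 0)
#' sample_gaze_stream(path, cfg, trial_bias = c(50, 0), duration_ms = 2000)
#' @export
sample_gaze_stream <- function(path, config = sim_config(),
                               trial_bias = c(0, 0),
                               duration_ms = max(path$t_ms)) {
  stopifnot(nrow(path) >= 1, min(path$t_ms) <= 0 || min(path$t_ms) == 0)
  t <- draw_times(duration_ms, config$sampling_rate_hz, config$jitter_frac)
  seg <- findInterval(t, path$t_ms)
  seg[seg < 1] <- 1L
  g <- perturb_gaze(path$x[seg], path$y[seg], trial_bias[1], trial_bias[2],
                    config$noise_sd_px, config$off_aoi_rate,
                    config$live_feed_rate, config$screen_w, config$screen_h)
  tibble(t_ms = t, x_px = g$x, y_px = g$y, live_feed = g$live_feed)
}
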