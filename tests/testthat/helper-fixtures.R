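# Small in-code fixtures shared across test files.

# Fixation-phase samples at a constant offset from the cross.
fixation_samples <- function(layout, dx = 0, dy = 0, n = 10,
                             t = seq(100, layout$fixation_ms - 100,
                                     length.out = n)) {
  tibble::tibble(t_ms = t, x_px = layout$fix_x + dx, y_px = layout$fix_y + dy,
                 live_feed = FALSE)
}

bias_est <- function(dx, dy = 0, n = 10L, sd_x = 0) {
  structure(list(dx = dx, dy = dy, n_samples_used = n, sd_x = sd_x),
            class = "bias_estimate")
}

# A clean generator config: no offset, no noise, regular sampling, no
# off-AOI replacement -- every sample is exactly where the process looks.
clean_config <- function(n_participants = 3, n_trials = 4, seed = 1,
                         preference = list(), ...) {
  sim_config(
    n_participants = n_participants, n_trials = n_trials,
    noise_sd_px = 0, jitter_frac = 0,
    bias_sd_participant_x = 0, bias_sd_trial_x = 0,
    bias_sd_participant_y = 0, bias_sd_trial_y = 0,
    off_aoi_rate = 0, live_feed_rate = 0,
    lab_noise_sd_px = 0, lab_off_aoi_rate = 0, lab_bias_sd_px = 0,
    preference = preference, seed = seed, ...
  )
}

# Minimal hand-built clean object for paradigm functions: one participant,
# one cascade trial with explicit AOI-labeled window samples.
toy_cascade_clean <- function(aoi_labels, t_ms, response_time_ms = 1000,
                              chosen = "left") {
  trials <- tibble::tibble(
    participant_id = 1L, condition = "online", trial_id = 1L,
    paradigm = "cascade", screen_w = 1280, screen_h = 720,
    fix_x = 640, fix_y = 360, fixation_ms = 2000,
    stim_onset_ms = 2000, stim_dur_ms = response_time_ms,
    response_time_ms = response_time_ms, chosen_label = chosen,
    true_midline_x = 640, true_midline_y = NA_real_
  )
  gaze <- tibble::tibble(
    participant_id = 1L, condition = "online", trial_id = 1L,
    phase = "decision", t_ms = t_ms, x_px = 0, y_px = 0,
    live_feed = FALSE, aoi = aoi_labels
  )
  list(gaze = gaze, trials = trials)
}
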