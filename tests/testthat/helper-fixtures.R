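# shared fixtures built in code

test_layout <- function(...) task_layout(...)

# a profile with every source of trial-to-trial variability switched off;
# with a constant target schedule and sequential scanning, every trial is
# identical
degenerate_profile <- function(label = "flat") {
  group_profile(label,
                entry_to_cue = c(2500, 0, 0, 0),
                cue_duration = c(600, 0, 0, 0),
                cue_count = c(1, 0),
                search_duration = c(250, 0, 0, 0),
                fix_duration_spread = 0,
                revisit_probability = 0, cue_recheck_probability = 0,
                refix_probability = 0, scan_order = "sequential",
                motor_delay = c(450, 0),
                miss_probability = 0, error_probability = 0,
                prescan_probability = 0, position_jitter = 0)
}

# run a simulated participant (ground-truth fixations) through labelling
# and segmentation; returns list(fx, seg, meta, truth)
segment_participant <- function(p, layout) {
  meta <- score_responses(p$meta, p$responses)
  fx <- assign_trials(p$fixations[, c("start", "end", "x", "y", "duration")],
                      p$meta, layout$trial_span)
  fx <- label_fixations(fx, layout)
  seg <- segment_trials(fx, meta)
  list(fx = fx, seg = seg, meta = meta, truth = p$truth)
}

# hand-built labelled trial for segmentation rule tests: each row is
# (start, duration, aoi); returns the fixation tibble
trial_fx <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(start = r[[1]], duration = r[[2]], aoi = r[[3]])
  }))
  df$end <- df$start + df$duration
  df$trial_id <- 1L
  df$x <- 0; df$y <- 0
  tibble::as_tibble(df)
}

trial_meta <- function(outcome = "correct", response_time = 8000,
                       target_cell = 5L, trial_id = 1L) {
  tibble::tibble(trial_id = trial_id, target_cell = target_cell,
                 outcome = outcome, response_time = response_time)
}
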