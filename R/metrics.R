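#' Per-trial oculomotor variables
#'
#' Computes, for every valid trial: `entry_to_cue` (= encoding start, ms
#' from trial onset), `entry_to_grid` (= encoding end), `cue_fix_count` and
#' `cue_fix_duration` (number and total duration of cue fixations within
#' the encoding phase, `[encoding_start, encoding_end)`),
#' `search_fix_count` and `search_fix_duration` (count and per-fixation
#' mean duration of all fixations -- whatever their AOI -- starting within
#' `[search_start, search_end]`), and `rt` (final correct button press
#' relative to stimulus onset, i.e. trial-relative response time minus the
#' fixation-cross duration).
#'
#' @param fixations AOI-labelled, trial-relative fixations.
#' @param segments Output of [segment_trials()]; only `status == "valid"`
#'   rows contribute.
#' @param cross_duration Fixation-cross duration, ms (default 2000); only
#'   used to re-express the response time as an RT from stimulus onset.
#' @return A tibble with one row per valid trial.
#' @export
trial_features <- function(fixations, segments, cross_duration = 2000) {
  keys <- intersect(c("participant_id", "trial_id"), names(segments))
  seg <- filter(segments, .data$status == "valid")
  fx <- fixations |>
    inner_join(seg[, c(keys, "encoding_start", "encoding_end",
                       "search_start", "search_end", "response_time",
                       "target_cell")],
               by = keys)
  feats <- fx |>
    group_by(pick(all_of(keys))) |>
    summarise(
      target_cell = .data$target_cell[1],
      entry_to_cue = .data$encoding_start[1],
      entry_to_grid = .data$encoding_end[1],
      cue_fix_count = sum(.data$aoi == "cue" &
                            .data$start >= .data$encoding_start[1] &
                            .data$start < .data$encoding_end[1]),
      cue_fix_duration = sum(.data$duration[
        .data$aoi == "cue" & .data$start >= .data$encoding_start[1] &
          .data$start < .data$encoding_end[1]]),
      search_fix_count = sum(.data$start >= .data$search_start[1] &
                               .data$start <= .data$search_end[1]),
      search_fix_duration = mean(.data$duration[
        .data$start >= .data$search_start[1] &
          .data$start <= .data$search_end[1]]),
      rt = .data$response_time[1] - cross_duration,
      .groups = "drop")
  feats
}

#' Names of the per-trial feature variables
#'
#' @return Character vector of the variables summarised per participant.
#' @export
feature_variables <- function() {
  c("entry_to_cue", "cue_fix_duration", "cue_fix_count", "entry_to_grid",
    "search_fix_duration", "search_fix_count", "rt")
}

#' Per-participant performance and intra-subject variability summaries
#'
#' For every feature the mean over valid trials indexes performance and the
#' sample SD (denominator n-1) over valid trials indexes intra-subject
#' variability (ISV); for reaction time these are the classic RT mean and
#' RTSD.  With a single valid trial the SD is undefined and reported as
#' `NA`, never 0.  Participants with fewer than `min_trials` valid trials
#' are flagged `excluded` and should not enter group statistics.
#'
#' @param features Output of [trial_features()]; a `group` column (e.g.
#'   from the study's participant table) is carried through if present.
#' @param min_trials Minimum number of valid trials for inclusion.
#' @return A tibble, one row per participant: `n_valid`, then
#'   `mean_<feature>` / `sd_<feature>` for each feature (for `rt` named
#'   `rt_mean` / `rtsd`), and `excluded`.
#' @export
summarize_participants <- function(features, min_trials = 10) {
  keys <- intersect(c("participant_id", "group"), names(features))
  out <- features |>
    group_by(pick(all_of(keys))) |>
    summarise(
      n_valid = dplyr::n(),
      across(all_of(setdiff(feature_variables(), "rt")),
             list(mean = ~mean(.x), sd = ~sd(.x)),
             .names = "{.fn}_{.col}"),
      rt_mean = mean(.data$rt),
      rtsd = sd(.data$rt),
      .groups = "drop") |>
    mutate(excluded = .data$n_valid < min_trials)
  out
}
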