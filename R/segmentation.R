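#' Assign recording-relative fixations to trials
#'
#' Each fixation belongs to the trial whose window `[trial_onset,
#' trial_onset + trial_span)` contains its onset; fixation times become
#' trial-relative (trial onset = 0).  Fixations before the first trial are
#' dropped.
#'
#' @param fixations Fixation tibble with recording-relative `start`, `end`.
#' @param meta Trial metadata with `trial_id`, `trial_onset`.
#' @param trial_span Trial length in ms (cross + stimulus; 9000 for the
#'   default layout).
#' @return `fixations` with a `trial_id` column and trial-relative times.
#' @export
assign_trials <- function(fixations, meta, trial_span) {
  if ("participant_id" %in% names(fixations) &&
      "participant_id" %in% names(meta)) {
    fx_split <- split(fixations, fixations$participant_id)
    meta_split <- split(meta, meta$participant_id)
    out <- map(names(fx_split), function(id) {
      if (is.null(meta_split[[id]])) {
        abort(paste0("no trial metadata for participant '", id, "'"))
      }
      assign_trials_one(fx_split[[id]], meta_split[[id]], trial_span)
    })
    return(list_rbind(out))
  }
  assign_trials_one(fixations, meta, trial_span)
}

assign_trials_one <- function(fixations, meta, trial_span) {
  meta <- arrange(meta, .data$trial_onset)
  idx <- findInterval(fixations$start, meta$trial_onset)
  keep <- idx >= 1 &
    fixations$start < meta$trial_onset[pmax(idx, 1)] + trial_span
  out <- fixations[keep, ]
  idx <- idx[keep]
  out$trial_id <- meta$trial_id[idx]
  onset <- meta$trial_onset[idx]
  out$start <- out$start - onset
  out$end <- out$end - onset
  out
}

#' Label fixations with the AOI containing their centroid
#'
#' AOIs are half-open rectangles (`xmin <= x < xmax`, `ymin <= y < ymax`);
#' centroids in no AOI are labelled `"outside"`.
#'
#' @param fixations Fixation tibble with `x`, `y` centroids.
#' @param layout A [task_layout()] or an AOI tibble as returned by [aois()].
#' @return `fixations` with an `aoi` column.
#' @export
label_fixations <- function(fixations, layout) {
  aoi_tbl <- if (inherits(layout, "vs_layout")) aois(layout) else layout
  lab <- rep("outside", nrow(fixations))
  for (k in seq_len(nrow(aoi_tbl))) {
    hit <- fixations$x >= aoi_tbl$xmin[k] & fixations$x < aoi_tbl$xmax[k] &
      fixations$y >= aoi_tbl$ymin[k] & fixations$y < aoi_tbl$ymax[k]
    lab[hit] <- aoi_tbl$aoi[k]
  }
  fixations$aoi <- lab
  fixations
}

#' Segment trials into encoding and search phases
#'
#' Applies the trial-validity rules in a fixed order; a trial failing rule
#' k is never tested on rule k+1, so each rejected trial carries exactly
#' one primary reason:
#' \enumerate{
#'   \item outcome filter -- only `correct` or `corrected` trials proceed
#'     (reasons `incorrect_response`, `missing_response`);
#'   \item cue-window rule -- the onset of the first cue fixation must lie
#'     inside `window` (closed interval, default 1700-3300 ms from trial
#'     onset; reason `no_cue_fixation_in_window`);
#'   \item pre-scan rule -- before that cue fixation at most
#'     `max_prescan_fixations` grid fixations, none longer than
#'     `max_prescan_duration` ms (reason `premature_grid_scanning`);
#'   \item encoding end = onset of the first grid fixation after the cue
#'     fixation; search end = onset of the last fixation on the target
#'     cell at or after encoding end and before the final correct button
#'     press (reason `no_search_end` when either is absent).
#' }
#'
#' Segments follow the half-open convention `[start, end)`: a fixation
#' starting exactly at a boundary belongs to the later phase.  A cue
#' fixation qualifies for the window by its onset alone, even if it ends
#' after the window.
#'
#' @param fixations AOI-labelled fixations with `trial_id` and
#'   trial-relative times ([assign_trials()] + [label_fixations()]).
#' @param meta Scored trial metadata ([score_responses()]): `trial_id`,
#'   `target_cell`, `outcome`, `response_time` and (if times are
#'   recording-relative) `trial_onset`.
#' @param window Closed acceptance window for the first cue fixation onset,
#'   ms from trial onset.
#' @param max_prescan_fixations,max_prescan_duration Pre-scan limits.
#' @return One row per trial: `trial_id`, `outcome`, `status`
#'   (`"valid"`/`"rejected"`), `rejection_reason`, `encoding_start`,
#'   `encoding_end`, `search_start`, `search_end`, `response_time`
#'   (trial-relative), `target_cell`.  Boundary columns are `NA` for
#'   rejected trials.
#' @export
segment_trials <- function(fixations, meta, window = c(1700, 3300),
                           max_prescan_fixations = 1,
                           max_prescan_duration = 300) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!"aoi" %in% names(fixations)) {
    abort("`fixations` must carry an `aoi` column; run label_fixations()")
  }
  bad_sort <- fixations |>
    group_by(pick(any_of(c("participant_id", "trial_id")))) |>
    summarise(ok = !is.unsorted(.data$start), .groups = "drop")
  if (!all(bad_sort$ok)) abort("fixations must be time-sorted within trials")

  keys <- intersect(c("participant_id", "trial_id"), names(meta))
  meta <- meta |> mutate(
    response_rel = if ("trial_onset" %in% names(meta))
      .data$response_time - .data$trial_onset else .data$response_time)

  fx <- fixations |>
    left_join(meta[, c(keys, "target_cell", "response_rel")], by = keys) |>
    mutate(is_grid = startsWith(.data$aoi, "cell_"),
           is_target = .data$aoi == cell_label(.data$target_cell))

  agg <- fx |>
    group_by(pick(all_of(keys))) |>
    summarise(
      first_cue = suppressWarnings(min(.data$start[.data$aoi == "cue"])),
      n_prescan = sum(.data$is_grid & .data$start < .data$first_cue[1]),
      prescan_max_dur = suppressWarnings(
        max(c(.data$duration[.data$is_grid &
                               .data$start < .data$first_cue[1]], -Inf))),
      enc_end = suppressWarnings(
        min(.data$start[.data$is_grid & .data$start > .data$first_cue[1]])),
      search_end = suppressWarnings(
        max(.data$start[.data$is_target & !is.na(.data$response_rel) &
                          .data$start >= .data$enc_end[1] &
                          .data$start < .data$response_rel])),
      .groups = "drop")

  out <- meta |>
    left_join(agg, by = keys) |>
    mutate(
      first_cue = dplyr::coalesce(.data$first_cue, Inf),
      n_prescan = dplyr::coalesce(.data$n_prescan, 0L),
      prescan_max_dur = dplyr::coalesce(.data$prescan_max_dur, -Inf),
      enc_end = dplyr::coalesce(.data$enc_end, Inf),
      search_end = dplyr::coalesce(.data$search_end, -Inf),
      rejection_reason = dplyr::case_when(
        .data$outcome == "incorrect" ~ "incorrect_response",
        .data$outcome == "missing" ~ "missing_response",
        !is.finite(.data$first_cue) | .data$first_cue < window[1] |
          .data$first_cue > window[2] ~ "no_cue_fixation_in_window",
        .data$n_prescan > max_prescan_fixations |
          .data$prescan_max_dur > max_prescan_duration ~
          "premature_grid_scanning",
        !is.finite(.data$enc_end) | !is.finite(.data$search_end) ~
          "no_search_end",
        TRUE ~ NA_character_),
      status = ifelse(is.na(.data$rejection_reason), "valid", "rejected"),
      encoding_start = ifelse(.data$status == "valid", .data$first_cue, NA),
      encoding_end = ifelse(.data$status == "valid", .data$enc_end, NA),
      search_start = .data$encoding_end,
      search_end = ifelse(.data$status == "valid", .data$search_end, NA))
  out[, c(keys, "outcome", "status", "rejection_reason", "encoding_start",
          "encoding_end", "search_start", "search_end", "response_rel",
          "target_cell")] |>
    rename(response_time = "response_rel")
}

#' Tally trial validity per participant
#'
#' Partitions each participant's trials into valid, incorrect, missing and
#' segmentation-rejected (correct trials failing the cue-window, pre-scan
#' or search-end rules).
#'
#' @param segments Output of [segment_trials()].
#' @return A tibble with one row per participant (or a single row when no
#'   `participant_id` column is present): `n_trials`, `n_valid`,
#'   `n_incorrect`, `n_missing`, `n_rejected_segmentation`.
#' @export
tabulate_validity <- function(segments) {
  keys <- intersect("participant_id", names(segments))
  segments |>
    group_by(pick(all_of(keys))) |>
    summarise(
      n_trials = dplyr::n(),
      n_valid = sum(.data$status == "valid"),
      n_incorrect = sum(.data$outcome == "incorrect"),
      n_missing = sum(.data$outcome == "missing"),
      n_rejected_segmentation = sum(.data$status == "rejected" &
                                      !.data$outcome %in%
                                      c("incorrect", "missing")),
      .groups = "drop")
}
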