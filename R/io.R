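#' Format dialect for delimited gaze files
#'
#' The canonical on-disk format is UTF-8 TSV with a one-line header and the
#' canonical column names (`t`, `x`, `y`, `valid` for samples; `start`,
#' `end`, `x`, `y` for fixation events).  Vendor exports use other names; a
#' dialect maps them onto the canonical ones and fixes the missing-data
#' policy, which is deliberately explicit because vendor defaults differ.
#'
#' @param time,x,y,valid Column names in the file for sample time (ms),
#'   horizontal and vertical position (px) and the track-validity flag.
#'   `valid` may be `NULL` if the file has no such column; rows with missing
#'   coordinates are then flagged invalid.
#' @param delim Field delimiter (default tab).
#' @param missing Track-loss policy: `"flag"` keeps invalid rows with
#'   `valid = FALSE` (the default -- downstream detection decides how to
#'   bridge them); `"drop"` removes them but reports how many were dropped.
#' @return A `vs_dialect` list.
#' @export
gaze_dialect <- function(time = "t", x = "x", y = "y", valid = "valid",
                         delim = "\t", missing = c("flag", "drop")) {
  structure(list(time = time, x = x, y = y, valid = valid, delim = delim,
                 missing = match.arg(missing)),
            class = "vs_dialect")
}

read_delimited <- function(path, delim) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
  # exact numeric conversion (correctly rounded strtod)
  as_tibble(lapply(raw, function(col) {
    utils::type.convert(col, as.is = TRUE)
  }))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema error in '", path, "': missing column",
                 if (length(missing) > 1) "s" else "", " ",
                 paste0("'", missing, "'", collapse = ", ")))
  }
}

#' Read a raw gaze-sample stream
#'
#' Reads a delimited sample file (one row per eye-tracker sample) and
#' validates it: sample times must be strictly increasing, and coordinates
#' of valid samples must lie on the screen.  Invalid (track-loss) rows are
#' flagged, never silently dropped; with `missing = "drop"` in the dialect
#' they are removed and counted in the `rejected` attribute so that
#' rows-in always equals rows-kept + rows-rejected.
#'
#' @param path Path to a delimited text file.
#' @param dialect A [gaze_dialect()] describing the file's column names.
#' @param sampling_rate Sampling rate in Hz (120 default; 60 allowed for
#'   recordings made at the lower rate).
#' @param participant_id Optional identifier stored as an attribute.
#' @param screen Optional [screen_geometry()]; when given, on-screen bounds
#'   of valid samples are checked.
#' @return A tibble with canonical columns `t` (ms), `x`, `y` (px), `valid`
#'   (logical), plus attributes `sampling_rate`, `participant_id` and
#'   `rejected` (tibble of dropped rows with reasons; empty under the
#'   `"flag"` policy).
#' @export
read_gaze_samples <- function(path, dialect = gaze_dialect(),
                              sampling_rate = 120, participant_id = NULL,
                              screen = NULL) {
  raw <- read_delimited(path, dialect$delim)
  need <- c(dialect$time, dialect$x, dialect$y)
  require_columns(raw, need, path)
  out <- tibble(t = as.numeric(raw[[dialect$time]]),
                x = as.numeric(raw[[dialect$x]]),
                y = as.numeric(raw[[dialect$y]]))
  if (!is.null(dialect$valid) && dialect$valid %in% names(raw)) {
    out$valid <- as.logical(raw[[dialect$valid]])
  } else {
    out$valid <- TRUE
  }
  out$valid <- out$valid & !is.na(out$x) & !is.na(out$y)
  bad_t <- which(diff(out$t) <= 0)
  if (length(bad_t) > 0) {
    abort(paste0("data error in '", path, "': sample time not strictly ",
                 "increasing at row ", bad_t[1] + 1L))
  }
  if (!is.null(screen)) {
    off <- out$valid &
      (out$x < 0 | out$x >= screen$width_px |
         out$y < 0 | out$y >= screen$height_px)
    if (any(off)) {
      inform(paste0(sum(off), " valid sample(s) off screen; flagged invalid"))
      out$valid[off] <- FALSE
    }
  }
  rejected <- tibble(row = integer(), reason = character())
  if (dialect$missing == "drop") {
    drop <- !out$valid
    if (any(drop)) {
      rejected <- tibble(row = which(drop), reason = "track_loss")
      inform(paste0("dropped ", sum(drop), " track-loss row(s)"))
      out <- out[!drop, ]
    }
  }
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "participant_id") <- participant_id
  attr(out, "rejected") <- rejected
  out
}

#' Write a gaze-sample stream
#'
#' @param samples Tibble with columns `t`, `x`, `y` and optionally `valid`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_gaze_samples <- function(samples, path) {
  cols <- intersect(c("t", "x", "y", "valid"), names(samples))
  write_table(samples[, cols], path)
}

#' Read a fixation-event table
#'
#' Supports ingesting pre-detected events (e.g. exported by vendor
#' software) as an alternative entry point to [detect_fixations()].
#' Events must be time-ordered and non-overlapping.
#'
#' @param path Path to a delimited file with columns `start`, `end`, `x`,
#'   `y` (ms and px).
#' @param delim Field delimiter.
#' @return A tibble `start`, `end`, `x`, `y`, `duration`, sorted by onset.
#' @export
read_fixations <- function(path, delim = "\t") {
  raw <- read_delimited(path, delim)
  require_columns(raw, c("start", "end", "x", "y"), path)
  out <- tibble(start = as.numeric(raw$start), end = as.numeric(raw$end),
                x = as.numeric(raw$x), y = as.numeric(raw$y))
  out <- arrange(out, .data$start)
  if (any(out$end <= out$start)) {
    abort(paste0("data error in '", path, "': fixation with end <= start"))
  }
  ov <- which(out$start[-1] < out$end[-nrow(out)])
  if (length(ov) > 0) {
    abort(paste0("data error in '", path, "': overlapping fixation events ",
                 "(rows ", ov[1], " and ", ov[1] + 1L, " after sorting)"))
  }
  out$duration <- out$end - out$start
  out
}

#' Write a fixation-event table
#'
#' @param fixations Tibble with at least `start`, `end`, `x`, `y`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  write_table(fixations[, intersect(c("start", "end", "x", "y"),
                                    names(fixations))], path)
}

#' Read trial metadata
#'
#' @param path Delimited file with columns `trial_id`, `trial_onset` (ms,
#'   onset of the fixation cross), `cue_onset` (ms) and `target_cell`
#'   (1-based grid-cell index).
#' @param delim Field delimiter.
#' @return A tibble sorted by `trial_id`.
#' @export
read_trial_meta <- function(path, delim = "\t") {
  raw <- read_delimited(path, delim)
  require_columns(raw, c("trial_id", "trial_onset", "cue_onset",
                         "target_cell"), path)
  out <- as_tibble(raw[, c("trial_id", "trial_onset", "cue_onset",
                           "target_cell")])
  out$trial_id <- as.integer(out$trial_id)
  out$target_cell <- as.integer(out$target_cell)
  arrange(out, .data$trial_id)
}

#' Read button responses
#'
#' @param path Delimited file with columns `trial_id`, `t` (ms, press time)
#'   and `cell` (grid cell pressed).
#' @param delim Field delimiter.
#' @return A tibble sorted by trial and time.
#' @export
read_responses <- function(path, delim = "\t") {
  raw <- read_delimited(path, delim)
  require_columns(raw, c("trial_id", "t", "cell"), path)
  out <- as_tibble(raw[, c("trial_id", "t", "cell")])
  out$trial_id <- as.integer(out$trial_id)
  out$cell <- as.integer(out$cell)
  arrange(out, .data$trial_id, .data$t)
}

#' Score trial outcomes from button responses
#'
#' A trial is `correct` when its first press hits the target cell,
#' `corrected` when the first press is wrong but the last press hits the
#' target (corrected trials count as correct downstream), `incorrect` when
#' presses occur but the last one misses, and `missing` without any press.
#' `response_time` is the time of the final, correct press (`NA` otherwise).
#'
#' @param meta Trial metadata ([read_trial_meta()] shape).
#' @param responses Button presses ([read_responses()] shape); times on the
#'   same clock as `meta`.
#' @return `meta` plus columns `outcome` (factor), `response_time`,
#'   `n_responses`.
#' @export
score_responses <- function(meta, responses) {
  keys <- intersect(c("participant_id", "trial_id"), names(meta))
  if (nrow(responses) == 0) {
    out <- meta
    out$n_responses <- 0L
    out$response_time <- NA_real_
    out$outcome <- factor("missing",
                          levels = c("correct", "corrected", "incorrect",
                                     "missing"))
    return(out[, c(names(meta), "outcome", "response_time", "n_responses")])
  }
  scored <- responses |>
    arrange(pick(all_of(keys)), .data$t) |>
    left_join(meta[, c(keys, "target_cell")], by = keys) |>
    group_by(pick(all_of(keys))) |>
    summarise(
      n_responses = dplyr::n(),
      first_hit = .data$cell[1] == .data$target_cell[1],
      last_hit = .data$cell[dplyr::n()] == .data$target_cell[1],
      response_time = if (.data$last_hit[1]) .data$t[dplyr::n()] else NA_real_,
      .groups = "drop")
  out <- left_join(meta, scored, by = keys) |>
    mutate(
      n_responses = dplyr::coalesce(.data$n_responses, 0L),
      outcome = dplyr::case_when(
        .data$n_responses == 0L ~ "missing",
        .data$first_hit ~ "correct",
        .data$last_hit & .data$n_responses >= 2L ~ "corrected",
        TRUE ~ "incorrect"),
      outcome = factor(.data$outcome,
                       levels = c("correct", "corrected", "incorrect",
                                  "missing")))
  out$first_hit <- out$last_hit <- NULL
  out
}

#' Write any result table as TSV
#'
#' Plain UTF-8 TSV with a one-line header.  Doubles are serialised with 17
#' significant digits, so write/read cycles reproduce them bit-exactly
#' (and integers exactly).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  is_dbl <- vapply(x, function(col) is.double(col) && !inherits(col, "Date"),
                   logical(1))
  x[is_dbl] <- lapply(x[is_dbl], function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- NA_character_
    out
  })
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  read_delimited(path, "\t")
}
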