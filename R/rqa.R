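#' Categorical recurrence matrix of an AOI-labelled scanpath
#'
#' Two fixations recur when they share an AOI label; fixations labelled
#' `"outside"` (or any label in `exclude`) stay in the sequence -- so the
#' temporal indexing and lag structure are preserved -- but never recur.
#'
#' @param labels Character vector of AOI labels, one per fixation, in
#'   temporal order.
#' @param exclude Labels that never recur (default `"outside"`).
#' @return An `N x N` logical matrix with `FALSE` diagonal; symmetric by
#'   construction.
#' @export
recurrence_matrix <- function(labels, exclude = "outside") {
  n <- length(labels)
  m <- outer(labels, labels, "==") & !(labels %in% exclude)
  diag(m) <- FALSE
  m
}

#' Recurrence quantification of a scanpath
#'
#' Computes, over the upper triangle of the recurrence matrix with `R`
#' recurrent pairs among `N` fixations:
#' \describe{
#'   \item{recurrence}{`100 * 2R / (N(N-1))` -- the percentage of fixation
#'     pairs revisiting the same AOI;}
#'   \item{determinism}{percentage of recurrent points lying on diagonal
#'     lines of length >= `min_line` -- repeated sub-scanpaths;}
#'   \item{laminarity}{`100 * (|H| + |V|) / (2R)` with horizontal and
#'     vertical line structures of length >= `min_line` -- prolonged
#'     dwelling on single AOIs;}
#'   \item{corm}{`100 * sum((j - i) r_ij) / ((N-1) R)` -- centre of
#'     recurrence mass; small values mean revisits close in time.}
#' }
#' With no recurrent pair, recurrence is 0 and the line-based measures are
#' undefined (`NA`); with fewer than two fixations everything is `NA`.
#'
#' @param labels AOI label sequence, or a precomputed [recurrence_matrix()].
#' @param min_line Minimum line length for determinism/laminarity
#'   (default 2; with `min_line = 1` determinism is trivially 100 whenever
#'   `R > 0`, a useful configuration sanity check).
#' @param exclude Passed to [recurrence_matrix()] when `labels` is a
#'   character vector.
#' @return One-row tibble: `n`, `r`, `recurrence`, `determinism`,
#'   `laminarity`, `corm`.
#' @examples
#' rqa_measures(c("A", "B", "A", "B"))
#' @export
rqa_measures <- function(labels, min_line = 2, exclude = "outside") {
  m <- if (is.matrix(labels)) labels else recurrence_matrix(labels, exclude)
  n <- nrow(m)
  if (n < 2) {
    return(tibble(n = n, r = NA_integer_, recurrence = NA_real_,
                  determinism = NA_real_, laminarity = NA_real_,
                  corm = NA_real_))
  }
  ut <- upper.tri(m)
  r <- sum(m[ut])
  if (r == 0) {
    return(tibble(n = n, r = 0L, recurrence = 0,
                  determinism = NA_real_, laminarity = NA_real_,
                  corm = NA_real_))
  }
  rec <- 100 * 2 * r / (n * (n - 1))
  # diagonal lines (parallel to the main diagonal) in the upper triangle
  d_pts <- 0L
  for (d in seq_len(n - 1)) {
    i <- seq_len(n - d)
    d_pts <- d_pts + run_points(m[cbind(i, i + d)], min_line)
  }
  # horizontal / vertical line structures in the upper triangle
  hv_pts <- 0L
  for (i in seq_len(n - 1)) {
    hv_pts <- hv_pts + run_points(m[i, (i + 1):n], min_line)   # horizontal
  }
  for (j in 2:n) {
    hv_pts <- hv_pts + run_points(m[seq_len(j - 1), j], min_line) # vertical
  }
  corm <- 100 * sum((col(m)[ut] - row(m)[ut]) * m[ut]) / ((n - 1) * r)
  tibble(n = n, r = as.integer(r),
         recurrence = rec,
         determinism = 100 * d_pts / r,
         laminarity = 100 * hv_pts / (2 * r),
         corm = corm)
}

# number of TRUE points lying in runs of length >= min_line
run_points <- function(v, min_line) {
  if (length(v) == 0) return(0L)
  rl <- rle(v)
  sum(rl$lengths[rl$values & rl$lengths >= min_line])
}

#' Per-trial RQA over the search segments of a study
#'
#' Extracts each valid trial's search-segment scanpath (fixations starting
#' within `[search_start, search_end]`, AOI alphabet = cue + the 12 grid
#' cells, `"outside"` retained but non-recurring) and computes
#' [rqa_measures()] per trial.  Trials with fewer than two search
#' fixations yield `NA` measures.
#'
#' @param fixations AOI-labelled, trial-relative fixations.
#' @param segments Output of [segment_trials()].
#' @param min_line Minimum line length (default 2).
#' @return A tibble, one row per valid trial, with `target_cell` and the
#'   RQA measures.
#' @export
rqa_trials <- function(fixations, segments, min_line = 2) {
  keys <- intersect(c("participant_id", "trial_id"), names(segments))
  sp <- search_scanpaths(fixations, segments)
  sp |>
    group_by(pick(all_of(c(keys, "target_cell")))) |>
    summarise(rqa_measures(.data$aoi, min_line = min_line), .groups = "drop")
}

# fixations inside each valid trial's search segment
search_scanpaths <- function(fixations, segments) {
  keys <- intersect(c("participant_id", "trial_id"), names(segments))
  seg <- filter(segments, .data$status == "valid")
  fixations |>
    inner_join(seg[, c(keys, "search_start", "search_end", "target_cell")],
               by = keys) |>
    filter(.data$start >= .data$search_start,
           .data$start <= .data$search_end)
}

#' Subtracted RQA as an intra-subject variability measure
#'
#' Re-expresses the RQA measures per target cell: within each participant,
#' trials sharing a target cell are compared pairwise and the absolute
#' differences of each measure are averaged over all such pairs.  Low
#' values mean the participant re-ran structurally similar searches
#' whenever the target sat in the same cell.
#'
#' @param trial_rqa Output of [rqa_trials()].
#' @param measures Which measures to subtract.
#' @return A tibble, one row per participant: `n_pairs` and
#'   `isv_<measure>` columns (`NA` when no target cell has two valid
#'   trials with defined measures).
#' @export
rqa_isv <- function(trial_rqa,
                    measures = c("recurrence", "determinism", "laminarity",
                                 "corm")) {
  keys <- intersect(c("participant_id", "group"), names(trial_rqa))
  if (length(keys) == 0) {
    trial_rqa$participant_id <- "all"
    keys <- "participant_id"
  }
  pairs <- trial_rqa |>
    inner_join(trial_rqa,
               by = c(keys, "target_cell"),
               suffix = c("_a", "_b"),
               relationship = "many-to-many") |>
    filter(.data$trial_id_a < .data$trial_id_b)
  for (m in measures) {
    pairs[[paste0("isv_", m)]] <-
      abs(pairs[[paste0(m, "_a")]] - pairs[[paste0(m, "_b")]])
  }
  pairs |>
    group_by(pick(all_of(keys))) |>
    summarise(
      n_pairs = dplyr::n(),
      across(all_of(paste0("isv_", measures)), ~mean(.x, na.rm = TRUE)),
      .groups = "drop")
}
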