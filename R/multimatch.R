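#' Build a scanpath from fixations
#'
#' A scanpath is the ordered sequence of fixations `(x, y, duration)`; the
#' saccade vectors between consecutive fixations carry its shape.
#'
#' @param fixations Tibble with `x`, `y`, `duration` in temporal order.
#' @return A tibble of class `vs_scanpath`.
#' @export
scanpath <- function(fixations) {
  out <- as_tibble(fixations[, c("x", "y", "duration")])
  class(out) <- c("vs_scanpath", class(out))
  out
}

sacc_vectors <- function(p) {
  n <- nrow(p)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(diff(p$x), diff(p$y))
}

vec_norm <- function(v) sqrt(rowSums(v^2))

# absolute angle between 2-d vectors, in [0, pi]; NA if either is zero
angle_between <- function(u, w) {
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * w) / (nu * nw))))
}

#' Simplify a scanpath by merging small or collinear saccades
#'
#' Iteratively merges consecutive saccade pairs until no merge applies:
#' amplitude-based -- both saccades shorter than `amp_threshold` (a
#' fraction of the screen diagonal) and the fixation between them shorter
#' than `dur_threshold` ms; direction-based -- the two saccades differ in
#' direction by less than `dir_threshold` degrees.  Merging removes the
#' intermediate fixation, so the merged vector is the vector sum; the
#' removed fixation's duration is added to the preceding fixation
#' (`merge_duration = "sum"`) or dropped.
#'
#' Simplification is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param path A [scanpath()] (or fixation tibble).
#' @param screen A [screen_geometry()] (supplies the diagonal).
#' @param amp_threshold Amplitude threshold as a fraction of the screen
#'   diagonal (default 0.1).
#' @param dir_threshold Direction threshold, degrees (default 45).
#' @param dur_threshold Intervening-fixation duration threshold, ms
#'   (default 300).
#' @param merge_duration `"sum"` or `"drop"`.
#' @return The simplified scanpath.
#' @export
simplify_scanpath <- function(path, screen = screen_geometry(),
                              amp_threshold = 0.1, dir_threshold = 45,
                              dur_threshold = 300,
                              merge_duration = c("sum", "drop")) {
  merge_duration <- match.arg(merge_duration)
  p <- scanpath(path)
  if (nrow(p) <= 2) return(p)
  amp_px <- amp_threshold * screen$diag_px
  dir_rad <- dir_threshold * pi / 180
  repeat {
    v <- sacc_vectors(p)
    if (nrow(v) < 2) break
    amps <- vec_norm(v)
    merged <- FALSE
    for (k in seq_len(nrow(v) - 1)) {
      ang <- angle_between(v[k, ], v[k + 1, ])
      amp_merge <- amps[k] < amp_px && amps[k + 1] < amp_px &&
        p$duration[k + 1] < dur_threshold
      dir_merge <- !is.na(ang) && ang < dir_rad
      if (amp_merge || dir_merge) {
        if (merge_duration == "sum") {
          p$duration[k] <- p$duration[k] + p$duration[k + 1]
        }
        p <- p[-(k + 1), ]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  p
}

#' Align two scanpaths' saccade-vector sequences
#'
#' Builds the cost matrix `M[i, j] = |v_i - w_j|` (Euclidean norm of the
#' vector difference) and finds the minimum-total-cost monotone path from
#' `(1, 1)` to `(n, m)` moving right, down or diagonally; ties prefer the
#' diagonal, so aligning a path with itself returns the exact diagonal.
#'
#' @param p,q Scanpaths with at least 2 fixations (1 saccade vector) each.
#' @return A tibble of matched vector index pairs `i`, `j` along the
#'   optimal path, with attribute `total_cost`; `NULL` when either path
#'   has no vector.
#' @export
align_scanpaths <- function(p, q) {
  vp <- sacc_vectors(scanpath(p)); vq <- sacc_vectors(scanpath(q))
  n <- nrow(vp); m <- nrow(vq)
  if (n == 0 || m == 0) return(NULL)
  M <- matrix(0, n, m)
  for (i in seq_len(n)) {
    d <- cbind(vq[, 1] - vp[i, 1], vq[, 2] - vp[i, 2])
    M[i, ] <- sqrt(rowSums(d^2))
  }
  D <- matrix(Inf, n, m)
  D[1, 1] <- M[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1 && j > 1) best <- D[i - 1, j - 1]
      if (i > 1) best <- min(best, D[i - 1, j])
      if (j > 1) best <- min(best, D[i, j - 1])
      D[i, j] <- M[i, j] + best
    }
  }
  # backtrack, preferring the diagonal on ties
  path <- matrix(NA_integer_, n + m, 2)
  k <- 1; i <- n; j <- m
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 && D[i - 1, j - 1] <= D[i - 1, j] + 1e-12 &&
        D[i - 1, j - 1] <= D[i, j - 1] + 1e-12) {
      i <- i - 1; j <- j - 1
    } else if (i > 1 && (j == 1 || D[i - 1, j] <= D[i, j - 1])) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    k <- k + 1
    path[k, ] <- c(i, j)
  }
  out <- tibble(i = rev(path[seq_len(k), 1]), j = rev(path[seq_len(k), 2]))
  attr(out, "total_cost") <- D[n, m]
  out
}

#' Five-dimension MultiMatch similarity for an aligned pair
#'
#' For each matched vector pair, normalised differences are computed --
#' vector: `|v_i - w_j| / (2 diag)`; length: `||v_i| - |w_j|| / diag`;
#' direction: angular difference / pi; position: distance between the
#' vectors' source fixations / diag; duration: `|d_i - d_j| /
#' max(d_i, d_j)` of the source fixations -- and each dimension's
#' similarity is 1 minus the aggregate (median by default) of its
#' differences over the alignment.  Pairs whose direction (zero-amplitude
#' vector) or duration (zero durations) difference is undefined are left
#' out of that dimension's aggregate.
#'
#' @param p,q Scanpaths (already simplified, if desired).
#' @param alignment Output of [align_scanpaths()]; computed when `NULL`.
#' @param screen A [screen_geometry()].
#' @param aggregate `"median"` (customary) or `"mean"`.
#' @return One-row tibble: `vector_similarity`, `length_similarity`,
#'   `direction_similarity`, `position_similarity`,
#'   `duration_similarity`, `n_matched`; all similarities in `[0, 1]`.
#' @export
similarity_dimensions <- function(p, q, alignment = NULL,
                                  screen = screen_geometry(),
                                  aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  p <- scanpath(p); q <- scanpath(q)
  alignment <- alignment %||% align_scanpaths(p, q)
  if (is.null(alignment)) {
    return(tibble(vector_similarity = NA_real_, length_similarity = NA_real_,
                  direction_similarity = NA_real_,
                  position_similarity = NA_real_,
                  duration_similarity = NA_real_, n_matched = 0L))
  }
  vp <- sacc_vectors(p); vq <- sacc_vectors(q)
  diag_px <- screen$diag_px
  i <- alignment$i; j <- alignment$j
  dv <- vp[i, , drop = FALSE] - vq[j, , drop = FALSE]
  vec_diff <- vec_norm(dv) / (2 * diag_px)
  len_diff <- abs(vec_norm(vp[i, , drop = FALSE]) -
                    vec_norm(vq[j, , drop = FALSE])) / diag_px
  dir_diff <- vapply(seq_along(i), function(k) {
    angle_between(vp[i[k], ], vq[j[k], ])
  }, numeric(1)) / pi
  pos_diff <- sqrt((p$x[i] - q$x[j])^2 + (p$y[i] - q$y[j])^2) / diag_px
  dmax <- pmax(p$duration[i], q$duration[j])
  dur_diff <- ifelse(dmax > 0, abs(p$duration[i] - q$duration[j]) / dmax,
                     NA_real_)
  agg <- function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    1 - if (aggregate == "median") median(d) else mean(d)
  }
  tibble(vector_similarity = agg(vec_diff),
         length_similarity = agg(len_diff),
         direction_similarity = agg(dir_diff),
         position_similarity = agg(pos_diff),
         duration_similarity = agg(dur_diff),
         n_matched = length(i))
}

#' MultiMatch similarity of two scanpaths
#'
#' Convenience wrapper: simplify both paths, align, score.
#'
#' @inheritParams similarity_dimensions
#' @inheritParams simplify_scanpath
#' @param simplify Apply [simplify_scanpath()] first (default `TRUE`).
#' @return One-row tibble as in [similarity_dimensions()].
#' @export
multimatch_pair <- function(p, q, screen = screen_geometry(),
                            simplify = TRUE, amp_threshold = 0.1,
                            dir_threshold = 45, dur_threshold = 300,
                            aggregate = c("median", "mean")) {
  p <- scanpath(p); q <- scanpath(q)
  if (simplify) {
    p <- simplify_scanpath(p, screen, amp_threshold, dir_threshold,
                           dur_threshold)
    q <- simplify_scanpath(q, screen, amp_threshold, dir_threshold,
                           dur_threshold)
  }
  similarity_dimensions(p, q, NULL, screen, aggregate)
}

#' MultiMatch scanpath similarity as an intra-subject variability measure
#'
#' Compares, within each participant, the search-segment scanpaths of all
#' pairs of valid trials whose target sat in the same grid cell, and
#' averages each of the five similarity dimensions over those pairs.  Low
#' similarity means high scanpath ISV.
#'
#' @param fixations AOI-labelled, trial-relative fixations.
#' @param segments Output of [segment_trials()].
#' @param screen A [screen_geometry()].
#' @inheritParams multimatch_pair
#' @return One row per participant: mean similarities and `n_pairs`
#'   (participants with no comparable pair are absent).
#' @export
multimatch_isv <- function(fixations, segments, screen = screen_geometry(),
                           simplify = TRUE, amp_threshold = 0.1,
                           dir_threshold = 45, dur_threshold = 300,
                           aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  keys <- intersect(c("participant_id", "trial_id"), names(segments))
  sp <- search_scanpaths(fixations, segments)
  pkey <- intersect("participant_id", keys)
  paths <- sp |>
    group_by(pick(all_of(c(pkey, "trial_id", "target_cell")))) |>
    summarise(path = list(pick("x", "y", "duration")), n_fix = dplyr::n(),
              .groups = "drop") |>
    filter(.data$n_fix >= 2)
  pairs <- paths |>
    inner_join(paths, by = c(pkey, "target_cell"), suffix = c("_a", "_b"),
               relationship = "many-to-many") |>
    filter(.data$trial_id_a < .data$trial_id_b)
  if (nrow(pairs) == 0) {
    return(tibble(participant_id = character(), n_pairs = integer()))
  }
  sims <- map2(pairs$path_a, pairs$path_b, function(a, b) {
    multimatch_pair(a, b, screen, simplify, amp_threshold, dir_threshold,
                    dur_threshold, aggregate)
  }) |> list_rbind()
  bind_cols(pairs[, c(pkey, "target_cell")], sims) |>
    group_by(pick(all_of(pkey))) |>
    summarise(n_pairs = dplyr::n(),
              across(ends_with("_similarity"), ~mean(.x, na.rm = TRUE)),
              .groups = "drop")
}
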