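#' Screen geometry and pixel/degree conversion
#'
#' Describes the display the gaze coordinates live on.  Coordinates are
#' 0-based pixels with the origin at the top-left corner and y increasing
#' downward; this convention is used everywhere in the package.  The
#' pixels-per-degree factor uses the small-angle approximation
#' `px_per_degree = (width_px / physical_width_cm) * distance_cm * pi / 180`,
#' appropriate for the central visual field of a desktop display.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param physical_width_cm Physical width of the visible display area, cm.
#' @param distance_cm Viewing distance, cm.
#' @return An object of class `vs_screen`: a list with the inputs plus
#'   `px_per_degree` and `diag_px` (screen diagonal in pixels).
#' @examples
#' scr <- screen_geometry()
#' scr$px_per_degree
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            physical_width_cm = 47.4, distance_cm = 70) {
  stopifnot(width_px > 0, height_px > 0, physical_width_cm > 0, distance_cm > 0)
  ppd <- width_px / physical_width_cm * distance_cm * pi / 180
  structure(
    list(width_px = width_px, height_px = height_px,
         physical_width_cm = physical_width_cm, distance_cm = distance_cm,
         px_per_degree = ppd,
         diag_px = sqrt(width_px^2 + height_px^2)),
    class = "vs_screen")
}

#' Pixels subtended by one degree of visual angle
#'
#' @param screen A [screen_geometry()] object.
#' @return Pixels per degree (scalar).
#' @export
px_per_degree <- function(screen = screen_geometry()) {
  stopifnot(inherits(screen, "vs_screen"))
  screen$px_per_degree
}

rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

#' Task layout: cue box, search grid, trial timing and target schedule
#'
#' Builds the geometry and timing of a cued visual-search trial: a fixation
#' cross on the left for `cross_duration` ms, then a cue box (left) plus a
#' grid of `n_cols * n_rows` word-pair cells (right) shown for
#' `stimulus_duration` ms.  The grid occupies the right part of the screen
#' starting at `grid_left_frac` of its width; cells are equal, disjoint
#' rectangles numbered row-major (`cell_1` top-left .. `cell_12`
#' bottom-right for the default 4 x 3 grid).
#'
#' The fixation cross sits below the cue box so that cross fixations are not
#' labelled as cue fixations: entry time to cue is then the arrival of gaze
#' in the cue box, not the residue of cross fixation.
#'
#' @param screen A [screen_geometry()].
#' @param n_cols,n_rows Grid dimensions; the product is the number of
#'   response cells (12 by default, matching a 12-field response pad).
#' @param grid_left_frac Fraction of screen width left of the grid.
#' @param cross_duration Fixation-cross duration, ms (default 2000).
#' @param stimulus_duration Cue + grid presentation, ms (default 7000).
#' @param n_trials Number of trials in the block (default 30).
#' @param target_schedule Optional integer vector (length `n_trials`) of
#'   target cell indices; defaults to [default_target_schedule()].
#' @return A `vs_layout` list: `screen`, `cue` / `cross` / `grid_cells`
#'   rectangles, durations, `trial_span` (= cross + stimulus duration),
#'   `n_trials`, `target_schedule`.
#' @examples
#' lay <- task_layout()
#' aois(lay)
#' @export
task_layout <- function(screen = screen_geometry(), n_cols = 4, n_rows = 3,
                        grid_left_frac = 0.25,
                        cross_duration = 2000, stimulus_duration = 7000,
                        n_trials = 30, target_schedule = NULL) {
  stopifnot(n_cols >= 1, n_rows >= 1, cross_duration > 0, stimulus_duration > 0,
            n_trials >= 1, grid_left_frac > 0, grid_left_frac < 1)
  n_cells <- n_cols * n_rows
  gx0 <- screen$width_px * grid_left_frac
  cw <- (screen$width_px - gx0) / n_cols
  ch <- screen$height_px / n_rows
  cells <- vector("list", n_cells)
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- (r - 1) * n_cols + cc
      cells[[k]] <- rect(gx0 + (cc - 1) * cw, gx0 + cc * cw,
                         (r - 1) * ch, r * ch)
    }
  }
  # cue box in the upper-left region, cross below it: disjoint from the grid
  # and from each other by construction
  cue <- rect(0.03 * screen$width_px, 0.22 * screen$width_px,
              0.24 * screen$height_px, 0.57 * screen$height_px)
  cross <- c(x = 0.125 * screen$width_px, y = 0.79 * screen$height_px)
  target_schedule <- target_schedule %||%
    default_target_schedule(n_trials, n_cells = n_cells)
  if (length(target_schedule) != n_trials ||
      !all(target_schedule %in% seq_len(n_cells))) {
    abort("`target_schedule` must hold one cell index in 1..n_cells per trial.")
  }
  structure(
    list(screen = screen, cue = cue, cross = cross, grid_cells = cells,
         n_cols = n_cols, n_rows = n_rows, n_cells = n_cells,
         cross_duration = cross_duration, stimulus_duration = stimulus_duration,
         trial_span = cross_duration + stimulus_duration,
         n_trials = n_trials, target_schedule = as.integer(target_schedule)),
    class = "vs_layout")
}

#' Default target-position schedule
#'
#' For a 30-trial block over 12 cells, 6 cells occur twice (12 trials) and 6
#' cells occur thrice (18 trials).  With `seed = NULL` the assignment of cells
#' to repetition counts and the trial order are a fixed interleaving; with a
#' seed both are randomised (reproducibly).
#'
#' @param n_trials Number of trials.
#' @param n_cells Number of grid cells (default 12).
#' @param seed Optional integer seed for a randomised schedule.
#' @return Integer vector of length `n_trials` with target cell per trial.
#' @export
default_target_schedule <- function(n_trials = 30, n_cells = 12, seed = NULL) {
  if (n_trials == 30 && n_cells == 12) {
    if (is.null(seed)) {
      pool <- c(rep(1:6, 2L), rep(7:12, 3L))
      # fixed de-clustered order: stride through the pool
      ord <- order(seq_along(pool) %% 7, seq_along(pool))
      return(as.integer(pool[ord]))
    }
    return(with_seed(seed, {
      cells <- sample.int(12)
      as.integer(sample(c(rep(cells[1:6], 2L), rep(cells[7:12], 3L))))
    }))
  }
  as.integer(rep_len(seq_len(n_cells), n_trials))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Areas of interest of a task layout
#'
#' @param layout A [task_layout()].
#' @return A tibble with columns `aoi` (`"cue"`, `"cell_1"`, ...),
#'   `xmin`, `xmax`, `ymin`, `ymax`.  Rectangles are half-open:
#'   a point belongs to an AOI when `xmin <= x < xmax` and `ymin <= y < ymax`.
#' @export
aois <- function(layout) {
  stopifnot(inherits(layout, "vs_layout"))
  rects <- c(list(cue = layout$cue),
             setNames(layout$grid_cells,
                      paste0("cell_", seq_along(layout$grid_cells))))
  out <- map_dfr(rects, ~ as_tibble(as.list(.x)))
  out$aoi <- names(rects)
  out[, c("aoi", "xmin", "xmax", "ymin", "ymax")]
}

cell_label <- function(cell) paste0("cell_", cell)

rect_center <- function(r) c((r["xmin"] + r["xmax"]) / 2,
                             (r["ymin"] + r["ymax"]) / 2)
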