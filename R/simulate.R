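#' Group-level generative profile for synthetic participants
#'
#' A profile fixes the distributions a synthetic group is drawn from.  Each
#' oculomotor variable is parameterised as
#' `c(mean, between_sd, isv, isv_spread)`: a subject-level mean is drawn from
#' `Normal(mean, between_sd)`, a subject-level trial-to-trial SD (the
#' intra-subject variability, ISV) from a Gamma distribution with mean `isv`
#' and SD `isv_spread`, and per-trial values from the subject's own Normal
#' law.  Defaults follow the magnitudes observed in school-age visual-search
#' cohorts (entry to cue ~2.5 s from trial onset with ~130 ms trial-to-trial
#' SD, ~600 ms total cue dwell, ~250 ms search fixations).
#'
#' @param label Group label (e.g. `"TD"`, `"ADHD"`, `"ASD-"`, `"ASD+"`).
#' @param entry_to_cue `c(mean, between_sd, isv, isv_spread)` of the onset of
#'   the first cue fixation, ms from trial onset.
#' @param cue_duration Same parameterisation for the total cue dwell in the
#'   encoding phase, ms.
#' @param cue_count `c(mean, between_sd)` of the per-trial cue-fixation
#'   count; trial counts are `1 + Binomial(2, p)` with subject-level `p`.
#' @param search_duration `c(mean, between_sd, isv, isv_spread)` for the
#'   per-trial mean search-fixation duration, ms.
#' @param fix_duration_spread Within-trial SD of individual search-fixation
#'   durations around the trial level, ms.
#' @param revisit_probability After each newly scanned cell, probability of
#'   revisiting an already-scanned cell before moving on.
#' @param cue_recheck_probability After each newly scanned cell, probability
#'   of glancing back at the cue.
#' @param refix_probability Probability that a cell visit contains a second
#'   fixation (reading both words of the pair).
#' @param scan_order `"random"` scans unvisited cells in random order;
#'   `"sequential"` scans them in cell order (useful for degenerate,
#'   variance-free scenarios).
#' @param motor_delay `c(mean, sd)` of the press delay after the last target
#'   fixation, ms.
#' @param miss_probability Probability a trial gets no button press on top
#'   of natural misses (searches censored by the stimulus offset).
#' @param error_probability Probability the first press is a wrong cell.
#' @param correction_probability Given a wrong first press, probability that
#'   a correcting press on the target follows.
#' @param prescan_probability Probability of a grid glance before the cue is
#'   first fixated (exercises the pre-scan rejection rule downstream).
#' @param position_jitter Scale factor for fixation-placement jitter within
#'   AOIs (0 gives deterministic positions).
#' @return A `vs_profile` list.
#' @seealso [default_profiles()] for a ready-made four-group set.
#' @export
group_profile <- function(label,
                          entry_to_cue = c(2493, 83, 129, 41),
                          cue_duration = c(604, 220, 158, 91),
                          cue_count = c(1.42, 0.25),
                          search_duration = c(249, 31, 60, 25),
                          fix_duration_spread = 40,
                          revisit_probability = 0.2,
                          cue_recheck_probability = 0.15,
                          refix_probability = 0.3,
                          scan_order = c("random", "sequential"),
                          motor_delay = c(450, 120),
                          miss_probability = 0.01,
                          error_probability = 0.02,
                          correction_probability = 0.6,
                          prescan_probability = 0.05,
                          position_jitter = 1) {
  p <- list(label = label,
            entry_to_cue = entry_to_cue, cue_duration = cue_duration,
            cue_count = cue_count, search_duration = search_duration,
            fix_duration_spread = fix_duration_spread,
            revisit_probability = revisit_probability,
            cue_recheck_probability = cue_recheck_probability,
            refix_probability = refix_probability,
            scan_order = match.arg(scan_order),
            motor_delay = motor_delay,
            miss_probability = miss_probability,
            error_probability = error_probability,
            correction_probability = correction_probability,
            prescan_probability = prescan_probability,
            position_jitter = position_jitter)
  for (v in c("entry_to_cue", "cue_duration", "search_duration")) {
    if (length(p[[v]]) != 4 || any(p[[v]][-1] < 0) || p[[v]][1] <= 0)
      abort(paste0("`", v, "` must be c(mean, between_sd, isv, isv_spread), ",
                   "mean > 0, spreads >= 0"))
  }
  probs <- c(p$revisit_probability, p$cue_recheck_probability,
             p$refix_probability, p$miss_probability, p$error_probability,
             p$correction_probability, p$prescan_probability)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(p, class = "vs_profile")
}

#' Default four-group profile set
#'
#' Group profiles for a typically-developing group and three clinical groups
#' (ADHD, ASD without and with comorbid ADHD).  Entry-to-cue, cue-dwell and
#' search-fixation laws differ across groups in both level and ISV: the
#' groups with ADHD symptoms (ADHD, ASD+) carry larger trial-to-trial SDs,
#' and the comorbid group is slowest.
#'
#' @return Named list of four [group_profile()] objects
#'   (`TD`, `ADHD`, `ASD-`, `ASD+`).
#' @export
default_profiles <- function() {
  list(
    "TD" = group_profile("TD",
      entry_to_cue = c(2493, 83, 129, 41),
      cue_duration = c(604, 220, 158, 91),
      cue_count = c(1.42, 0.25),
      search_duration = c(249, 31, 60, 25),
      miss_probability = 0.01, error_probability = 0.02),
    "ADHD" = group_profile("ADHD",
      entry_to_cue = c(2540, 111, 163, 61),
      cue_duration = c(655, 169, 220, 128),
      cue_count = c(1.50, 0.24),
      search_duration = c(264, 36, 70, 26),
      miss_probability = 0.03, error_probability = 0.03),
    "ASD-" = group_profile("ASD-",
      entry_to_cue = c(2508, 99, 127, 36),
      cue_duration = c(601, 145, 161, 77),
      cue_count = c(1.52, 0.22),
      search_duration = c(242, 37, 62, 27),
      revisit_probability = 0.15,
      miss_probability = 0.03, error_probability = 0.03),
    "ASD+" = group_profile("ASD+",
      entry_to_cue = c(2662, 120, 169, 35),
      cue_duration = c(717, 220, 246, 138),
      cue_count = c(1.51, 0.30),
      search_duration = c(277, 38, 67, 24),
      miss_probability = 0.06, error_probability = 0.03))
}

# truncated-normal draw; degenerates gracefully when sd == 0
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# gamma draw by mean/sd; sd == 0 gives the constant
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# saccade duration from amplitude (main-sequence flavoured), ms
saccade_ms <- function(dist_px, ppd) 21 + 2.2 * dist_px / ppd

#' Simulate one participant's visual-search session
#'
#' Generates, trial by trial: a cross fixation; optionally a premature grid
#' glance; a first cue fixation whose onset is drawn from the subject's
#' entry-time law truncated to `[cue_onset - 300, trial end]`; further cue
#' fixations realising the subject's dwell law; then a scan over grid cells
#' (unvisited cells in random or sequential order, with revisits and cue
#' re-checks at the profile's rates, 1-2 fixations per cell) until the
#' target cell is fixated; a button press one motor delay later; and a
#' post-response rest fixation.  Searches still running close to the
#' stimulus offset are censored and become missing trials, on top of the
#' profile's explicit miss probability.
#'
#' All generated fixations, the segment boundaries and the per-trial
#' variable values are recorded as ground truth, so downstream detection,
#' segmentation and metrics can be verified against what was generated.
#'
#' @param profile A [group_profile()].
#' @param layout A [task_layout()].
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   output bit-identically.
#' @param participant_id Identifier carried through all outputs.
#' @param render_samples If `TRUE`, also render raw gaze samples at
#'   `sampling_rate` with within-fixation Gaussian jitter (SD `jitter_deg`)
#'   and linear saccadic sweeps between fixations.
#' @param sampling_rate Samples per second for rendering (120 default).
#' @param jitter_deg Within-fixation jitter SD in degrees; keep well below
#'   the detector's dispersion threshold for recoverable fixations.
#' @return A list of class `vs_participant`:
#' \describe{
#'   \item{samples}{tibble `t, x, y, valid` (or `NULL`), recording-relative ms}
#'   \item{fixations}{ground-truth fixations `trial_id, start, end, x, y,
#'     duration, aoi` (recording-relative)}
#'   \item{meta}{`trial_id, trial_onset, cue_onset, target_cell`}
#'   \item{responses}{`trial_id, t, cell` (recording-relative press times)}
#'   \item{truth}{per-trial variables and segment boundaries
#'     (trial-relative ms), including the intended `outcome`}
#' }
#' @export
simulate_participant <- function(profile, layout = task_layout(), seed = 1,
                                 participant_id = "p01",
                                 render_samples = FALSE, sampling_rate = 120,
                                 jitter_deg = 0.12) {
  stopifnot(inherits(profile, "vs_profile"), inherits(layout, "vs_layout"))
  set.seed(seed)
  scr <- layout$screen
  ppd <- scr$px_per_degree
  span <- layout$trial_span
  cue_on <- layout$cross_duration
  n_tr <- layout$n_trials
  entry_lo <- cue_on - 300
  entry_hi <- span

  # infeasible profile: essentially no mass inside the stimulus window
  p_in <- stats::pnorm(entry_hi, profile$entry_to_cue[1],
                       max(profile$entry_to_cue[3], 1e-9)) -
    stats::pnorm(entry_lo, profile$entry_to_cue[1],
                 max(profile$entry_to_cue[3], 1e-9))
  if (profile$entry_to_cue[3] == 0) {
    p_in <- as.numeric(profile$entry_to_cue[1] >= entry_lo &
                         profile$entry_to_cue[1] <= entry_hi)
  }
  if (p_in < 0.01) {
    abort(paste0("infeasible profile '", profile$label, "': entry-to-cue ",
                 "law has ~no mass inside the stimulus window"))
  }

  cue_c <- rect_center(layout$cue)
  cross_xy <- layout$cross
  rest_xy <- c(cross_xy["x"], cross_xy["y"] - 200)
  cells_c <- t(vapply(layout$grid_cells, rect_center, numeric(2)))
  cell_h <- layout$grid_cells[[1]]["ymax"] - layout$grid_cells[[1]]["ymin"]
  n_cells <- layout$n_cells
  pj <- profile$position_jitter

  # subject level
  s_entry_m <- rnorm(1, profile$entry_to_cue[1], profile$entry_to_cue[2])
  s_entry_sd <- rgamma_ms(1, profile$entry_to_cue[3], profile$entry_to_cue[4])
  s_dwell_m <- max(150, rnorm(1, profile$cue_duration[1],
                              profile$cue_duration[2]))
  s_dwell_sd <- rgamma_ms(1, profile$cue_duration[3], profile$cue_duration[4])
  s_cnt_m <- min(3, max(1, rnorm(1, profile$cue_count[1],
                                 profile$cue_count[2])))
  s_cnt_p <- (s_cnt_m - 1) / 2
  s_sdur_m <- max(120, rnorm(1, profile$search_duration[1],
                             profile$search_duration[2]))
  s_sdur_sd <- rgamma_ms(1, profile$search_duration[3],
                         profile$search_duration[4])

  # per-trial draws (vectorised)
  entry <- rtnorm(n_tr, s_entry_m, s_entry_sd, entry_lo, entry_hi)
  dwell_lvl <- rtnorm(n_tr, s_dwell_m, s_dwell_sd, 100, Inf)
  cue_cnt <- 1L + rbinom(n_tr, 2L, s_cnt_p)
  sdur_lvl <- rtnorm(n_tr, s_sdur_m, s_sdur_sd, 100, Inf)
  forced_miss <- runif(n_tr) < profile$miss_probability
  press_err <- runif(n_tr) < profile$error_probability
  err_corrected <- runif(n_tr) < profile$correction_probability
  prescan <- runif(n_tr) < profile$prescan_probability & entry > cue_on + 400
  delay <- pmax(150, rnorm(n_tr, profile$motor_delay[1],
                           profile$motor_delay[2]))

  # participant-level accumulators (avoid per-trial data-frame overhead)
  fxl_start <- vector("list", n_tr); fxl_dur <- vector("list", n_tr)
  fxl_x <- vector("list", n_tr); fxl_y <- vector("list", n_tr)
  fxl_aoi <- vector("list", n_tr)
  resp_trial <- integer(0); resp_time <- numeric(0); resp_cell <- integer(0)
  na_tr <- rep(NA_real_, n_tr)
  tr_outcome <- character(n_tr)
  tr_cue_cnt <- rep(NA_integer_, n_tr); tr_cue_dur <- na_tr
  tr_entry_grid <- na_tr; tr_sfc <- na_tr; tr_sfd <- na_tr
  tr_search_end <- na_tr; tr_rt <- na_tr; tr_resp <- na_tr
  cell_labs <- paste0("cell_", seq_len(n_cells))
  refix_p <- profile$refix_probability
  revisit_p <- profile$revisit_probability
  recheck_p <- profile$cue_recheck_probability
  fds <- profile$fix_duration_spread

  for (i in seq_len(n_tr)) {
    onset <- (i - 1) * span
    target <- layout$target_schedule[i]
    # fixation record accumulators (trial-relative)
    fx_start <- numeric(0); fx_dur <- numeric(0)
    fx_x <- numeric(0); fx_y <- numeric(0); fx_aoi <- character(0)

    add_fix <- function(start, dur, x, y, aoi) {
      # never let a fixation cross the trial boundary
      dur <- min(dur, span - 35 - start)
      if (dur < 60) return(0)
      fx_start <<- c(fx_start, start); fx_dur <<- c(fx_dur, dur)
      fx_x <<- c(fx_x, x); fx_y <<- c(fx_y, y); fx_aoi <<- c(fx_aoi, aoi)
      dur
    }

    # --- pre-cue phase -------------------------------------------------
    pre_rows <- NULL
    if (prescan[i]) {
      n_pre <- 1L + (runif(1) < 0.3)
      pre_cells <- sample.int(n_cells, n_pre)
      pre_durs <- pmax(80, rgamma_ms(n_pre, 210, 80))
      pre_end <- entry[i] - 60   # leave room for the saccade back to cue
      pre_start <- pre_end - sum(pre_durs) - 35 * (n_pre - 1)
      if (pre_start > 400) {
        tcur <- pre_start
        for (k in seq_len(n_pre)) {
          px <- cells_c[pre_cells[k], 1] + pj * runif(1, -40, 40)
          py <- cells_c[pre_cells[k], 2] + pj * runif(1, -40, 40)
          add_fix(tcur, pre_durs[k], px, py, cell_labs[pre_cells[k]])
          tcur <- tcur + pre_durs[k] + 35
        }
        pre_rows <- seq_len(n_pre)
      }
    }
    first_pre_start <- if (length(fx_start)) fx_start[1] else entry[i]
    # cross fixation occupies the head of the trial
    cross_end <- first_pre_start - saccade_ms(400, ppd)
    if (cross_end > 80) {
      fx_start <- c(0, fx_start); fx_dur <- c(cross_end, fx_dur)
      fx_x <- c(cross_xy["x"], fx_x); fx_y <- c(cross_xy["y"], fx_y)
      fx_aoi <- c("outside", fx_aoi)
    }

    # --- cue fixations (encoding) --------------------------------------
    ccnt <- cue_cnt[i]
    parts <- rgamma(ccnt, shape = 5)
    cdurs <- pmax(80, dwell_lvl[i] * parts / sum(parts))
    tcur <- entry[i]
    cue_pos_x <- cue_c[1] + ifelse(seq_len(ccnt) %% 2 == 1, -85, 85) +
      pj * runif(ccnt, -20, 20)
    cue_pos_y <- cue_c[2] + pj * runif(ccnt, -30, 30)
    for (k in seq_len(ccnt)) {
      if (tcur > span - 200) break
      dk <- add_fix(tcur, cdurs[k], cue_pos_x[k], cue_pos_y[k], "cue")
      if (dk == 0) break
      tcur <- tcur + dk + (if (k < ccnt) saccade_ms(170, ppd) else 0)
    }
    cue_total <- sum(fx_dur[fx_aoi == "cue"])
    last_xy <- c(tail(fx_x, 1), tail(fx_y, 1))

    # --- search walk ---------------------------------------------------
    order_cells <- if (profile$scan_order == "sequential") seq_len(n_cells)
      else sample.int(n_cells)
    tcur <- tcur + saccade_ms(sqrt(sum((cells_c[order_cells[1], ] -
                                          last_xy)^2)), ppd)
    entry_grid <- tcur
    visited <- integer(0)
    target_found <- FALSE
    last_target_onset <- NA_real_
    last_target_end <- NA_real_
    budget <- span - 230     # leave room for press + rest
    word_side <- -1
    visit_cell <- function(cell, tcur) {
      nf <- 1L + (runif(1) < refix_p)
      for (f in seq_len(nf)) {
        if (tcur > budget) return(list(t = tcur, done = FALSE))
        d <- max(90, rnorm(1, sdur_lvl[i], fds))
        word_side <<- -word_side
        px <- cells_c[cell, 1] + pj * runif(1, -35, 35)
        py <- cells_c[cell, 2] + word_side * cell_h / 4 +
          pj * runif(1, -20, 20)
        d <- add_fix(tcur, d, px, py, cell_labs[cell])
        if (d == 0) return(list(t = tcur, done = FALSE))
        if (cell == target) {
          last_target_onset <<- tcur; last_target_end <<- tcur + d
        }
        tcur <- tcur + d + saccade_ms(250, ppd)
      }
      list(t = tcur, done = TRUE)
    }
    for (cell in order_cells) {
      if (tcur > budget) break
      res <- visit_cell(cell, tcur)
      tcur <- res$t
      if (!res$done) break
      visited <- c(visited, cell)
      if (cell == target) { target_found <- TRUE; break }
      if (length(visited) > 1 && runif(1) < revisit_p && tcur <= budget) {
        res <- visit_cell(sample(visited, 1), tcur)
        tcur <- res$t
        if (!res$done) break
      }
      if (runif(1) < recheck_p && tcur <= budget) {
        d <- max(90, rnorm(1, 0.8 * sdur_lvl[i], fds))
        d <- add_fix(tcur, d, cue_c[1] + pj * runif(1, -40, 40),
                     cue_c[2] + pj * runif(1, -30, 30), "cue")
        if (d == 0) break
        tcur <- tcur + d + saccade_ms(600, ppd)
      }
    }

    # --- response ------------------------------------------------------
    resp_t <- if (target_found) last_target_end + delay[i] else NA_real_
    outcome <- "missing"
    presses_t <- numeric(0); presses_cell <- integer(0)
    if (target_found && !forced_miss[i] && !is.na(resp_t) && resp_t <= span) {
      if (press_err[i]) {
        wrong <- sample(setdiff(seq_len(n_cells), target), 1)
        presses_t <- resp_t; presses_cell <- wrong
        corr_t <- resp_t + 300 + rgamma_ms(1, 350, 120)
        if (err_corrected[i] && corr_t <= span) {
          presses_t <- c(presses_t, corr_t)
          presses_cell <- c(presses_cell, target)
          outcome <- "corrected"; resp_t <- corr_t
        } else {
          outcome <- "incorrect"; resp_t <- NA_real_
        }
      } else {
        presses_t <- resp_t; presses_cell <- target
        outcome <- "correct"
      }
    } else {
      resp_t <- NA_real_
    }

    # --- post-response rest fixation ----------------------------------
    last_end <- if (length(fx_start)) max(fx_start + fx_dur) else 0
    rest_start <- last_end + saccade_ms(500, ppd)
    rest_end <- span - 30
    if (rest_end - rest_start > 80) {
      add_fix(rest_start, rest_end - rest_start,
              rest_xy[1] + pj * runif(1, -15, 15),
              rest_xy[2] + pj * runif(1, -15, 15), "outside")
    }

    fxl_start[[i]] <- onset + fx_start
    fxl_dur[[i]] <- fx_dur
    fxl_x[[i]] <- fx_x; fxl_y[[i]] <- fx_y; fxl_aoi[[i]] <- fx_aoi
    if (length(presses_t)) {
      resp_trial <- c(resp_trial, rep(i, length(presses_t)))
      resp_time <- c(resp_time, onset + presses_t)
      resp_cell <- c(resp_cell, presses_cell)
    }
    ok_tr <- outcome %in% c("correct", "corrected")
    in_search <- if (is.na(last_target_onset)) rep(FALSE, length(fx_start))
      else fx_start >= entry_grid & fx_start <= last_target_onset
    tr_outcome[i] <- outcome
    tr_cue_cnt[i] <- sum(fx_aoi == "cue" & fx_start >= entry[i] &
                           fx_start < entry_grid)
    tr_cue_dur[i] <- cue_total
    tr_entry_grid[i] <- entry_grid
    if (ok_tr) {
      tr_sfc[i] <- sum(in_search)
      tr_sfd[i] <- mean(fx_dur[in_search])
      tr_search_end[i] <- last_target_onset
      tr_rt[i] <- resp_t - cue_on
      tr_resp[i] <- resp_t
    }
  }

  nfx <- lengths(fxl_start)
  st <- unlist(fxl_start, use.names = FALSE)
  du <- unlist(fxl_dur, use.names = FALSE)
  fixations <- tibble(trial_id = rep(seq_len(n_tr), nfx),
                      start = st, end = st + du,
                      x = unlist(fxl_x, use.names = FALSE),
                      y = unlist(fxl_y, use.names = FALSE),
                      duration = du,
                      aoi = unlist(fxl_aoi, use.names = FALSE))
  responses <- tibble(trial_id = resp_trial, t = resp_time, cell = resp_cell)
  meta <- tibble(trial_id = seq_len(n_tr),
                 trial_onset = (seq_len(n_tr) - 1) * span,
                 cue_onset = (seq_len(n_tr) - 1) * span + cue_on,
                 target_cell = layout$target_schedule)
  truth <- tibble(trial_id = seq_len(n_tr),
                  target_cell = layout$target_schedule,
                  outcome = tr_outcome,
                  entry_to_cue = entry,
                  cue_fix_count = tr_cue_cnt,
                  cue_fix_duration = tr_cue_dur,
                  entry_to_grid = tr_entry_grid,
                  search_fix_count = tr_sfc,
                  search_fix_duration = tr_sfd,
                  encoding_start = entry, encoding_end = tr_entry_grid,
                  search_start = tr_entry_grid, search_end = tr_search_end,
                  rt = tr_rt, response_time = tr_resp)
  samples <- NULL
  if (render_samples) {
    samples <- render_gaze(fixations, sampling_rate = sampling_rate,
                           jitter_px = jitter_deg * ppd,
                           total_span = n_tr * span)
  }
  structure(list(samples = samples, fixations = fixations, meta = meta,
                 responses = responses, truth = truth,
                 participant_id = participant_id, group = profile$label,
                 layout = layout, sampling_rate = sampling_rate),
            class = "vs_participant")
}

#' Render ground-truth fixations to raw gaze samples
#'
#' Produces a regular sample stream: within each fixation the gaze sits at
#' the fixation centre plus isotropic Gaussian jitter; between fixations it
#' sweeps linearly from one centre to the next; after the last fixation it
#' holds position.  By default in-flight (saccadic) samples carry
#' `valid = FALSE`, mimicking the reduced pupil/corneal-reflection
#' confidence video trackers report during fast motion; the detector's
#' gap bridging absorbs them.  Set `flag_saccades = FALSE` for a stream
#' in which every sample is marked valid.
#'
#' @param fixations Tibble `start, end, x, y` (recording-relative ms),
#'   non-overlapping and time-ordered.
#' @param sampling_rate Hz.
#' @param jitter_px Within-fixation jitter SD in pixels.
#' @param total_span Total recording length, ms (defaults to the last
#'   fixation end).
#' @param flag_saccades Mark in-flight samples invalid (default `TRUE`).
#' @return A samples tibble `t, x, y, valid`.
#' @export
render_gaze <- function(fixations, sampling_rate = 120, jitter_px = 6,
                        total_span = NULL, flag_saccades = TRUE) {
  fx <- arrange(fixations, .data$start)
  dt <- 1000 / sampling_rate
  total_span <- total_span %||% max(fx$end)
  t <- seq(0, total_span - dt / 2, by = dt)
  idx <- findInterval(t, fx$start)
  x <- numeric(length(t)); y <- numeric(length(t))
  # before the first fixation: hold its centre
  pre <- idx == 0
  x[pre] <- fx$x[1]; y[pre] <- fx$y[1]
  ok <- !pre
  i <- pmax(idx, 1)
  in_fix <- ok & t < fx$end[i]
  x[in_fix] <- fx$x[i[in_fix]]
  y[in_fix] <- fx$y[i[in_fix]]
  sweep <- ok & !in_fix
  j <- pmin(i + 1, nrow(fx))
  frac <- (t - fx$end[i]) / pmax(fx$start[j] - fx$end[i], 1e-9)
  frac <- pmin(pmax(frac, 0), 1)
  x[sweep] <- fx$x[i[sweep]] + frac[sweep] * (fx$x[j[sweep]] - fx$x[i[sweep]])
  y[sweep] <- fx$y[i[sweep]] + frac[sweep] * (fx$y[j[sweep]] - fx$y[i[sweep]])
  x[in_fix] <- x[in_fix] + rnorm(sum(in_fix), 0, jitter_px)
  y[in_fix] <- y[in_fix] + rnorm(sum(in_fix), 0, jitter_px)
  tibble(t = t, x = x, y = y,
         valid = if (flag_saccades) !(sweep | pre) else TRUE)
}

#' Simulate a full multi-group study
#'
#' Draws `n_per_group[g]` participants from each profile.  Each participant
#' gets an independent RNG stream seeded from the study seed and the
#' participant index, so the study is reproducible as a whole and
#' participant-by-participant.
#'
#' @param profiles Named list of [group_profile()]s (default:
#'   [default_profiles()]).
#' @param n_per_group Integer vector, one count per profile (each >= 2).
#' @param layout A [task_layout()].
#' @param seed Study seed.
#' @param render_samples Render raw samples for every participant (slow;
#'   off by default -- ground-truth fixations feed the pipeline directly).
#' @param sampling_rate,jitter_deg Passed to [simulate_participant()].
#' @return A `vs_study` list: `participants` (tibble `participant_id, group,
#'   seed`), `fixations`, `meta`, `responses`, `truth` (all with
#'   `participant_id`), `samples` (named list or `NULL`), `layout`,
#'   `profiles`, `seed`.
#' @export
simulate_group_study <- function(profiles = default_profiles(),
                                 n_per_group = c(29, 23, 15, 18),
                                 layout = task_layout(), seed = 1,
                                 render_samples = FALSE, sampling_rate = 120,
                                 jitter_deg = 0.12) {
  stopifnot(length(n_per_group) == length(profiles))
  if (any(n_per_group < 2)) abort("each group needs n >= 2")
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, "", "label")
  n_total <- sum(n_per_group)
  pseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  grp <- rep(names(profiles), n_per_group)
  code <- tolower(gsub("\\+", "p", gsub("-", "m", gsub("[^A-Za-z+-]", "", grp))))
  idx_in_grp <- stats::ave(seq_len(n_total), grp, FUN = seq_along)
  ids <- sprintf("%s_%02d", code, idx_in_grp)
  parts <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    parts[[k]] <- simulate_participant(
      profiles[[grp[k]]], layout, seed = pseeds[k], participant_id = ids[k],
      render_samples = render_samples, sampling_rate = sampling_rate,
      jitter_deg = jitter_deg)
  }
  bind_part <- function(field) {
    list_rbind(map2(parts, ids, function(p, id) {
      df <- p[[field]]
      if (nrow(df) == 0) return(df)
      mutate(df, participant_id = id, .before = 1)
    }))
  }
  fixations <- bind_part("fixations")
  meta <- bind_part("meta")
  responses <- bind_part("responses")
  truth <- bind_part("truth")
  samples <- NULL
  if (render_samples) {
    samples <- setNames(map(parts, "samples"), ids)
  }
  structure(list(
    participants = tibble(participant_id = ids, group = grp, seed = pseeds),
    fixations = fixations, meta = meta, responses = responses, truth = truth,
    samples = samples, layout = layout, profiles = profiles, seed = seed),
    class = "vs_study")
}
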