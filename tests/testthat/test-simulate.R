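test_that("same seed and configuration reproduce a participant exactly", {
  lay <- test_layout()
  prof <- default_profiles()[["ADHD"]]
  a <- simulate_participant(prof, lay, seed = 7, render_samples = TRUE)
  b <- simulate_participant(prof, lay, seed = 7, render_samples = TRUE)
  expect_identical(a, b)
  c <- simulate_participant(prof, lay, seed = 8)
  expect_false(identical(a$truth, c$truth))
})

test_that("a variance-free profile produces identical trials and zero ISV", {
  lay <- task_layout(n_trials = 12, target_schedule = rep(5L, 12))
  p <- simulate_participant(degenerate_profile(), lay, seed = 1)
  sp <- segment_participant(p, lay)
  expect_true(all(sp$seg$status == "valid"))
  f <- trial_features(sp$fx, sp$seg)
  s <- summarize_participants(f, min_trials = 2)
  for (v in c("sd_entry_to_cue", "sd_cue_fix_duration", "sd_cue_fix_count",
              "sd_entry_to_grid", "sd_search_fix_duration",
              "sd_search_fix_count", "rtsd")) {
    expect_lt(abs(s[[v]]), 1e-8, label = v)
  }
})

test_that("miss probability one yields only missing trials", {
  lay <- task_layout(n_trials = 10, target_schedule = rep(3L, 10))
  prof <- group_profile("allmiss", miss_probability = 1)
  p <- simulate_participant(prof, lay, seed = 3)
  expect_true(all(p$truth$outcome == "missing"))
  expect_equal(nrow(p$responses), 0)
  sp <- segment_participant(p, lay)
  tv <- tabulate_validity(sp$seg)
  expect_equal(tv$n_valid, 0)
  expect_equal(tv$n_missing, 10)
})

test_that("ground-truth fixations are valid events on the trial timeline", {
  lay <- test_layout()
  p <- simulate_participant(default_profiles()[["ASD+"]], lay, seed = 5)
  fx <- p$fixations
  expect_true(all(diff(fx$start) > 0))
  expect_true(all(fx$start[-1] >= fx$end[-nrow(fx)] - 1e-9))  # no overlap
  expect_true(all(fx$duration >= 60))
  # fixations never cross their trial's boundary
  rel_end <- fx$end - (fx$trial_id - 1) * lay$trial_span
  expect_true(all(rel_end <= lay$trial_span))
})

test_that("per-trial variables recomputed by the pipeline equal ground truth", {
  lay <- test_layout()
  for (g in c("TD", "ASD+")) {
    p <- simulate_participant(default_profiles()[[g]], lay, seed = 11)
    sp <- segment_participant(p, lay)
    expect_identical(as.character(sp$meta$outcome), p$truth$outcome)
    f <- trial_features(sp$fx, sp$seg)
    tv <- p$truth[match(f$trial_id, p$truth$trial_id), ]
    for (v in c("entry_to_cue", "cue_fix_count", "cue_fix_duration",
                "entry_to_grid", "search_fix_count", "search_fix_duration",
                "rt")) {
      expect_equal(f[[v]], tv[[v]], tolerance = 1e-9, label = paste(g, v))
    }
    valid <- sp$seg$status == "valid"
    expect_equal(sp$seg$encoding_start[valid], tv$encoding_start,
                 tolerance = 1e-9)
    expect_equal(sp$seg$search_end[valid], tv$search_end, tolerance = 1e-9)
  }
})

test_that("AOI labelling recovers the generator's cell sequence", {
  lay <- test_layout()
  p <- simulate_participant(default_profiles()[["TD"]], lay, seed = 13)
  lab <- label_fixations(p$fixations[, c("start", "end", "x", "y",
                                         "duration")], lay)
  expect_identical(lab$aoi, p$fixations$aoi)
})

test_that("group study has the requested sizes and is seed-reproducible", {
  lay <- test_layout()
  prof <- default_profiles()
  st <- simulate_group_study(prof, n_per_group = c(2, 2, 3, 2),
                             layout = lay, seed = 5)
  expect_equal(nrow(st$participants), 9)
  expect_equal(as.vector(table(st$participants$group)[c("TD", "ADHD",
                                                        "ASD-", "ASD+")]),
               c(2, 2, 3, 2))
  expect_false(any(duplicated(st$participants$participant_id)))
  st2 <- simulate_group_study(prof, n_per_group = c(2, 2, 3, 2),
                              layout = lay, seed = 5)
  expect_identical(st$fixations, st2$fixations)
  expect_identical(st$truth, st2$truth)
  expect_error(simulate_group_study(prof, n_per_group = c(1, 2, 2, 2),
                                    layout = lay),
               "n >= 2")
})

test_that("population means are recovered across many simulated subjects", {
  lay <- test_layout()
  prof <- default_profiles()[["TD"]]
  n_sub <- 150
  entries <- numeric(n_sub)
  dwells <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    p <- simulate_participant(prof, lay, seed = 5000 + s)
    entries[s] <- mean(p$truth$entry_to_cue)
    dwells[s] <- mean(p$truth$cue_fix_duration[p$truth$cue_fix_count >= 1])
  }
  # SE of the mean-of-subject-means ~ sqrt(83^2 + 129^2/30) / sqrt(150)
  se_entry <- sqrt(prof$entry_to_cue[2]^2 +
                     prof$entry_to_cue[3]^2 / lay$n_trials) / sqrt(n_sub)
  expect_lt(abs(mean(entries) - prof$entry_to_cue[1]), 4 * se_entry)
  # cue dwell is truncated below, so allow a small upward bias band
  expect_lt(abs(mean(dwells) - prof$cue_duration[1]),
            0.06 * prof$cue_duration[1])
})

test_that("infeasible entry-time laws are rejected", {
  lay <- test_layout()
  bad <- group_profile("bad", entry_to_cue = c(25000, 0, 50, 0))
  expect_error(simulate_participant(bad, lay, seed = 1), "infeasible")
})

test_that("rendered streams respect the sampling grid and validity flags", {
  lay <- task_layout(n_trials = 3, target_schedule = c(1L, 5L, 9L))
  p <- simulate_participant(default_profiles()[["TD"]], lay, seed = 2,
                            render_samples = TRUE, sampling_rate = 120)
  s <- p$samples
  expect_equal(unique(round(diff(s$t), 6)), round(1000 / 120, 6))
  expect_gt(mean(s$valid), 0.8)       # most samples are fixational
  expect_lt(mean(s$valid), 1)         # saccadic flight flagged invalid
  expect_equal(nrow(s), 3 * lay$trial_span * 120 / 1000)
})
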