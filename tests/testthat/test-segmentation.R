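lay <- task_layout()

test_that("fixation centroids map to AOIs with half-open boundaries", {
  a <- aois(lay)
  cue <- a[a$aoi == "cue", ]
  c1 <- a[a$aoi == "cell_1", ]
  fx <- tibble::tibble(
    x = c(mean(c(cue$xmin, cue$xmax)), 10, c1$xmin, c1$xmax,
          c1$xmin, mean(c(c1$xmin, c1$xmax))),
    y = c(mean(c(cue$ymin, cue$ymax)), 10, c1$ymin + 1, c1$ymin + 1,
          c1$ymax, mean(c(c1$ymin, c1$ymax))),
    start = 1:6, end = 2:7, duration = 1)
  lab <- label_fixations(fx, lay)
  expect_equal(lab$aoi, c("cue", "outside", "cell_1", "cell_2",
                          "cell_5", "cell_1"))
})

test_that("cue-window rule is closed on both boundaries", {
  run_case <- function(entry) {
    fx <- trial_fx(list(entry, 500, "cue"),
                   list(entry + 600, 400, "cell_5"))
    segment_trials(fx, trial_meta())$rejection_reason
  }
  expect_equal(run_case(1699), "no_cue_fixation_in_window")
  expect_true(is.na(run_case(1700)))
  expect_true(is.na(run_case(3300)))
  expect_equal(run_case(3301), "no_cue_fixation_in_window")
})

test_that("a trial with no cue fixation at all is rejected", {
  fx <- trial_fx(list(2000, 400, "cell_2"), list(2500, 400, "cell_5"))
  seg <- segment_trials(fx, trial_meta())
  expect_equal(seg$rejection_reason, "no_cue_fixation_in_window")
})

test_that("pre-scan rule allows one short grid glance, no more", {
  base <- function(...) {
    segment_trials(trial_fx(..., list(2500, 500, "cue"),
                            list(3200, 400, "cell_5")),
                   trial_meta())
  }
  # one glance of exactly 300 ms passes
  ok <- base(list(900, 300, "cell_3"))
  expect_equal(ok$status, "valid")
  # one glance of 301 ms fails
  expect_equal(base(list(900, 301, "cell_3"))$rejection_reason,
               "premature_grid_scanning")
  # two short glances fail
  expect_equal(base(list(700, 200, "cell_3"),
                    list(1000, 200, "cell_7"))$rejection_reason,
               "premature_grid_scanning")
})

test_that("rules are applied in order: a trial fails at most one rule", {
  # incorrect outcome AND premature scanning: outcome filter wins
  fx <- trial_fx(list(700, 400, "cell_3"), list(1200, 400, "cell_7"),
                 list(2500, 500, "cue"), list(3200, 400, "cell_5"))
  seg <- segment_trials(fx, trial_meta(outcome = "incorrect",
                                       response_time = NA))
  expect_equal(seg$rejection_reason, "incorrect_response")
  seg <- segment_trials(fx, trial_meta(outcome = "missing",
                                       response_time = NA))
  expect_equal(seg$rejection_reason, "missing_response")
  # bad cue window AND premature scanning: window rule wins
  fx2 <- trial_fx(list(700, 400, "cell_3"), list(1200, 400, "cell_7"),
                  list(3400, 500, "cue"), list(4000, 400, "cell_5"))
  expect_equal(segment_trials(fx2, trial_meta())$rejection_reason,
               "no_cue_fixation_in_window")
})

test_that("segment boundaries follow the stated definitions", {
  fx <- trial_fx(list(2000, 500, "cue"),       # encoding starts
                 list(2600, 300, "cell_2"),    # first grid fixation
                 list(3000, 300, "cell_5"),    # target visited
                 list(3400, 300, "cue"),       # cue re-check in search
                 list(3800, 300, "cell_5"),    # last target fixation
                 list(4300, 400, "cell_9"))
  seg <- segment_trials(fx, trial_meta(response_time = 4600))
  expect_equal(seg$status, "valid")
  expect_equal(seg$encoding_start, 2000)
  expect_equal(seg$encoding_end, 2600)
  expect_equal(seg$search_start, 2600)
  expect_equal(seg$search_end, 3800)
})

test_that("corrected trials use the final press; late target looks ignored", {
  fx <- trial_fx(list(2000, 500, "cue"),
                 list(2600, 300, "cell_2"),
                 list(3000, 300, "cell_5"),
                 list(5400, 300, "cell_5"))  # after the final press
  seg <- segment_trials(fx, trial_meta(outcome = "corrected",
                                       response_time = 5200))
  expect_equal(seg$status, "valid")
  expect_equal(seg$search_end, 3000)
  # fixation starting exactly at the press no longer counts (half-open)
  seg2 <- segment_trials(fx, trial_meta(response_time = 3000))
  expect_equal(seg2$rejection_reason, "no_search_end")
})

test_that("no grid fixation after cue means no measurable search", {
  fx <- trial_fx(list(2000, 500, "cue"), list(2600, 400, "cue"))
  expect_equal(segment_trials(fx, trial_meta())$rejection_reason,
               "no_search_end")
  # target fixated only before the cue: still no search end
  fx2 <- trial_fx(list(1200, 250, "cell_5"), list(2000, 500, "cue"),
                  list(2600, 300, "cell_2"))
  expect_equal(segment_trials(fx2, trial_meta())$rejection_reason,
               "no_search_end")
})

test_that("unsorted fixations violate the contract", {
  fx <- trial_fx(list(2600, 300, "cell_2"), list(2000, 500, "cue"))
  fx <- fx[c(1, 2), ]
  expect_error(segment_trials(fx, trial_meta()), "time-sorted")
})

test_that("validity tallies partition each participant's trials", {
  lay2 <- test_layout()
  st <- simulate_group_study(default_profiles(),
                             n_per_group = c(2, 2, 2, 2),
                             layout = lay2, seed = 19)
  meta <- score_responses(st$meta, st$responses)
  fx <- label_fixations(
    assign_trials(st$fixations[, c("participant_id", "start", "end", "x",
                                   "y", "duration")], st$meta,
                  lay2$trial_span), lay2)
  seg <- segment_trials(fx, meta)
  tv <- tabulate_validity(seg)
  expect_equal(nrow(tv), 8)
  expect_true(all(tv$n_valid + tv$n_incorrect + tv$n_missing +
                    tv$n_rejected_segmentation == tv$n_trials))
  # tallies agree with the generator's intended outcomes
  truth_tally <- dplyr::count(st$truth, participant_id,
                              outcome = factor(outcome,
                                               c("correct", "corrected",
                                                 "incorrect", "missing")))
  miss <- dplyr::filter(truth_tally, outcome == "missing")
  expect_equal(tv$n_missing[match(miss$participant_id,
                                  tv$participant_id)], miss$n)
})
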