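scr <- screen_geometry()

test_that("collinear saccades merge into their vector sum", {
  p <- tibble::tibble(x = c(0, 100, 200), y = c(0, 0, 0),
                      duration = c(200, 100, 200))
  s <- simplify_scanpath(p, scr)
  expect_equal(nrow(s), 2)
  expect_equal(s$x, c(0, 200))
  expect_equal(s$duration[1], 300)   # absorbed middle fixation
  s2 <- simplify_scanpath(p, scr, merge_duration = "drop")
  expect_equal(s2$duration[1], 200)
})

test_that("large orthogonal saccades never merge", {
  p <- tibble::tibble(x = c(0, 900, 900), y = c(0, 0, 900),
                      duration = c(200, 400, 200))
  s <- simplify_scanpath(p, scr)
  expect_equal(nrow(s), 3)
})

test_that("small-amplitude saccades merge only under the duration gate", {
  amp <- 0.04 * scr$diag_px
  p <- tibble::tibble(x = c(0, amp, 0), y = c(0, 0, amp),
                      duration = c(200, 100, 200))
  expect_equal(nrow(simplify_scanpath(p, scr)), 2)      # 100 < 300 ms
  p$duration[2] <- 400
  expect_equal(nrow(simplify_scanpath(p, scr)), 3)      # gate blocks it
})

test_that("simplification is idempotent", {
  set.seed(15)
  for (k in 1:20) {
    p <- random_scanpath(sample(3:12, 1))
    s1 <- simplify_scanpath(p, scr)
    s2 <- simplify_scanpath(s1, scr)
    expect_equal(s2, s1)
  }
})

test_that("aligning a path with itself gives the diagonal at zero cost", {
  set.seed(16)
  p <- random_scanpath(7)
  al <- align_scanpaths(p, p)
  expect_equal(al$i, 1:6)
  expect_equal(al$j, 1:6)
  expect_equal(attr(al, "total_cost"), 0)
})

test_that("single-vector paths align as one matched pair", {
  p <- tibble::tibble(x = c(0, 100), y = c(0, 50), duration = c(100, 100))
  q <- tibble::tibble(x = c(5, 90), y = c(0, 60), duration = c(100, 100))
  al <- align_scanpaths(p, q)
  expect_equal(nrow(al), 1)
  expect_null(align_scanpaths(p[1, ], q))
})

test_that("alignment cost equals exhaustive path enumeration", {
  set.seed(17)
  for (k in 1:20) {
    p <- random_scanpath(sample(3:7, 1))
    q <- random_scanpath(sample(3:7, 1))
    al <- align_scanpaths(p, q)
    vp <- cbind(diff(p$x), diff(p$y)); vq <- cbind(diff(q$x), diff(q$y))
    M <- matrix(0, nrow(vp), nrow(vq))
    for (i in seq_len(nrow(vp))) {
      for (j in seq_len(nrow(vq))) {
        M[i, j] <- sqrt(sum((vp[i, ] - vq[j, ])^2))
      }
    }
    expect_equal(attr(al, "total_cost"), align_brute_cost(M))
    # monotone path from corner to corner
    expect_equal(unlist(al[1, ]), c(i = 1, j = 1))
    expect_equal(unlist(al[nrow(al), ]), c(i = nrow(vp), j = nrow(vq)))
    expect_true(all(diff(al$i) %in% 0:1) && all(diff(al$j) %in% 0:1))
  }
})

test_that("self-comparison scores one on all five dimensions", {
  set.seed(18)
  for (k in 1:10) {
    p <- random_scanpath(sample(3:10, 1))
    r <- multimatch_pair(p, p, scr)
    expect_equal(unlist(r[, 1:5]), setNames(rep(1, 5), names(r)[1:5]))
  }
})

test_that("similarity is symmetric in its arguments", {
  set.seed(19)
  for (k in 1:10) {
    p <- random_scanpath(sample(3:8, 1))
    q <- random_scanpath(sample(3:8, 1))
    a <- multimatch_pair(p, q, scr)
    b <- multimatch_pair(q, p, scr)
    expect_equal(a[, 1:5], b[, 1:5], tolerance = 1e-12)
  }
})

test_that("opposite single saccades of equal length disagree only in direction", {
  p <- tibble::tibble(x = c(0, 400), y = c(500, 500), duration = c(200, 200))
  q <- tibble::tibble(x = c(400, 0), y = c(500, 500), duration = c(200, 200))
  r <- similarity_dimensions(p, q, screen = scr)
  expect_equal(r$direction_similarity, 0)
  expect_equal(r$length_similarity, 1)
  expect_equal(r$duration_similarity, 1)
})

test_that("all dimensions stay in [0, 1] on random pairs", {
  set.seed(20)
  for (k in 1:20) {
    r <- multimatch_pair(random_scanpath(sample(3:10, 1)),
                         random_scanpath(sample(3:10, 1)), scr)
    vals <- unlist(r[, 1:5])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("translating both paths changes nothing; one path, only position", {
  set.seed(21)
  p <- random_scanpath(6)
  q <- random_scanpath(6)
  shift <- function(d, dx, dy) dplyr::mutate(d, x = x + dx, y = y + dy)
  base <- similarity_dimensions(p, q, screen = scr)
  both <- similarity_dimensions(shift(p, 60, -40), shift(q, 60, -40),
                                screen = scr)
  expect_equal(both, base, tolerance = 1e-12)
  one <- similarity_dimensions(shift(p, 200, 150), q, screen = scr)
  # saccade vectors are translation-invariant
  expect_equal(one$vector_similarity, base$vector_similarity)
  expect_equal(one$length_similarity, base$length_similarity)
  expect_equal(one$direction_similarity, base$direction_similarity)
  expect_equal(one$duration_similarity, base$duration_similarity)
  expect_lt(one$position_similarity, base$position_similarity)
})

test_that("zero-duration fixations drop out of the duration dimension", {
  p <- tibble::tibble(x = c(0, 300, 600), y = c(0, 0, 0),
                      duration = c(0, 200, 100))
  q <- tibble::tibble(x = c(0, 300, 600), y = c(50, 50, 50),
                      duration = c(0, 200, 100))
  r <- similarity_dimensions(p, q, screen = scr)
  expect_equal(r$duration_similarity, 1)   # the defined pair matches
})

test_that("within-cell trial pairs aggregate into participant similarity", {
  # two identical trials in one cell: perfect similarity
  fx <- dplyr::bind_rows(
    trial_fx(list(2000, 400, "cue"), list(2600, 200, "cell_2"),
             list(2900, 250, "cell_7"), list(3250, 220, "cell_5")),
    dplyr::mutate(
      trial_fx(list(2000, 400, "cue"), list(2600, 200, "cell_2"),
               list(2900, 250, "cell_7"), list(3250, 220, "cell_5")),
      trial_id = 2L))
  fx$x <- rep(c(240, 660, 1300, 700), 2)
  fx$y <- rep(c(430, 180, 540, 540), 2)
  meta <- dplyr::bind_rows(trial_meta(), trial_meta(trial_id = 2L))
  seg <- segment_trials(fx, meta)
  expect_equal(seg$status, c("valid", "valid"))
  mm <- multimatch_isv(fx, seg, scr)
  expect_equal(mm$n_pairs, 1L)
  expect_equal(unlist(mm[, grep("_similarity", names(mm))]),
               setNames(rep(1, 5),
                        grep("_similarity", names(mm), value = TRUE)))
})

test_that("three same-cell trials yield three pairwise comparisons", {
  lay <- task_layout(n_trials = 3, target_schedule = c(5L, 5L, 5L))
  p <- simulate_participant(default_profiles()[["TD"]], lay, seed = 31)
  sp <- segment_participant(p, lay)
  expect_equal(sum(sp$seg$status == "valid"), 3)
  mm <- multimatch_isv(sp$fx, sp$seg, scr)
  expect_equal(mm$n_pairs, 3L)
})
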