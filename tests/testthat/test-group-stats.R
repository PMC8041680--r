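test_that("equal group means give a zero F statistic", {
  d <- data.frame(g = rep(c("a", "b", "c", "d"), each = 3),
                  y = rep(c(-1, 0, 1), 4) + 5)
  an <- oneway_anova(d, "y", "g")
  expect_equal(an$f, 0)
  expect_equal(an$eta_squared, 0)
})

test_that("F and eta squared match a hand-computed decomposition", {
  d <- data.frame(g = rep(c("a", "b", "c"), c(4, 4, 4)),
                  y = c(6, 8, 4, 5, 8, 12, 9, 11, 13, 9, 11, 8))
  an <- oneway_anova(d, "y", "g")
  gm <- mean(d$y)
  means <- tapply(d$y, d$g, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((d$y - means[d$g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(an$f, f_hand)
  expect_equal(an$eta_squared, ssb / (ssb + ssw))
  expect_equal(unname(an$df), c(2, 9))
  expect_equal(an$p, pf(f_hand, 2, 9, lower.tail = FALSE))
})

test_that("85 participants in four groups leave 81 error df", {
  set.seed(2)
  d <- data.frame(g = rep(c("TD", "ADHD", "ASD-", "ASD+"),
                          c(29, 23, 15, 18)),
                  y = rnorm(85))
  an <- oneway_anova(d, "y", "g")
  expect_equal(an$df[["error"]], 81)
  ph <- tukey_posthoc(an)
  expect_equal(nrow(ph), 6)
  expect_true(all(ph$df == 81))
})

test_that("sums of squares decompose exactly", {
  set.seed(3)
  for (k in 1:50) {
    ns <- sample(3:20, 4, replace = TRUE)
    d <- data.frame(g = rep(letters[1:4], ns),
                    y = rnorm(sum(ns), rep(rnorm(4, 0, 2), ns)))
    an <- oneway_anova(d, "y", "g")
    ss_tot <- sum((d$y - mean(d$y))^2)
    expect_lt(abs(an$ss[["between"]] + an$ss[["within"]] - ss_tot) /
                ss_tot, 1e-9)
  }
})

test_that("groups with fewer than two observations are named in the error", {
  d <- data.frame(g = c("a", "a", "b"), y = 1:3)
  expect_error(oneway_anova(d, "y", "g"), "b")
})

test_that("identical groups give zero t and d; adjusted p matches TukeyHSD", {
  d <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                  y = c(1:6, 1:6, 7:12))
  an <- oneway_anova(d, "y", "g")
  ph <- tukey_posthoc(an)
  ab <- ph[ph$group1 == "a" & ph$group2 == "b", ]
  expect_equal(ab$t, 0)
  expect_equal(ab$cohens_d, 0)

  set.seed(8)
  for (k in 1:10) {
    ns <- sample(4:15, 4, replace = TRUE)
    d <- data.frame(g = rep(letters[1:4], ns),
                    y = rnorm(sum(ns), rep(c(0, 0.5, 1, 0.2), ns)))
    an <- oneway_anova(d, "y", "g")
    ph <- tukey_posthoc(an)
    hsd <- TukeyHSD(an$fit)$g
    key <- paste(ph$group2, ph$group1, sep = "-")
    expect_equal(ph$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-10)
    expect_equal(-ph$diff, unname(hsd[key, "diff"]), tolerance = 1e-12)
  }
})

test_that("Cohen's d uses the pooled two-group SD", {
  d <- data.frame(g = rep(c("a", "b"), each = 10),
                  y = c(rnorm(10, 0, 1), rnorm(10, 1, 1)))
  an <- oneway_anova(d, "y", "g")
  ph <- tukey_posthoc(an)
  ya <- d$y[d$g == "a"]; yb <- d$y[d$g == "b"]
  sp <- sqrt((9 * var(ya) + 9 * var(yb)) / 18)
  expect_equal(ph$cohens_d, (mean(ya) - mean(yb)) / sp)
})

test_that("the 3-SD rule removes only extreme members, one pass", {
  d <- data.frame(g = rep("a", 21), y = c(rep(1, 20), 100),
                  id = paste0("p", 1:21))
  out <- remove_outliers(d, "y", "g", id = "id")
  expect_equal(out$removed_ids, "p21")
  expect_equal(nrow(out$data), 20)
  # in small groups the rule is self-masking: with n = 10 no value can sit
  # more than (n-1)/sqrt(n) ~ 2.85 SDs out, so nothing is ever removed
  d10 <- data.frame(g = rep("a", 10), y = c(rep(1, 9), 100))
  expect_equal(nrow(remove_outliers(d10, "y", "g")$removed), 0)
  # all-equal group: nothing to remove
  d0 <- data.frame(g = "a", y = rep(4, 8))
  expect_equal(nrow(remove_outliers(d0, "y", "g")$removed), 0)
  # borderline: exactly 3 SD is kept (strict inequality)
  y <- c(rnorm(20), 0)
  y[21] <- mean(y[1:20])
  d1 <- data.frame(g = "a", y = y)
  k <- 3 * sd(d1$y) # not an outlier by construction
  expect_equal(nrow(remove_outliers(d1, "y", "g")$removed), 0)
})

test_that("outlier removal shrinks the error df in the comparison table", {
  set.seed(10)
  summ <- tibble::tibble(
    participant_id = paste0("p", 1:60),
    group = rep(c("a", "b", "c", "d"), each = 15),
    v = c(rnorm(59), 50), excluded = FALSE)
  gs <- group_stats(summ, "v", outlier_rule = "v")
  expect_equal(gs$comparisons$n_outliers_removed, 1)
  expect_equal(gs$comparisons$df_error, 55)          # 59 - 4
  expect_equal(gs$comparisons$df_error_nominal, 56)  # 60 - 4
  gs2 <- group_stats(summ, "v")
  expect_equal(gs2$comparisons$n_outliers_removed, 0)
  expect_equal(gs2$comparisons$df_error, 56)
})

test_that("ANCOVA collapses to the ANOVA when the covariate is useless", {
  set.seed(11)
  d <- data.frame(g = rep(letters[1:4], each = 15),
                  y = rnorm(60, rep(c(0, 1, 2, 0.5), each = 15)))
  d$z <- rnorm(60)   # independent of everything
  an <- oneway_anova(d, "y", "g")
  ac <- ancova(d, "y", "g", "z")
  expect_lt(abs(ac$f - an$f) / an$f, 0.25)
  expect_equal(ac$df[["error"]], an$df[["error"]] - 1)

  # covariate that fully explains the group differences
  d2 <- d
  d2$z <- d2$y + rnorm(60, 0, 1e-3)
  ac2 <- ancova(d2, "y", "g", "z")
  expect_lt(ac2$f, an$f / 5)
})

test_that("ANCOVA group F equals the type-II general-linear-model oracle", {
  set.seed(12)
  d <- data.frame(g = rep(letters[1:3], c(8, 12, 10)))
  d$z <- rnorm(30, 100, 15)
  d$y <- 0.02 * d$z + rnorm(30, rep(c(0, 0.5, 1), c(8, 12, 10)), 0.5)
  ac <- ancova(d, "y", "g", "z")
  cf <- car::Anova(stats::lm(y ~ z + g, data = d), type = 2)
  expect_equal(ac$f, cf["g", "F value"], tolerance = 1e-10)
  expect_equal(ac$p, cf["g", "Pr(>F)"], tolerance = 1e-10)
})

test_that("rows with a missing covariate are dropped with a message", {
  d <- data.frame(g = rep(c("a", "b"), each = 6), y = rnorm(12),
                  z = c(NA, rnorm(11)))
  expect_message(ac <- ancova(d, "y", "g", "z"), "dropping 1")
  expect_equal(ac$n_dropped, 1)
})

test_that("tidy and glance expose the comparison in broom shapes", {
  d <- data.frame(g = rep(c("a", "b", "c"), each = 5), y = rnorm(15))
  an <- oneway_anova(d, "y", "g")
  td <- tidy(an)
  expect_equal(td$term, c("group", "residuals"))
  expect_equal(td$sumsq[1] / sum(td$sumsq), an$eta_squared)
  gl <- glance(an)
  expect_equal(gl$nobs, 15)
  expect_equal(gl$statistic, an$f)
})
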