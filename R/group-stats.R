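#' Within-group outlier screening
#'
#' Removes, in a single pass, observations further than `k_sd` group SDs
#' from their own group mean.  Zero-variance groups never lose members.
#' Screening is applied per variable and only where an analysis plan asks
#' for it, mirroring selective use in practice.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the outcome and the
#'   grouping factor.
#' @param k_sd Cut-off in group SDs (default 3).
#' @param id Optional column naming observations; removed ids are reported.
#' @return A list: `data` (kept rows), `removed` (dropped rows),
#'   `removed_ids` (character vector, possibly empty).
#' @examples
#' d <- data.frame(g = rep("a", 10), y = c(rep(1, 9), 100))
#' remove_outliers(d, "y", "g")$removed
#' @export
remove_outliers <- function(data, value, group, k_sd = 3, id = NULL) {
  y <- data[[value]]
  g <- data[[group]]
  mu <- stats::ave(y, g, FUN = mean)
  sdev <- stats::ave(y, g, FUN = sd)
  out <- !is.na(y) & sdev > 0 & abs(y - mu) > k_sd * sdev
  removed_ids <- if (!is.null(id)) as.character(data[[id]][out]) else
    character(0)
  list(data = data[!out, , drop = FALSE],
       removed = data[out, , drop = FALSE],
       removed_ids = removed_ids)
}

#' One-way between-subjects ANOVA
#'
#' Classical fixed-effects ANOVA of `value` on a grouping factor with k
#' levels, reporting F with (k-1, N-k) degrees of freedom, the p value and
#' eta squared (`SS_between / SS_total`).  With a single between-subjects
#' factor, type-I and type-III sums of squares coincide.
#'
#' @param data A data frame.
#' @param value,group Column names (strings).
#' @return A `vs_anova` object; use [tidy()], [glance()], [autoplot()] or
#'   [tukey_posthoc()] on it.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                 y = c(rnorm(5), rnorm(5, 1), rnorm(5, 2)))
#' glance(oneway_anova(d, "y", "g"))
#' @export
oneway_anova <- function(data, value, group) {
  d <- data.frame(y = data[[value]], g = factor(data[[group]]))
  d <- d[complete.cases(d), ]
  counts <- table(d$g)
  if (any(counts < 2)) {
    abort(paste0("group(s) with fewer than 2 observations: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  fit <- aov(y ~ g, data = d)
  ss <- summary(fit)[[1]]
  ss_b <- ss["g", "Sum Sq"]
  ss_w <- ss["Residuals", "Sum Sq"]
  groups <- tibble(g = factor(levels(d$g), levels = levels(d$g)),
                   n = as.integer(counts),
                   mean = as.numeric(tapply(d$y, d$g, mean)),
                   sd = as.numeric(tapply(d$y, d$g, sd)))
  structure(list(
    variable = value,
    f = ss["g", "F value"],
    df = c(between = ss["g", "Df"], error = ss["Residuals", "Df"]),
    p = ss["g", "Pr(>F)"],
    eta_squared = ss_b / (ss_b + ss_w),
    ss = c(between = ss_b, within = ss_w, total = ss_b + ss_w),
    ms_error = ss["Residuals", "Mean Sq"],
    groups = groups,
    fit = fit, data = d), class = "vs_anova")
}

#' @export
print.vs_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on '%s': F(%d, %d) = %.2f, p = %.4g, ",
              x$variable, x$df[1], x$df[2], x$f, x$p))
  cat(sprintf("eta^2 = %.3f\n", x$eta_squared))
  invisible(x)
}

#' Tukey post hoc comparisons with effect sizes
#'
#' All pairwise group contrasts of a fitted [oneway_anova()].  The t
#' statistic uses the pooled error mean square with the ANOVA error df;
#' the adjusted p value comes from the studentized-range distribution
#' (Tukey's HSD); Cohen's d uses the pooled SD of the two groups involved.
#' Post hoc rows are reported for every pair regardless of the omnibus
#' result, leaving the decision rule to the analyst.
#'
#' @param comparison A `vs_anova` object.
#' @return A tibble, one row per pair: `group1`, `group2`, `diff`, `t`,
#'   `df`, `p_adj`, `cohens_d`.
#' @export
tukey_posthoc <- function(comparison) {
  stopifnot(inherits(comparison, "vs_anova"))
  g <- comparison$groups
  k <- nrow(g)
  df_err <- comparison$df[["error"]]
  mse <- comparison$ms_error
  combs <- utils::combn(k, 2)
  map_dfr(seq_len(ncol(combs)), function(c_idx) {
    a <- combs[1, c_idx]; b <- combs[2, c_idx]
    diff <- g$mean[a] - g$mean[b]
    se <- sqrt(mse * (1 / g$n[a] + 1 / g$n[b]))
    tval <- diff / se
    p_adj <- ptukey(sqrt(2) * abs(tval), nmeans = k, df = df_err,
                    lower.tail = FALSE)
    sp <- sqrt(((g$n[a] - 1) * g$sd[a]^2 + (g$n[b] - 1) * g$sd[b]^2) /
                 (g$n[a] + g$n[b] - 2))
    tibble(group1 = as.character(g$g[a]), group2 = as.character(g$g[b]),
           diff = diff, t = tval, df = df_err, p_adj = p_adj,
           cohens_d = if (sp > 0) diff / sp else 0)
  })
}

#' One-way ANCOVA with a single covariate
#'
#' Adjusts the group effect for a covariate (typically IQ) under the
#' homogeneity-of-slopes assumption: the group F compares
#' `value ~ covariate` against `value ~ covariate + group`.  Rows with a
#' missing covariate are dropped with a message.
#'
#' @param data A data frame.
#' @param value,group,covariate Column names (strings).
#' @return A `vs_ancova` object: `f`, `df`, `p` for the adjusted group
#'   effect, `n_dropped`, plus the unadjusted [oneway_anova()] for
#'   reference.
#' @export
ancova <- function(data, value, group, covariate) {
  d <- data.frame(y = data[[value]], g = factor(data[[group]]),
                  z = data[[covariate]])
  n_dropped <- sum(!complete.cases(d))
  if (n_dropped > 0) {
    inform(paste0("dropping ", n_dropped,
                  " row(s) with missing covariate or outcome"))
  }
  d <- d[complete.cases(d), ]
  m0 <- lm(y ~ z, data = d)
  m1 <- lm(y ~ z + g, data = d)
  cmp <- anova(m0, m1)
  structure(list(
    variable = value, covariate = covariate,
    f = cmp$F[2],
    df = c(between = cmp$Df[2], error = cmp$Res.Df[2]),
    p = cmp$`Pr(>F)`[2],
    n_dropped = n_dropped,
    unadjusted = oneway_anova(d, "y", "g"),
    fit = m1), class = "vs_ancova")
}

#' @export
print.vs_ancova <- function(x, ...) {
  cat(sprintf(
    "ANCOVA on '%s' (covariate '%s'): F(%d, %d) = %.2f, p = %.4g\n",
    x$variable, x$covariate, x$df[1], x$df[2], x$f, x$p))
  invisible(x)
}

#' Group-comparison layer over participant summaries
#'
#' Runs, per variable: optional within-group outlier screening (3-SD rule,
#' only for variables listed in `outlier_rule`), a one-way ANOVA over
#' groups, and Tukey post hoc contrasts.  Where outliers were removed the
#' error df shrinks accordingly; both the nominal df (all participants)
#' and the effective df (after removal) are reported.
#'
#' @param summaries Participant summaries ([summarize_participants()]
#'   shape) with a `group` column; `excluded` participants are dropped.
#' @param variables Character vector of summary columns to analyse.
#' @param outlier_rule Character vector of variables to screen with the
#'   `k_sd` rule (default none), or a named numeric vector of per-variable
#'   cut-offs.
#' @param k_sd Default outlier cut-off in group SDs.
#' @return A list of class `vs_group_stats`: `comparisons` (one row per
#'   variable: F, df, p, eta squared, outliers removed) and `posthoc`
#'   (one row per variable and pair).
#' @export
group_stats <- function(summaries, variables,
                        outlier_rule = character(0), k_sd = 3) {
  if ("excluded" %in% names(summaries)) {
    summaries <- filter(summaries, !.data$excluded)
  }
  if (is.numeric(outlier_rule)) {
    cuts <- outlier_rule
  } else {
    cuts <- setNames(rep(k_sd, length(outlier_rule)), outlier_rule)
  }
  comp_rows <- list(); ph_rows <- list()
  for (v in variables) {
    d <- summaries[!is.na(summaries[[v]]), ]
    removed <- character(0)
    if (v %in% names(cuts)) {
      scr <- remove_outliers(d, v, "group", k_sd = cuts[[v]],
                             id = intersect("participant_id", names(d))[1])
      removed <- scr$removed_ids
      d <- scr$data
    }
    an <- oneway_anova(d, v, "group")
    ph <- tukey_posthoc(an)
    n_nominal <- sum(!is.na(summaries[[v]]))
    comp_rows[[v]] <- tibble(
      variable = v, f = an$f, df_between = an$df[["between"]],
      df_error = an$df[["error"]],
      df_error_nominal = n_nominal - nrow(an$groups),
      p = an$p, eta_squared = an$eta_squared,
      n_outliers_removed = length(removed),
      outliers_removed = paste(removed, collapse = ";"))
    ph_rows[[v]] <- mutate(ph, variable = v, .before = 1)
  }
  structure(list(comparisons = list_rbind(comp_rows),
                 posthoc = list_rbind(ph_rows)),
            class = "vs_group_stats")
}

#' @export
print.vs_group_stats <- function(x, ...) {
  cat("Group comparisons:\n")
  print(x$comparisons)
  invisible(x)
}
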