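#' Tidy a one-way ANOVA
#'
#' @param x A `vs_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per term (`group`, `residuals`).
#' @export
tidy.vs_anova <- function(x, ...) {
  tibble(term = c("group", "residuals"),
         df = c(x$df[["between"]], x$df[["error"]]),
         sumsq = c(x$ss[["between"]], x$ss[["within"]]),
         meansq = c(x$ss[["between"]] / x$df[["between"]], x$ms_error),
         statistic = c(x$f, NA),
         p.value = c(x$p, NA))
}

#' Glance at a one-way ANOVA
#'
#' @param x A `vs_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `df.residual`, `p.value`,
#'   `eta.squared`, `nobs`.
#' @export
glance.vs_anova <- function(x, ...) {
  tibble(statistic = x$f, df = x$df[["between"]],
         df.residual = x$df[["error"]], p.value = x$p,
         eta.squared = x$eta_squared, nobs = nrow(x$data))
}

#' Tidy an ANCOVA
#'
#' @param x A `vs_ancova` object.
#' @param ... Unused.
#' @return A one-row tibble for the covariate-adjusted group effect.
#' @export
tidy.vs_ancova <- function(x, ...) {
  tibble(term = "group (adjusted)", df = x$df[["between"]],
         df.residual = x$df[["error"]], statistic = x$f, p.value = x$p)
}

#' Glance at an ANCOVA
#'
#' @param x A `vs_ancova` object.
#' @param ... Unused.
#' @return A one-row tibble: adjusted and unadjusted group F and p.
#' @export
glance.vs_ancova <- function(x, ...) {
  tibble(statistic = x$f, df = x$df[["between"]],
         df.residual = x$df[["error"]], p.value = x$p,
         statistic.unadjusted = x$unadjusted$f,
         p.value.unadjusted = x$unadjusted$p,
         n.dropped = x$n_dropped)
}
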