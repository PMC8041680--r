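#' Detect fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Classic I-DT: a candidate window of consecutive samples is grown while
#' its spatial dispersion stays at or below `max_dispersion`; once the
#' window spans at least `min_duration` and can no longer grow, it is
#' emitted as a fixation with the centroid of its member samples.  All
#' other samples are saccade/unclassified.  Dispersion is
#' `(max(x) - min(x)) + (max(y) - min(y))` by default (the
#' Salvucci-Goldberg convention); `dispersion_metric = "max"` uses the
#' larger of the two ranges instead.
#'
#' Track-loss handling: invalid samples are removed, and the stream is
#' split wherever the resulting time gap exceeds `gap_bridge` ms; shorter
#' gaps are bridged.  The default 75 ms sits above the 60 ms minimum
#' fixation duration, so two sub-threshold stretches can never be merged
#' into a spuriously valid fixation across a long loss.
#'
#' @param samples Tibble `t, x, y` and optionally `valid` (ms, px).
#' @param screen A [screen_geometry()]; supplies the pixels-per-degree
#'   conversion.
#' @param min_duration Minimum fixation duration, ms (default 60).
#' @param max_dispersion Dispersion threshold in degrees (default 2).
#' @param dispersion_metric `"sum"` (x-range + y-range) or `"max"`.
#' @param gap_bridge Maximum bridged gap across invalid/missing samples, ms.
#' @param sampling_rate Hz; when `NULL`, taken from the `sampling_rate`
#'   attribute of `samples` or inferred from the median sample interval.
#' @return A fixation tibble `start, end, x, y, duration, n_samples`
#'   (times in ms on the input clock; `end` is the last member sample plus
#'   one sample interval).
#' @examples
#' scr <- screen_geometry()
#' s <- tibble::tibble(t = seq(0, 495, by = 1000 / 120) * 1,
#'                     x = 500, y = 400, valid = TRUE)
#' detect_fixations(s, scr)
#' @export
detect_fixations <- function(samples, screen = screen_geometry(),
                             min_duration = 60, max_dispersion = 2,
                             dispersion_metric = c("sum", "max"),
                             gap_bridge = 75, sampling_rate = NULL) {
  dispersion_metric <- match.arg(dispersion_metric)
  stopifnot(min_duration > 0, max_dispersion > 0)
  if (!inherits(screen, "vs_screen")) {
    abort("`screen` must be a screen_geometry(); pixels-per-degree unknown")
  }
  empty <- tibble(start = numeric(), end = numeric(), x = numeric(),
                  y = numeric(), duration = numeric(),
                  n_samples = integer())
  if (nrow(samples) == 0) return(empty)
  sampling_rate <- sampling_rate %||% attr(samples, "sampling_rate")
  valid <- if ("valid" %in% names(samples)) samples$valid else
    rep(TRUE, nrow(samples))
  valid <- valid & !is.na(samples$x) & !is.na(samples$y)
  s <- samples[valid, c("t", "x", "y")]
  if (nrow(s) < 2) return(empty)
  dt <- if (!is.null(sampling_rate)) 1000 / sampling_rate else
    stats::median(diff(s$t))
  thresh_px <- max_dispersion * screen$px_per_degree

  chunk <- cumsum(c(0, diff(s$t) > gap_bridge))
  out <- vector("list", 64); n_out <- 0
  for (ck in unique(chunk)) {
    sel <- chunk == ck
    res <- idt_chunk(s$t[sel], s$x[sel], s$y[sel], dt, min_duration,
                     thresh_px, dispersion_metric)
    if (!is.null(res)) { n_out <- n_out + 1; out[[n_out]] <- res }
  }
  if (n_out == 0) return(empty)
  fx <- as_tibble(do.call(rbind, out[seq_len(n_out)]))
  fx$duration <- fx$end - fx$start
  fx$n_samples <- as.integer(fx$n_samples)
  fx[, c("start", "end", "x", "y", "duration", "n_samples")]
}

# I-DT over one gap-free chunk; returns a data.frame or NULL
idt_chunk <- function(t, x, y, dt, min_duration, thresh_px, metric) {
  n <- length(t)
  res <- list(); m <- 0
  i <- 1
  while (i <= n) {
    # smallest window [i, j] spanning min_duration
    j <- i
    while (j <= n && t[j] + dt - t[i] < min_duration) j <- j + 1
    if (j > n) break
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    disp <- if (metric == "sum") (xmax - xmin) + (ymax - ymin) else
      max(xmax - xmin, ymax - ymin)
    if (disp > thresh_px) { i <- i + 1; next }
    while (j < n) {
      nxmin <- min(xmin, x[j + 1]); nxmax <- max(xmax, x[j + 1])
      nymin <- min(ymin, y[j + 1]); nymax <- max(ymax, y[j + 1])
      ndisp <- if (metric == "sum") (nxmax - nxmin) + (nymax - nymin) else
        max(nxmax - nxmin, nymax - nymin)
      if (ndisp > thresh_px) break
      j <- j + 1
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
    }
    m <- m + 1
    res[[m]] <- c(start = t[i], end = t[j] + dt,
                  x = mean(x[i:j]), y = mean(y[i:j]),
                  n_samples = j - i + 1)
    i <- j + 1
  }
  if (m == 0) return(NULL)
  as.data.frame(do.call(rbind, res))
}
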