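# Independent brute-force oracles, deliberately written with plain loops so
# they share no code with the implementation under test.

# points lying in TRUE-runs of length >= L (loop-based, no rle)
count_run_points <- function(v, L) {
  pts <- 0L; run <- 0L
  for (b in v) {
    if (isTRUE(b)) run <- run + 1L
    else { if (run >= L) pts <- pts + run; run <- 0L }
  }
  if (run >= L) pts <- pts + run
  pts
}

# full-matrix line-scan RQA
rqa_brute <- function(labels, min_line = 2, exclude = "outside") {
  n <- length(labels)
  if (n < 2) {
    return(list(n = n, r = NA_integer_, recurrence = NA_real_,
                determinism = NA_real_, laminarity = NA_real_,
                corm = NA_real_))
  }
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- i != j && labels[i] == labels[j] &&
        !(labels[i] %in% exclude)
    }
  }
  r <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) r <- r + m[i, j]
  rec <- 100 * 2 * r / (n * (n - 1))
  if (r == 0) {
    return(list(n = n, r = 0L, recurrence = 0, determinism = NA_real_,
                laminarity = NA_real_, corm = NA_real_))
  }
  diag_pts <- 0L
  for (d in c(-(n - 1):-1, 1:(n - 1))) {
    ii <- if (d > 0) 1:(n - d) else (1 - d):n
    v <- logical(length(ii))
    for (k in seq_along(ii)) v[k] <- m[ii[k], ii[k] + d]
    diag_pts <- diag_pts + count_run_points(v, min_line)
  }
  row_pts <- 0L; col_pts <- 0L
  for (i in seq_len(n)) row_pts <- row_pts + count_run_points(m[i, ], min_line)
  for (j in seq_len(n)) col_pts <- col_pts + count_run_points(m[, j], min_line)
  corm_num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) if (m[i, j]) corm_num <- corm_num + (j - i)
  }
  list(n = n, r = r, recurrence = rec,
       determinism = 100 * diag_pts / (2 * r),
       laminarity = 100 * (row_pts + col_pts) / (2 * (2 * r)),
       corm = 100 * corm_num / ((n - 1) * r))
}

# exhaustive enumeration of monotone alignment paths (right/down/diagonal)
align_brute_cost <- function(M) {
  n <- nrow(M); m <- ncol(M)
  best <- Inf
  rec <- function(i, j, cost) {
    cost <- cost + M[i, j]
    if (cost > best) return(invisible())
    if (i == n && j == m) { best <<- min(best, cost); return(invisible()) }
    if (i < n && j < m) rec(i + 1, j + 1, cost)
    if (i < n) rec(i + 1, j, cost)
    if (j < m) rec(i, j + 1, cost)
    invisible()
  }
  rec(1, 1, 0)
  best
}

# unbiasing constant: E[sample SD] = sigma * c4(n) for normal data
c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

random_scanpath <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(x = runif(n, 0, 1920), y = runif(n, 0, 1080),
                 duration = runif(n, 80, 600))
}
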