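# Statistical layer: exact/approximate paired Wilcoxon signed-rank tests,
# running pointwise tests with Benjamini-Hochberg FDR control, and
# sleep-architecture summaries.

# null distribution of W over all 2^n sign assignments for rank vector r
enumerate_w <- function(r) {
  n <- length(r)
  m <- 2^n
  w <- numeric(m)
  idx <- 0:(m - 1)
  for (j in seq_len(n))
    w <- w + r[j] * (bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0)
  w
}

# cache of untied-rank null distributions and two-sided p lookup tables,
# keyed by n (W is integer-valued when ranks are untied)
.w_cache <- new.env(parent = emptyenv())
untied_w_distribution <- function(n) {
  key <- as.character(n)
  if (is.null(.w_cache[[key]]))
    .w_cache[[key]] <- enumerate_w(as.numeric(seq_len(n)))
  .w_cache[[key]]
}
untied_p_table <- function(n) {
  key <- paste0("p", n)
  if (is.null(.w_cache[[key]])) {
    wd <- untied_w_distribution(n)
    wmax <- n * (n + 1) / 2
    cdf <- cumsum(tabulate(wd + 1L, nbins = wmax + 1L)) / length(wd)
    lower <- cdf
    upper <- 1 - c(0, cdf[-length(cdf)])
    .w_cache[[key]] <- pmin(1, 2 * pmin(lower, upper))
  }
  .w_cache[[key]]
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks. For n (after zero removal) up to `exact_max_n` the two-sided
#' p-value is exact, computed by enumerating all `2^n` sign assignments;
#' beyond that a normal approximation with tie correction is used. If every
#' difference is zero the test is degenerate and p = 1.
#'
#' @param x,y paired samples of equal length.
#' @param exact_max_n largest n for exact enumeration (default 15,
#'   i.e. at most 32768 sign patterns).
#' @return list with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided), `n` (pairs after zero removal), `method` and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 15) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    if (anyDuplicated(abs(d))) {
      wd <- enumerate_w(r)
      p <- min(1, 2 * min(mean(wd <= W), mean(wd >= W)))
    } else {
      p <- untied_p_table(n)[round(W) + 1L]
    }
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the p-values ascending and rejects all hypotheses up to the
#' largest `i` with `p(i) <= i * q / m`; adjusted p-values are the step-up
#' minima `min_{j >= i} m * p(j) / j`, capped at 1, returned in the input
#' order. Rejections are monotone in `q`, and the FDR mask is always a
#' subset of the raw `p < q` mask.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q target false discovery rate.
#' @return list with `adjusted` p-values and logical `reject` mask.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj_sorted <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  k <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

#' Running paired Wilcoxon tests along a time grid
#'
#' At every time point, a paired Wilcoxon signed-rank test across subjects
#' compares the two condition stacks; both the uncorrected `p < alpha` mask
#' and the Benjamini-Hochberg mask at FDR `q` are returned, mirroring the
#' dual display (uncorrected and FDR-corrected) customary for
#' stimulus-locked traces. The correction family is the time grid of one
#' comparison (one channel).
#'
#' @param traces_a,traces_b matrices (subjects x time points) in identical
#'   subject order on the same grid.
#' @param time_s optional time grid (defaults to the column index).
#' @param alpha raw significance level.
#' @param q false discovery rate for the corrected mask.
#' @return object of class `running_test_result`: list with `time_s`,
#'   `p_raw`, `significant_raw`, `significant_fdr`, `n_pairs`.
#' @export
running_wilcoxon <- function(traces_a, traces_b, time_s = NULL,
                             alpha = 0.05, q = 0.05) {
  if (!all(dim(traces_a) == dim(traces_b)))
    stop("condition stacks must share subject order and time grid")
  n_sub <- nrow(traces_a)
  if (n_sub < 5) stop("need at least 5 subjects")
  n_t <- ncol(traces_a)
  if (is.null(time_s)) time_s <- seq_len(n_t)
  if (length(time_s) != n_t) stop("time grid does not match the traces")
  p_raw <- vapply(seq_len(n_t), function(j)
    wilcoxon_signed_rank(traces_a[, j], traces_b[, j])$p_value, numeric(1))
  bh <- benjamini_hochberg(p_raw, q)
  structure(list(time_s = time_s, p_raw = p_raw,
                 significant_raw = p_raw < alpha,
                 significant_fdr = bh$reject,
                 n_pairs = n_sub),
            class = "running_test_result")
}

#' @export
print.running_test_result <- function(x, ...) {
  cat(sprintf(
    "<running_test_result> %d time points, n = %d pairs: %d raw-significant, %d FDR-significant\n",
    length(x$time_s), x$n_pairs, sum(x$significant_raw),
    sum(x$significant_fdr)))
  invisible(x)
}

#' Sleep-architecture metrics from a hypnogram
#'
#' Total sleep time (minutes in N1+N2+N3+REM), wake after sleep onset
#' (wake minutes after the first sleep epoch), sleep efficiency
#' (TST as a percentage of time in bed), per-stage minutes and percentage
#' of TST, REM minutes in the first versus second half of time in bed
#' (split at the midpoint), and per-hour stage percentages.
#'
#' @param hyp a [hypnogram()].
#' @return object of class `sleep_architecture` (a named list).
#' @export
sleep_architecture <- function(hyp) {
  if (!length(hyp$stages)) stop("empty hypnogram")
  el_min <- hyp$epoch_length_s / 60
  st <- hyp$stages
  n <- length(st)
  sleep_stages <- c("N1", "N2", "N3", "REM")
  tib_min <- n * el_min
  onset <- which(st %in% sleep_stages)[1]
  tst_min <- sum(st %in% sleep_stages) * el_min
  waso_min <- if (is.na(onset)) 0 else sum(st[onset:n] == "Wake") * el_min
  eff <- 100 * tst_min / tib_min
  stage_min <- vapply(sleep_stages, function(s) sum(st == s) * el_min,
                      numeric(1))
  stage_pct <- if (tst_min > 0) 100 * stage_min / tst_min else
    stats::setNames(rep(NA_real_, length(sleep_stages)), sleep_stages)
  half <- n / 2
  rem_first <- sum(st[seq_len(floor(half))] == "REM") * el_min
  rem_second <- sum(st == "REM") * el_min - rem_first
  hour_of <- ceiling(seq_len(n) * el_min / 60)
  per_hour <- do.call(rbind, lapply(unique(hour_of), function(h) {
    sel <- st[hour_of == h]
    row <- vapply(c("Wake", sleep_stages),
                  function(s) 100 * mean(sel == s), numeric(1))
    data.frame(hour = h, t(row))
  }))
  structure(list(
    TST_min = tst_min,
    WASO_min = waso_min,
    sleep_efficiency_pct = eff,
    time_in_bed_min = tib_min,
    stage_min = stage_min,
    stage_pct_of_TST = stage_pct,
    REM_first_half_min = rem_first,
    REM_second_half_min = rem_second,
    stage_pct_per_hour = per_hour),
    class = "sleep_architecture")
}

#' @export
print.sleep_architecture <- function(x, ...) {
  cat(sprintf("<sleep_architecture> TIB %.1f min, TST %.1f min, WASO %.1f min, efficiency %.1f%%\n",
              x$time_in_bed_min, x$TST_min, x$WASO_min,
              x$sleep_efficiency_pct))
  cat("  stage minutes:",
      paste(sprintf("%s %.1f", names(x$stage_min), x$stage_min),
            collapse = ", "), "\n")
  cat(sprintf("  REM first/second half: %.1f / %.1f min\n",
              x$REM_first_half_min, x$REM_second_half_min))
  invisible(x)
}
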