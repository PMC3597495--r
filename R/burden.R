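# Case-control CNV size-burden analysis: exact 2x2 machinery, the size-
# threshold scan that picks the cut-off maximizing case-control separation,
# and the pooled-quintile analysis of per-bin CNV fractions.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of all tables (with
#' the observed margins) no more probable than the observed one; the odds
#' ratio is the sample cross-product ratio `a*d / (b*c)` (`Inf` when
#' `b*c == 0` and the numerator is positive).
#'
#' @param a,b,c,d non-negative counts, or `a` may be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) .stopf("cells must be non-negative integers")
  if (sum(cells) == 0) .stopf("all-zero table: odds ratio and p undefined")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- probs[a - lo + 1L]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Size-threshold scan of CNV burden
#'
#' For each threshold t, counts calls with size > t vs <= t in cases and
#' controls, computes the odds ratio and two-sided Fisher p, and selects the
#' threshold with minimal p (ties broken toward the smaller threshold). The
#' counting unit is the CNV call; `unit = "sample"` instead counts samples
#' carrying at least one call above t.
#'
#' @param case_calls,control_calls call tables.
#' @param thresholds_kb numeric vector of thresholds; default a log-spaced
#'   grid of 200 points on 50-1000 kb.
#' @param unit count calls (default) or samples.
#' @param alpha familywise level used to flag the selected threshold
#'   (Bonferroni over the grid).
#' @return list with `scan` (data.frame `threshold_kb`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`), `selected_kb`, `selected_p`, `significant`.
#' @export
threshold_scan <- function(case_calls, control_calls,
                           thresholds_kb = exp(seq(log(50), log(1000), length.out = 200L)),
                           unit = c("call", "sample"), alpha = 0.05) {
  unit <- match.arg(unit)
  if (length(thresholds_kb) == 0L) .stopf("empty threshold grid")
  if (nrow(case_calls) == 0L || nrow(control_calls) == 0L)
    .stopf("both groups must contain calls")
  count_above <- function(calls, t) {
    if (unit == "call") sum(calls$size_kb > t)
    else length(unique(calls$sample_id[calls$size_kb > t]))
  }
  n_case <- if (unit == "call") nrow(case_calls) else length(unique(case_calls$sample_id))
  n_ctrl <- if (unit == "call") nrow(control_calls) else length(unique(control_calls$sample_id))
  rows <- lapply(thresholds_kb, function(t) {
    a <- count_above(case_calls, t); cc <- count_above(control_calls, t)
    ft <- fisher_exact_2x2(a, n_case - a, cc, n_ctrl - cc)
    data.frame(threshold_kb = t, a = a, b = n_case - a, c = cc, d = n_ctrl - cc,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  scan <- do.call(rbind, rows)
  best <- which(scan$p_value == min(scan$p_value))[1L]  # grid sorted: first = smallest t
  list(scan = scan,
       selected_kb = scan$threshold_kb[best],
       selected_p = scan$p_value[best],
       significant = scan$p_value[best] < alpha / length(thresholds_kb))
}

#' Pooled-quintile CNV size analysis
#'
#' Quintile borders are the 20/40/60/80/100th percentiles of the pooled
#' (case + control) size distribution, computed by linear interpolation
#' between order statistics (type 7). Per-bin fractions are computed within
#' each group and each bin is tested with a Fisher exact test of in-bin vs
#' out-of-bin call counts.
#'
#' @param case_calls,control_calls call tables.
#' @param probs percentile borders (default quintiles).
#' @return list with `borders_kb` and `bins` (data.frame `bin`, `border_kb`,
#'   `case_fraction`, `control_fraction`, `p_value`).
#' @export
quintile_analysis <- function(case_calls, control_calls, probs = seq(0.2, 1, 0.2)) {
  pooled <- c(case_calls$size_kb, control_calls$size_kb)
  if (length(pooled) < 5L) .stopf("need at least 5 pooled sizes")
  borders <- unname(stats::quantile(pooled, probs, type = 7))
  bin_of <- function(x) findInterval(x, borders, left.open = TRUE) + 1L
  # values above the top border (none under type 7) would overflow; clamp
  case_bin <- pmin(bin_of(case_calls$size_kb), length(borders))
  ctrl_bin <- pmin(bin_of(control_calls$size_kb), length(borders))
  n_case <- nrow(case_calls); n_ctrl <- nrow(control_calls)
  rows <- lapply(seq_along(borders), function(i) {
    a <- sum(case_bin == i); cc <- sum(ctrl_bin == i)
    ft <- fisher_exact_2x2(a, n_case - a, cc, n_ctrl - cc)
    data.frame(bin = i, border_kb = borders[i],
               case_fraction = a / n_case, control_fraction = cc / n_ctrl,
               p_value = ft$p_value)
  })
  list(borders_kb = borders, bins = do.call(rbind, rows))
}
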