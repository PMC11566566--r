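# Size-binned case-control frequency comparison: two-proportion tests and
# odds ratios with Woolf confidence intervals.
#
# Two p-value dialects coexist on purpose, matching the summary-file
# convention this reproduces: the two-proportion P.value column carries the
# Yates-corrected chi-square p, while the P column attached to the odds
# ratio carries the uncorrected Pearson chi-square p.

#' Size bin edges
#'
#' Default edges 50, 100, 200, 500, 1000 kb with an unbounded top bin
#' (labelled up to 1,000,000 kb). Bins are lower-inclusive, upper-exclusive;
#' the lowest edge must equal the global size-filter minimum so every
#' filtered call lands in a bin.
#'
#' @param edges_kb strictly increasing numeric vector of bin edges in kb;
#'   the last value closes the top bin's label.
#' @return list(edges_kb, labels).
#' @export
size_bins <- function(edges_kb = c(50, 100, 200, 500, 1000, 1e6)) {
  if (length(edges_kb) < 2L || any(diff(edges_kb) <= 0)) {
    stopf("size_bins: edges must be strictly increasing with >= 2 values")
  }
  k <- length(edges_kb) - 1L
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  labels <- sprintf("%sKB_%sKB", fmt(edges_kb[-(k + 1L)]), fmt(edges_kb[-1L]))
  list(edges_kb = edges_kb, labels = labels)
}

#' Assign calls to size bins
#'
#' @param calls CNV call data.frame that already passed the size filter.
#' @param bins bins from [size_bins()].
#' @return the calls with a `bin_label` column.
#' @export
bin_by_size <- function(calls, bins = size_bins()) {
  len_kb <- calls$length / 1000
  if (any(len_kb < bins$edges_kb[1])) {
    stopf("bin_by_size: %d call(s) below the lowest edge; size filter contract violated",
          sum(len_kb < bins$edges_kb[1]))
  }
  idx <- findInterval(len_kb, bins$edges_kb[-length(bins$edges_kb)])
  calls$bin_label <- bins$labels[idx]
  calls
}

#' Two-proportion test (Yates-corrected chi-square)
#'
#' Two-sided test of a/n1 = b/n2 via the 2x2 chi-square with continuity
#' correction, with the correction clamped so the statistic never goes
#' negative (equal proportions give p = 1). This is the dialect of
#' `prop.test()` with default settings.
#'
#' @param a,b successes in the two groups.
#' @param n1,n2 group sizes.
#' @return two-sided p-value.
#' @export
two_proportion_test <- function(a, n1, b, n2) {
  a <- as.numeric(a); n1 <- as.numeric(n1); b <- as.numeric(b); n2 <- as.numeric(n2)
  if (n1 <= 0 || n2 <= 0) stopf("two_proportion_test: group sizes must be positive")
  cells <- c(a, n1 - a, b, n2 - b)
  if (any(cells < 0)) stopf("two_proportion_test: negative cell count")
  N <- n1 + n2
  cross <- abs(a * (n2 - b) - b * (n1 - a))
  num <- max(0, cross - N / 2)^2 * N
  den <- n1 * n2 * (a + b) * (N - a - b)
  if (den == 0) stopf("two_proportion_test: degenerate margins")
  stats::pchisq(num / den, df = 1, lower.tail = FALSE)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = a(n2-b) / (b(n1-a)); the CI is exp(log OR +/- z * sqrt(sum of
#' reciprocal cells)) with z the two-sided normal quantile (Woolf's
#' method). The associated p-value is the uncorrected Pearson chi-square on
#' the 2x2. When any cell is zero, the Haldane-Anscombe continuity
#' correction (0.5 added to all four cells) is applied to the OR and CI only
#' — never to counts or frequencies — and flagged in the result.
#'
#' @param a,b successes in the two groups.
#' @param n1,n2 group sizes.
#' @param conf_level confidence level (default 0.95).
#' @return list(or, ci_low, ci_high, p, continuity_corrected).
#' @export
odds_ratio_woolf <- function(a, n1, b, n2, conf_level = 0.95) {
  a <- as.numeric(a); n1 <- as.numeric(n1); b <- as.numeric(b); n2 <- as.numeric(n2)
  cells <- c(a, n1 - a, b, n2 - b)
  if (any(cells < 0)) stopf("odds_ratio_woolf: negative cell count")
  if ((a == n1 && b == n2) || (a == 0 && b == 0)) {
    stopf("odds_ratio_woolf: degenerate margins, odds ratio undefined")
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[3] * cc[2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cc))
  N <- n1 + n2
  chi <- (a * (n2 - b) - b * (n1 - a))^2 * N / (n1 * n2 * (a + b) * (N - a - b))
  list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    continuity_corrected = corrected
  )
}

#' Size-binned association summary (the Tables 2/3 shape)
#'
#' One ALL row per cnv_type plus one row per (cnv_type, bin). `a` and `b`
#' count rare CNVs of that type/bin in cases and controls; frequencies
#' divide the counts by the case/control cohort sizes (counts, not carriers
#' — a sample with two qualifying CNVs contributes two). Empty bins are
#' emitted with zero counts and NA statistics.
#'
#' @param rare_calls rare calls (post rare-extraction).
#' @param cohort post-filter cohort (reference controls excluded).
#' @param bins bins from [size_bins()].
#' @return data.frame with columns cnv_type, bin_label, a, b, n1, n2,
#'   case_freq, control_freq, p_two_prop, or_estimate, ci_low, ci_high, p_or.
#' @export
association_summary <- function(rare_calls, cohort, bins = size_bins()) {
  n1 <- sum(cohort$phenotype == "case")
  n2 <- sum(cohort$phenotype == "control")
  if (n1 == 0L || n2 == 0L) stopf("association_summary: both phenotype groups must be non-empty")
  binned <- bin_by_size(rare_calls, bins)
  is_case_call <- binned$sample_id %in% cohort$sample_id[cohort$phenotype == "case"]
  rows <- list()
  for (tp in c("DEL", "DUP")) {
    sub <- binned$cnv_type == tp
    for (lab in c("ALL", bins$labels)) {
      mask <- sub & (lab == "ALL" | binned$bin_label == lab)
      a <- sum(mask & is_case_call)
      b <- sum(mask & !is_case_call)
      p2 <- or <- cil <- cih <- por <- NA_real_
      if (a > n1 || b > n2) {
        # CNV counts exceed the cohort size: the binomial reading of the
        # 2x2 breaks down, statistics are reported as undefined
        warnf("association_summary: counts exceed cohort size in %s/%s; statistics undefined", tp, lab)
      } else if (a + b > 0) {
        p2 <- two_proportion_test(a, n1, b, n2)
        orr <- odds_ratio_woolf(a, n1, b, n2)
        or <- orr$or; cil <- orr$ci_low; cih <- orr$ci_high; por <- orr$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cnv_type = tp, bin_label = lab, a = a, b = b, n1 = n1, n2 = n2,
        case_freq = a / n1, control_freq = b / n2,
        p_two_prop = p2, or_estimate = or, ci_low = cil, ci_high = cih, p_or = por,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Format an association summary like the printed summary files
#'
#' Column order CNV/Length, Cases, Controls, Cases_freq, Controls_freq,
#' P.value, OR, X95.CI, P with 4-decimal rounding, ready for diffing.
#'
#' @param summary output of [association_summary()].
#' @return data.frame of formatted character columns.
#' @export
format_association_summary <- function(summary) {
  data.frame(
    CNV = ifelse(summary$bin_label == "ALL", paste0(summary$cnv_type, "s"),
                 summary$bin_label),
    Type = summary$cnv_type,
    Cases = summary$a, Controls = summary$b,
    Cases_freq = sprintf("%.4f", summary$case_freq),
    Controls_freq = sprintf("%.4f", summary$control_freq),
    P.value = sprintf("%.4f", summary$p_two_prop),
    OR = sprintf("%.4f", summary$or_estimate),
    X95.CI = sprintf("%.4f,%.4f", summary$ci_low, summary$ci_high),
    P = sprintf("%.4f", summary$p_or),
    stringsAsFactors = FALSE
  )
}
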