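# Global case-control CNV burden over four per-sample metrics.

#' Per-sample burden metrics
#'
#' RATE = number of segments, PROP = indicator of carrying any segment,
#' TOTKB = total kb spanned (bp / 1000, exact), AVGKB = mean segment size in
#' kb, NA for zero-CNV samples. Every cohort sample gets a record, so
#' zero-CNV samples enter the denominators.
#'
#' @param calls CNV call data.frame.
#' @param cohort cohort table.
#' @return data.frame(sample_id, rate, prop, totkb, avgkb).
#' @export
per_sample_metrics <- function(calls, cohort) {
  lv <- factor(calls$sample_id, levels = cohort$sample_id)
  rate <- as.integer(table(lv))
  totkb <- as.numeric(tapply(calls$length / 1000, lv, sum, default = 0))
  totkb[is.na(totkb)] <- 0
  data.frame(
    sample_id = cohort$sample_id,
    rate = rate,
    prop = as.integer(rate > 0L),
    totkb = totkb,
    avgkb = ifelse(rate > 0L, totkb / rate, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Permutation burden test
#'
#' For each metric the statistic is the case mean minus the control mean
#' (AVGKB averaged over CNV-carrying samples only). Phenotype labels are
#' permuted jointly across the four metrics; the empirical p-value uses the
#' add-one estimator (1 + exceedances) / (n_perm + 1), so p is never zero
#' and lies in [1/(n_perm+1), 1].
#'
#' @param metrics output of [per_sample_metrics()].
#' @param cohort cohort table aligned with `metrics`.
#' @param n_perm number of null permutations (default 10,000).
#' @param seed RNG seed for the permutations.
#' @param alternative "case_greater" (one-sided, the default, following the
#'   usual CNV-burden convention) or "two_sided" on |statistic|.
#' @return data.frame(metric, case_mean, control_mean, statistic,
#'   empirical_p, testable).
#' @export
burden_test <- function(metrics, cohort, n_perm = 10000L, seed = 1L,
                        alternative = c("case_greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(identical(metrics$sample_id, cohort$sample_id))
  is_case <- cohort$phenotype == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 == 0L || n2 == 0L) stopf("burden_test: both phenotype groups must be non-empty")
  carrier <- metrics$rate > 0L
  # columns: rate, prop, totkb, avgkb numerator (0 for non-carriers), carrier flag
  X <- cbind(
    metrics$rate, metrics$prop, metrics$totkb,
    ifelse(carrier, metrics$avgkb, 0), as.numeric(carrier)
  )
  n <- nrow(X)
  group_stats <- function(case_mask) {
    s_case <- colSums(X[case_mask, , drop = FALSE])
    s_all <- colSums(X)
    s_ctrl <- s_all - s_case
    nc1 <- sum(case_mask)
    nc2 <- n - nc1
    case_mean <- c(s_case[1:3] / nc1, if (s_case[5] > 0) s_case[4] / s_case[5] else NA_real_)
    ctrl_mean <- c(s_ctrl[1:3] / nc2, if (s_ctrl[5] > 0) s_ctrl[4] / s_ctrl[5] else NA_real_)
    list(case = case_mean, ctrl = ctrl_mean, stat = case_mean - ctrl_mean)
  }
  obs <- group_stats(is_case)
  testable <- !is.na(obs$stat)
  set.seed(seed)
  perm_stats <- matrix(NA_real_, nrow = n_perm, ncol = 4L)
  for (p in seq_len(n_perm)) {
    mask <- logical(n)
    mask[sample.int(n, n1)] <- TRUE
    perm_stats[p, ] <- group_stats(mask)$stat
  }
  emp_p <- vapply(1:4, function(j) {
    if (!testable[j]) return(NA_real_)
    ps <- perm_stats[, j]
    ok <- !is.na(ps)
    if (alternative == "case_greater") {
      exceed <- sum(ps[ok] >= obs$stat[j])
    } else {
      exceed <- sum(abs(ps[ok]) >= abs(obs$stat[j]))
    }
    (1 + exceed) / (sum(ok) + 1)
  }, 0)
  data.frame(
    metric = c("RATE", "PROP", "TOTKB", "AVGKB"),
    case_mean = obs$case, control_mean = obs$ctrl, statistic = obs$stat,
    empirical_p = emp_p, testable = testable,
    stringsAsFactors = FALSE
  )
}
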