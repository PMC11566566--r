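# Per-sample quality control using PennCNV-style signal metrics.
#
# Boundary semantics differ deliberately between the two rule families:
# signal metrics (LRR_SD, BAF_drift, |WF|, and any optional bounds) use a
# strict "<" pass rule, while NumCNV fails only when strictly greater than
# the limit, so a sample sitting exactly at the call-count limit passes.

#' Quality-control thresholds
#'
#' Defaults are the study defaults for Illumina SNP-array data:
#' LRR_SD < 0.3, BAF_drift < 0.01, |WF| < 0.05, NumCNV <= 50. The NumCNV
#' limit has no universal default in PennCNV; 50 is study-specific and meant
#' to be overridden after inspecting the per-cohort distribution. Optional
#' upper bounds on further metrics (lrr_mean, lrr_median, baf_mean,
#' baf_median, baf_sd, as absolute values) can be supplied via `extra`.
#'
#' @param lrr_sd_max strict upper bound on the LRR standard deviation.
#' @param baf_drift_max strict upper bound on BAF drift.
#' @param wf_abs_max strict upper bound on |waviness factor|.
#' @param num_cnv_max samples with more calls than this fail.
#' @param extra named list of strict absolute bounds on optional metrics,
#'   e.g. `list(baf_sd = 0.1)`.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(lrr_sd_max = 0.3, baf_drift_max = 0.01, wf_abs_max = 0.05,
                          num_cnv_max = 50L, extra = list()) {
  th <- list(
    lrr_sd_max = lrr_sd_max, baf_drift_max = baf_drift_max,
    wf_abs_max = wf_abs_max, num_cnv_max = num_cnv_max, extra = extra
  )
  bounds <- c(lrr_sd_max, baf_drift_max, wf_abs_max, num_cnv_max, unlist(extra))
  if (any(!is.finite(bounds)) || any(bounds <= 0)) stopf("qc_thresholds: bounds must be positive")
  th
}

#' Apply sample-level quality control
#'
#' A sample passes iff every active criterion holds; every violated criterion
#' is listed by name. Decisions are per sample and independent of input
#' order.
#'
#' @param records QC-summary data.frame from [read_qc_summary()].
#' @param thresholds thresholds from [qc_thresholds()].
#' @return data.frame(sample_id, passed, failed_criteria) where
#'   failed_criteria is a comma-joined string ("" when passed).
#' @export
apply_sample_qc <- function(records, thresholds = qc_thresholds()) {
  if (nrow(records) == 0L) stopf("apply_sample_qc: no QC records")
  need <- function(col, crit) {
    v <- records[[col]]
    if (is.null(v) || any(is.na(v))) {
      stopf("apply_sample_qc: metric '%s' needed by criterion %s is absent for some samples", col, crit)
    }
    v
  }
  fails <- list(
    LRR_SD = !(need("lrr_sd", "LRR_SD") < thresholds$lrr_sd_max),
    BAF_drift = !(need("baf_drift", "BAF_drift") < thresholds$baf_drift_max),
    WF = !(abs(need("wf", "WF")) < thresholds$wf_abs_max),
    NumCNV = need("num_cnv", "NumCNV") > thresholds$num_cnv_max
  )
  for (nm in names(thresholds$extra)) {
    crit <- toupper(nm)
    fails[[crit]] <- !(abs(need(nm, crit)) < thresholds$extra[[nm]])
  }
  failmat <- do.call(cbind, fails)
  failed <- apply(failmat, 1L, function(row) paste(colnames(failmat)[row], collapse = ","))
  data.frame(
    sample_id = records$sample_id,
    passed = !apply(failmat, 1L, any),
    failed_criteria = failed,
    stringsAsFactors = FALSE
  )
}

#' Summarize QC metrics split by pass/fail
#'
#' Produces the numbers behind the usual QC box plots: per-metric five-number
#' summaries for passing and failing samples, plus sample/call loss counts.
#'
#' @param records QC-summary data.frame.
#' @param decisions output of [apply_sample_qc()] on the same records.
#' @param calls optional call table; when given, the number of calls removed
#'   with failing samples is reported.
#' @return list(metrics = data.frame of five-number summaries,
#'   counts = data.frame(initial_samples, final_samples, lost_samples,
#'   initial_calls, final_calls, lost_calls)).
#' @export
qc_summary_table <- function(records, decisions, calls = NULL) {
  stopifnot(identical(records$sample_id, decisions$sample_id))
  metrics <- c("lrr_mean", "lrr_median", "lrr_sd", "baf_mean", "baf_median",
               "baf_sd", "baf_drift", "wf", "num_cnv")
  rows <- list()
  for (m in metrics) {
    v <- records[[m]]
    if (all(is.na(v))) next
    for (grp in c(TRUE, FALSE)) {
      vv <- v[decisions$passed == grp]
      vv <- vv[!is.na(vv)]
      if (length(vv) == 0L) next
      q <- stats::quantile(vv, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = if (grp) "pass" else "fail", n = length(vv),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE
      )
    }
  }
  lost_ids <- decisions$sample_id[!decisions$passed]
  counts <- data.frame(
    initial_samples = nrow(records),
    final_samples = sum(decisions$passed),
    lost_samples = length(lost_ids),
    initial_calls = if (is.null(calls)) NA_integer_ else nrow(calls),
    final_calls = if (is.null(calls)) NA_integer_ else sum(!(calls$sample_id %in% lost_ids)),
    lost_calls = if (is.null(calls)) NA_integer_ else sum(calls$sample_id %in% lost_ids)
  )
  list(metrics = do.call(rbind, rows), counts = counts)
}

#' Drop calls belonging to QC-failing samples
#' @param calls CNV call data.frame.
#' @param decisions output of [apply_sample_qc()].
#' @return the calls of passing samples.
#' @export
drop_failed_sample_calls <- function(calls, decisions) {
  pass <- decisions$sample_id[decisions$passed]
  calls[calls$sample_id %in% pass, , drop = FALSE]
}
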