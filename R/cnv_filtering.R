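# Core-sample retention and size/probe filtering ahead of association work.

#' Restrict the analysis to core samples
#'
#' Core samples (unrelated, genetically unstratified individuals identified
#' upstream via PCA/MDS and IBD) are supplied as an id list. The returned
#' cohort contains exactly the core samples — including zero-CNV samples,
#' which are needed for correct frequency denominators — and the calls are
#' restricted accordingly.
#'
#' @param calls CNV call data.frame.
#' @param cohort cohort table.
#' @param core_ids character vector of core sample ids.
#' @return list(calls, cohort); the cohort's `is_core` flag is set.
#' @export
retain_core_samples <- function(calls, cohort, core_ids) {
  unknown <- setdiff(core_ids, cohort$sample_id)
  if (length(unknown) > 0L) {
    warnf("retain_core_samples: %d core id(s) not in cohort: %s",
          length(unknown), paste(unknown, collapse = ", "))
  }
  keep <- cohort$sample_id %in% core_ids
  if (!any(keep)) stopf("retain_core_samples: no cohort sample is in the core list")
  cohort2 <- cohort[keep, , drop = FALSE]
  cohort2$is_core <- TRUE
  rownames(cohort2) <- NULL
  list(
    calls = calls[calls$sample_id %in% cohort2$sample_id, , drop = FALSE],
    cohort = cohort2
  )
}

#' Filter calls by size and probe support
#'
#' Keeps calls strictly larger than `min_length_bp` and covered by strictly
#' more than `min_probes` probes ("larger than 50 kb, more than 5 probes");
#' boundary cases are removed, which matters when reconciling counts against
#' non-strict implementations.
#'
#' @param calls CNV call data.frame.
#' @param min_length_bp minimum length in bp, exclusive (default 50,000).
#' @param min_probes minimum probe count, exclusive (default 5).
#' @return list(kept, removed) partitioning the input.
#' @export
filter_by_size_probes <- function(calls, min_length_bp = 50000, min_probes = 5L) {
  if (min_length_bp <= 0) stopf("filter_by_size_probes: min_length_bp must be positive")
  if (min_probes < 0) stopf("filter_by_size_probes: min_probes must be >= 0")
  keep <- calls$length > min_length_bp & calls$num_snps > min_probes
  list(kept = calls[keep, , drop = FALSE], removed = calls[!keep, , drop = FALSE])
}
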