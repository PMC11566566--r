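# Common/rare partitioning by overlap-based frequency in a reference
# control subset.
#
# Two overlap metrics coexist deliberately. Discovery of common CNVs uses
# the symmetric union-intersection fraction |A n B| / |A u B| (the PLINK
# frequency-counting semantics); removal of common variants from the
# analysis cohort uses the asymmetric query fraction (share of the call's
# own length covered, the BEDTools -f semantics).

#' Rare-extraction configuration
#'
#' @param overlap_threshold union-intersection fraction at or above which two
#'   CNVs count as overlapping during discovery (default 0.5).
#' @param common_min_count overlap count (including self) at or above which a
#'   reference CNV is classified common; the default 4 in a 200-sample
#'   reference corresponds to a 2% carrier frequency.
#' @param reference_size number of controls to draw (seeded) as the
#'   reference subset when no explicit id list is given (default 200).
#' @param reference_ids optional explicit reference control ids.
#' @param query_overlap_threshold fraction of a call's own length that a
#'   common CNV must cover for the call to be removed (default 0.5).
#' @return list configuration.
#' @export
rare_config <- function(overlap_threshold = 0.5, common_min_count = 4L,
                        reference_size = 200L, reference_ids = NULL,
                        query_overlap_threshold = 0.5) {
  if (overlap_threshold <= 0 || overlap_threshold > 1) stopf("rare_config: overlap_threshold in (0,1]")
  if (query_overlap_threshold <= 0 || query_overlap_threshold > 1) {
    stopf("rare_config: query_overlap_threshold in (0,1]")
  }
  list(
    overlap_threshold = overlap_threshold, common_min_count = as.integer(common_min_count),
    reference_size = as.integer(reference_size), reference_ids = reference_ids,
    query_overlap_threshold = query_overlap_threshold
  )
}

#' Union-intersection overlap fraction of two intervals
#'
#' |a n b| / |a u b| with closed-interval bp lengths; 0 across chromosomes,
#' symmetric, 1 iff identical.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric vector of fractions in [0, 1].
#' @export
union_overlap_fraction <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b) + 1)
  uni <- (end_a - start_a + 1) + (end_b - start_b + 1) - inter
  out <- inter / uni
  out[normalize_chrom(chrom_a) != normalize_chrom(chrom_b)] <- 0
  out
}

#' Overlap counts within a call set
#'
#' For each call, the number of calls in the set (including itself) whose
#' union-intersection overlap with it is at least `threshold`. All calls must
#' be of one cnv_type; deletions and duplications are counted separately by
#' the callers.
#'
#' @param calls CNV call data.frame of a single cnv_type.
#' @param threshold union-intersection threshold (default 0.5).
#' @return integer vector of counts aligned with `calls` rows; always >= 1.
#' @export
overlap_counts <- function(calls, threshold = 0.5) {
  if (nrow(calls) == 0L) return(integer(0))
  if (length(unique(calls$cnv_type)) > 1L) {
    stopf("overlap_counts: calls must be of a single cnv_type")
  }
  hits <- overlap_hits(calls, calls) # includes self-hits
  frac <- hits$inter_bp /
    (calls$length[hits$qi] + calls$length[hits$si] - hits$inter_bp)
  good <- hits$qi[frac >= threshold]
  counts <- integer(nrow(calls))
  tab <- table(good)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Select the reference control subset
#'
#' Prefers an explicit id list; otherwise draws a seeded uniform sample of
#' `reference_size` controls. The returned cohort has
#' `is_reference_control` set on the chosen samples.
#'
#' @param cohort cohort table.
#' @param config configuration from [rare_config()].
#' @param seed RNG seed used when sampling.
#' @return cohort table with the reference flag set.
#' @export
select_reference_controls <- function(cohort, config = rare_config(), seed = 1L) {
  controls <- cohort$sample_id[cohort$phenotype == "control"]
  if (!is.null(config$reference_ids)) {
    bad <- setdiff(config$reference_ids, controls)
    if (length(bad) > 0L) {
      stopf("select_reference_controls: not control samples: %s", paste(bad, collapse = ", "))
    }
    ref <- config$reference_ids
  } else {
    if (config$reference_size > length(controls)) {
      stopf("select_reference_controls: reference_size %d exceeds control pool %d",
            config$reference_size, length(controls))
    }
    set.seed(seed)
    ref <- sample(controls, config$reference_size)
  }
  cohort$is_reference_control <- cohort$sample_id %in% ref
  cohort
}

#' Identify common CNVs in the reference subset
#'
#' Counts union-intersection overlaps within each cnv_type separately
#' (cross-type overlap never makes a variant common) and classifies calls
#' with count >= `common_min_count` as common.
#'
#' @param reference_calls calls belonging to the reference controls.
#' @param config configuration from [rare_config()].
#' @return list(common = common calls with a `count` column,
#'   counts = all reference calls with their counts).
#' @export
identify_common <- function(reference_calls, config = rare_config()) {
  counts <- integer(nrow(reference_calls))
  for (tp in unique(reference_calls$cnv_type)) {
    idx <- which(reference_calls$cnv_type == tp)
    counts[idx] <- overlap_counts(reference_calls[idx, , drop = FALSE], config$overlap_threshold)
  }
  with_counts <- reference_calls
  with_counts$count <- counts
  list(
    common = with_counts[counts >= config$common_min_count, , drop = FALSE],
    counts = with_counts
  )
}

#' Remove common variants and the reference controls from the cohort
#'
#' The reference controls leave the cohort (they informed the common set and
#' would bias the tests). A call of the remaining samples is removed iff some
#' common CNV of the same cnv_type covers at least `query_overlap_threshold`
#' of the call's own length — per-pair coverage by default (BEDTools -f
#' semantics); set `union_mode` for coverage by the union of common CNVs.
#'
#' @param calls CNV call data.frame of the analysis cohort.
#' @param common_set common CNVs from [identify_common()].
#' @param cohort cohort table with the reference flag set.
#' @param config configuration from [rare_config()].
#' @param union_mode use union coverage instead of per-pair coverage.
#' @return list(rare_calls, removed, cohort) where cohort excludes reference
#'   controls and rare_calls/removed partition the calls of that cohort.
#' @export
filter_rare <- function(calls, common_set, cohort, config = rare_config(),
                        union_mode = FALSE) {
  cohort2 <- cohort[!cohort$is_reference_control, , drop = FALSE]
  rownames(cohort2) <- NULL
  calls2 <- calls[calls$sample_id %in% cohort2$sample_id, , drop = FALSE]
  rownames(calls2) <- NULL
  if (nrow(common_set) == 0L || nrow(calls2) == 0L) {
    return(list(rare_calls = calls2, removed = calls2[integer(0), , drop = FALSE], cohort = cohort2))
  }
  removed_mask <- logical(nrow(calls2))
  for (tp in unique(calls2$cnv_type)) {
    ci <- which(calls2$cnv_type == tp)
    com <- common_set[common_set$cnv_type == tp, , drop = FALSE]
    if (nrow(com) == 0L) next
    if (union_mode) {
      cov <- union_coverage_bp(calls2[ci, , drop = FALSE], com)
      removed_mask[ci] <- cov / calls2$length[ci] >= config$query_overlap_threshold
    } else {
      hits <- overlap_hits(calls2[ci, , drop = FALSE], com)
      frac <- hits$inter_bp / calls2$length[ci][hits$qi]
      removed_mask[ci[unique(hits$qi[frac >= config$query_overlap_threshold])]] <- TRUE
    }
  }
  list(
    rare_calls = calls2[!removed_mask, , drop = FALSE],
    removed = calls2[removed_mask, , drop = FALSE],
    cohort = cohort2
  )
}

#' Carrier-frequency table for the rare set
#'
#' For each rare call, its union-intersection overlap count within the
#' post-filter call set (within cnv_type) divided by the post-filter cohort
#' size. Feeds the frequency histogram used to check that everything kept is
#' below the common threshold.
#'
#' @param rare_calls rare calls from [filter_rare()].
#' @param cohort post-filter cohort (reference controls excluded).
#' @param threshold union-intersection threshold (default 0.5).
#' @return rare calls with `count` and `carrier_freq` columns.
#' @export
carrier_frequency_table <- function(rare_calls, cohort, threshold = 0.5) {
  out <- rare_calls
  out$count <- integer(nrow(out))
  for (tp in unique(out$cnv_type)) {
    idx <- which(out$cnv_type == tp)
    out$count[idx] <- overlap_counts(out[idx, , drop = FALSE], threshold)
  }
  out$carrier_freq <- out$count / nrow(cohort)
  out
}
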