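# Fixture builders and independent brute-force oracles. The oracles stay in
# base R and never share code with the implementation paths they check.

make_calls <- function(chrom, start, end, cn = 1L, sample_id = NULL, num_snps = 10L,
                       conf = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(n))
  cnv_calls(sample_id = sample_id, chrom = chrom, start = start, end = end,
            cn = cn, num_snps = num_snps, conf = conf)
}

# O(n^2) all-pairs union-intersection overlap counting.
bf_overlap_counts <- function(calls, threshold = 0.5) {
  n <- nrow(calls)
  counts <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (calls$chrom[i] != calls$chrom[j]) next
      inter <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j]) + 1
      if (inter <= 0) next
      uni <- (calls$end[i] - calls$start[i] + 1) + (calls$end[j] - calls$start[j] + 1) - inter
      if (inter / uni >= threshold) cnt <- cnt + 1L
    }
    counts[i] <- cnt
  }
  counts
}

random_interval_calls <- function(n, n_chrom = 3L, max_pos = 1e6, cn = 1L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(5e4, n, replace = TRUE)
  make_calls(
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + len, cn = cn,
    sample_id = sprintf("S%04d", seq_len(n))
  )
}

# Exhaustive merge oracle: applies every possible order of pairwise merges
# (same sample/chrom/state, gap/span <= f) to a fixpoint and returns the set
# of distinct outcomes (as canonical strings).
bf_merge_all_orders <- function(calls, f) {
  canon <- function(df) {
    df <- df[order(df$sample_id, df$chrom, df$start, df$end), , drop = FALSE]
    paste(df$sample_id, df$chrom, df$start, df$end, df$cn, df$num_snps, collapse = ";")
  }
  explore <- function(df) {
    n <- nrow(df)
    pairs <- list()
    if (n >= 2L) {
      df <- df[order(df$sample_id, df$chrom, df$cn, df$start, df$end), , drop = FALSE]
      for (i in seq_len(n - 1L)) {
        j <- i + 1L
        if (df$sample_id[i] != df$sample_id[j] || df$chrom[i] != df$chrom[j] ||
            df$cn[i] != df$cn[j]) next
        gap <- df$start[j] - df$end[i] - 1
        span <- max(df$end[j], df$end[i]) - df$start[i] + 1
        if (gap / span <= f) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
    if (length(pairs) == 0L) return(canon(df))
    out <- character(0)
    for (p in pairs) {
      merged <- df
      merged$end[p[1]] <- max(merged$end[p[1]], merged$end[p[2]])
      merged$num_snps[p[1]] <- merged$num_snps[p[1]] + merged$num_snps[p[2]]
      merged <- merged[-p[2], , drop = FALSE]
      merged$length <- merged$end - merged$start + 1
      out <- c(out, explore(merged))
    }
    unique(out)
  }
  explore(calls)
}

# Base-pair coverage set per sample/chrom, for the no-base-lost invariant.
covered_bp <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(calls)), function(i) {
    paste(calls$sample_id[i], calls$chrom[i], seq(calls$start[i], calls$end[i]))
  }))
}

tiny_cohort <- function(n_case = 3L, n_ctrl = 3L) {
  cohort_table(
    sample_id = c(sprintf("CA%02d", seq_len(n_case)), sprintf("CO%02d", seq_len(n_ctrl))),
    phenotype = c(rep("case", n_case), rep("control", n_ctrl))
  )
}

qc_record <- function(sample_id = "S001", lrr_sd = 0.1, baf_drift = 0.001, wf = 0.01,
                      num_cnv = 5L, ...) {
  base <- data.frame(
    sample_id = sample_id, lrr_mean = NA_real_, lrr_median = NA_real_, lrr_sd = lrr_sd,
    baf_mean = NA_real_, baf_median = NA_real_, baf_sd = NA_real_,
    baf_drift = baf_drift, wf = wf, num_cnv = as.integer(num_cnv),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}
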