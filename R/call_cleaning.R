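# Region-based call removal and merging of artificially split adjacent calls.

#' Merge configuration
#'
#' Adjacent same-sample calls are merged when the gap between them is small
#' relative to the merged span: gap / span <= fraction, with
#' gap = next.start - prev.end - 1 and span over the merged extent. The
#' fractions are applied as sequential passes (default 0.5 then 0.4), each
#' iterated to a fixpoint, following the PennCNV clean_cnv "combineseg"
#' semantics.
#'
#' @param fractions ordered numeric vector of gap fractions in (0, 1).
#' @param require_same_state merge only calls with identical copy number.
#' @return list configuration.
#' @export
merge_config <- function(fractions = c(0.5, 0.4), require_same_state = TRUE) {
  if (length(fractions) == 0L || any(fractions <= 0 | fractions >= 1)) {
    stopf("merge_config: fractions must be a non-empty vector in (0,1)")
  }
  list(fractions = fractions, require_same_state = isTRUE(require_same_state))
}

#' Remove calls intersecting spurious genomic regions
#'
#' Default mode removes a call on any overlap (>= 1 bp) with any region —
#' the blunt rule used for HLA/centromere/telomere cleaning. In
#' `query_fraction` mode a call is removed only when the union of regions
#' covers at least `min_overlap_fraction` of the call's own length.
#'
#' @param calls CNV call data.frame (coordinates normalized).
#' @param regions data.frame(chrom, start, end, label) in internal 1-based
#'   inclusive coordinates (see [read_bed_regions()]).
#' @param min_overlap_fraction threshold used in `query_fraction` mode.
#' @param mode "any_overlap" or "query_fraction".
#' @return list(kept, removed); `removed` carries a `region_label` column
#'   with the label of the first overlapping region. kept and removed
#'   partition the input.
#' @export
exclude_regions <- function(calls, regions, min_overlap_fraction = 0.5,
                            mode = c("any_overlap", "query_fraction")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0L || nrow(regions) == 0L) {
    removed <- calls[integer(0), , drop = FALSE]
    removed$region_label <- character(0)
    return(list(kept = calls, removed = removed))
  }
  hits <- overlap_hits(calls, regions)
  if (mode == "any_overlap") {
    rm_idx <- sort(unique(hits$qi))
  } else {
    cov <- union_coverage_bp(calls, regions)
    rm_idx <- which(cov / calls$length >= min_overlap_fraction)
  }
  first_label <- rep(NA_character_, nrow(calls))
  if (nrow(hits) > 0L) {
    hits <- hits[order(hits$qi, hits$si), , drop = FALSE]
    fst <- hits[!duplicated(hits$qi), , drop = FALSE]
    first_label[fst$qi] <- regions$label[fst$si]
  }
  removed <- calls[rm_idx, , drop = FALSE]
  removed$region_label <- first_label[rm_idx]
  list(kept = calls[setdiff(seq_len(nrow(calls)), rm_idx), , drop = FALSE], removed = removed)
}

#' Merge adjacent CNV calls
#'
#' For each gap fraction in order, repeatedly merges consecutive calls of the
#' same sample and chromosome (and same copy number unless
#' `require_same_state` is off) whose gap-to-span ratio is at or below the
#' fraction, until a fixpoint. The merged call spans both parents
#' (start = min, end covering both), num_snps is the sum and conf the larger
#' parent confidence. The number of calls never increases and no covered
#' base pair is lost.
#'
#' @param calls CNV call data.frame.
#' @param config configuration from [merge_config()].
#' @return merged call data.frame.
#' @export
merge_adjacent <- function(calls, config = merge_config()) {
  if (nrow(calls) < 2L) return(calls)
  key_cols <- if (config$require_same_state) c("sample_id", "chrom", "cn") else c("sample_id", "chrom")
  ord <- do.call(order, c(unname(calls[key_cols]), list(calls$start, calls$end)))
  if (!identical(ord, seq_len(nrow(calls)))) {
    message("merge_adjacent: input not sorted; sorting internally")
    calls <- calls[ord, , drop = FALSE]
  }
  rownames(calls) <- NULL
  for (f in config$fractions) {
    repeat {
      n <- nrow(calls)
      if (n < 2L) break
      prev <- seq_len(n - 1L)
      nxt <- prev + 1L
      same <- calls$sample_id[prev] == calls$sample_id[nxt] &
        calls$chrom[prev] == calls$chrom[nxt]
      if (config$require_same_state) same <- same & calls$cn[prev] == calls$cn[nxt]
      gap <- calls$start[nxt] - calls$end[prev] - 1
      span <- pmax(calls$end[nxt], calls$end[prev]) - calls$start[prev] + 1
      cand <- which(same & gap / span <= f)
      if (length(cand) == 0L) break
      # resolve chains left-first: a row may take part in one merge per sweep
      sel <- integer(0)
      last <- -1L
      for (i in cand) {
        if (i > last + 1L || length(sel) == 0L) {
          sel <- c(sel, i)
          last <- i
        } else if (i == last + 1L) {
          next # row `i` is the right partner of the previous merge
        }
      }
      drop <- sel + 1L
      calls$end[sel] <- pmax(calls$end[sel], calls$end[drop])
      calls$num_snps[sel] <- calls$num_snps[sel] + calls$num_snps[drop]
      calls$conf[sel] <- pmax(calls$conf[sel], calls$conf[drop], na.rm = TRUE)
      calls$conf[sel][is.infinite(calls$conf[sel])] <- NA_real_
      calls <- calls[-drop, , drop = FALSE]
      calls$length <- calls$end - calls$start + 1
      rownames(calls) <- NULL
    }
  }
  calls
}
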