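# End-to-end pipeline runner with cascade reporting.
#
# Stage order: qc -> clean -> merge -> filter (core + size) -> burden ->
# rare -> assoc -> enrich. Each stage logs sample/call counts; the cascade
# report chains so that every row's initial counts equal the previous row's
# final counts. Merging is reported with lost_calls = combined count — calls
# are combined, not lost, which the report footnotes.

#' Pipeline configuration
#'
#' File-based inputs; every analysis default equals the shipped module
#' default. `stages` may be truncated to stop the run early.
#'
#' @param rawcnv,qcsum,fam paths to the call file, QC summary and FAM file.
#' @param region_files named character vector of BED exclusion files
#'   (names are used as stage labels); may be empty.
#' @param gene_map,gene_set paths for the enrichment stage (BED4 and one id
#'   per line); required only when "enrich" is among the stages.
#' @param core_ids path to the core-sample id list; NULL keeps all samples.
#' @param qc thresholds from [qc_thresholds()].
#' @param merge configuration from [merge_config()].
#' @param min_length_bp,min_probes size filter bounds (exclusive).
#' @param rare configuration from [rare_config()].
#' @param bins bins from [size_bins()].
#' @param n_perm permutations for burden and enrichment.
#' @param seed seed for reference sampling and permutations.
#' @param stages ordered subset of the stage names to run.
#' @return configuration list.
#' @export
pipeline_config <- function(rawcnv, qcsum, fam, region_files = character(0),
                            gene_map = NULL, gene_set = NULL, core_ids = NULL,
                            qc = qc_thresholds(), merge = merge_config(),
                            min_length_bp = 50000, min_probes = 5L,
                            rare = rare_config(), bins = size_bins(),
                            n_perm = 10000L, seed = 1L,
                            stages = c("qc", "clean", "merge", "filter", "burden",
                                       "rare", "assoc", "enrich")) {
  list(
    rawcnv = rawcnv, qcsum = qcsum, fam = fam, region_files = region_files,
    gene_map = gene_map, gene_set = gene_set, core_ids = core_ids,
    qc = qc, merge = merge, min_length_bp = min_length_bp, min_probes = min_probes,
    rare = rare, bins = bins, n_perm = as.integer(n_perm), seed = as.integer(seed),
    stages = stages
  )
}

#' Run the pipeline
#'
#' Fails fast: every input file named by the configuration is checked before
#' any stage runs. Outputs (summary TSVs, cleaned calls, cascade report and
#' a log of applied thresholds) are written under `out_dir` when given;
#' everything is also returned in memory. Reruns with the same configuration
#' and seed produce byte-identical outputs.
#'
#' @param config configuration from [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list(results, cascade, log) where `results` holds each stage's
#'   tables and `cascade` is the chained count report.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  inputs <- c(config$rawcnv, config$qcsum, config$fam, config$region_files,
              config$gene_map, config$gene_set, config$core_ids)
  missing <- inputs[!vapply(inputs, file.exists, TRUE)]
  if (length(missing) > 0L) {
    stopf("run_pipeline: missing input file(s): %s", paste(missing, collapse = ", "))
  }
  if ("enrich" %in% config$stages && (is.null(config$gene_map) || is.null(config$gene_set))) {
    stopf("run_pipeline: the enrich stage needs gene_map and gene_set")
  }
  log <- c(
    sprintf("thresholds: LRR_SD<%g BAF_drift<%g |WF|<%g NumCNV<=%d", config$qc$lrr_sd_max,
            config$qc$baf_drift_max, config$qc$wf_abs_max, config$qc$num_cnv_max),
    sprintf("merge fractions: %s", paste(config$merge$fractions, collapse = ",")),
    sprintf("size filter: length>%d bp, probes>%d", config$min_length_bp, config$min_probes),
    sprintf("rare: overlap>=%g, common count>=%d, reference=%s, removal fraction>=%g",
            config$rare$overlap_threshold, config$rare$common_min_count,
            if (is.null(config$rare$reference_ids)) sprintf("%d sampled (seed %d)",
              config$rare$reference_size, config$seed) else "explicit list",
            config$rare$query_overlap_threshold),
    sprintf("permutations: %d (seed %d)", config$n_perm, config$seed),
    "note: no multiple-testing adjustment is applied; p-values are raw"
  )

  calls <- read_rawcnv(config$rawcnv)
  qc_rec <- read_qc_summary(config$qcsum, calls = calls)
  cohort <- read_fam(config$fam)
  all_sample_ids <- cohort$sample_id
  results <- list()
  cascade <- list()
  n_samples <- nrow(cohort)
  n_calls <- nrow(calls)
  add_row <- function(stage, samples_after, calls_after, note = "") {
    cascade[[length(cascade) + 1L]] <<- data.frame(
      stage = stage,
      initial_samples = n_samples, final_samples = samples_after,
      lost_samples = n_samples - samples_after,
      initial_calls = n_calls, final_calls = calls_after,
      lost_calls = n_calls - calls_after,
      note = note, stringsAsFactors = FALSE
    )
    n_samples <<- samples_after
    n_calls <<- calls_after
  }
  add_row("input", n_samples, n_calls)

  for (stage in config$stages) {
    if (stage == "qc") {
      decisions <- apply_sample_qc(qc_rec, config$qc)
      results$qc_decisions <- decisions
      results$qc_summary <- qc_summary_table(qc_rec, decisions, calls)
      calls <- drop_failed_sample_calls(calls, decisions)
      cohort <- cohort[cohort$sample_id %in% decisions$sample_id[decisions$passed], , drop = FALSE]
      add_row("sample_qc", nrow(cohort), nrow(calls))
    } else if (stage == "clean") {
      removal_log <- list()
      for (lbl in names(config$region_files)) {
        regions <- read_bed_regions(config$region_files[[lbl]], default_label = lbl)
        ex <- exclude_regions(calls, regions)
        calls <- ex$kept
        removal_log[[lbl]] <- ex$removed
        add_row(paste0("clean_", lbl), nrow(cohort), nrow(calls))
      }
      results$removal_log <- if (length(removal_log)) do.call(rbind, removal_log) else NULL
    } else if (stage == "merge") {
      calls <- merge_adjacent(calls, config$merge)
      add_row("merge", nrow(cohort), nrow(calls), note = "calls combined, not lost")
    } else if (stage == "filter") {
      if (!is.null(config$core_ids)) {
        # ids dropped earlier (sample QC) are not "unknown"; only warn about
        # ids never seen in the cohort file
        core_ids <- intersect(read_id_list(config$core_ids), all_sample_ids)
        core <- retain_core_samples(calls, cohort, core_ids)
        calls <- core$calls
        cohort <- core$cohort
        add_row("core_samples", nrow(cohort), nrow(calls))
      }
      fs <- filter_by_size_probes(calls, config$min_length_bp, config$min_probes)
      calls <- fs$kept
      add_row("size_probe_filter", nrow(cohort), nrow(calls))
    } else if (stage == "burden") {
      metrics <- per_sample_metrics(calls, cohort)
      results$burden <- burden_test(metrics, cohort, n_perm = config$n_perm, seed = config$seed)
    } else if (stage == "rare") {
      cohort <- select_reference_controls(cohort, config$rare, seed = config$seed)
      ref_calls <- calls[calls$sample_id %in%
                           cohort$sample_id[cohort$is_reference_control], , drop = FALSE]
      common <- identify_common(ref_calls, config$rare)
      results$common_cnvs <- common$common
      fr <- filter_rare(calls, common$common, cohort, config$rare)
      calls <- fr$rare_calls
      cohort <- fr$cohort
      results$carrier_freq <- carrier_frequency_table(calls, cohort, config$rare$overlap_threshold)
      add_row("rare_extraction", nrow(cohort), nrow(calls))
    } else if (stage == "assoc") {
      results$association <- association_summary(calls, cohort, config$bins)
      results$association_formatted <- format_association_summary(results$association)
    } else if (stage == "enrich") {
      gm <- read_gene_map(config$gene_map)
      gs <- read_gene_set(config$gene_set, gm)
      covars <- compute_covariates(calls, cohort, gm, gs)
      results$enrichment <- enrichment_tests(covars, cohort, n_perm = config$n_perm,
                                             seed = config$seed)
    } else {
      stopf("run_pipeline: unknown stage '%s'", stage)
    }
  }
  results$calls <- calls
  results$cohort <- cohort
  cascade <- do.call(rbind, cascade)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    wt(results$qc_decisions, "qc_decisions.tsv")
    wt(results$qc_summary$metrics, "qc_metric_summaries.tsv")
    wt(results$burden, "burden_summary.tsv")
    wt(results$common_cnvs, "common_cnvs.tsv")
    wt(results$carrier_freq, "carrier_frequency.tsv")
    wt(results$association_formatted, "association_summary.tsv")
    wt(results$association, "forest_plot_data.tsv")
    wt(results$enrichment, "enrichment_summary.tsv")
    wt(cascade, "cascade_report.tsv")
    write_rawcnv(calls, file.path(out_dir, "final_calls.rawcnv"))
    write_plink_cnv(calls, cohort, file.path(out_dir, "final"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(results = results, cascade = cascade, log = log)
}

#' Check the cascade chaining invariant
#'
#' final = initial - lost per row, and each row's initial counts equal the
#' previous row's final counts.
#'
#' @param cascade cascade data.frame from [run_pipeline()].
#' @return TRUE invisibly; errors otherwise.
#' @export
check_cascade <- function(cascade) {
  ok <- all(cascade$final_samples == cascade$initial_samples - cascade$lost_samples) &&
    all(cascade$final_calls == cascade$initial_calls - cascade$lost_calls)
  if (nrow(cascade) > 1L) {
    ok <- ok &&
      all(cascade$initial_samples[-1] == cascade$final_samples[-nrow(cascade)]) &&
      all(cascade$initial_calls[-1] == cascade$final_calls[-nrow(cascade)])
  }
  if (!ok) stopf("check_cascade: chaining invariant violated")
  invisible(TRUE)
}
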