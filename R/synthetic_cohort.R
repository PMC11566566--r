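# Synthetic cohort generator: emits every input the pipeline consumes
# (calls, QC summary, phenotypes, region/gene files, core ids) with a known
# planted structure, so each stage can be tested without external data.
#
# The defaults describe a cohort of the size analysed in a typical
# autoimmune-disease rare-CNV study: 1182 cases and 4010 controls (200 of
# which will serve as the common-CNV reference), ~10 calls per sample after
# calling, call lengths log-uniform between 20 kb and 2 Mb, ~2% of samples
# failing signal QC, and a probe every 5 kb (a ~700k-marker genome-wide
# array).

#' Synthetic cohort specification
#'
#' @param n_cases,n_controls cohort sizes (controls include the future
#'   reference subset).
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @param background_rate Poisson mean number of background CNV calls per
#'   sample.
#' @param length_range_kb log-uniform bounds of background call lengths.
#' @param del_fraction probability that a background call is a deletion.
#' @param common_loci data.frame(chrom, start, end, cnv_type, carrier_freq)
#'   of polymorphic loci carried by cases and controls alike.
#' @param planted_effects data.frame(chrom, start, end, cnv_type,
#'   case_carrier_freq, control_carrier_freq) of case-enriched loci. The
#'   default plants one >1 Mb deletion with a carrier odds ratio of 4
#'   (control carrier frequency 0.005).
#' @param qc_fail_fraction fraction of samples pushed past exactly one QC
#'   threshold.
#' @param genome data.frame(chrom, length_bp); defaults to 22 autosomes with
#'   approximate human lengths.
#' @param probe_spacing_bp probe grid spacing; num_snps = ceil(length/spacing).
#' @param noncore_fraction fraction of samples left out of the core id list
#'   (emulating relatedness/stratification exclusions).
#' @return validated spec list.
#' @export
synthetic_cohort_spec <- function(n_cases = 1182L, n_controls = 4010L, seed = 1L,
                                  background_rate = 10,
                                  length_range_kb = c(20, 2000),
                                  del_fraction = 0.55,
                                  common_loci = default_common_loci(),
                                  planted_effects = default_planted_effects(),
                                  qc_fail_fraction = 0.02,
                                  genome = default_genome(),
                                  probe_spacing_bp = 5000L,
                                  noncore_fraction = 0.02) {
  spec <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    seed = as.integer(seed), background_rate = background_rate,
    length_range_kb = length_range_kb, del_fraction = del_fraction,
    common_loci = common_loci, planted_effects = planted_effects,
    qc_fail_fraction = qc_fail_fraction, genome = genome,
    probe_spacing_bp = as.integer(probe_spacing_bp),
    noncore_fraction = noncore_fraction
  )
  if (nrow(genome) == 0L) stopf("synthetic_cohort_spec: genome must be non-empty")
  freqs <- c(common_loci$carrier_freq, planted_effects$case_carrier_freq,
             planted_effects$control_carrier_freq, del_fraction, qc_fail_fraction)
  if (any(freqs < 0 | freqs > 1)) stopf("synthetic_cohort_spec: frequencies must be in [0,1]")
  for (loci in list(common_loci, planted_effects)) {
    if (nrow(loci) == 0L) next
    glen <- genome$length_bp[match(normalize_chrom(loci$chrom), genome$chrom)]
    if (anyNA(glen) || any(loci$end > glen) || any(loci$start < 1)) {
      stopf("synthetic_cohort_spec: planted interval outside the genome")
    }
  }
  spec
}

#' Default genome: 22 autosomes, approximate GRCh37 lengths
#' @return data.frame(chrom, length_bp).
#' @export
default_genome <- function() {
  data.frame(
    chrom = as.character(1:22),
    length_bp = c(
      249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6, 141e6, 136e6,
      135e6, 134e6, 115e6, 107e6, 103e6, 90e6, 81e6, 78e6, 59e6, 63e6, 48e6, 51e6
    ),
    stringsAsFactors = FALSE
  )
}

#' Default polymorphic common loci (10% carrier frequency)
#' @return data.frame(chrom, start, end, cnv_type, carrier_freq).
#' @export
default_common_loci <- function() {
  data.frame(
    chrom = c("8", "16"),
    start = c(30e6, 40e6), end = c(30.15e6, 40.12e6),
    cnv_type = c("DEL", "DUP"), carrier_freq = c(0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Default planted case-enriched effect: a >1 Mb deletion, carrier OR = 4
#'
#' Control carrier frequency 0.005; the case frequency solves
#' odds(case) = 4 x odds(control).
#' @return data.frame(chrom, start, end, cnv_type, case_carrier_freq,
#'   control_carrier_freq).
#' @export
default_planted_effects <- function() {
  p0 <- 0.005
  odds1 <- 4 * p0 / (1 - p0)
  data.frame(
    chrom = "2", start = 20e6, end = 21.2e6, cnv_type = "DEL",
    case_carrier_freq = odds1 / (1 + odds1), control_carrier_freq = p0,
    stringsAsFactors = FALSE
  )
}

# Spurious-region file emulating the usual exclusion lists: per-chromosome
# telomeres (0.5 Mb ends) and a 3 Mb centromere band, plus HLA and an
# immunoglobulin-like region.
synthetic_regions <- function(genome) {
  tel1 <- data.frame(chrom = genome$chrom, start = 1, end = 5e5, label = "telomere")
  tel2 <- data.frame(chrom = genome$chrom, start = genome$length_bp - 5e5 + 1,
                     end = genome$length_bp, label = "telomere")
  cen <- data.frame(chrom = genome$chrom,
                    start = round(genome$length_bp * 0.45),
                    end = round(genome$length_bp * 0.45) + 3e6 - 1,
                    label = "centromere")
  special <- data.frame(
    chrom = c("6", "14"), start = c(28477797, 105e6), end = c(33448354, 106.5e6),
    label = c("HLA", "immunoglobulin")
  )
  rbind(tel1, tel2, cen, special)
}

#' Generate a synthetic cohort in memory
#'
#' Background calls are placed uniformly (chromosome chosen proportional to
#' length) at Poisson(background_rate) per sample; carriers of common and
#' planted loci are independent Bernoulli draws per sample, with endpoint
#' jitter bounded to 5% of the locus length per side so any two carriers of
#' a locus keep a union-intersection overlap >= 2/3. QC metrics come from
#' pass-region normal distributions; `qc_fail_fraction` of samples are
#' pushed past exactly one threshold (rotating over LRR_SD, BAF_drift, WF
#' and NumCNV; NumCNV failures receive extra small calls so the call file
#' stays consistent with the QC table).
#'
#' @param spec specification from [synthetic_cohort_spec()].
#' @return list(calls, qc, cohort, regions, genes, gene_set, core_ids,
#'   truth) — all in the internal representations.
#' @export
simulate_cohort <- function(spec = synthetic_cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  ids <- sprintf("S%05d", seq_len(n))
  phen <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  cohort <- cohort_table(ids, phen)
  genome <- spec$genome
  genome$chrom <- normalize_chrom(genome$chrom)

  place_calls <- function(sample_ids, counts) {
    tot <- sum(counts)
    if (tot == 0L) return(empty_calls())
    ci <- sample.int(nrow(genome), tot, replace = TRUE, prob = genome$length_bp)
    len <- round(exp(stats::runif(tot, log(spec$length_range_kb[1] * 1000),
                                  log(spec$length_range_kb[2] * 1000))))
    start <- floor(stats::runif(tot, 1, genome$length_bp[ci] - len + 1))
    cnv_type <- ifelse(stats::runif(tot) < spec$del_fraction, "DEL", "DUP")
    cn <- ifelse(cnv_type == "DEL", 1L, 3L)
    cnv_calls(
      sample_id = rep(sample_ids, counts), chrom = genome$chrom[ci],
      start = start, end = start + len - 1, cn = cn,
      num_snps = pmax(1L, as.integer(ceiling(len / spec$probe_spacing_bp))),
      conf = round(stats::runif(tot, 10, 100), 1)
    )
  }

  bg_counts <- stats::rpois(n, spec$background_rate)
  calls <- place_calls(ids, bg_counts)

  truth <- list()
  plant <- function(locus, carrier_mask, label) {
    k <- sum(carrier_mask)
    if (k == 0L) return(empty_calls())
    len <- locus$end - locus$start + 1
    j1 <- round(stats::runif(k, -0.05, 0.05) * len)
    j2 <- round(stats::runif(k, -0.05, 0.05) * len)
    start <- pmax(1, locus$start + j1)
    end <- pmin(genome$length_bp[genome$chrom == normalize_chrom(locus$chrom)], locus$end + j2)
    cnv_calls(
      sample_id = ids[carrier_mask], chrom = locus$chrom, start = start, end = end,
      cn = if (locus$cnv_type == "DEL") 1L else 3L,
      num_snps = pmax(1L, as.integer(ceiling((end - start + 1) / spec$probe_spacing_bp))),
      conf = round(stats::runif(k, 10, 100), 1)
    )
  }
  if (nrow(spec$common_loci) > 0L) {
    for (i in seq_len(nrow(spec$common_loci))) {
      locus <- spec$common_loci[i, ]
      mask <- stats::runif(n) < locus$carrier_freq
      calls <- rbind(calls, plant(locus, mask, "common"))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = normalize_chrom(locus$chrom), start = locus$start, end = locus$end,
        cnv_type = locus$cnv_type, classification = "common",
        n_case_carriers = sum(mask & phen == "case"),
        n_control_carriers = sum(mask & phen == "control"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(spec$planted_effects) > 0L) {
    for (i in seq_len(nrow(spec$planted_effects))) {
      locus <- spec$planted_effects[i, ]
      pr <- ifelse(phen == "case", locus$case_carrier_freq, locus$control_carrier_freq)
      mask <- stats::runif(n) < pr
      calls <- rbind(calls, plant(locus, mask, "effect"))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = normalize_chrom(locus$chrom), start = locus$start, end = locus$end,
        cnv_type = locus$cnv_type, classification = "planted_effect",
        n_case_carriers = sum(mask & phen == "case"),
        n_control_carriers = sum(mask & phen == "control"),
        stringsAsFactors = FALSE
      )
    }
  }

  # QC metrics from the pass region; a chosen subset is pushed past exactly
  # one threshold each.
  qc <- data.frame(
    sample_id = ids,
    lrr_mean = stats::rnorm(n, 0, 0.01),
    lrr_median = stats::rnorm(n, 0, 0.01),
    lrr_sd = pmin(0.29, abs(stats::rnorm(n, 0.15, 0.04))),
    baf_mean = stats::rnorm(n, 0.5, 0.005),
    baf_median = stats::rnorm(n, 0.5, 0.005),
    baf_sd = abs(stats::rnorm(n, 0.04, 0.005)),
    baf_drift = pmin(0.009, abs(stats::rnorm(n, 0.002, 0.002))),
    wf = pmax(-0.049, pmin(0.049, stats::rnorm(n, 0, 0.015))),
    num_cnv = NA_integer_,
    stringsAsFactors = FALSE
  )
  n_fail <- round(spec$qc_fail_fraction * n)
  fail_idx <- if (n_fail > 0L) sample.int(n, n_fail) else integer(0)
  fail_reason <- rep_len(c("LRR_SD", "BAF_drift", "WF", "NumCNV"), n_fail)
  for (k in seq_along(fail_idx)) {
    i <- fail_idx[k]
    if (fail_reason[k] == "LRR_SD") qc$lrr_sd[i] <- stats::runif(1, 0.31, 0.5)
    if (fail_reason[k] == "BAF_drift") qc$baf_drift[i] <- stats::runif(1, 0.011, 0.05)
    if (fail_reason[k] == "WF") qc$wf[i] <- sample(c(-1, 1), 1) * stats::runif(1, 0.051, 0.1)
    if (fail_reason[k] == "NumCNV") {
      extra <- 51L + stats::rpois(1, 10) - sum(calls$sample_id == ids[i])
      if (extra > 0L) calls <- rbind(calls, place_calls(ids[i], extra))
    }
  }
  qc$num_cnv <- as.integer(table(factor(calls$sample_id, levels = ids)))
  qc_truth <- data.frame(
    sample_id = ids[fail_idx], planted_fail = fail_reason, stringsAsFactors = FALSE
  )
  # a NumCNV push can be a no-op if the sample already had > 50 calls budget;
  # record the intended reason regardless (tests compare against decisions)

  # gene map: tiled genes of 10-200 kb, ~500 genes; gene set = 50 of them
  n_genes <- 500L
  gc <- sample.int(nrow(genome), n_genes, replace = TRUE, prob = genome$length_bp)
  glen <- round(stats::runif(n_genes, 1e4, 2e5))
  gstart <- floor(stats::runif(n_genes, 1, genome$length_bp[gc] - glen + 1))
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = genome$chrom[gc], start = gstart, end = gstart + glen - 1,
    stringsAsFactors = FALSE
  )
  gene_set <- sort(sample(genes$gene_id, 50L))

  core_ids <- sort(sample(ids, round((1 - spec$noncore_fraction) * n)))

  calls <- calls[call_order(calls), , drop = FALSE]
  rownames(calls) <- NULL
  list(
    calls = calls, qc = qc, cohort = cohort,
    regions = synthetic_regions(genome), genes = genes, gene_set = gene_set,
    core_ids = core_ids,
    truth = list(loci = if (length(truth)) do.call(rbind, truth) else NULL, qc_fail = qc_truth)
  )
}

#' Generate a synthetic cohort and write all input files
#'
#' Writes rawcnv, QC summary TSV, FAM, regions BED, genes BED, gene-set
#' list, core-id list and a truth table into `dir`. Byte-identical across
#' runs with the same spec.
#'
#' @param spec specification from [synthetic_cohort_spec()].
#' @param dir output directory (created if needed).
#' @return invisible named character vector of file paths.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(spec)
  paths <- c(
    rawcnv = file.path(dir, "cohort.rawcnv"),
    qcsum = file.path(dir, "cohort.qcsum"),
    fam = file.path(dir, "cohort.fam"),
    regions = file.path(dir, "regions.bed"),
    genes = file.path(dir, "genes.bed"),
    gene_set = file.path(dir, "gene_set.txt"),
    core_ids = file.path(dir, "core_ids.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_rawcnv(sim$calls, paths["rawcnv"])
  qc_out <- sim$qc
  names(qc_out) <- c("sample_id", "LRR_mean", "LRR_median", "LRR_SD", "BAF_mean",
                     "BAF_median", "BAF_SD", "BAF_drift", "WF", "NumCNV")
  utils::write.table(qc_out, paths["qcsum"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s %s 0 0 0 %d", sim$cohort$sample_id, sim$cohort$sample_id,
                     ifelse(sim$cohort$phenotype == "case", 2L, 1L)), paths["fam"])
  write_bed_regions(sim$regions, paths["regions"])
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$genes$chrom, as.integer(sim$genes$start) - 1L,
                     as.integer(sim$genes$end), sim$genes$gene_id), paths["genes"])
  writeLines(sim$gene_set, paths["gene_set"])
  writeLines(sim$core_ids, paths["core_ids"])
  if (!is.null(sim$truth$loci)) {
    utils::write.table(sim$truth$loci, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("chrom\tstart\tend\tcnv_type\tclassification", paths["truth"])
  }
  invisible(paths)
}
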