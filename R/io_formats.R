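# Readers and writers for the external formats the pipeline touches.
#
# Internal convention: all coordinates are 1-based inclusive (the PennCNV /
# PLINK convention). BED input (0-based half-open) is converted at the
# boundary and converted back on write. Chromosome names are normalized with
# normalize_chrom(). CNV call tables are plain data.frames with columns
#   sample_id, chrom, start, end, cn, cnv_type, num_snps, length, conf
# where length is always recomputed as end - start + 1 and cnv_type is DEL
# iff cn < 2, DUP iff cn > 2 (cn = 2 is not a call and is rejected).

#' Construct and validate a CNV call table
#'
#' Normalizes chromosome names, recomputes `length` and derives `cnv_type`
#' from the copy number. Diploid records (cn = 2) are rejected: a call is by
#' definition a deviation from two copies.
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome names (normalized internally).
#' @param start,end 1-based inclusive bp coordinates, start <= end.
#' @param cn integer copy number (0, 1, 3, 4, ...; never 2).
#' @param num_snps positive integer probe counts.
#' @param conf optional confidence scores (NA when absent).
#' @return data.frame with the canonical call columns.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cn, num_snps, conf = NA_real_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cn = as.integer(cn),
    num_snps = as.integer(num_snps),
    conf = as.numeric(conf),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stopf("cnv_calls: start > end in %d record(s)", sum(df$start > df$end))
  if (any(df$cn == 2L)) stopf("cnv_calls: %d record(s) with cn = 2 (diploid is not a call)", sum(df$cn == 2L))
  if (any(df$num_snps < 1L)) stopf("cnv_calls: non-positive probe count")
  df$cnv_type <- cnv_type_from_cn(df$cn)
  df$length <- df$end - df$start + 1
  df[, c("sample_id", "chrom", "start", "end", "cn", "cnv_type", "num_snps", "length", "conf")]
}

empty_calls <- function() {
  cnv_calls(character(0), character(0), numeric(0), numeric(0), integer(0), integer(0), numeric(0))
}

#' Read a PennCNV-style .rawcnv call file
#'
#' Each non-empty line has the form
#' `chrN:start-end numsnp=K length=L state S,cn=C <sample> startsnp=.. endsnp=.. [conf=..]`.
#' Thousands separators inside `numsnp=`/`length=` are tolerated. The declared
#' `length=` field is cross-checked against the coordinates; on disagreement a
#' warning is raised and the coordinates win.
#'
#' @param path path to the call file.
#' @return CNV call data.frame (see [cnv_calls()]).
#' @export
read_rawcnv <- function(path) {
  if (!file.exists(path)) stopf("read_rawcnv: file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_calls())
  rx <- paste0(
    "^\\s*(\\S+):(\\d+)-(\\d+)", # region
    "\\s+numsnp=([0-9,]+)",
    "\\s+length=([0-9,]+)",
    "\\s+state(\\d+),cn=(\\d+)",
    "\\s+(\\S+)", # sample id
    "\\s+startsnp=(\\S+)",
    "\\s+endsnp=(\\S+)",
    "(?:\\s+conf=(\\S+))?",
    "\\s*$"
  )
  m <- regmatches(lines[keep], regexec(rx, lines[keep]))
  bad <- which(vapply(m, length, 0L) == 0L)
  if (length(bad) > 0L) {
    stopf("read_rawcnv: malformed line %d in %s: %s", keep[bad[1]], path, lines[keep[bad[1]]])
  }
  fields <- do.call(rbind, m)
  denum <- function(x) as.numeric(gsub(",", "", x))
  cn <- as.integer(fields[, 8])
  if (any(cn == 2L)) {
    stopf("read_rawcnv: line %d declares cn=2; diploid records are rejected", keep[which(cn == 2L)[1]])
  }
  calls <- cnv_calls(
    sample_id = fields[, 9],
    chrom = fields[, 2],
    start = denum(fields[, 3]),
    end = denum(fields[, 4]),
    cn = cn,
    num_snps = denum(fields[, 5]),
    conf = ifelse(nzchar(fields[, 12]), suppressWarnings(as.numeric(fields[, 12])), NA_real_)
  )
  declared <- denum(fields[, 6])
  mism <- which(declared != calls$length)
  if (length(mism) > 0L) {
    warnf(
      "read_rawcnv: declared length differs from end-start+1 on %d line(s) (first: line %d); coordinates win",
      length(mism), keep[mism[1]]
    )
  }
  calls
}

#' Write calls in the .rawcnv dialect
#'
#' @param calls CNV call data.frame.
#' @param path output path.
#' @export
write_rawcnv <- function(calls, path) {
  calls <- calls[call_order(calls), , drop = FALSE]
  lines <- sprintf(
    "chr%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s startsnp=na endsnp=na%s",
    calls$chrom, as.integer(calls$start), as.integer(calls$end),
    calls$num_snps, as.integer(calls$length),
    ifelse(calls$cn < 2L, calls$cn + 1L, calls$cn + 2L), calls$cn,
    calls$sample_id,
    ifelse(is.na(calls$conf), "", sprintf(" conf=%g", calls$conf))
  )
  writeLines(lines, path)
  invisible(path)
}

qc_aliases_default <- function() {
  list(
    sample_id = c("sample_id", "ID", "Sample", "sample", "IID", "File", "file"),
    lrr_mean = c("LRR_mean"), lrr_median = c("LRR_median"), lrr_sd = c("LRR_SD"),
    baf_mean = c("BAF_mean"), baf_median = c("BAF_median"), baf_sd = c("BAF_SD"),
    baf_drift = c("BAF_drift"), wf = c("WF"), num_cnv = c("NumCNV", "NumCNVs")
  )
}

#' Read a PennCNV QC-summary table
#'
#' Tab-separated with a header naming at least the sample id, LRR_SD,
#' BAF_drift and WF columns. NumCNV may be absent if a call table is supplied,
#' in which case it is recomputed by counting calls per sample; when both are
#' available they are cross-checked (warning on mismatch). Missing optional
#' columns (LRR_mean, LRR_median, BAF_mean, BAF_median, BAF_SD) are stored as
#' NA, never as zero.
#'
#' @param path path to the TSV file.
#' @param calls optional CNV call data.frame used to recompute/check NumCNV.
#' @param aliases named list of accepted header names per canonical field;
#'   merged over the defaults.
#' @return data.frame with columns sample_id, lrr_mean, lrr_median, lrr_sd,
#'   baf_mean, baf_median, baf_sd, baf_drift, wf, num_cnv.
#' @export
read_qc_summary <- function(path, calls = NULL, aliases = list()) {
  if (!file.exists(path)) stopf("read_qc_summary: file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  al <- utils::modifyList(qc_aliases_default(), aliases)
  pick <- function(field) {
    hit <- intersect(al[[field]], names(tab))
    if (length(hit) == 0L) return(NULL)
    tab[[hit[1]]]
  }
  mandatory <- c("sample_id", "lrr_sd", "baf_drift", "wf")
  if (is.null(calls)) mandatory <- c(mandatory, "num_cnv")
  missing <- mandatory[vapply(mandatory, function(f) is.null(pick(f)), TRUE)]
  if (length(missing) > 0L) {
    stopf("read_qc_summary: missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  num_or_na <- function(field) {
    v <- pick(field)
    if (is.null(v)) rep(NA_real_, nrow(tab)) else as.numeric(v)
  }
  rec <- data.frame(
    sample_id = as.character(pick("sample_id")),
    lrr_mean = num_or_na("lrr_mean"), lrr_median = num_or_na("lrr_median"),
    lrr_sd = num_or_na("lrr_sd"),
    baf_mean = num_or_na("baf_mean"), baf_median = num_or_na("baf_median"),
    baf_sd = num_or_na("baf_sd"),
    baf_drift = num_or_na("baf_drift"), wf = num_or_na("wf"),
    num_cnv = if (is.null(pick("num_cnv"))) rep(NA_real_, nrow(tab)) else as.numeric(pick("num_cnv")),
    stringsAsFactors = FALSE
  )
  dup <- rec$sample_id[duplicated(rec$sample_id)]
  if (length(dup) > 0L) stopf("read_qc_summary: duplicated sample_id: %s", paste(unique(dup), collapse = ", "))
  if (!is.null(calls)) {
    counted <- table(factor(calls$sample_id, levels = rec$sample_id))
    if (all(is.na(rec$num_cnv))) {
      rec$num_cnv <- as.numeric(counted)
    } else {
      off <- which(!is.na(rec$num_cnv) & rec$num_cnv != as.numeric(counted))
      if (length(off) > 0L) {
        warnf(
          "read_qc_summary: NumCNV disagrees with the call file for %d sample(s) (first: %s)",
          length(off), rec$sample_id[off[1]]
        )
      }
    }
  }
  rec$num_cnv <- as.integer(rec$num_cnv)
  rec
}

#' Read a BED3/BED4 region file
#'
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' inclusive convention: start + 1, end unchanged. A missing name column
#' defaults the label to "region".
#'
#' @param path path to the BED file.
#' @param default_label label used when the file has only three columns.
#' @return data.frame(chrom, start, end, label).
#' @export
read_bed_regions <- function(path, default_label = "region") {
  if (!file.exists(path)) stopf("read_bed_regions: file not found: %s", path)
  tab <- utils::read.table(path,
    header = FALSE, sep = "\t", stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "label", "V5", "V6")[1:max(3, count_bed_cols(path))],
    fill = TRUE
  )
  if (any(tab$start >= tab$end)) {
    stopf("read_bed_regions: BED start >= end on %d line(s)", sum(tab$start >= tab$end))
  }
  data.frame(
    chrom = normalize_chrom(tab$chrom),
    start = as.numeric(tab$start) + 1,
    end = as.numeric(tab$end),
    label = if ("label" %in% names(tab)) as.character(tab$label) else default_label,
    stringsAsFactors = FALSE
  )
}

count_bed_cols <- function(path) {
  first <- readLines(path, n = 1L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' Write regions as BED (inverse of [read_bed_regions()])
#' @param regions data.frame(chrom, start, end, label) in internal coordinates.
#' @param path output path.
#' @export
write_bed_regions <- function(regions, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s", regions$chrom, as.integer(regions$start) - 1L,
    as.integer(regions$end), regions$label
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate a cohort table
#'
#' @param sample_id character vector, unique.
#' @param phenotype "case" or "control" per sample.
#' @param is_core logical, sample in the core (unrelated, unstratified) set.
#' @param is_reference_control logical, control used for common-CNV discovery.
#' @return data.frame(sample_id, phenotype, is_core, is_reference_control).
#' @export
cohort_table <- function(sample_id, phenotype, is_core = TRUE, is_reference_control = FALSE) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    phenotype = as.character(phenotype),
    is_core = rep_len(as.logical(is_core), length(sample_id)),
    is_reference_control = rep_len(as.logical(is_reference_control), length(sample_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stopf("cohort_table: duplicated sample_id")
  if (!all(df$phenotype %in% c("case", "control"))) stopf("cohort_table: phenotype must be 'case' or 'control'")
  if (any(df$is_reference_control & df$phenotype != "control")) {
    stopf("cohort_table: reference samples must be controls")
  }
  df
}

#' Read a PLINK FAM file as a cohort table
#'
#' Phenotype column coded 1 = control, 2 = case; anything else is an error
#' (the case-control analysis needs every phenotype).
#'
#' @param path path to the .fam file.
#' @return cohort table (see [cohort_table()]).
#' @export
read_fam <- function(path) {
  if (!file.exists(path)) stopf("read_fam: file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stopf("read_fam: expected 6 columns, found %d", ncol(tab))
  ph <- tab[[6]]
  if (!all(ph %in% c(1, 2))) stopf("read_fam: phenotype must be 1 (control) or 2 (case)")
  cohort_table(tab[[2]], ifelse(ph == 2, "case", "control"))
}

#' Write calls and cohort as a PLINK CNV-list pair (.cnv + .fam)
#'
#' .cnv columns: FID IID CHR BP1 BP2 TYPE SCORE SITES with TYPE the copy
#' number, SCORE the confidence (0 when absent) and SITES the probe count.
#' .fam phenotype is 1 for controls, 2 for cases; FID = IID.
#'
#' @param calls CNV call data.frame; every sample_id must be in the cohort.
#' @param cohort cohort table.
#' @param path_prefix output prefix; writes `<prefix>.cnv` and `<prefix>.fam`.
#' @return invisible character vector of the two paths.
#' @export
write_plink_cnv <- function(calls, cohort, path_prefix) {
  orphans <- setdiff(calls$sample_id, cohort$sample_id)
  if (length(orphans) > 0L) {
    stopf("write_plink_cnv: call sample(s) absent from cohort: %s", paste(orphans, collapse = ", "))
  }
  cnv_path <- paste0(path_prefix, ".cnv")
  fam_path <- paste0(path_prefix, ".fam")
  calls <- calls[order(calls$sample_id, chrom_order_key(calls$chrom), calls$start), , drop = FALSE]
  header <- "FID IID CHR BP1 BP2 TYPE SCORE SITES"
  rows <- sprintf(
    "%s %s %s %d %d %d %g %d",
    calls$sample_id, calls$sample_id, calls$chrom,
    as.integer(calls$start), as.integer(calls$end), calls$cn,
    ifelse(is.na(calls$conf), 0, calls$conf), calls$num_snps
  )
  writeLines(c(header, rows), cnv_path)
  fam <- sprintf(
    "%s %s 0 0 0 %d", cohort$sample_id, cohort$sample_id,
    ifelse(cohort$phenotype == "case", 2L, 1L)
  )
  writeLines(fam, fam_path)
  invisible(c(cnv_path, fam_path))
}

#' Read a PLINK CNV-list pair written by [write_plink_cnv()]
#'
#' @param path_prefix prefix of the `.cnv`/`.fam` pair.
#' @return list(calls, cohort). SCORE 0 maps back to an absent confidence.
#' @export
read_plink_cnv <- function(path_prefix) {
  cnv_path <- paste0(path_prefix, ".cnv")
  fam_path <- paste0(path_prefix, ".fam")
  cohort <- read_fam(fam_path)
  tab <- utils::read.table(cnv_path, header = TRUE, stringsAsFactors = FALSE)
  calls <- cnv_calls(
    sample_id = tab$IID, chrom = tab$CHR, start = tab$BP1, end = tab$BP2,
    cn = tab$TYPE, num_snps = tab$SITES,
    conf = ifelse(tab$SCORE == 0, NA_real_, tab$SCORE)
  )
  list(calls = calls, cohort = cohort)
}

#' Read a gene map (BED4 or 1-based four-column table)
#'
#' @param path path to the file.
#' @param dialect "bed4" (0-based half-open, columns chrom/start/end/gene_id)
#'   or "table1" (same columns, already 1-based inclusive).
#' @return data.frame(gene_id, chrom, start, end); gene_id unique.
#' @export
read_gene_map <- function(path, dialect = c("bed4", "table1")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("read_gene_map: file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stopf("read_gene_map: expected 4 columns, found %d", ncol(tab))
  start <- as.numeric(tab[[2]])
  end <- as.numeric(tab[[3]])
  if (dialect == "bed4") {
    if (any(start >= end)) stopf("read_gene_map: BED start >= end")
    start <- start + 1
  } else if (any(start > end)) {
    stopf("read_gene_map: start > end")
  }
  gm <- data.frame(
    gene_id = as.character(tab[[4]]), chrom = normalize_chrom(tab[[1]]),
    start = start, end = end, stringsAsFactors = FALSE
  )
  dup <- unique(gm$gene_id[duplicated(gm$gene_id)])
  if (length(dup) > 0L) stopf("read_gene_map: duplicated gene_id: %s", paste(dup, collapse = ", "))
  gm
}

#' Read a gene-set file (one gene id per line)
#'
#' @param path path to the file.
#' @param gene_map optional gene map; members absent from the map are
#'   reported with a warning (not dropped).
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stopf("read_gene_set: file not found: %s", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) stopf("read_gene_set: empty gene set (enrichment undefined)")
  if (!is.null(gene_map)) {
    missing <- setdiff(ids, gene_map$gene_id)
    if (length(missing) > 0L) {
      warnf("read_gene_set: %d gene(s) not in the gene map: %s",
            length(missing), paste(missing, collapse = ", "))
    }
  }
  ids
}

#' Read a plain-text sample id list (one id per line)
#' @param path path to the file.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stopf("read_id_list: file not found: %s", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
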