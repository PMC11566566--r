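# Case-control gene-set enrichment: logistic regression on per-sample gene
# counts with CNV-rate and size covariates, permutation-based empirical p.

#' Per-sample enrichment covariates
#'
#' GCNT sums, over a sample's CNVs, the number of distinct genes each CNV
#' intersects by at least 1 bp — a gene hit by two CNVs of one sample counts
#' twice, so the covariate tracks the rate of gene-impacting CNVs.
#' `gcnt_set` restricts the counted genes to the tested gene set. NSEG and
#' AVGKB mirror the burden metrics, with AVGKB set to 0 for zero-CNV samples
#' so the regression is defined for everyone.
#'
#' @param calls CNV call data.frame.
#' @param cohort cohort table (zero-CNV samples included).
#' @param gene_map gene map from [read_gene_map()].
#' @param gene_set character vector of gene ids (may be empty only if the
#'   gene-set test is not run).
#' @param distinct_per_sample count each gene at most once per sample
#'   instead of once per CNV.
#' @return data.frame(sample_id, gcnt, gcnt_set, nseg, avgkb).
#' @export
compute_covariates <- function(calls, cohort, gene_map, gene_set = character(0),
                               distinct_per_sample = FALSE) {
  if (nrow(gene_map) == 0L) stopf("compute_covariates: empty gene map")
  hits <- overlap_hits(calls, gene_map)
  lv <- factor(calls$sample_id, levels = cohort$sample_id)
  in_set <- gene_map$gene_id[hits$si] %in% gene_set
  if (distinct_per_sample) {
    sample_of_hit <- calls$sample_id[hits$qi]
    gcnt <- tapply(gene_map$gene_id[hits$si], factor(sample_of_hit, levels = cohort$sample_id),
                   function(g) length(unique(g)))
    gcnt_set <- tapply(gene_map$gene_id[hits$si][in_set],
                       factor(sample_of_hit[in_set], levels = cohort$sample_id),
                       function(g) length(unique(g)))
    gcnt <- ifelse(is.na(gcnt), 0L, gcnt)
    gcnt_set <- ifelse(is.na(gcnt_set), 0L, gcnt_set)
  } else {
    per_call <- table(factor(hits$qi, levels = seq_len(nrow(calls))))
    per_call_set <- table(factor(hits$qi[in_set], levels = seq_len(nrow(calls))))
    gcnt <- as.numeric(tapply(as.numeric(per_call), lv, sum, default = 0))
    gcnt_set <- as.numeric(tapply(as.numeric(per_call_set), lv, sum, default = 0))
    gcnt[is.na(gcnt)] <- 0
    gcnt_set[is.na(gcnt_set)] <- 0
  }
  bm <- per_sample_metrics(calls, cohort)
  data.frame(
    sample_id = cohort$sample_id,
    gcnt = as.integer(gcnt), gcnt_set = as.integer(gcnt_set),
    nseg = bm$rate, avgkb = ifelse(bm$rate > 0L, bm$avgkb, 0),
    stringsAsFactors = FALSE
  )
}

fit_logistic_coef <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) return(NA_real_)
  unname(fit$coefficients[2L])
}

#' Permutation gene-set enrichment test
#'
#' Fits phenotype ~ GCNT + NSEG + AVGKB (genic test) or
#' phenotype ~ GCNT_set + GCNT + NSEG + AVGKB (gene-set test) by logistic
#' regression; the statistic is the coefficient of the first predictor.
#' Phenotype labels are permuted `n_perm` times; the two-sided empirical p
#' is (1 + #\{|coef_perm| >= |coef_obs|\}) / (converged + 1). Non-converged
#' permutations are dropped from both sides and reported via
#' `converged_fraction`. Supplying the same `perms` matrix to both tests
#' shares the permutation indices within a run.
#'
#' @param covariates output of [compute_covariates()].
#' @param cohort cohort table aligned with `covariates`.
#' @param test_name "genic" or "gene_set".
#' @param n_perm number of permutations (default 10,000).
#' @param seed RNG seed used when `perms` is not supplied.
#' @param perms optional n_samples x n_perm matrix of permuted row indices,
#'   from [make_permutations()].
#' @return data.frame(test_name, coefficient, empirical_p, n_perm,
#'   converged_fraction).
#' @export
enrichment_test <- function(covariates, cohort, test_name = c("genic", "gene_set"),
                            n_perm = 10000L, seed = 1L, perms = NULL) {
  test_name <- match.arg(test_name)
  stopifnot(identical(covariates$sample_id, cohort$sample_id))
  y <- as.numeric(cohort$phenotype == "case")
  if (all(y == 1) || all(y == 0)) stopf("enrichment_test: both phenotype groups must be non-empty")
  preds <- if (test_name == "genic") {
    cbind(GCNT = covariates$gcnt, NSEG = covariates$nseg, AVGKB = covariates$avgkb)
  } else {
    cbind(GCNT_set = covariates$gcnt_set, GCNT = covariates$gcnt,
          NSEG = covariates$nseg, AVGKB = covariates$avgkb)
  }
  if (stats::sd(preds[, 1]) == 0) {
    # degenerate: the tested predictor carries no information
    return(data.frame(test_name = test_name, coefficient = 0, empirical_p = 1,
                      n_perm = as.integer(n_perm), converged_fraction = 1))
  }
  keep <- c(TRUE, apply(preds[, -1, drop = FALSE], 2L, stats::sd) > 0)
  X <- cbind(1, preds[, keep, drop = FALSE])
  coef_obs <- fit_logistic_coef(X, y)
  if (is.na(coef_obs)) {
    stopf(paste0(
      "enrichment_test: observed fit failed to converge (possible separation: ",
      "predictor '%s' ranges %.3g-%.3g in cases vs %.3g-%.3g in controls)"),
      colnames(preds)[1], min(preds[y == 1, 1]), max(preds[y == 1, 1]),
      min(preds[y == 0, 1]), max(preds[y == 0, 1]))
  }
  if (is.null(perms)) perms <- make_permutations(length(y), n_perm, seed)
  coef_perm <- vapply(seq_len(ncol(perms)), function(p) {
    fit_logistic_coef(X, y[perms[, p]])
  }, 0)
  ok <- !is.na(coef_perm)
  data.frame(
    test_name = test_name,
    coefficient = coef_obs,
    empirical_p = (1 + sum(abs(coef_perm[ok]) >= abs(coef_obs))) / (sum(ok) + 1),
    n_perm = as.integer(ncol(perms)),
    converged_fraction = mean(ok),
    stringsAsFactors = FALSE
  )
}

#' Generate a shared permutation-index matrix
#' @param n number of samples.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return n x n_perm integer matrix of permuted indices.
#' @export
make_permutations <- function(n, n_perm, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

#' Run the genic and gene-set enrichment tests with shared permutations
#'
#' @inheritParams enrichment_test
#' @return data.frame with one row per test.
#' @export
enrichment_tests <- function(covariates, cohort, n_perm = 10000L, seed = 1L) {
  perms <- make_permutations(nrow(cohort), n_perm, seed)
  rbind(
    enrichment_test(covariates, cohort, "genic", perms = perms),
    enrichment_test(covariates, cohort, "gene_set", perms = perms)
  )
}
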