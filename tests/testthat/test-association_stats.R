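# Size binning, two-proportion tests, Woolf odds ratios, summary tables.
# Published four-decimal values used below were re-verified against the
# independent stats:: oracle before being frozen.

test_that("bin_by_size follows the half-open convention", {
  calls <- make_calls(rep("1", 3), c(1, 1, 1), c(100000, 1500000, 50001),
                      sample_id = c("A", "B", "C"))
  binned <- bin_by_size(calls)
  expect_equal(binned$bin_label, c("100KB_200KB", "1000KB_1000000KB", "50KB_100KB"))
  expect_error(bin_by_size(make_calls("1", 1, 10000)), "below the lowest edge")
  expect_error(size_bins(c(100, 50)), "strictly increasing")
})

test_that("two_proportion_test reproduces the published Yates p-values", {
  expect_equal(round(two_proportion_test(827, 1182, 2615, 3810), 4), 0.4077)
  expect_equal(round(two_proportion_test(13, 1182, 10, 3810), 4), 0.0005)
  expect_equal(two_proportion_test(10, 100, 10, 100), 1) # equal proportions clamp at 0
  expect_error(two_proportion_test(5, 0, 5, 10), "positive")
})

test_that("two_proportion_test agrees with the prop.test oracle", {
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- rbinom(1, n1, runif(1, 0.05, 0.95)); b <- rbinom(1, n2, runif(1, 0.05, 0.95))
    if (a + b == 0 || a + b == n1 + n2) next
    expect_equal(
      two_proportion_test(a, n1, b, n2),
      suppressWarnings(stats::prop.test(c(a, b), c(n1, n2))$p.value),
      tolerance = 1e-12
    )
  }
})

test_that("odds_ratio_woolf reproduces the published estimates and CIs", {
  del <- odds_ratio_woolf(827, 1182, 2615, 3810)
  expect_equal(round(del$or, 4), 1.0646)
  expect_equal(round(del$p, 4), 0.3876)
  dup <- odds_ratio_woolf(721, 1182, 2367, 3810)
  expect_equal(round(dup$or, 4), 0.9535)
  big <- odds_ratio_woolf(13, 1182, 10, 3810)
  expect_equal(round(big$or, 4), 4.2258)
  expect_equal(round(big$ci_low, 2), 1.85)
  expect_equal(round(big$ci_high, 2), 9.66)
  expect_equal(round(big$p, 4), 0.0002)
})

test_that("odds_ratio_woolf matches the chi-square / normal-quantile oracle", {
  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- sample(seq_len(n1 - 1), 1); b <- sample(seq_len(n2 - 1), 1)
    res <- odds_ratio_woolf(a, n1, b, n2)
    m <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    expect_equal(res$p, stats::chisq.test(m, correct = FALSE)$p.value, tolerance = 1e-12)
    lor <- log(a) - log(n1 - a) - log(b) + log(n2 - b)
    se <- sqrt(1 / a + 1 / (n1 - a) + 1 / b + 1 / (n2 - b))
    expect_equal(res$ci_low, exp(lor - stats::qnorm(0.975) * se), tolerance = 1e-12)
    expect_equal(res$ci_high, exp(lor + stats::qnorm(0.975) * se), tolerance = 1e-12)
  }
})

test_that("odds ratio symmetry, CI behaviour and degenerate handling", {
  even <- odds_ratio_woolf(50, 100, 50, 100)
  expect_equal(even$or, 1)
  expect_equal(even$ci_low * even$ci_high, 1, tolerance = 1e-12) # log-symmetric about 1

  set.seed(19)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    a <- sample(seq_len(n1 - 1), 1); b <- sample(seq_len(n2 - 1), 1)
    fwd <- odds_ratio_woolf(a, n1, b, n2)
    rev <- odds_ratio_woolf(b, n2, a, n1) # swap case/control labels
    expect_equal(fwd$or, 1 / rev$or, tolerance = 1e-12)
    dbl <- odds_ratio_woolf(2 * a, 2 * n1, 2 * b, 2 * n2)
    expect_equal(dbl$or, fwd$or, tolerance = 1e-12)
    expect_lt(fwd$ci_low, dbl$ci_low) # doubling shrinks the CI
    expect_gt(fwd$ci_high, dbl$ci_high)
  }

  zero <- odds_ratio_woolf(0, 50, 5, 50)
  expect_true(zero$continuity_corrected) # Haldane-Anscombe applied
  expect_gt(zero$or, 0)
  expect_error(odds_ratio_woolf(0, 50, 0, 50), "degenerate")
  expect_error(odds_ratio_woolf(50, 50, 60, 60), "degenerate")
})

test_that("association_summary reproduces published deletion-bin odds ratios", {
  # inject the printed per-bin counts as synthetic calls at the published
  # cohort sizes and recompute every statistic
  n1 <- 1182L; n2 <- 3810L
  cohort <- cohort_table(
    c(sprintf("CA%04d", 1:n1), sprintf("CO%04d", 1:n2)),
    c(rep("case", n1), rep("control", n2))
  )
  del_counts <- list(a = c(435L, 260L, 102L, 17L, 13L), b = c(1298L, 919L, 323L, 65L, 10L))
  dup_counts <- list(a = c(297L, 204L, 157L, 48L, 15L), b = c(1050L, 614L, 488L, 150L, 65L))
  mid_len <- c(75, 150, 350, 750, 1500) * 1000 # one representative length per bin
  build <- function(counts, cn, ids) {
    do.call(rbind, lapply(seq_along(mid_len), function(i) {
      k <- counts[i]
      if (k == 0L) return(NULL)
      make_calls(rep("1", k), seq(1, by = 2e6, length.out = k),
                 seq(1, by = 2e6, length.out = k) + mid_len[i] - 1,
                 cn = cn, sample_id = rep_len(ids, k))
    }))
  }
  calls <- rbind(
    build(del_counts$a, 1L, sprintf("CA%04d", 1:n1)),
    build(del_counts$b, 1L, sprintf("CO%04d", 1:n2)),
    build(dup_counts$a, 3L, sprintf("CA%04d", 1:n1)),
    build(dup_counts$b, 3L, sprintf("CO%04d", 1:n2))
  )
  summ <- association_summary(calls, cohort)
  del <- summ[summ$cnv_type == "DEL" & summ$bin_label != "ALL", ]
  expect_equal(del$a, del_counts$a)
  expect_equal(del$b, del_counts$b)
  expect_equal(round(del$or_estimate, 4), c(1.1270, 0.8871, 1.0196, 0.8407, 4.2258))
  expect_equal(round(del$p_two_prop, 4), c(0.0911, 0.1435, 0.9174, 0.6158, 0.0005))
  dup <- summ[summ$cnv_type == "DUP" & summ$bin_label != "ALL", ]
  expect_equal(round(dup$or_estimate, 4), c(0.8821, 1.0857, 1.0427, 1.0328, 0.7406))
  # ALL rows aggregate the bins
  all_del <- summ[summ$cnv_type == "DEL" & summ$bin_label == "ALL", ]
  expect_equal(all_del$a, sum(del$a))
  expect_equal(round(all_del$or_estimate, 4), 1.0646)
  expect_equal(round(all_del$case_freq, 4), 0.6997)
  fmt <- format_association_summary(summ)
  expect_equal(fmt$OR[fmt$CNV == "DELs"], "1.0646")
  expect_equal(fmt$X95.CI[fmt$CNV == "1000KB_1000000KB" & fmt$Type == "DEL"], "1.8482,9.6622")
})

test_that("association_summary emits empty bins with zero counts and NA stats", {
  cohort <- tiny_cohort(2, 2)
  calls <- make_calls("1", 1, 60000, sample_id = "CA01") # one DEL in 50-100 kb
  summ <- association_summary(calls, cohort)
  empty <- summ[summ$cnv_type == "DUP" & summ$bin_label == "50KB_100KB", ]
  expect_equal(empty$a, 0L)
  expect_equal(empty$b, 0L)
  expect_true(is.na(empty$or_estimate))
  hit <- summ[summ$cnv_type == "DEL" & summ$bin_label == "50KB_100KB", ]
  expect_equal(hit$case_freq, 0.5)
})
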