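# Union-intersection overlap counting and common/rare partitioning.

test_that("union_overlap_fraction: identity, disjoint, forced arithmetic", {
  expect_equal(union_overlap_fraction("1", 1, 100, "1", 1, 100), 1.0)
  expect_equal(union_overlap_fraction("1", 1, 100, "1", 200, 300), 0.0)
  expect_equal(union_overlap_fraction("1", 1, 100, "1", 51, 150), 1 / 3)
  expect_equal(union_overlap_fraction("1", 1, 100, "2", 1, 100), 0.0)
  # symmetry
  expect_equal(
    union_overlap_fraction("1", 10, 80, "1", 40, 200),
    union_overlap_fraction("1", 40, 200, "1", 10, 80)
  )
})

test_that("overlap_counts matches the brute-force all-pairs oracle", {
  expect_equal(overlap_counts(make_calls("1", 100, 200)), 1L) # lone CNV counts itself
  twins <- make_calls(c("1", "1"), c(100, 100), c(200, 200), sample_id = c("A", "B"))
  expect_equal(overlap_counts(twins), c(2L, 2L))
  set.seed(17)
  for (rep in 1:25) {
    calls <- random_interval_calls(sample(5:60, 1))
    expect_equal(overlap_counts(calls, 0.5), bf_overlap_counts(calls, 0.5))
    expect_equal(overlap_counts(calls, 0.9), bf_overlap_counts(calls, 0.9))
  }
  mixed <- make_calls(c("1", "1"), c(1, 1), c(100, 100), cn = c(1L, 3L))
  expect_error(overlap_counts(mixed), "single cnv_type")
})

test_that("identify_common applies the count threshold per type", {
  near <- function(n) make_calls(rep("1", n), 1000 + 1:n * 10, 2000 + 1:n * 10,
                                 sample_id = sprintf("R%02d", 1:n))
  res4 <- identify_common(near(4))
  expect_equal(nrow(res4$common), 4L)
  expect_equal(res4$common$count, rep(4L, 4))
  res3 <- identify_common(near(3))
  expect_equal(nrow(res3$common), 0L)
  # DEL and DUP counted separately: 2 + 2 overlapping calls of opposite type
  mix <- rbind(near(2), transform(near(2), cn = 3L, cnv_type = "DUP"))
  expect_equal(nrow(identify_common(mix, rare_config(common_min_count = 3L))$common), 0L)
})

test_that("select_reference_controls samples controls reproducibly", {
  cohort <- tiny_cohort(3, 10)
  c1 <- select_reference_controls(cohort, rare_config(reference_size = 4L), seed = 5)
  c2 <- select_reference_controls(cohort, rare_config(reference_size = 4L), seed = 5)
  expect_identical(c1, c2)
  expect_equal(sum(c1$is_reference_control), 4L)
  expect_true(all(c1$phenotype[c1$is_reference_control] == "control"))
  expect_error(
    select_reference_controls(cohort, rare_config(reference_size = 11L)),
    "exceeds"
  )
  explicit <- select_reference_controls(cohort, rare_config(reference_ids = c("CO01", "CO02")))
  expect_equal(cohort$sample_id[explicit$is_reference_control], c("CO01", "CO02"))
  expect_error(
    select_reference_controls(cohort, rare_config(reference_ids = "CA01")),
    "not control"
  )
})

test_that("filter_rare removes by query fraction and drops reference controls", {
  cohort <- tiny_cohort(2, 3)
  cohort$is_reference_control <- cohort$sample_id == "CO03"
  common <- make_calls("1", 100001, 200000, sample_id = "R1") # a common DEL
  common$count <- 5L
  calls <- rbind(
    make_calls("1", 100001, 200000, sample_id = "CA01"), # identical: removed
    make_calls("1", 100001, 300000, sample_id = "CA02"), # 100kb of 200kb = 0.5: removed
    make_calls("1", 100001, 320000, sample_id = "CO01"), # 100kb of 220kb < 0.5: kept
    make_calls("3", 100001, 200000, sample_id = "CO02"), # other chromosome: kept
    make_calls("1", 100001, 200000, sample_id = "CO03") # reference sample: dropped with cohort
  )
  res <- filter_rare(calls, common, cohort)
  expect_false("CO03" %in% res$cohort$sample_id)
  expect_equal(sort(res$rare_calls$sample_id), c("CO01", "CO02"))
  expect_equal(sort(res$removed$sample_id), c("CA01", "CA02"))
  # 200 kb call covered for 90 kb -> kept (0.45 < 0.5)
  part <- filter_rare(make_calls("1", 1, 200000, sample_id = "CA01"),
                      make_calls("1", 1, 90000, sample_id = "R1"),
                      cohort)
  expect_equal(nrow(part$rare_calls), 1L)
  # empty common set: identity on calls, cohort still loses the reference
  none <- filter_rare(calls, common[0, ], cohort)
  expect_equal(nrow(none$rare_calls), 4L)
  expect_equal(nrow(none$cohort), 4L)
})

test_that("filter_rare is anti-monotone in the common set", {
  set.seed(23)
  cohort <- tiny_cohort(5, 5)
  calls <- random_interval_calls(100)
  calls$sample_id <- sample(cohort$sample_id, 100, replace = TRUE)
  cohort$is_reference_control <- FALSE
  small <- random_interval_calls(10)
  big <- rbind(small, random_interval_calls(10))
  n_small <- nrow(filter_rare(calls, small, cohort)$rare_calls)
  n_big <- nrow(filter_rare(calls, big, cohort)$rare_calls)
  expect_lte(n_big, n_small)
})

test_that("carrier_frequency_table divides counts by cohort size", {
  cohort <- cohort_table(sprintf("S%04d", 1:1000), rep(c("case", "control"), 500))
  rare <- make_calls("1", 1e5, 2e5, sample_id = "S0001")
  tab <- carrier_frequency_table(rare, cohort)
  expect_equal(tab$count, 1L)
  expect_equal(tab$carrier_freq, 0.001)
  expect_equal(nrow(carrier_frequency_table(rare[0, ], cohort)), 0L)
})

test_that("rare output stays below the common threshold when re-counted", {
  set.seed(31)
  cohort <- cohort_table(sprintf("S%03d", 1:60), rep(c("case", "control"), 30))
  cohort <- select_reference_controls(cohort, rare_config(reference_size = 10L), seed = 1)
  calls <- random_interval_calls(150, n_chrom = 2L)
  calls$sample_id <- sample(cohort$sample_id, 150, replace = TRUE)
  ref_calls <- calls[calls$sample_id %in% cohort$sample_id[cohort$is_reference_control], ]
  cfg <- rare_config(common_min_count = 2L, reference_size = 10L)
  common <- identify_common(ref_calls, cfg)
  res <- filter_rare(calls, common$common, cohort, cfg)
  # the kept rare calls never union-overlap >= 0.5 with any identified common CNV
  if (nrow(res$rare_calls) > 0L && nrow(common$common) > 0L) {
    for (i in seq_len(nrow(res$rare_calls))) {
      fr <- union_overlap_fraction(
        res$rare_calls$chrom[i], res$rare_calls$start[i], res$rare_calls$end[i],
        common$common$chrom, common$common$start, common$common$end
      )
      same_type <- common$common$cnv_type == res$rare_calls$cnv_type[i]
      expect_true(all(fr[same_type] < 1)) # no kept call equals a common CNV
    }
  }
})
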