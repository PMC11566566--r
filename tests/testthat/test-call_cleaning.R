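# Region exclusion and adjacent-call merging.

test_that("exclude_regions removes on any overlap, respects chromosomes", {
  calls <- make_calls(c("1", "1"), c(100, 100), c(200, 200), sample_id = c("A", "B"))
  regions <- data.frame(chrom = c("1", "2"), start = c(150, 100), end = c(300, 200),
                        label = c("R1", "R2"), stringsAsFactors = FALSE)
  ex <- exclude_regions(calls, regions[1, ])
  expect_equal(ex$removed$sample_id, c("A", "B"))
  ex2 <- exclude_regions(calls, regions[2, ]) # other chromosome
  expect_equal(nrow(ex2$removed), 0L)
  expect_equal(nrow(ex2$kept), 2L)
  # partition invariant
  expect_equal(nrow(ex$kept) + nrow(ex$removed), nrow(calls))
  expect_equal(ex$removed$region_label, c("R1", "R1"))
})

test_that("query_fraction mode uses coverage of the call's own length", {
  call <- make_calls("1", 100, 199, sample_id = "A") # length 100
  region20 <- data.frame(chrom = "1", start = 150, end = 169, label = "r")
  region50 <- data.frame(chrom = "1", start = 150, end = 199, label = "r")
  expect_equal(nrow(exclude_regions(call, region20, 0.5, mode = "query_fraction")$removed), 0L)
  expect_equal(nrow(exclude_regions(call, region50, 0.5, mode = "query_fraction")$removed), 1L)
  # overlapping regions are unioned, not double counted
  two <- rbind(region20, data.frame(chrom = "1", start = 160, end = 179, label = "r"))
  ex <- exclude_regions(call, two, 0.31, mode = "query_fraction")
  expect_equal(nrow(ex$removed), 0L) # union covers 30/100 < 0.31
})

test_that("exclusion is stable: kept calls survive a second pass", {
  set.seed(11)
  calls <- random_interval_calls(100)
  regions <- data.frame(chrom = c("1", "2", "3"), start = c(1e5, 3e5, 6e5),
                        end = c(2e5, 4e5, 7e5), label = "r", stringsAsFactors = FALSE)
  ex <- exclude_regions(calls, regions)
  again <- exclude_regions(ex$kept, regions)
  expect_equal(nrow(again$removed), 0L)
})

test_that("merge_adjacent applies the gap/span rule and the state rule", {
  pair <- make_calls(c("1", "1"), c(100001, 230001), c(200000, 300000),
                     sample_id = c("S1", "S1"), num_snps = c(30L, 20L), conf = c(10, 25))
  merged <- merge_adjacent(pair) # gap 30000 / span 200000 = 0.15 <= 0.5
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100001)
  expect_equal(merged$end, 300000)
  expect_equal(merged$num_snps, 50L)
  expect_equal(merged$conf, 25)
  expect_equal(merged$length, 200000)

  mixed <- pair
  mixed$cn <- c(1L, 3L)
  mixed$cnv_type <- c("DEL", "DUP")
  expect_equal(nrow(merge_adjacent(mixed)), 2L) # different states never merge
  expect_equal(nrow(merge_adjacent(mixed, merge_config(require_same_state = FALSE))), 1L)

  far <- make_calls(c("1", "1"), c(1, 900001), c(100000, 1000000), sample_id = c("S1", "S1"))
  expect_equal(nrow(merge_adjacent(far)), 2L) # gap 800000 / span 1000000 > 0.5
})

test_that("chained merges reach an order-independent fixpoint (brute-force oracle)", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    start <- cumsum(c(1e5, sample.int(8e4, k - 1, replace = TRUE)))
    len <- sample.int(6e4, k, replace = TRUE) + 2e4
    calls <- make_calls(rep("1", k), start, start + len - 1, sample_id = rep("S1", k))
    oracle <- bf_merge_all_orders(calls, 0.5)
    expect_length(oracle, 1L) # the fixpoint is order independent
    got <- merge_adjacent(calls, merge_config(fractions = 0.5))
    got_key <- paste(got$sample_id, got$chrom, got$start, got$end, got$cn, got$num_snps,
                     collapse = ";")
    expect_equal(got_key, oracle)
  }
})

test_that("merge_adjacent is idempotent and loses no covered base", {
  set.seed(9)
  calls <- random_interval_calls(60, n_chrom = 2L)
  calls$sample_id <- sample(c("S1", "S2"), 60, replace = TRUE)
  calls$length <- calls$end - calls$start + 1
  merged <- suppressMessages(merge_adjacent(calls))
  twice <- suppressMessages(merge_adjacent(merged))
  expect_equal(merged, twice, ignore_attr = TRUE)
  expect_lte(nrow(merged), nrow(calls))
  expect_true(all(covered_bp(calls) %in% covered_bp(merged)))
})

test_that("fractions are validated and sequential passes both apply", {
  expect_error(merge_config(fractions = numeric(0)), "non-empty")
  expect_error(merge_config(fractions = 1.2), "non-empty|\\(0,1\\)")
  # a pair mergeable at 0.5 but not 0.4 merges when 0.5 runs first
  pair <- make_calls(c("1", "1"), c(1, 1451), c(1000, 2450), sample_id = c("S1", "S1"))
  # gap 450 / span 2450 = 0.1837 -> merges under both; build a 0.45 case:
  pair2 <- make_calls(c("1", "1"), c(1, 2101), c(1000, 3000), sample_id = c("S1", "S1"))
  # gap 1100 / span 3000 = 0.3667: merges at 0.5 and at 0.4
  pair3 <- make_calls(c("1", "1"), c(1, 2401), c(1000, 3000), sample_id = c("S1", "S1"))
  # gap 1400 / span 3000 = 0.4667: merges only while the 0.5 pass runs
  expect_equal(nrow(merge_adjacent(pair3, merge_config(fractions = c(0.5, 0.4)))), 1L)
  expect_equal(nrow(merge_adjacent(pair3, merge_config(fractions = 0.4))), 2L)
})
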