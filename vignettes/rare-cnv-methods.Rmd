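---
title: "Rare CNV case-control analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV case-control analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`rarecnv` implements the analysis half of a rare copy number variant (CNV)
case-control study from SNP-array data: it starts from per-sample CNV calls
(as produced by an HMM caller such as PennCNV) and per-sample signal-quality
summaries, and carries them through sample QC, call cleaning, rare/common
partitioning, burden and frequency association statistics, and gene-set
enrichment. CNV *calling* itself — deriving segments from LRR/BAF intensity
traces — is out of scope, as is the upstream relatedness/stratification
analysis that yields the core-sample list; both are consumed as inputs.

# The pipeline model

## Sample quality control

A sample passes QC iff

* `LRR_SD < 0.3` — standard deviation of the log R ratio (unitless signal
  noise),
* `BAF_drift < 0.01` — systematic deviation of B-allele frequencies from
  their expected clusters,
* `|WF| < 0.05` — waviness factor, a signed measure of genomic-wave
  artifact,
* `NumCNV <= 50` — number of calls in the sample.

The first three rules are strict `<` bounds; the call-count rule instead
fails only samples *strictly above* the limit. The asymmetry is deliberate:
the signal thresholds are quoted as strict inequalities while the
call-count rule is quoted as "samples with more than 50 were removed", so a
sample sitting exactly at 50 passes. The NumCNV limit has no
platform-universal default — 50 suits a genome-wide array cohort with a
typical ~10 calls/sample load and should be re-examined per study via
`qc_summary_table()`, which provides the pass/fail box-plot numbers. Calls
belonging to failing samples leave the analysis together with the sample.

## Call cleaning

Calls intersecting spurious regions (HLA, immunoglobulin loci, centromeric
and telomeric neighbourhoods — supplied as BED files) are removed on any
1 bp overlap by default; a `query_fraction` mode removes only calls whose
own length is covered above a threshold by the union of regions, for
studies wanting a gentler rule.

Adjacent same-sample, same-copy-number calls are merged when the gap
between them is small relative to the merged span:
`gap / span <= f`, with `gap = next.start - prev.end - 1` and `span` the
merged extent. The shipped fractions `(0.5, 0.4)` are applied as sequential
passes, each iterated to a fixpoint — mirroring the PennCNV
`clean_cnv combineseg` semantics. On small inputs the fixpoint is provably
order-independent (the test suite enumerates all merge orders), merging
never increases the call count, and no covered base pair is lost. The
merged confidence score is the larger parent's (no principled combination
of the two exists; the maximum is conservative). One deliberate deviation
from a literal reading of the rule: the merged end coordinate is
`max(prev.end, next.end)` rather than `next.end`, so a nested call can
never truncate its host.

## Size and probe filtering

Only calls *strictly* larger than 50 kb and covered by *strictly* more than
5 probes are analysed; SNP arrays do not call smaller events reliably.
Both inequalities are strict, matching the "larger than / more than"
phrasing; implementations using `>=` will count boundary calls differently,
which is why removals are reported separately.

## Burden

Four per-sample metrics: RATE (segment count), PROP (0/1 any-segment
indicator), TOTKB (total kb spanned, bp/1000 exactly) and AVGKB (mean
segment kb, undefined for zero-CNV samples and averaged over carriers
only). The test statistic per metric is the case mean minus the control
mean; phenotype labels are permuted jointly across metrics and the
empirical p uses the add-one estimator `(1 + exceedances)/(n_perm + 1)`,
bounded below by `1/(n_perm + 1)`. The default is one-sided
(case > control), the usual convention for CNV burden; the sidedness of the
original analysis is not documented, so a two-sided option exists.

## Rare/common partitioning

Commonness is determined in a reference subset of healthy controls
(default: 200, drawn with a seeded uniform sample when no explicit list is
given). Within each CNV type separately, each reference call receives a
count of reference calls (itself included) whose **union-intersection
overlap** `|A∩B| / |A∪B|` is at least 0.5; calls with count >= 4 — a 2%
carrier frequency at the default reference size — are common. Discovery
and removal deliberately use different overlap metrics: removal excises
calls of the remaining cohort whose own length is covered >= 50% by a
common CNV (the asymmetric BEDTools `-f` query fraction, per-pair). The
asymmetry mirrors the two tools the procedure descends from (PLINK
frequency counting and BEDTools filtering). Cross-type overlap never makes
a variant common. The reference controls are then dropped from the cohort
to avoid re-using them in the test statistics, and
`carrier_frequency_table()` lets the user verify that everything kept sits
below the common threshold.

## Association statistics

Rare calls are binned by length — `[50,100)`, `[100,200)`, `[200,500)`,
`[500,1000)` kb and an unbounded `>= 1000 kb` bin, lower edge inclusive —
and counted per type and bin in cases (`a` of `n1`) and controls (`b` of
`n2`). Frequencies are counts over cohort sizes: a sample carrying two
qualifying CNVs contributes two, so frequencies are CNV rates, not carrier
rates; the distinction only matters for multi-CNV samples and is noted in
the output. Two p-value dialects coexist by design:

* `P.value` — the two-proportion chi-square **with** Yates continuity
  correction (clamped at zero, so equal proportions give p = 1);
* `P` — the Pearson chi-square on the 2x2 **without** correction,
  accompanying the odds ratio.

The odds ratio is `a(n2-b) / (b(n1-a))` with the Woolf log-scale normal
confidence interval `exp(ln OR ± z √(1/a + 1/(n1-a) + 1/b + 1/(n2-b)))`.
When a cell is zero the Haldane–Anscombe correction (0.5 on all four
cells) applies to the OR and CI only, never to the printed counts, and is
flagged. No multiple-testing adjustment is applied; p-values are raw, and
the report says so.

## Enrichment

Per sample, GCNT sums over its CNVs the number of distinct genes each CNV
intersects (>= 1 bp), so a gene hit by two CNVs counts twice — the
covariate tracks the *rate of gene-impacting CNVs*, and a
distinct-genes-per-sample mode is available. The genic test fits the
logistic model `phenotype ~ GCNT + NSEG + AVGKB` and the gene-set test
`phenotype ~ GCNT_set + GCNT + NSEG + AVGKB`, each statistic being the
first coefficient; NSEG and AVGKB adjust for overall CNV rate and size,
and AVGKB is 0 for zero-CNV samples so the model is defined for everyone.
The exact covariate structure of the original PLINK-based analysis is not
printed anywhere; this formula set is this package's documented choice,
and it is configurable in the sense that both tests and both counting
modes are exposed. Empirical p-values come from two-sided phenotype-label
permutation on `|coefficient|` (the original direction is undocumented),
with permutation indices shared between the two tests in one run.
Non-converged permutation fits are excluded from both the numerator and
the denominator of the empirical p and reported via `converged_fraction`;
constant predictors short-circuit to coefficient 0, p = 1.

# The synthetic cohort generator

`simulate_cohort()` / `generate_cohort()` emit every input the pipeline
reads. The defaults describe the stated world of a large autoimmune
case-control array study and are fixed once:

* 1182 cases, 4010 controls (200 of which will serve as the reference),
* Poisson(10) background calls per sample (a post-calling load of ~10
  calls/sample), log-uniform lengths 20–2000 kb, 55% deletions,
* probe spacing 5 kb (a ~700k-marker genome-wide array on ~3 Gb),
* 2% of samples pushed past exactly one QC threshold,
* two common loci at 10% carrier frequency (one deletion, one
  duplication),
* one planted >1 Mb deletion with a carrier odds ratio of 4 (control
  carrier frequency 0.5%).

Carrier endpoint jitter is bounded to 5% of the locus length per side, so
any two carriers of a locus retain a union-intersection overlap of at
least ~2/3 — comfortably above the 0.5 discovery threshold; without that
bound the common-locus recovery tests would be flaky for reasons unrelated
to the code under test. Probe counts come from a uniform grid
(`ceil(length / spacing)`), which is enough to exercise the probe filter
but does not emulate real probe density variation.

What the generator does **not** emulate: LRR/BAF signal traces and caller
behaviour (calls appear ex nihilo), linkage between loci, length-dependent
call quality, batch effects, and population structure (the core-id list is
a random 98% subset rather than a PCA result). A green test therefore
establishes the correctness of the *analysis* stages on data with known
structure — not the end-to-end fidelity of a calling pipeline on real
intensity data.

# Numerical choices and degenerate inputs

* All statistics are computed in double precision; 2x2 inputs are coerced
  from integer to double before forming cross-products (the Pearson
  numerator overflows 32-bit integers already at cohort sizes of a few
  thousand).
* Yates correction is clamped at zero statistic, so equal proportions give
  exactly p = 1.
* Degenerate 2x2 margins (both counts zero, or both at their maximum) are
  errors for the odds ratio; empty association bins are emitted with zero
  counts and NA statistics rather than errors. Counts exceeding the cohort
  size (possible on dense synthetic data, where the binomial reading of
  the 2x2 breaks down) yield NA statistics with a warning.
* Sorting of calls is canonical (chromosome string order with numeric-
  first display ordering, then start); merge input is re-sorted with a
  logged message rather than rejected.
* Empirical p-values always use the add-one estimator and are therefore
  never 0 and never below `1/(n_perm+1)`.

# Known limitations

* Frequencies in the association tables are CNV counts over cohort sizes;
  for samples with several CNVs in one bin these are not carrier
  frequencies (see above).
* The enrichment model formula is a documented default, not a reproduction
  of an undocumented original.
* Chromosome handling is string-based; only a leading "chr" is stripped
  and X/Y/MT upper-cased. No genome-build awareness or liftover.
* The region-exclusion default (any 1 bp overlap) is blunt by intent;
  cohorts with very large calls near, e.g., centromeres may prefer the
  query-fraction mode.
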