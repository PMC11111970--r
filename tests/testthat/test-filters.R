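make_mixed_callset <- function(mean_depth = 18) {
  rec <- sv_records(
    id = paste0("r", 1:6),
    svtype = c("DEL", "DEL", "BND", "BND", "DUP", "INV"),
    chrom1 = c("chr3", "chr1", "chr12", "chr1", "chr1", "chr2"),
    pos1 = c(35660443L, 1000L, 11874372L, 5000L, 2000L, 3000L),
    chrom2 = c("chr3", "chr1", "chr21", "chr1", "chr1", "chr2"),
    pos2 = c(61437807L, 51000L, 34948109L, 105000L, 102001L, 103001L),
    size = c(25777364L, 50000L, 0L, 100000L, 100001L, 100001L),
    support = 10L, position_coverage = 20)
  sv_callset(rec, "mix", technology = "long_read", mean_depth = mean_depth)
}

test_that("large-SV pre-filter keeps >100 kb and interchromosomal breakends", {
  res <- prefilter_large(make_mixed_callset())
  kept <- res$retained$records$id
  expect_setequal(kept, c("r1", "r3", "r5", "r6"))
  expect_equal(res$discarded_count, 2L)  # 50 kb DEL, intrachromosomal 100 kb BND
  # idempotent
  again <- prefilter_large(res$retained)
  expect_equal(again$retained$records, res$retained$records)
  expect_equal(again$discarded_count, 0L)
})

test_that("support/coverage thresholds follow the stated arithmetic", {
  mk <- function(support, coverage, qpass = TRUE, mean_depth = 18) {
    cs <- toy_callset("t", pos1 = 1000L, support = support,
                      quality_pass = qpass, position_coverage = coverage,
                      mean_depth = mean_depth)
    support_coverage_filter(cs)
  }
  # mean depth 18: 5 >= 5, 5 > 3.6, 20 <= 27 -> retained
  expect_equal(nrow(mk(5L, 20)$retained$records), 1L)
  # mean depth 34.7: support must strictly exceed 6.94
  expect_equal(mk(6L, 20, mean_depth = 34.7)$rejected$reason,
               "support-fraction")
  expect_equal(nrow(mk(7L, 20, mean_depth = 34.7)$retained$records), 1L)
  # criterion 1 dominates regardless of support
  expect_equal(mk(100L, 20, qpass = FALSE)$rejected$reason, "quality")
  # coverage cap is inclusive at 150%
  expect_equal(nrow(mk(10L, 27)$retained$records), 1L)
  expect_equal(mk(10L, 27.1)$rejected$reason, "coverage")
  expect_equal(mk(10L, NA)$rejected$reason, "no-coverage")
  expect_equal(mk(4L, 20)$rejected$reason, "min-support")
})

test_that("every record is either retained or rejected with one reason", {
  set.seed(3)
  cfg <- sim_config(seed = 3, n_truth_sv = c(DEL = 80L, DUP = 30L),
                    n_translocations = 10L)
  truth <- make_truth(cfg)
  for (p in cfg$tech_profiles) {
    cs <- simulate_sv_callset(truth, p, cfg)
    res <- support_coverage_filter(cs)
    expect_equal(nrow(res$retained$records) + nrow(res$rejected),
                 nrow(cs$records))
    expect_false(any(res$retained$records$id %in% res$rejected$id))
  }
})

test_that("raising support thresholds never increases the retained count", {
  set.seed(5)
  cfg <- sim_config(seed = 5, n_truth_sv = c(DEL = 100L),
                    n_translocations = 0L)
  truth <- make_truth(cfg)
  cs <- simulate_sv_callset(truth, cfg$tech_profiles[[2]], cfg)
  n_at <- function(min_support = 5L, frac = 0.2, cap = 1.5) {
    nrow(support_coverage_filter(cs, filter_config(
      min_support = min_support, support_depth_fraction = frac,
      coverage_cap_fraction = cap))$retained$records)
  }
  base <- n_at()
  expect_true(all(diff(sapply(c(1L, 5L, 8L, 12L), function(m)
    n_at(min_support = m))) <= 0))
  expect_true(all(diff(sapply(c(0.1, 0.2, 0.5, 0.8), function(f)
    n_at(frac = f))) <= 0))
  expect_true(all(diff(sapply(c(1.1, 1.5, 2.0), function(cc)
    n_at(cap = cc))) >= 0))
  expect_equal(n_at(), base)  # deterministic
})

test_that("exact-support sampling is deterministic and complete", {
  cs <- toy_callset("t", pos1 = c(4000L, 1000L, 3000L, 2000L),
                    support = c(14L, 15L, 15L, 16L))
  got <- sample_by_support(cs)
  expect_equal(got$records$support, c(15L, 15L))
  expect_equal(got$records$pos1, c(1000L, 3000L))  # sorted, stable
  expect_equal(sample_by_support(got)$records, got$records)
  none <- toy_callset("t", pos1 = 1000L, support = 3L)
  expect_equal(nrow(sample_by_support(none)$records), 0L)
})

test_that("cross-callset confirmation honors the distance boundary", {
  cand <- toy_callset("cand", pos1 = 100000L, size = 5000L)
  near <- function(d) toy_callset("o", pos1 = 100000L + d, size = 5000L)
  expect_equal(nrow(cross_callset_confirm(cand, list(near(1000L)))$records), 1L)
  expect_equal(nrow(cross_callset_confirm(cand, list(near(1001L)))$records), 0L)
  expect_equal(nrow(cross_callset_confirm(cand, list(near(0L), near(5L)))$records), 1L)
  expect_equal(nrow(cross_callset_confirm(cand, list())$records), 0L)
})

test_that("size strata follow the Small/Medium/Large boundaries", {
  sizes <- c(99L, 100L, 1000L, 1001L, 10000L, 10001L, 150L, 5000L, 20000L)
  rec <- sv_records(id = paste0("s", seq_along(sizes)), svtype = "DEL",
                    chrom1 = "chr1", pos1 = 1000L, size = sizes)
  res <- stratify_sizes(rec)
  expect_equal(res$n_below_min, 1L)
  expect_equal(unname(res$counts),
               c(sum(sizes >= 100 & sizes <= 1000),
                 sum(sizes > 1000 & sizes <= 10000),
                 sum(sizes > 10000)))
  expect_equal(res$labels[res$records$size == 1000L], "Small")
  expect_equal(res$labels[res$records$size == 1001L], "Medium")
  expect_equal(res$labels[res$records$size == 10001L], "Large")
  expect_equal(sum(res$counts), length(res$labels))
})

test_that("heatmap bins conserve breakpoint counts", {
  rec <- sv_records(
    id = c("a", "b", "c"), svtype = c("DEL", "BND", "DEL"),
    chrom1 = c("chr1", "chr1", "chr2"),
    pos1 = c(500L, 999999L, 1500000L),
    chrom2 = c("chr1", "chr2", "chr2"),
    pos2 = c(900L, 3L, 1500900L),
    size = c(400L, 0L, 900L))
  bins <- heatmap_bins(rec, window = 1e6)
  # intrachromosomal events count once, interchromosomal twice
  expect_equal(sum(bins$count), 2L + 2L * 1L)
  expect_equal(bins$count[bins$chrom == "chr1" & bins$start == 1], 2L)
  expect_equal(bins$count[bins$chrom == "chr2" & bins$start == 1], 1L)
  expect_equal(bins$count[bins$chrom == "chr2" & bins$start == 1000001], 1L)
  expect_equal(nrow(heatmap_bins(rec[0, ], 1e6)), 0L)
})

test_that("SNV impact filter applies rarity, consequence and transcript fraction", {
  snvs <- data.frame(
    chrom = "chr1", pos = 1:6 * 100L, ref = "A", alt = "T",
    depth = 30L, alt_depth = 15L, vaf = 0.5,
    population_af = c(0.001, NA, 1e-5, NA, 1e-4, NA),
    consequence = c("LOF", "NMD", "other", "LOF", "NMD", "LOF"),
    affected_transcript_fraction = c(0.5, 0.25, 0.9, 0.24, 0.3, NA),
    stringsAsFactors = FALSE)
  got <- snv_impact_filter(snvs)
  # row 1 too common, row 3 wrong consequence, row 4 below 25%, row 6 unknown
  expect_equal(got$pos, c(200L, 500L))
})
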