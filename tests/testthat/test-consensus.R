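test_that("self-merge groups every record with its copy", {
  a <- toy_callset("A", pos1 = c(1000L, 50000L, 200000L))
  b <- a; b$name <- "B"
  cons <- merge_callsets(list(a, b))
  expect_equal(length(cons$groups), 3L)
  expect_true(all(vapply(cons$groups, function(g)
    setequal(g$supported_by, c("A", "B")), logical(1))))
})

test_that("breakpoint distance threshold separates groups at 1 kb", {
  # brute-force oracle: two records co-cluster iff both end distances <= 1000
  for (offset in c(0L, 999L, 1000L, 1001L, 5000L)) {
    a <- toy_callset("A", pos1 = 100000L, size = 5000L)
    b <- toy_callset("B", pos1 = 100000L + offset, size = 5000L)
    cons <- merge_callsets(list(a, b))
    expect_equal(length(cons$groups), if (offset <= 1000L) 1L else 2L,
                 info = paste("offset", offset))
  }
})

test_that("type and strand agreement are required for co-clustering", {
  a <- toy_callset("A", pos1 = 100000L, svtype = "DEL")
  b <- toy_callset("B", pos1 = 100000L, svtype = "DUP")
  expect_equal(length(merge_callsets(list(a, b))$groups), 2L)
  # strand-incompatible breakends at identical coordinates stay apart
  bnd <- function(name, sp) sv_callset(
    sv_records(id = "x", svtype = "BND", chrom1 = "chr1", pos1 = 100L,
               chrom2 = "chr2", pos2 = 5000L, size = 0L,
               strand_pair = sp),
    name, technology = "long_read", mean_depth = 20)
  expect_equal(length(merge_callsets(list(bnd("A", "++"),
                                          bnd("B", "--")))$groups), 2L)
  # missing strand is compatible with anything
  expect_equal(length(merge_callsets(list(bnd("A", "++"),
                                          bnd("B", NA)))$groups), 1L)
})

test_that("combination counts match an enumerated toy and sum to group count", {
  # constructed overlaps: 2 records only in A, 1 shared A+B, 3 shared by all
  far <- function(k) 1e6 * k
  a <- toy_callset("A", pos1 = as.integer(far(1:6)))
  b <- toy_callset("B", pos1 = as.integer(far(3:6)))
  c_ <- toy_callset("C", pos1 = as.integer(far(4:6)))
  cons <- merge_callsets(list(a, b, c_))
  cc <- combination_counts(cons)
  got <- stats::setNames(cc$count, cc$combination)
  expect_equal(got[["A"]], 2L)
  expect_equal(got[["A+B"]], 1L)
  expect_equal(got[["A+B+C"]], 3L)
  expect_equal(sum(cc$count), length(cons$groups))
})

test_that("combination counts are invariant under callset order", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_truth_sv = c(DEL = 40L, INV = 20L),
                    n_translocations = 5L)
  truth <- make_truth(cfg)
  css <- lapply(cfg$tech_profiles, function(p)
    simulate_sv_callset(truth, p, cfg))
  cc1 <- combination_counts(merge_callsets(css))
  cc2 <- combination_counts(merge_callsets(rev(css)))
  expect_equal(cc1, cc2)
})

test_that("consensus subsets nest and honor the empty requirement", {
  set.seed(4)
  cfg <- sim_config(seed = 4, n_truth_sv = c(DEL = 50L),
                    n_translocations = 0L)
  truth <- make_truth(cfg)
  css <- lapply(cfg$tech_profiles, function(p)
    simulate_sv_callset(truth, p, cfg))
  cons <- merge_callsets(css)
  all3 <- consensus_subset(cons, c("illumina", "ont", "pacbio"))
  lr <- consensus_subset(cons, c("ont", "pacbio"))
  expect_true(length(all3$groups) <= length(lr$groups))
  ids3 <- vapply(all3$groups, function(g) g$members$id[1], character(1))
  idsl <- vapply(lr$groups, function(g) g$members$id[1], character(1))
  expect_true(all(ids3 %in% idsl))
  expect_equal(length(consensus_subset(cons, character(0))$groups),
               length(cons$groups))
  expect_error(consensus_subset(cons, "nonesuch"), "unknown")
})

test_that("merging a merged representative set with itself is idempotent", {
  set.seed(9)
  cfg <- sim_config(seed = 9, n_truth_sv = c(DEL = 60L, DUP = 20L),
                    n_translocations = 10L)
  truth <- make_truth(cfg)
  css <- lapply(cfg$tech_profiles, function(p)
    simulate_sv_callset(truth, p, cfg))
  cons <- merge_callsets(css)
  reps <- consensus_records(cons)
  rcs <- sv_callset(reps, "reps", technology = "long_read", mean_depth = 20)
  again <- merge_callsets(list(rcs))
  expect_equal(length(again$groups), length(cons$groups))
})

test_that("min-size and blacklist exclusions conserve the input count", {
  rec <- sv_records(id = paste0("r", 1:5),
                    svtype = c("DEL", "DEL", "BND", "DEL", "DUP"),
                    chrom1 = "chr1",
                    pos1 = c(1000L, 5000L, 9000L, 20000L, 400000L),
                    chrom2 = c("chr1", "chr1", "chr2", "chr1", "chr1"),
                    pos2 = c(1050L, 5500L, 700L, 20500L, 400700L),
                    size = c(50L, 500L, 0L, 500L, 700L))
  cs <- sv_callset(rec, "A", technology = "long_read", mean_depth = 20)
  bl <- load_blacklist(write_bed(data.frame("chr1", 19000L, 21000L)))
  cons <- merge_callsets(list(cs),
                         consensus_config(blacklist = bl))
  n_members <- sum(vapply(cons$groups, function(g) nrow(g$members),
                          integer(1)))
  expect_equal(cons$n_excluded_min_size, 1L)   # the 50 bp DEL; BND exempt
  expect_equal(cons$n_excluded_blacklist, 1L)
  expect_equal(cons$n_excluded_min_size + cons$n_excluded_blacklist +
                 n_members, nrow(rec))
  # BND below "size" threshold survives (no length)
  expect_true(any(vapply(cons$groups, function(g)
    g$representative$svtype == "BND", logical(1))))
})

test_that("group allele fractions average members and flag het/hom modes", {
  a <- toy_callset("A", pos1 = c(1e6L, 2e6L), allele_fraction = c(0.4, 1.0))
  b <- toy_callset("B", pos1 = c(1e6L, 2e6L), allele_fraction = c(0.6, 1.0))
  cons <- merge_callsets(list(a, b))
  af <- sort(as.numeric(sv_allele_fractions(cons)))
  expect_equal(af, c(0.5, 1.0))
  # groups with no AF data are skipped and counted
  c_ <- toy_callset("C", pos1 = 5e6L)
  cons2 <- merge_callsets(list(c_))
  af2 <- sv_allele_fractions(cons2)
  expect_length(af2, 0L)
  expect_equal(attr(af2, "n_skipped"), 1L)
})

test_that("synthetic het/hom mixtures give a bimodal consensus AF summary", {
  set.seed(21)
  cfg <- sim_config(seed = 21, n_truth_sv = c(DEL = 200L),
                    n_translocations = 0L)
  truth <- make_truth(cfg)
  css <- lapply(cfg$tech_profiles, function(p)
    simulate_sv_callset(truth, p, cfg))
  af <- as.numeric(sv_allele_fractions(merge_callsets(css)))
  expect_true(all(af >= 0 & af <= 1))
  expect_gt(sum(af > 0.3 & af < 0.7), 20)   # heterozygous mode near 0.5
  expect_gt(sum(af > 0.9), 20)              # homozygous mode near 1.0
  expect_lt(sum(af >= 0.7 & af <= 0.9), sum(af > 0.9))
})
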