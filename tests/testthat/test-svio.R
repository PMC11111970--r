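test_that("symbolic SV records are normalized with size = end - start", {
  path <- write_vcf_lines(c(
    "chr3\t35660443\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=61437807;SUPPORT=10",
    "chr1\t1000\tdup1\tN\t<DUP>\t60\tPASS\tSVTYPE=DUP;SVLEN=5000;SUPPORT=4",
    "chr1\t50000\tins1\tN\t<INS>\t60\tLowQual\tSVTYPE=INS;SVLEN=300;SUPPORT=7"))
  cs <- parse_sv_vcf(path, caller = "sniffles", technology = "long_read",
                     mean_depth = 18)
  rec <- cs$records
  expect_equal(nrow(rec), 3L)
  del <- rec[rec$id == "del1", ]
  expect_equal(del$size, 61437807L - 35660443L)
  expect_equal(del$size, 25777364L)
  dup <- rec[rec$id == "dup1", ]
  expect_equal(dup$pos2, 6000L)   # SVLEN fallback when END is absent
  ins <- rec[rec$id == "ins1", ]
  expect_equal(ins$size, 300L)
  expect_equal(ins$pos2 - ins$pos1, ins$size)
  expect_false(ins$quality_pass)
  expect_equal(rec$support, c(10L, 4L, 7L))
})

test_that("header-only VCF yields an empty callset", {
  path <- write_vcf_lines(character(0))
  cs <- parse_sv_vcf(path, caller = "tiddit", technology = "short_read",
                     mean_depth = 34)
  expect_s3_class(cs, "sv_callset")
  expect_equal(nrow(cs$records), 0L)
})

test_that("BND mate pairs collapse to one record with the smaller end first", {
  path <- write_vcf_lines(c(
    "chr12\t11874372\tbnd1\tN\tN[chr21:34948109[\t60\tPASS\tSVTYPE=BND;SUPPORT=8",
    "chr21\t34948109\tbnd1_mate\tN\t]chr12:11874372]N\t60\tPASS\tSVTYPE=BND;SUPPORT=8"))
  cs <- parse_sv_vcf(path, caller = "sniffles", technology = "long_read",
                     mean_depth = 18)
  rec <- cs$records
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$chrom1, "chr12")
  expect_equal(rec$pos1, 11874372L)
  expect_equal(rec$chrom2, "chr21")
  expect_equal(rec$pos2, 34948109L)
  expect_equal(rec$size, 0L)
})

test_that("BND deduplication halves a mate-complete VCF", {
  alts <- list(c("N[chr2:5000[", "]chr1:1000]N"),
               c("N]chr2:9000]", "N]chr1:2000]"),
               c("[chr2:13000[N", "[chr1:3000[N"))
  body <- unlist(lapply(seq_along(alts), function(i) c(
    sprintf("chr1\t%d\tb%d\tN\t%s\t60\tPASS\tSVTYPE=BND;SUPPORT=5",
            i * 1000L, i, alts[[i]][1]),
    sprintf("chr2\t%d\tb%dm\tN\t%s\t60\tPASS\tSVTYPE=BND;SUPPORT=5",
            i * 4000L + 1000L, i, alts[[i]][2]))))
  cs <- parse_sv_vcf(write_vcf_lines(body), caller = "x",
                     technology = "long_read", mean_depth = 20)
  expect_equal(nrow(cs$records), 3L)
  expect_true(all(cs$records$chrom1 == "chr1"))
})

test_that("malformed BND ALT raises an error naming the record", {
  path <- write_vcf_lines(
    "chr1\t1000\tbadbnd\tN\tN[chr2:notanumber[\t60\tPASS\tSVTYPE=BND")
  expect_error(parse_sv_vcf(path, "x", "long_read", 20), "badbnd")
})

test_that("missing END and SVLEN is rejected, missing support warns", {
  path <- write_vcf_lines("chr1\t1000\tnosize\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL")
  expect_error(parse_sv_vcf(path, "x", "long_read", 20), "nosize")
  path2 <- write_vcf_lines(
    "chr1\t1000\tnosup\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000")
  expect_warning(cs <- parse_sv_vcf(path2, "x", "long_read", 20), "support")
  expect_equal(cs$records$support, 0L)
})

test_that("write/parse round-trips all five SV types field by field", {
  rec <- sv_records(
    id = c("d1", "u1", "v1", "i1", "b1", "b2"),
    svtype = c("DEL", "DUP", "INV", "INS", "BND", "BND"),
    chrom1 = c("chr1", "chr1", "chr2", "chr2", "chr1", "chr3"),
    pos1 = c(1000L, 9000L, 5000L, 70000L, 500L, 100L),
    chrom2 = c("chr1", "chr1", "chr2", "chr2", "chr2", "chr3"),
    pos2 = c(2500L, 15000L, 45000L, 70150L, 8000L, 4100L),
    size = c(1500L, 6000L, 40000L, 150L, 0L, 4000L),
    support = c(5L, 8L, 13L, 2L, 21L, 3L),
    strand_pair = c(NA, NA, NA, NA, "-+", "++"),
    quality_pass = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    position_coverage = c(20, NA, 31, 18, 25, 12),
    allele_fraction = c(0.5, 1.0, NA, 0.25, 0.4, 1.0))
  cs <- sv_callset(rec, name = "rt", caller = "sim",
                   technology = "long_read", mean_depth = 18)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(cs, path)
  back <- parse_sv_vcf(path, caller = "sim", technology = "long_read",
                       mean_depth = 18, name = "rt")
  got <- back$records[match(rec$id, back$records$id), ]
  rownames(got) <- NULL
  expect_equal(got, rec)
})

test_that("round-trip holds for the confirmed REH event table", {
  rec <- reh_truth_records("pacbio")
  cs <- sv_callset(rec, "reh", technology = "long_read", mean_depth = 15)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(cs, path)
  back <- parse_sv_vcf(path, "reh", "long_read", 15)
  got <- back$records[match(rec$id, back$records$id), ]
  rownames(got) <- NULL
  # BND strand defaults to "+-" on write when unspecified
  expect_equal(got[, setdiff(names(got), "strand_pair")],
               rec[, setdiff(names(rec), "strand_pair")])
  intra <- got$chrom1 == got$chrom2
  expect_equal(got$size[intra], got$pos2[intra] - got$pos1[intra])
})

test_that("SNV parsing computes VAF from allele depths and drops unusable rows", {
  path <- write_snv_lines(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tAD\t10,10",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tAD\t0,12",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.\tAD\t."))
  expect_message(snv <- parse_snv_vcf(path), "dropped 1")
  expect_equal(nrow(snv), 2L)
  expect_equal(snv$vaf, c(0.5, 1.0))
  expect_equal(snv$depth, c(20L, 12L))
})

test_that("SnpEff-style LOF/NMD annotation and population AF are read", {
  path <- write_snv_lines(c(
    "chr5\t100\t.\tA\tT\t50\tPASS\tPOP_AF=0.001;LOF=(NR3C1|g1|4|0.25)\tAD\t12,11",
    "chr9\t200\t.\tC\tG\t50\tPASS\tNMD=(PAX5|g2|8|0.50)\tAD\t15,14"))
  snv <- parse_snv_vcf(path)
  expect_equal(snv$consequence, c("LOF", "NMD"))
  expect_equal(snv$affected_transcript_fraction, c(0.25, 0.5))
  expect_equal(snv$population_af, c(0.001, NA))
})

test_that("blacklist point queries honor BED half-open intervals", {
  bed <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(100L, 150L, 500L),
                    end = c(200L, 260L, 600L))
  bl <- load_blacklist(write_bed(bed))
  queries <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr3"),
    pos = c(150L, 100L, 200L, 261L, 501L, 150L))
  got <- blacklist_contains(bl, queries$chrom, queries$pos)
  want <- mapply(point_in_bed, chrom = queries$chrom, pos = queries$pos,
                 MoreArgs = list(bed = bed))
  expect_equal(got, unname(want))
  expect_true(got[1])                       # mid-interval
  expect_false(blacklist_contains(bl, "chr1", 261))
  # overlapping intervals still answer a plain membership query
  expect_true(blacklist_contains(bl, "chr1", 255))
})

test_that("degenerate BED intervals are rejected", {
  expect_error(load_blacklist(write_bed(
    data.frame(c("chr1"), c(200L), c(200L)))), "start")
})
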