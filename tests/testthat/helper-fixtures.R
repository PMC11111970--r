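# Fixtures are built in code: small VCF/BED writers and toy callsets.

write_vcf_lines <- function(body, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"s\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, body), path)
  path
}

write_snv_lines <- function(body, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# one-record-per-event toy callset at given breakpoints
toy_callset <- function(name, pos1, pos2 = pos1 + size, size = 500L,
                        svtype = "DEL", chrom = "chr1", support = 10L,
                        mean_depth = 30, technology = "long_read", ...) {
  n <- max(length(pos1), length(svtype))
  rec <- sv_records(id = paste0(name, "_", seq_len(n)), svtype = svtype,
                    chrom1 = chrom, pos1 = pos1, pos2 = pos2, size = size,
                    support = support, ...)
  sv_callset(rec, name = name, technology = technology,
             mean_depth = mean_depth)
}

# brute-force oracle: is a 1-based point inside any BED (0-based, half-open)
# interval on the chromosome
point_in_bed <- function(bed, chrom, pos) {
  any(bed[[1]] == chrom & bed[[2]] <= pos - 1 & pos - 1 < bed[[3]])
}
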