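Package: svkaryo
Title: Multi-Technology Structural-Variant Consensus and Karyotype
    Profiling for Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the genome of a cancer cell line from
    short- and long-read sequencing callsets: normalization of
    structural-variant (SV) VCFs across caller dialects, cross-callset
    consensus merging with breakpoint-distance clustering, size
    stratification and support/coverage candidate filtering, chromosome
    copy-state calling from depth-of-coverage ratios, loss-of-heterozygosity
    segmentation from SNV allele fractions, fusion-gene candidate screening
    with panel-of-normals subtraction and tiered filtering, and
    sensitivity/false-positive evaluation of SV and fusion callers against
    a confirmed truth set. A synthetic cell-line generator reproduces the
    statistical structure the analysis assumes (binomial heterozygous
    allele fractions, aneuploid depth ratios, caller-like SV and fusion
    callsets), so the full pipeline can be exercised without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
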