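# Normalized SV record model and VCF/BED input-output.
#
# Every caller dialect is reduced to one flat record per event:
# two breakpoints, a type, a size, and the read support the caller
# reported (split reads for long-read data, discordant mates for
# short-read data).

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "BND")
STRAND_PAIRS <- c("++", "+-", "-+", "--")

#' Construct a normalized SV record table
#'
#' Builds the flat per-event table used throughout the package. Breakpoint 1
#' is always the lexicographically smaller (chromosome, position) end.
#' Intrachromosomal events satisfy `size == pos2 - pos1` (insertions are
#' normalized so that `pos2 = pos1 + size`); interchromosomal breakends have
#' `size = 0`.
#'
#' @param id record identifiers (unique within a callset)
#' @param svtype one of `DEL`, `DUP`, `INV`, `INS`, `BND`
#' @param chrom1,pos1 first breakpoint (1-based)
#' @param chrom2,pos2 second breakpoint; defaults to `chrom1` and
#'   `pos1 + size` for intrachromosomal types
#' @param size event size in bp (0 for interchromosomal breakends)
#' @param support supporting reads reported by the caller
#' @param strand_pair breakend orientation (`"++"`, `"+-"`, `"-+"`, `"--"`)
#'   or `NA` for symmetric types
#' @param quality_pass logical, did the record pass the caller's filters
#' @param position_coverage local read depth at the breakpoint, or `NA`
#' @param allele_fraction fraction of reads supporting the variant, or `NA`
#' @return a `data.frame` with one row per SV record
#' @export
sv_records <- function(id, svtype, chrom1, pos1, chrom2 = chrom1,
                       pos2 = pos1 + size, size = 0L, support = 0L,
                       strand_pair = NA_character_, quality_pass = TRUE,
                       position_coverage = NA_real_,
                       allele_fraction = NA_real_) {
  if (length(id) == 0L) {
    return(data.frame(id = character(0), svtype = character(0),
                      chrom1 = character(0), pos1 = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      size = integer(0), support = integer(0),
                      strand_pair = character(0), quality_pass = logical(0),
                      position_coverage = numeric(0),
                      allele_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    id = as.character(id), svtype = as.character(svtype),
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
    size = as.integer(size), support = as.integer(support),
    strand_pair = as.character(strand_pair),
    quality_pass = as.logical(quality_pass),
    position_coverage = as.numeric(position_coverage),
    allele_fraction = as.numeric(allele_fraction),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
}

#' @rdname sv_records
#' @param df a candidate record `data.frame`
#' @export
validate_sv_records <- function(df) {
  if (nrow(df) == 0) return(df)
  bad <- setdiff(unique(df$svtype), SV_TYPES)
  if (length(bad)) .stopf("unknown svtype: %s", paste(bad, collapse = ", "))
  if (any(df$pos1 < 1L) || any(df$pos2 < 1L))
    .stopf("breakpoint positions must be >= 1")
  if (any(df$support < 0L)) .stopf("support must be >= 0")
  inter <- df$chrom1 != df$chrom2
  if (any(inter & df$svtype != "BND"))
    .stopf("interchromosomal records must be of type BND")
  intra <- !inter
  if (any(intra & df$pos2 < df$pos1))
    .stopf("intrachromosomal records require pos2 >= pos1")
  if (any(intra & df$size != df$pos2 - df$pos1))
    .stopf("intrachromosomal size must equal pos2 - pos1")
  sp <- df$strand_pair
  if (any(!is.na(sp) & !sp %in% STRAND_PAIRS))
    .stopf("invalid strand_pair")
  df
}

#' Construct a callset
#'
#' A callset bundles the normalized records of one caller run on one
#' sequencing technology with the dataset's mean depth of coverage, which
#' the support/coverage filters are expressed relative to.
#'
#' @param records an [sv_records()] table
#' @param name callset label (used in consensus bookkeeping)
#' @param caller caller name (e.g. `"sniffles"`, `"tiddit"`)
#' @param technology `"short_read"` or `"long_read"`
#' @param mean_depth mean depth of coverage of the dataset (reads)
#' @return an object of class `sv_callset`
#' @export
sv_callset <- function(records, name, caller = name,
                       technology = c("short_read", "long_read"),
                       mean_depth) {
  technology <- match.arg(technology)
  stopifnot(is.numeric(mean_depth), mean_depth > 0)
  records <- validate_sv_records(records)
  if (anyDuplicated(records$id))
    .stopf("record ids must be unique within callset '%s'", name)
  structure(list(name = name, caller = caller, technology = technology,
                 mean_depth = mean_depth, records = records),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset '%s'> caller=%s technology=%s mean_depth=%.1f\n",
              x$name, x$caller, x$technology, x$mean_depth))
  cat(sprintf("  %d records: %s\n", nrow(x$records),
              paste(names(table(x$records$svtype)),
                    table(x$records$svtype), sep = "=", collapse = " ")))
  invisible(x)
}

# ---- BND bracket notation ---------------------------------------------------

# orientation of a breakend junction from its bracket form:
#   t[p[ -> "+-"   t]p] -> "++"   [p[t -> "--"   ]p]t -> "-+"
.parse_bnd_alt <- function(alt, id) {
  re <- "^([A-Za-z.*]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)[\\[\\]]([A-Za-z.*]*)$"
  g <- regmatches(alt, regexec(re, alt, perl = TRUE))[[1]]
  if (length(g) == 0L)
    .stopf("malformed BND ALT in record '%s': %s", id, alt)
  seq_first <- nzchar(g[2])
  bracket <- g[3]
  strand <- if (seq_first) {
    if (bracket == "[") "+-" else "++"
  } else {
    if (bracket == "[") "--" else "-+"
  }
  list(chrom = g[4], pos = as.integer(g[5]), strand_pair = strand)
}

.bnd_alt_string <- function(chrom2, pos2, strand_pair) {
  loc <- paste0(chrom2, ":", pos2)
  switch(strand_pair,
         "+-" = paste0("N[", loc, "["),
         "++" = paste0("N]", loc, "]"),
         "--" = paste0("[", loc, "[N"),
         "-+" = paste0("]", loc, "]N"),
         paste0("N[", loc, "["))
}

# put the lexicographically smaller (chrom, pos) end first; swapping ends
# reverses the orientation pair
.orient_records <- function(df) {
  swap <- which(!.bp_le(df$chrom1, df$pos1, df$chrom2, df$pos2))
  if (length(swap)) {
    tmp_c <- df$chrom1[swap]; tmp_p <- df$pos1[swap]
    df$chrom1[swap] <- df$chrom2[swap]; df$pos1[swap] <- df$pos2[swap]
    df$chrom2[swap] <- tmp_c; df$pos2[swap] <- tmp_p
    sp <- df$strand_pair[swap]
    df$strand_pair[swap] <- ifelse(is.na(sp), sp,
                                   paste0(substr(sp, 2, 2), substr(sp, 1, 1)))
  }
  df
}

# ---- VCF reading ------------------------------------------------------------

#' Read an SV VCF and normalize it into a callset
#'
#' Handles symbolic ALT records (`<DEL>`, `<DUP>`, `<INV>`, `<INS>`) and
#' breakend records in bracket notation, covering the dialects written by
#' short-read discordant-pair callers and long-read split-read callers.
#' Breakend mate pairs are deduplicated to one record per junction, keeping
#' the lexicographically smaller (chromosome, position) end as breakpoint 1.
#' Insertions are normalized so that `pos2 = pos1 + size`.
#'
#' @param path VCF file
#' @param caller,technology,mean_depth,name callset metadata, see
#'   [sv_callset()]
#' @param support_fields INFO (then FORMAT) keys tried in order for the
#'   read-support count; first hit wins. The default covers Sniffles
#'   (`SUPPORT`, `RE`) and discordant-pair/split-read style tags.
#' @param coverage_fields INFO keys tried for breakpoint-local coverage
#' @param af_fields INFO keys tried for the variant allele fraction
#' @return an [sv_callset()]
#' @export
parse_sv_vcf <- function(path, caller, technology = c("short_read", "long_read"),
                         mean_depth, name = caller,
                         support_fields = c("SUPPORT", "RE", "SR", "PE", "DV", "SU"),
                         coverage_fields = c("COV", "COVERAGE", "DP"),
                         af_fields = c("AF", "VAF")) {
  technology <- match.arg(technology)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0)
    return(sv_callset(sv_records(character(0), character(0), character(0),
                                 integer(0)),
                      name, caller, technology, mean_depth))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0("rec", seq_len(nrow(fix))), fix$ID)

  svtype <- .info_get(info, "SVTYPE")
  sym <- regmatches(fix$ALT, regexec("^<([A-Z]+)>$", fix$ALT))
  sym <- vapply(sym, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                character(1))
  svtype[is.na(svtype)] <- sym[is.na(svtype)]
  is_bnd_alt <- grepl("[][]", fix$ALT)
  svtype[is.na(svtype) & is_bnd_alt] <- "BND"
  svtype[svtype == "TRA"] <- "BND"
  keep <- svtype %in% SV_TYPES
  if (any(!keep))
    warning(sprintf("%d records with unrecognized SV type dropped", sum(!keep)))
  fix <- fix[keep, , drop = FALSE]; info <- info[keep]
  ids <- ids[keep]; svtype <- svtype[keep]; is_bnd_alt <- is_bnd_alt[keep]

  n <- nrow(fix)
  chrom1 <- fix$CHROM
  pos1 <- as.integer(fix$POS)
  chrom2 <- chrom1
  pos2 <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  end_f <- suppressWarnings(as.integer(.info_get(info, "END")))
  svlen <- suppressWarnings(as.integer(.info_get(info, "SVLEN")))

  for (i in seq_len(n)) {
    if (svtype[i] == "BND") {
      if (!is_bnd_alt[i])
        .stopf("malformed BND ALT in record '%s': %s", ids[i], fix$ALT[i])
      mate <- .parse_bnd_alt(fix$ALT[i], ids[i])
      chrom2[i] <- mate$chrom
      pos2[i] <- mate$pos
      strand[i] <- mate$strand_pair
    } else if (svtype[i] == "INS") {
      if (is.na(svlen[i]) && is.na(end_f[i]))
        .stopf("record '%s' has neither SVLEN nor END; cannot size it", ids[i])
      len <- if (!is.na(svlen[i])) abs(svlen[i]) else end_f[i] - pos1[i]
      pos2[i] <- pos1[i] + len
    } else {
      if (is.na(end_f[i]) && is.na(svlen[i]))
        .stopf("record '%s' has neither END nor SVLEN; cannot size it", ids[i])
      pos2[i] <- if (!is.na(end_f[i])) end_f[i] else pos1[i] + abs(svlen[i])
    }
  }

  st <- .info_get(info, "STRANDS")
  use_st <- !is.na(st) & st %in% STRAND_PAIRS & svtype %in% c("BND")
  strand[use_st] <- st[use_st]

  support <- .info_num(info, support_fields)
  if (anyNA(support) && nrow(v@gt) > 0) {
    support[is.na(support)] <-
      .format_num(v, which(is.na(support)), keep, support_fields)
  }
  if (anyNA(support)) {
    warning(sprintf("%d records missing a support field; support set to 0",
                    sum(is.na(support))))
    support[is.na(support)] <- 0
  }

  df <- data.frame(
    id = ids, svtype = svtype, chrom1 = chrom1, pos1 = pos1,
    chrom2 = chrom2, pos2 = pos2, size = 0L, support = as.integer(support),
    strand_pair = strand,
    quality_pass = is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."),
    position_coverage = .info_num(info, coverage_fields),
    allele_fraction = .info_num(info, af_fields),
    stringsAsFactors = FALSE
  )
  df <- .orient_records(df)
  intra <- df$chrom1 == df$chrom2
  df$size[intra] <- df$pos2[intra] - df$pos1[intra]

  # breakend mates describe the same junction from both sides: after
  # orientation normalization they collapse onto one key
  bnd <- df$svtype == "BND"
  key <- paste(df$chrom1, df$pos1, df$chrom2, df$pos2, df$strand_pair)
  drop <- bnd & duplicated(key)
  df <- df[!drop, , drop = FALSE]
  rownames(df) <- NULL
  sv_callset(validate_sv_records(df), name, caller, technology, mean_depth)
}

# first-sample FORMAT lookup for the given keys, rows of the kept subset
.format_num <- function(v, rows, keep, keys) {
  gt <- v@gt[keep, , drop = FALSE]
  vapply(rows, function(i) {
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt[i, 2L], ":", fixed = TRUE)[[1]]
    for (k in keys) {
      j <- match(k, fmt)
      if (!is.na(j) && j <= length(val)) {
        x <- suppressWarnings(as.numeric(strsplit(val[j], ",")[[1]][1]))
        if (!is.na(x)) return(x)
      }
    }
    NA_real_
  }, numeric(1))
}

# ---- VCF writing ------------------------------------------------------------

#' Write a callset as VCF
#'
#' Emits symbolic ALT records for intrachromosomal types and single
#' bracket-notation records for breakends (one line per junction). Parsing
#' the written file with [parse_sv_vcf()] reproduces the callset's records
#' field for field.
#'
#' @param callset an [sv_callset()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sv_vcf <- function(callset, path) {
  stopifnot(inherits(callset, "sv_callset"))
  df <- callset$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svkaryo",
    sprintf("##svkaryo_callset=<name=%s,caller=%s,technology=%s,mean_depth=%g>",
            callset$name, callset$caller, callset$technology,
            callset$mean_depth),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=COV,Number=1,Type=Float,Description=\"Breakpoint coverage\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakend orientation\">",
    "##FILTER=<ID=LowQual,Description=\"Failed caller quality filters\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    info <- paste0("SVTYPE=", r$svtype)
    if (r$svtype == "BND") {
      alt <- .bnd_alt_string(r$chrom2, r$pos2,
                             if (is.na(r$strand_pair)) "+-" else r$strand_pair)
    } else {
      alt <- paste0("<", r$svtype, ">")
      info <- paste0(info, ";END=", r$pos2, ";SVLEN=", r$size)
    }
    info <- paste0(info, ";SUPPORT=", r$support)
    if (!is.na(r$position_coverage))
      info <- paste0(info, ";COV=", format(r$position_coverage, digits = 10))
    if (!is.na(r$allele_fraction))
      info <- paste0(info, ";AF=", format(r$allele_fraction, digits = 10))
    if (!is.na(r$strand_pair))
      info <- paste0(info, ";STRANDS=", r$strand_pair)
    lines[i] <- paste(r$chrom1, r$pos1, r$id, "N", alt, ".",
                      if (r$quality_pass) "PASS" else "LowQual", info,
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# ---- SNV VCF ----------------------------------------------------------------

#' Read an SNV VCF with allele depths
#'
#' Computes the variant allele fraction from the first sample's `AD` field
#' (ref,alt depths). Records without a usable `AD` are dropped and counted
#' in a message. Functional annotation, when present, is read from
#' SnpEff-style `LOF=(gene|id|n|fraction)` / `NMD=(...)` INFO fields or
#' from plain `CONSEQUENCE=` / `TFRAC=` keys; a population allele frequency
#' is read from the first of `pop_af_fields` found.
#'
#' @param path VCF file
#' @param pop_af_fields INFO keys tried for the population allele frequency
#' @return a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_depth`, `vaf`, `population_af`, `consequence`,
#'   `affected_transcript_fraction`
#' @export
parse_snv_vcf <- function(path, pop_af_fields = c("POP_AF", "POPAF", "gnomAD_AF")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) return(.empty_snv_table())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  ad <- if (nrow(v@gt) == n && ncol(v@gt) >= 2) {
    vcfR::extract.gt(v, element = "AD")[, 1L]
  } else rep(NA_character_, n)
  parts <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  ref_d <- suppressWarnings(as.integer(vapply(parts, function(x)
    if (length(x) >= 2) x[1] else NA_character_, character(1))))
  alt_d <- suppressWarnings(as.integer(vapply(parts, function(x)
    if (length(x) >= 2) x[2] else NA_character_, character(1))))
  depth <- ref_d + alt_d
  ok <- !is.na(depth) & depth > 0
  if (any(!ok))
    message(sprintf("dropped %d SNV records without usable allele depths",
                    sum(!ok)))
  info <- fix$INFO[ok]

  lof <- .info_get(info, "LOF"); nmd <- .info_get(info, "NMD")
  cons <- .info_get(info, "CONSEQUENCE")
  frac <- suppressWarnings(as.numeric(.info_get(info, "TFRAC")))
  snpeff_frac <- function(x) suppressWarnings(as.numeric(
    sub("^\\(?[^|]*\\|[^|]*\\|[^|]*\\|([0-9.]+)\\)?$", "\\1", x)))
  use_lof <- is.na(cons) & !is.na(lof)
  cons[use_lof] <- "LOF"; frac[use_lof] <- snpeff_frac(lof[use_lof])
  use_nmd <- is.na(cons) & !is.na(nmd)
  cons[use_nmd] <- "NMD"; frac[use_nmd] <- snpeff_frac(nmd[use_nmd])
  cons[is.na(cons) & !is.na(.info_get(info, "ANN"))] <- "other"

  data.frame(
    chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
    ref = fix$REF[ok], alt = fix$ALT[ok],
    depth = depth[ok], alt_depth = alt_d[ok],
    vaf = alt_d[ok] / depth[ok],
    population_af = .info_num(info, pop_af_fields),
    consequence = cons,
    affected_transcript_fraction = frac,
    stringsAsFactors = FALSE
  )
}

.empty_snv_table <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), depth = integer(0), alt_depth = integer(0),
             vaf = numeric(0), population_af = numeric(0),
             consequence = character(0),
             affected_transcript_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write an SNV table as VCF
#'
#' Inverse of [parse_snv_vcf()] for tables produced by the synthetic
#' generator or by hand: allele depths go into the `AD` FORMAT field and
#' optional annotation into `POP_AF` / `CONSEQUENCE` / `TFRAC` INFO keys.
#'
#' @param snvs a table as returned by [parse_snv_vcf()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_snv_vcf <- function(snvs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svkaryo",
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"Predicted consequence class\">",
    "##INFO=<ID=TFRAC,Number=1,Type=Float,Description=\"Fraction of transcripts affected\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  info <- rep(".", nrow(snvs))
  add <- function(info, key, val) {
    has <- !is.na(val)
    piece <- paste0(key, "=", val[has])
    info[has] <- ifelse(info[has] == ".", piece,
                        paste0(info[has], ";", piece))
    info
  }
  if (!is.null(snvs$population_af))
    info <- add(info, "POP_AF", snvs$population_af)
  if (!is.null(snvs$consequence))
    info <- add(info, "CONSEQUENCE", snvs$consequence)
  if (!is.null(snvs$affected_transcript_fraction))
    info <- add(info, "TFRAC", snvs$affected_transcript_fraction)
  lines <- paste(snvs$chrom, snvs$pos, ".", snvs$ref, snvs$alt, ".", "PASS",
                 info, "AD",
                 paste0(snvs$depth - snvs$alt_depth, ",", snvs$alt_depth),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# ---- blacklist --------------------------------------------------------------

#' Load blacklist intervals from BED
#'
#' Reads a 3+ column BED file (0-based, half-open) into a `GRanges`
#' suitable for breakpoint point queries (e.g. the ENCODE Blacklist of
#' anomalous-signal regions).
#'
#' @param path BED file
#' @return a [GenomicRanges::GRanges] object
#' @export
load_blacklist <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(IRanges::width(gr) < 1))
    .stopf("blacklist contains intervals with start >= end")
  gr
}

#' Point-query blacklist intervals
#'
#' @param blacklist a `GRanges` from [load_blacklist()] (or any `GRanges`)
#' @param chrom,pos 1-based query positions (vectorized)
#' @return logical vector, `TRUE` where the position lies in an interval
#' @export
blacklist_contains <- function(blacklist, chrom, pos) {
  if (length(blacklist) == 0 || length(chrom) == 0)
    return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  suppressWarnings(GenomicRanges::countOverlaps(q, blacklist) > 0)
}
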