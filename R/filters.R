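# Candidate filtering: the large-SV pre-filter, the three-criterion
# support/coverage filter, pseudorandom support-based sampling,
# cross-callset confirmation, size stratification, per-window breakpoint
# binning, and the SNV impact filter.

#' SV/SNV filter configuration
#'
#' Defaults follow the thresholds used for large-scale rearrangement
#' screening: a candidate is "large" above 100 kb (strictly); support must
#' be at least 5 reads and strictly above 20% of the dataset's mean depth;
#' breakpoint coverage may not exceed 150% of the mean depth (inclusive);
#' the pseudorandom short-read sample takes candidates with exactly 15
#' supporting reads. Size strata are Small \[100, 1000\], Medium
#' (1000, 10000\], Large (10000, Inf) bp. SNVs pass with population
#' frequency at most 1e-4 and a loss-of-function or nonsense-mediated-decay
#' consequence affecting at least 25% of the gene's transcripts.
#'
#' @param large_sv_min strict lower size bound (bp) for the large-SV
#'   pre-filter
#' @param min_support minimum supporting reads
#' @param support_depth_fraction support must strictly exceed this fraction
#'   of mean depth
#' @param coverage_cap_fraction breakpoint coverage cap as a fraction of
#'   mean depth (inclusive)
#' @param sample_support_value exact support count selecting the
#'   pseudorandom short-read sample
#' @param small_bin,medium_bin numeric length-2 bin boundaries (bp); Small
#'   is closed, Medium right-closed, Large is everything above
#' @param snv_max_pop_af maximum population allele frequency for SNVs
#' @param snv_min_transcript_fraction minimum fraction of transcripts
#'   affected
#' @return a `filter_config` list
#' @export
filter_config <- function(large_sv_min = 100000L, min_support = 5L,
                          support_depth_fraction = 0.2,
                          coverage_cap_fraction = 1.5,
                          sample_support_value = 15L,
                          small_bin = c(100, 1000), medium_bin = c(1000, 10000),
                          snv_max_pop_af = 1e-4,
                          snv_min_transcript_fraction = 0.25) {
  stopifnot(large_sv_min > 0, min_support > 0, support_depth_fraction > 0,
            coverage_cap_fraction > 0, sample_support_value > 0,
            small_bin[2] == medium_bin[1])
  structure(list(large_sv_min = large_sv_min, min_support = min_support,
                 support_depth_fraction = support_depth_fraction,
                 coverage_cap_fraction = coverage_cap_fraction,
                 sample_support_value = sample_support_value,
                 small_bin = small_bin, medium_bin = medium_bin,
                 snv_max_pop_af = snv_max_pop_af,
                 snv_min_transcript_fraction = snv_min_transcript_fraction),
            class = "filter_config")
}

#' Large-SV pre-filter
#'
#' Retains candidates that are either strictly longer than `large_sv_min`
#' or interchromosomal breakends; everything else is discarded (and
#' excluded from downstream accuracy statistics).
#'
#' @param callset an [sv_callset()]
#' @param cfg a [filter_config()]
#' @return list with `retained` (an `sv_callset`) and `discarded_count`
#' @export
prefilter_large <- function(callset, cfg = filter_config()) {
  stopifnot(inherits(callset, "sv_callset"))
  df <- callset$records
  keep <- df$size > cfg$large_sv_min |
    (df$svtype == "BND" & df$chrom1 != df$chrom2)
  out <- callset
  out$records <- df[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  list(retained = out, discarded_count = sum(!keep))
}

#' Support and coverage filter
#'
#' A record is retained iff it (1) passed the caller's quality filters,
#' (2) has at least `min_support` supporting reads, strictly more than
#' `support_depth_fraction` of the callset's mean depth, and (3) has
#' breakpoint coverage no greater than `coverage_cap_fraction` of the mean
#' depth. Rejections are labeled with the first failed criterion
#' (`"quality"`, `"min-support"`, `"support-fraction"`, `"coverage"`, or
#' `"no-coverage"` when the coverage value is missing).
#'
#' @param callset an [sv_callset()] with `mean_depth` set
#' @param cfg a [filter_config()]
#' @return list with `retained` (an `sv_callset`) and `rejected` (a
#'   `data.frame` of id and reason)
#' @export
support_coverage_filter <- function(callset, cfg = filter_config()) {
  stopifnot(inherits(callset, "sv_callset"))
  df <- callset$records
  dc <- callset$mean_depth
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(reason) & !df$quality_pass] <- "quality"
  reason[is.na(reason) & df$support < cfg$min_support] <- "min-support"
  reason[is.na(reason) &
           df$support <= cfg$support_depth_fraction * dc] <- "support-fraction"
  reason[is.na(reason) & is.na(df$position_coverage)] <- "no-coverage"
  reason[is.na(reason) &
           df$position_coverage > cfg$coverage_cap_fraction * dc] <- "coverage"
  out <- callset
  out$records <- df[is.na(reason), , drop = FALSE]
  rownames(out$records) <- NULL
  list(retained = out,
       rejected = data.frame(id = df$id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Pseudorandom sampling by exact support count
#'
#' Selects the records whose support equals `sample_support_value`. In a
#' high-false-positive short-read callset the set of candidates with one
#' arbitrary exact support count behaves as a pseudorandom sample of the
#' callset. Output order is deterministic (sorted by breakpoints then id).
#'
#' @param callset an [sv_callset()]
#' @param cfg a [filter_config()]
#' @return an `sv_callset` with the sampled records
#' @export
sample_by_support <- function(callset, cfg = filter_config()) {
  stopifnot(inherits(callset, "sv_callset"))
  df <- callset$records
  df <- df[df$support == cfg$sample_support_value, , drop = FALSE]
  df <- df[order(df$chrom1, df$pos1, df$chrom2, df$pos2, df$id), ,
           drop = FALSE]
  rownames(df) <- NULL
  out <- callset
  out$records <- df
  out
}

#' Cross-callset confirmation
#'
#' A deterministic proxy for manual read inspection: a candidate is
#' confirmed iff a record of the same type on the same chromosome pair,
#' with both breakpoints within `tol` bp, exists in at least one of the
#' other callsets (so the event is seen in at least two callsets overall).
#'
#' @param candidates an [sv_callset()] of candidates
#' @param others list of other [sv_callset()] objects
#' @param tol breakpoint distance tolerance (bp)
#' @return an `sv_callset` with the confirmed subset
#' @export
cross_callset_confirm <- function(candidates, others, tol = 1000L) {
  stopifnot(inherits(candidates, "sv_callset"))
  df <- candidates$records
  confirmed <- rep(FALSE, nrow(df))
  for (other in others) {
    o <- other$records
    if (nrow(o) == 0) next
    for (i in which(!confirmed)) {
      hit <- o$svtype == df$svtype[i] & o$chrom1 == df$chrom1[i] &
        o$chrom2 == df$chrom2[i] &
        abs(o$pos1 - df$pos1[i]) <= tol & abs(o$pos2 - df$pos2[i]) <= tol
      if (any(hit)) confirmed[i] <- TRUE
    }
  }
  out <- candidates
  out$records <- df[confirmed, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Stratify SV records by size
#'
#' Bins non-breakend records into Small \[100 bp, 1 kb\], Medium
#' (1 kb, 10 kb\] and Large (>10 kb) size strata. Records below the Small
#' lower bound are excluded and counted separately; breakends (no length)
#' are not stratified.
#'
#' @param records an [sv_records()] table
#' @param cfg a [filter_config()]
#' @return list with `counts` (named integer: Small/Medium/Large),
#'   `labels` (per retained record), `records` (the labeled subset),
#'   `n_below_min` and `n_bnd`
#' @export
stratify_sizes <- function(records, cfg = filter_config()) {
  bnd <- records$svtype == "BND"
  n_bnd <- sum(bnd)
  df <- records[!bnd, , drop = FALSE]
  below <- df$size < cfg$small_bin[1]
  n_below <- sum(below)
  df <- df[!below, , drop = FALSE]
  labels <- ifelse(df$size <= cfg$small_bin[2], "Small",
                   ifelse(df$size <= cfg$medium_bin[2], "Medium", "Large"))
  counts <- c(Small = sum(labels == "Small"),
              Medium = sum(labels == "Medium"),
              Large = sum(labels == "Large"))
  list(counts = counts, labels = labels, records = df,
       n_below_min = n_below, n_bnd = n_bnd)
}

#' Per-window breakpoint counts
#'
#' Counts each record once in the window containing its first breakpoint;
#' interchromosomal records additionally count once at the second
#' breakpoint, so the totals conserve the number of breakpoints. This is
#' the data behind chromosome heatmap displays of callset density.
#'
#' @param records an [sv_records()] table
#' @param window window width (bp)
#' @return `data.frame` with `chrom`, `start`, `end` (1-based, inclusive)
#'   and `count`
#' @export
heatmap_bins <- function(records, window = 1e6) {
  stopifnot(window > 0)
  chrom <- records$chrom1
  pos <- records$pos1
  inter <- records$chrom1 != records$chrom2
  chrom <- c(chrom, records$chrom2[inter])
  pos <- c(pos, records$pos2[inter])
  if (length(chrom) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), count = integer(0),
                      stringsAsFactors = FALSE))
  w <- floor((pos - 1) / window)
  tab <- table(paste(chrom, w, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.numeric(vapply(parts, `[`, character(1), 2L)) * window + 1,
    count = as.integer(tab), stringsAsFactors = FALSE)
  out$end <- out$start + window - 1
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "count")]
  rownames(out) <- NULL
  out
}

#' SNV impact filter
#'
#' Retains variants that are rare (population allele frequency missing or
#' at most `snv_max_pop_af`), predicted loss-of-function or
#' nonsense-mediated-decay, and affecting at least
#' `snv_min_transcript_fraction` of the gene's transcripts.
#'
#' @param snvs a table as returned by [parse_snv_vcf()]
#' @param cfg a [filter_config()]
#' @return the retained subset of `snvs`
#' @export
snv_impact_filter <- function(snvs, cfg = filter_config()) {
  keep <- (is.na(snvs$population_af) |
             snvs$population_af <= cfg$snv_max_pop_af) &
    !is.na(snvs$consequence) & snvs$consequence %in% c("LOF", "NMD") &
    !is.na(snvs$affected_transcript_fraction) &
    snvs$affected_transcript_fraction >= cfg$snv_min_transcript_fraction
  out <- snvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
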