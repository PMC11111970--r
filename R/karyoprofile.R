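# Karyotype profiling: chromosome copy states from depth-of-coverage
# ratios, heterozygosity windows from SNV allele fractions, and LOH /
# copy-neutral LOH segmentation.

#' Call chromosome copy states from depth ratios
#'
#' The diploid baseline is bootstrapped from the data: first the median
#' mean depth over autosomes, then one refinement pass excluding
#' chromosomes whose depth ratio falls outside \[`loss_below`,
#' `gain_above`\], after which the median is recomputed over the remaining
#' autosomes. Each chromosome's ratio against this baseline determines its
#' state: `loss` below `loss_below`, `gain` above `gain_above`, `disomy`
#' otherwise. A trisomy sits near ratio 1.5 and a monosomy near 0.5, well
#' clear of the default thresholds.
#'
#' @param depths `data.frame` with columns `chrom` and `mean_depth`
#' @param loss_below,gain_above ratio thresholds
#' @return `data.frame` with `chrom`, `mean_depth`, `ratio`, `state`, and
#'   attribute `baseline`
#' @export
call_copy_states <- function(depths, loss_below = 0.75, gain_above = 1.25) {
  stopifnot(all(c("chrom", "mean_depth") %in% names(depths)),
            nrow(depths) > 0)
  if (all(depths$mean_depth == 0)) .stopf("all chromosome depths are zero")
  auto <- !grepl("(X|Y)$", depths$chrom)
  base_chroms <- if (any(auto)) auto else rep(TRUE, nrow(depths))
  b0 <- stats::median(depths$mean_depth[base_chroms])
  r0 <- depths$mean_depth / b0
  refined <- base_chroms & r0 >= loss_below & r0 <= gain_above
  baseline <- if (any(refined)) stats::median(depths$mean_depth[refined]) else b0
  ratio <- depths$mean_depth / baseline
  out <- data.frame(chrom = depths$chrom, mean_depth = depths$mean_depth,
                    ratio = ratio,
                    state = ifelse(ratio < loss_below, "loss",
                                   ifelse(ratio > gain_above, "gain",
                                          "disomy")),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  out
}

#' Windowed heterozygosity profile from SNV allele fractions
#'
#' Assigns each SNV to the fixed-width window containing its position and
#' summarizes per window: the number of SNVs, the fraction called
#' heterozygous (allele fraction inside `het_band`), and the mean allele
#' fraction of those heterozygous calls. Under disomy heterozygous sites
#' are binomially spread around 0.5; a run of windows with (almost) no
#' heterozygous calls is the signature of LOH. Windows with no SNVs are
#' omitted.
#'
#' @param snvs a table as returned by [parse_snv_vcf()] (needs `chrom`,
#'   `pos`, `vaf`)
#' @param window window width (bp)
#' @param het_band inclusive allele-fraction band counted as heterozygous
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snv`,
#'   `het_fraction`, `mean_het_vaf`, sorted by (chrom, start)
#' @export
vaf_windows <- function(snvs, window = 1e6, het_band = c(0.2, 0.8)) {
  stopifnot(window > 0, length(het_band) == 2, het_band[1] < het_band[2])
  if (nrow(snvs) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snv = integer(0),
                      het_fraction = numeric(0), mean_het_vaf = numeric(0),
                      stringsAsFactors = FALSE))
  w <- floor((snvs$pos - 1) / window)
  het <- snvs$vaf >= het_band[1] & snvs$vaf <= het_band[2]
  key <- paste(snvs$chrom, w, sep = "\r")
  n <- tapply(het, key, length)
  nh <- tapply(het, key, sum)
  mh <- tapply(ifelse(het, snvs$vaf, NA_real_), key,
               function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.numeric(vapply(parts, `[`, character(1), 2L)) * window + 1,
    n_snv = as.integer(n),
    het_fraction = as.numeric(nh / n),
    mean_het_vaf = as.numeric(mh),
    stringsAsFactors = FALSE)
  out$end <- out$start + window - 1
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_snv", "het_fraction",
               "mean_het_vaf")]
  rownames(out) <- NULL
  out
}

#' Detect LOH and copy-neutral LOH segments
#'
#' Scans the windowed heterozygosity profile for maximal runs of at least
#' `min_run` consecutive windows whose heterozygous fraction is at most
#' `het_max`. Each run becomes a segment classified by the chromosome's
#' depth ratio: copy-neutral LOH (`cnLOH`) when the ratio lies inside
#' `neutral_band`, plain `LOH` (deletion-driven) otherwise.
#'
#' @param windows output of [vaf_windows()]
#' @param copy_states output of [call_copy_states()] (supplies per
#'   chromosome depth ratios)
#' @param min_run minimum number of consecutive depleted windows
#' @param het_max maximum heterozygous fraction inside a segment
#' @param neutral_band depth-ratio band considered copy-neutral
#' @return `data.frame` with `chrom`, `start`, `end`, `kind`,
#'   `mean_depth_ratio`, `n_windows`
#' @export
detect_loh <- function(windows, copy_states, min_run = 5L, het_max = 0.05,
                       neutral_band = c(0.8, 1.2)) {
  segs <- list()
  ratio_of <- stats::setNames(copy_states$ratio, copy_states$chrom)
  for (chrom in unique(windows$chrom)) {
    wc <- windows[windows$chrom == chrom, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    low <- wc$het_fraction <= het_max
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      ratio <- unname(ratio_of[chrom])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom,
        start = wc$start[starts[j]],
        end = wc$end[ends[j]],
        kind = if (!is.na(ratio) && ratio >= neutral_band[1] &&
                     ratio <= neutral_band[2]) "cnLOH" else "LOH",
        mean_depth_ratio = if (is.na(ratio)) NA_real_ else ratio,
        n_windows = r$lengths[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      mean_depth_ratio = numeric(0), n_windows = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
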