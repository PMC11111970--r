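# Curated confirmed large-scale SVs of the REH leukemia cell line.
#
# REH is an ETV6::RUNX1-positive B-cell precursor acute lymphoblastic
# leukemia cell line. The table shipped in extdata lists the confirmed
# interchromosomal and >100 kb structural variants with per-technology
# read support (split reads for the long-read callsets, discordant mates
# for the short-read callset) and which of the three WGS callsets called
# each event. It serves as the package's built-in truth set for caller
# evaluation and as a worked example of the record model.

REH_MEAN_DEPTH <- c(illumina = 34, pacbio = 15, ont = 18)

#' Confirmed large-scale REH structural variants
#'
#' @return `data.frame` with one row per confirmed event: breakpoints
#'   (breakpoint 1 is the lexicographically smaller end), size,
#'   per-technology read support, the callsets that detected it, and
#'   disrupted genes
#' @export
reh_confirmed_svs <- function() {
  utils::read.delim(system.file("extdata", "reh_confirmed_svs.tsv",
                                package = "svkaryo"),
                    stringsAsFactors = FALSE)
}

#' REH truth set as a normalized record table
#'
#' @param technology which technology's support column to carry
#'   (`"pacbio"`, `"ont"` or `"illumina"`)
#' @return an [sv_records()] table of the 23 confirmed events
#' @export
reh_truth_records <- function(technology = c("pacbio", "ont", "illumina")) {
  technology <- match.arg(technology)
  tab <- reh_confirmed_svs()
  sv_records(id = tab$id, svtype = tab$svtype,
             chrom1 = tab$chrom1, pos1 = tab$pos1,
             chrom2 = tab$chrom2, pos2 = tab$pos2,
             size = tab$size,
             support = tab[[paste0("support_", technology)]])
}

#' One technology's REH callset restricted to confirmed events
#'
#' Builds the [sv_callset()] of confirmed events that the given
#' technology's caller detected, with that technology's read support and
#' dataset mean depth (34x short-read, 15x and 18x long-read).
#'
#' @param technology `"illumina"`, `"pacbio"` or `"ont"`
#' @return an [sv_callset()]
#' @export
reh_technology_callset <- function(technology = c("illumina", "pacbio", "ont")) {
  technology <- match.arg(technology)
  tab <- reh_confirmed_svs()
  called <- vapply(strsplit(tab$callsets, ","), function(x)
    technology %in% x, logical(1))
  tab <- tab[called, , drop = FALSE]
  rec <- sv_records(id = tab$id, svtype = tab$svtype,
                    chrom1 = tab$chrom1, pos1 = tab$pos1,
                    chrom2 = tab$chrom2, pos2 = tab$pos2,
                    size = tab$size,
                    support = tab[[paste0("support_", technology)]])
  sv_callset(rec, name = technology,
             caller = if (technology == "illumina") "tiddit" else "sniffles",
             technology = if (technology == "illumina") "short_read"
             else "long_read",
             mean_depth = REH_MEAN_DEPTH[[technology]])
}
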