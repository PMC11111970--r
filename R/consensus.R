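# Cross-callset consensus merging: cluster SV records from independent
# callsets into groups that agree on type, orientation, and breakpoint
# position within a distance tolerance, then count support combinations.

#' Consensus-merge configuration
#'
#' @param max_distance maximum allowed distance (bp) between each breakpoint
#'   of a record and the group representative, on both ends
#' @param min_size minimum SV size (bp); smaller intrachromosomal records
#'   are excluded before merging (breakends, which have no length, are
#'   exempt)
#' @param require_type must members agree on SV type
#' @param require_strand must members have compatible orientation
#'   (equal strand pairs, or either missing)
#' @param blacklist optional `GRanges`; records with either breakpoint in a
#'   blacklisted interval are excluded before merging
#' @return a `consensus_config` list
#' @export
consensus_config <- function(max_distance = 1000L, min_size = 100L,
                             require_type = TRUE, require_strand = TRUE,
                             blacklist = NULL) {
  stopifnot(max_distance >= 0, min_size >= 0)
  structure(list(max_distance = as.integer(max_distance),
                 min_size = as.integer(min_size),
                 require_type = isTRUE(require_type),
                 require_strand = isTRUE(require_strand),
                 blacklist = blacklist),
            class = "consensus_config")
}

#' Merge callsets into consensus groups
#'
#' Greedy single-linkage clustering in deterministic record order (sorted
#' by `chrom1`, `pos1`, `chrom2`, `pos2`, `id`): a record joins the
#' matching group whose representative minimizes the summed breakpoint
#' distance (first group on ties); otherwise it seeds a new group whose
#' first member becomes the representative. Matching requires the same
#' chromosome pair, agreement on type and orientation per the
#' configuration, and both-end distance at most `max_distance`.
#'
#' @param callsets list of [sv_callset()] objects with distinct names
#' @param cfg a [consensus_config()]
#' @return an `sv_consensus` object: a list with `groups` (each holding
#'   `representative`, `members`, `supported_by`), the callset names, and
#'   exclusion counters `n_excluded_min_size` / `n_excluded_blacklist`
#' @export
merge_callsets <- function(callsets, cfg = consensus_config()) {
  stopifnot(length(callsets) >= 1)
  names_cs <- vapply(callsets, function(x) x$name, character(1))
  if (anyDuplicated(names_cs)) .stopf("callset names must be distinct")

  pool <- do.call(rbind, lapply(callsets, function(cs) {
    if (nrow(cs$records) == 0) return(NULL)
    cbind(cs$records, callset = cs$name, stringsAsFactors = FALSE)
  }))
  if (is.null(pool)) pool <- cbind(sv_records(character(0), character(0),
                                              character(0), integer(0)),
                                   callset = character(0))
  n_in <- nrow(pool)

  small <- pool$svtype != "BND" & pool$size < cfg$min_size
  n_small <- sum(small)
  pool <- pool[!small, , drop = FALSE]

  n_black <- 0L
  if (!is.null(cfg$blacklist) && nrow(pool) > 0) {
    hit <- blacklist_contains(cfg$blacklist, pool$chrom1, pool$pos1) |
      blacklist_contains(cfg$blacklist, pool$chrom2, pool$pos2)
    n_black <- sum(hit)
    pool <- pool[!hit, , drop = FALSE]
  }

  ord <- order(pool$chrom1, pool$pos1, pool$chrom2, pool$pos2, pool$id)
  pool <- pool[ord, , drop = FALSE]
  rownames(pool) <- NULL

  # bucket by (chrom pair, type when required) so only candidate groups in
  # the same bucket are scanned
  bucket <- paste(pool$chrom1, pool$chrom2,
                  if (cfg$require_type) pool$svtype else "")
  rep_pos1 <- integer(0); rep_pos2 <- integer(0)
  rep_strand <- character(0); rep_type <- character(0)
  grp_bucket <- character(0)
  assignment <- integer(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    cand <- which(grp_bucket == bucket[i])
    g <- 0L
    if (length(cand)) {
      d1 <- abs(rep_pos1[cand] - pool$pos1[i])
      d2 <- abs(rep_pos2[cand] - pool$pos2[i])
      ok <- d1 <= cfg$max_distance & d2 <= cfg$max_distance
      if (cfg$require_strand) {
        ok <- ok & (is.na(rep_strand[cand]) | is.na(pool$strand_pair[i]) |
                      rep_strand[cand] == pool$strand_pair[i])
      }
      if (any(ok)) {
        hits <- cand[ok]
        g <- hits[which.min(d1[ok] + d2[ok])]
      }
    }
    if (g == 0L) {
      rep_pos1 <- c(rep_pos1, pool$pos1[i])
      rep_pos2 <- c(rep_pos2, pool$pos2[i])
      rep_strand <- c(rep_strand, pool$strand_pair[i])
      rep_type <- c(rep_type, pool$svtype[i])
      grp_bucket <- c(grp_bucket, bucket[i])
      g <- length(rep_pos1)
    }
    assignment[i] <- g
  }

  groups <- lapply(seq_along(rep_pos1), function(g) {
    members <- pool[assignment == g, , drop = FALSE]
    rownames(members) <- NULL
    first <- members[1L, ]
    list(representative = list(chrom1 = first$chrom1, pos1 = first$pos1,
                               chrom2 = first$chrom2, pos2 = first$pos2,
                               svtype = first$svtype),
         members = members,
         supported_by = sort(unique(members$callset)))
  })

  structure(list(groups = groups, callset_names = sort(names_cs),
                 n_input = n_in, n_excluded_min_size = n_small,
                 n_excluded_blacklist = n_black, config = cfg),
            class = "sv_consensus")
}

#' @export
print.sv_consensus <- function(x, ...) {
  cat(sprintf("<sv_consensus> %d groups from %d records (%s)\n",
              length(x$groups), x$n_input,
              paste(x$callset_names, collapse = ", ")))
  cat(sprintf("  excluded: %d below min size, %d blacklisted\n",
              x$n_excluded_min_size, x$n_excluded_blacklist))
  invisible(x)
}

#' Count consensus groups by exact callset combination
#'
#' Each group is counted once under the exact set of callsets supporting
#' it (the Venn-diagram tallies of a multi-technology comparison); counts
#' sum to the number of groups.
#'
#' @param cons an `sv_consensus` from [merge_callsets()]
#' @return a `data.frame` with columns `combination` (callset names joined
#'   by `+`, sorted) and `count`
#' @export
combination_counts <- function(cons) {
  stopifnot(inherits(cons, "sv_consensus"))
  combos <- vapply(cons$groups,
                   function(g) paste(g$supported_by, collapse = "+"),
                   character(1))
  tab <- table(combos)
  out <- data.frame(combination = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$combination), , drop = FALSE]
}

#' Subset consensus groups by required support
#'
#' Returns the groups supported by (at least) all of the `required`
#' callsets, e.g. the long-read consensus (both long-read callsets) or the
#' three-way consensus (all callsets).
#'
#' @param cons an `sv_consensus`
#' @param required character vector of callset names; empty means all
#'   groups
#' @return an `sv_consensus` restricted to the matching groups
#' @export
consensus_subset <- function(cons, required = character(0)) {
  stopifnot(inherits(cons, "sv_consensus"))
  unknown <- setdiff(required, cons$callset_names)
  if (length(unknown))
    .stopf("unknown callset name(s): %s", paste(unknown, collapse = ", "))
  keep <- vapply(cons$groups,
                 function(g) all(required %in% g$supported_by), logical(1))
  out <- cons
  out$groups <- cons$groups[keep]
  out
}

#' Per-group SV allele fractions
#'
#' One value per group: the mean allele fraction across members that carry
#' one. Under a clonal cell line these are expected to be binomially
#' spread around 0.5 (heterozygous) and 1.0 (homozygous); subclones would
#' appear as additional modes.
#'
#' @param cons an `sv_consensus`
#' @return numeric vector of group allele fractions, with attribute
#'   `n_skipped` counting groups with no allele-fraction data
#' @export
sv_allele_fractions <- function(cons) {
  stopifnot(inherits(cons, "sv_consensus"))
  vals <- vapply(cons$groups, function(g) {
    af <- g$members$allele_fraction
    af <- af[!is.na(af)]
    if (length(af) == 0) NA_real_ else mean(af)
  }, numeric(1))
  out <- vals[!is.na(vals)]
  attr(out, "n_skipped") <- sum(is.na(vals))
  out
}

#' Flatten consensus groups to a representative record table
#'
#' One [sv_records()]-style row per group, taking the representative
#' breakpoints and the maximum member support.
#'
#' @param cons an `sv_consensus`
#' @return a record `data.frame`
#' @export
consensus_records <- function(cons) {
  stopifnot(inherits(cons, "sv_consensus"))
  if (length(cons$groups) == 0)
    return(sv_records(character(0), character(0), character(0), integer(0)))
  do.call(rbind, lapply(seq_along(cons$groups), function(i) {
    g <- cons$groups[[i]]
    first <- g$members[1L, , drop = FALSE]
    first$id <- sprintf("cg%04d", i)
    first$support <- max(g$members$support)
    af <- g$members$allele_fraction
    first$allele_fraction <- if (all(is.na(af))) NA_real_ else
      mean(af, na.rm = TRUE)
    first[, setdiff(names(first), "callset"), drop = FALSE]
  }))
}
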