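# Fusion-gene candidate screening: normalization of per-caller candidate
# tables, panel-of-normals subtraction, and the tiered retention filter.

#' Fusion filter configuration
#'
#' The four retention tiers: (T1) the pair contains a known
#' leukemia-associated gene and has at least `min_reads_tier1` supporting
#' reads across platforms; (T2) called by at least one short-read and one
#' long-read tool; (T3) called by at least `min_sr_callers_tier3`
#' short-read tools; (T4) supported by at least `min_lr_reads_tier4` long
#' reads. A candidate is retained if it satisfies any tier (self-pairs are
#' always dropped).
#'
#' @param all_genes character vector of disease-associated gene symbols;
#'   defaults to the B-ALL gene list shipped with the package
#' @param min_reads_tier1,min_sr_callers_tier3,min_lr_reads_tier4
#'   tier thresholds
#' @return a `fusion_filter_config` list
#' @export
fusion_filter_config <- function(all_genes = default_all_genes(),
                                 min_reads_tier1 = 5L,
                                 min_sr_callers_tier3 = 3L,
                                 min_lr_reads_tier4 = 10L) {
  stopifnot(min_reads_tier1 > 0, min_sr_callers_tier3 > 0,
            min_lr_reads_tier4 > 0)
  structure(list(all_genes = all_genes, min_reads_tier1 = min_reads_tier1,
                 min_sr_callers_tier3 = min_sr_callers_tier3,
                 min_lr_reads_tier4 = min_lr_reads_tier4),
            class = "fusion_filter_config")
}

#' Default B-ALL-associated gene list
#'
#' Genes recurrently altered in B-cell acute lymphoblastic leukemia,
#' shipped as a plain-text list (one symbol per line) in the package's
#' `extdata`. Replaceable by any user list.
#'
#' @return character vector of gene symbols
#' @export
default_all_genes <- function() {
  readLines(system.file("extdata", "all_genes.txt", package = "svkaryo"))
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file
#' @return character vector
#' @export
load_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Normalize one fusion caller's candidate table
#'
#' Reads a tab-separated candidate table and maps its columns onto the
#' common model via `col_map`. Rows reporting the same (directional) gene
#' pair are collapsed, summing reads.
#'
#' @param path TSV file with a header row
#' @param caller caller name
#' @param class `"short_read"` or `"long_read"`
#' @param col_map named list mapping the model fields `gene5`, `gene3`,
#'   `reads` to column names in the file
#' @return `data.frame` with columns `gene5`, `gene3`, `caller`, `class`,
#'   `reads`
#' @export
normalize_caller_table <- function(path, caller,
                                   class = c("short_read", "long_read"),
                                   col_map = list(gene5 = "gene5",
                                                  gene3 = "gene3",
                                                  reads = "reads")) {
  class <- match.arg(class)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  need <- unlist(col_map[c("gene5", "gene3", "reads")])
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    .stopf("caller table '%s' lacks mapped column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0)
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      caller = character(0), class = character(0),
                      reads = integer(0), stringsAsFactors = FALSE))
  df <- data.frame(gene5 = as.character(tab[[col_map$gene5]]),
                   gene3 = as.character(tab[[col_map$gene3]]),
                   reads = as.integer(tab[[col_map$reads]]),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(reads ~ gene5 + gene3, data = df, FUN = sum)
  agg$caller <- caller
  agg$class <- class
  agg <- agg[order(agg$gene5, agg$gene3),
             c("gene5", "gene3", "caller", "class", "reads")]
  rownames(agg) <- NULL
  agg
}

#' Aggregate per-caller candidates into the common candidate model
#'
#' Combines normalized per-caller tables (rows of
#' [normalize_caller_table()] output, possibly concatenated) into one row
#' per directional gene pair, with per-class caller counts and summed
#' read support.
#'
#' @param per_caller `data.frame` with columns `gene5`, `gene3`, `caller`,
#'   `class`, `reads` (concatenation of normalized tables)
#' @return `data.frame` with one row per pair: `gene5`, `gene3`,
#'   `sr_callers`, `lr_callers` (comma-joined names), `n_sr_callers`,
#'   `n_lr_callers`, `sr_reads`, `lr_reads`
#' @export
aggregate_fusion_candidates <- function(per_caller) {
  if (nrow(per_caller) == 0)
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      sr_callers = character(0), lr_callers = character(0),
                      n_sr_callers = integer(0), n_lr_callers = integer(0),
                      sr_reads = integer(0), lr_reads = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(per_caller$gene5, per_caller$gene3, sep = "\r")
  rows <- lapply(split(seq_len(nrow(per_caller)), key), function(ix) {
    x <- per_caller[ix, , drop = FALSE]
    sr <- x$class == "short_read"
    data.frame(gene5 = x$gene5[1], gene3 = x$gene3[1],
               sr_callers = paste(sort(unique(x$caller[sr])), collapse = ","),
               lr_callers = paste(sort(unique(x$caller[!sr])), collapse = ","),
               n_sr_callers = length(unique(x$caller[sr])),
               n_lr_callers = length(unique(x$caller[!sr])),
               sr_reads = sum(x$reads[sr]), lr_reads = sum(x$reads[!sr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Subtract a panel of normals
#'
#' Removes candidates whose unordered gene pair was also called in a
#' non-neoplastic reference sample (technical-artifact subtraction).
#'
#' @param candidates aggregated candidates
#'   ([aggregate_fusion_candidates()])
#' @param panel `data.frame` with two gene-symbol columns (order
#'   irrelevant), or `NULL` for no subtraction
#' @return list with `retained` and `removed_count`
#' @export
subtract_panel <- function(candidates, panel) {
  if (is.null(panel) || nrow(panel) == 0)
    return(list(retained = candidates, removed_count = 0L))
  pk <- .pair_key(panel[[1]], panel[[2]])
  hit <- .pair_key(candidates$gene5, candidates$gene3) %in% pk
  retained <- candidates[!hit, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, removed_count = sum(hit))
}

#' Tiered fusion candidate filter
#'
#' Drops self-pairs, then retains each candidate satisfying at least one
#' tier (see [fusion_filter_config()]); the `tiers` column lists every
#' satisfied tier.
#'
#' @param candidates aggregated candidates (after panel subtraction)
#' @param cfg a [fusion_filter_config()]
#' @return list with `retained` (candidates plus a `tiers` column),
#'   `n_self_pair` and `n_no_tier`
#' @export
tiered_filter <- function(candidates, cfg = fusion_filter_config()) {
  self <- candidates$gene5 == candidates$gene3
  n_self <- sum(self)
  df <- candidates[!self, , drop = FALSE]
  total_reads <- df$sr_reads + df$lr_reads
  t1 <- (df$gene5 %in% cfg$all_genes | df$gene3 %in% cfg$all_genes) &
    total_reads >= cfg$min_reads_tier1
  t2 <- df$n_sr_callers >= 1 & df$n_lr_callers >= 1
  t3 <- df$n_sr_callers >= cfg$min_sr_callers_tier3
  t4 <- df$lr_reads >= cfg$min_lr_reads_tier4
  tiers <- cbind(T1 = t1, T2 = t2, T3 = t3, T4 = t4)
  keep <- rowSums(tiers) > 0
  labels <- apply(tiers[keep, , drop = FALSE], 1L, function(x)
    paste(colnames(tiers)[x], collapse = ","))
  retained <- df[keep, , drop = FALSE]
  retained$tiers <- as.character(labels)
  rownames(retained) <- NULL
  list(retained = retained, n_self_pair = n_self, n_no_tier = sum(!keep))
}
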