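# Truth-set matching and caller performance statistics.
#
# "FPR" here follows the operational definition used in multi-technology
# SV caller comparisons: FP / (FP + TP) over the evaluated candidate set,
# i.e. a false-discovery proportion. The reports carry the conventional
# name FDR alongside to avoid ambiguity.

#' Match SV candidates against a truth set
#'
#' Greedy one-to-one matching: a candidate matches a truth event of the
#' same type on the same chromosome pair when both breakpoints lie within
#' `tolerance` bp. Pairs are assigned in order of increasing summed
#' breakpoint distance (ties by candidate input order); each truth event
#' and each candidate is used at most once. Unmatched candidates are FP;
#' unmatched truth events are FN.
#'
#' @param candidates an [sv_records()] table or [sv_callset()]
#' @param truth an [sv_records()] table of confirmed events
#' @param tolerance breakpoint distance tolerance (bp)
#' @return list with `candidate_label` (`"TP"`/`"FP"` per candidate),
#'   `truth_matched` (logical per truth event), `tp`, `fp`, `fn`
#' @export
match_sv_truth <- function(candidates, truth, tolerance = 1000L) {
  if (inherits(candidates, "sv_callset")) candidates <- candidates$records
  nc <- nrow(candidates); nt <- nrow(truth)
  label <- rep("FP", nc)
  matched_t <- rep(FALSE, nt)
  if (nc > 0 && nt > 0) {
    ck <- paste(candidates$svtype, candidates$chrom1, candidates$chrom2)
    tk <- paste(truth$svtype, truth$chrom1, truth$chrom2)
    pairs <- NULL
    for (j in seq_len(nt)) {
      i <- which(ck == tk[j] &
                   abs(candidates$pos1 - truth$pos1[j]) <= tolerance &
                   abs(candidates$pos2 - truth$pos2[j]) <= tolerance)
      if (length(i)) {
        d <- abs(candidates$pos1[i] - truth$pos1[j]) +
          abs(candidates$pos2[i] - truth$pos2[j])
        pairs <- rbind(pairs, cbind(i = i, j = j, d = d))
      }
    }
    if (!is.null(pairs)) {
      pairs <- pairs[order(pairs[, "d"], pairs[, "i"]), , drop = FALSE]
      used_c <- rep(FALSE, nc)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, "i"]; j <- pairs[k, "j"]
        if (!used_c[i] && !matched_t[j]) {
          used_c[i] <- TRUE
          matched_t[j] <- TRUE
          label[i] <- "TP"
        }
      }
    }
  }
  list(candidate_label = label, truth_matched = matched_t,
       tp = sum(label == "TP"), fp = sum(label == "FP"),
       fn = sum(!matched_t))
}

#' Caller performance from match labels
#'
#' Sensitivity is `tp / (tp + fn)` and the false-positive rate is
#' `fp / (fp + tp)` (a false-discovery proportion, also reported as
#' `fdr`); both are percentages rounded half-up to two decimals. With no
#' positive calls the FPR is undefined and reported as `NA`.
#'
#' @param labels output of [match_sv_truth()], or a list with `tp`, `fp`,
#'   `fn`
#' @param caller optional caller name carried into the result
#' @return `data.frame` row with `caller`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `fpr`, `fdr`
#' @export
compute_sv_metrics <- function(labels, caller = NA_character_) {
  tp <- labels$tp; fp <- labels$fp; fn <- labels$fn
  sens <- if (tp + fn == 0) NA_real_ else
    round_half_up(100 * tp / (tp + fn), 2)
  fpr <- if (tp + fp == 0) NA_real_ else
    round_half_up(100 * fp / (fp + tp), 2)
  data.frame(caller = caller, tp = tp, fp = fp, fn = fn,
             sensitivity = sens, fpr = fpr, fdr = fpr,
             stringsAsFactors = FALSE)
}

#' Fusion caller performance against an ordered truth set
#'
#' Truth fusions are directional (5' partner then 3' partner). Candidates
#' whose unordered pair occurs in the panel of normals are discounted
#' entirely (neither TP nor FP); remaining candidates matching a truth
#' pair exactly (ordered) are TP, the rest FP; truth pairs never called
#' are FN. Metrics as in [compute_sv_metrics()].
#'
#' @param candidates `data.frame` with `gene5`, `gene3` (one row per
#'   called pair for one caller)
#' @param truth `data.frame` with `gene5`, `gene3` of confirmed fusions
#' @param panel optional panel of normals (two gene columns, unordered)
#' @param caller optional caller name
#' @return `data.frame` row as in [compute_sv_metrics()]
#' @export
compute_fusion_metrics <- function(candidates, truth, panel = NULL,
                                   caller = NA_character_) {
  if (!is.null(panel) && nrow(panel) > 0 && nrow(candidates) > 0) {
    pk <- .pair_key(panel[[1]], panel[[2]])
    candidates <- candidates[
      !.pair_key(candidates$gene5, candidates$gene3) %in% pk, , drop = FALSE]
  }
  ck <- unique(paste(candidates$gene5, candidates$gene3, sep = "\r"))
  tk <- paste(truth$gene5, truth$gene3, sep = "\r")
  tp <- sum(tk %in% ck)
  fp <- sum(!ck %in% tk)
  fn <- length(tk) - tp
  compute_sv_metrics(list(tp = tp, fp = fp, fn = fn), caller = caller)
}

#' Percentage of candidates passing a filter
#'
#' @param found number of candidates a caller reported
#' @param passed number of those that passed filtering
#' @return `100 * passed / found`, rounded half-up to two decimals; `NA`
#'   when `found` is zero
#' @export
percent_passing <- function(found, passed) {
  if (passed > found) .stopf("passed (%d) exceeds found (%d)", passed, found)
  if (found == 0) return(NA_real_)
  round_half_up(100 * passed / found, 2)
}

#' Mean read support
#'
#' Arithmetic mean of per-event supporting read counts, rounded half-up
#' to one decimal (the convention of published support summaries).
#'
#' @param support numeric vector of read-support values
#' @return the mean, or `NA` for empty input
#' @export
mean_read_support <- function(support) {
  support <- support[!is.na(support)]
  if (length(support) == 0) return(NA_real_)
  round_half_up(mean(support), 1)
}
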