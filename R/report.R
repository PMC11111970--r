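# End-to-end orchestration: run the characterization stages in order and
# assemble a machine-readable cell-line report.

#' Pipeline configuration
#'
#' Inputs may be in-memory objects or file paths; stages whose inputs are
#' absent are skipped and recorded as such in the report.
#'
#' @param callsets list of [sv_callset()] objects, or a list of lists
#'   `list(path=, caller=, technology=, mean_depth=)` to be read with
#'   [parse_sv_vcf()]
#' @param snvs an SNV table ([parse_snv_vcf()] output) or a VCF path
#' @param depth_table `data.frame` with `chrom`, `mean_depth`, or a TSV
#'   path
#' @param fusion_candidates normalized per-caller fusion rows
#'   (`gene5`, `gene3`, `caller`, `class`, `reads`)
#' @param fusion_panel panel of normals (two gene columns) or `NULL`
#' @param truth optional list with `sv` (record table) and/or `fusions`
#'   (`gene5`/`gene3` table) for evaluation
#' @param consensus a [consensus_config()]
#' @param filters a [filter_config()]
#' @param fusion_filters a [fusion_filter_config()]
#' @param window heatmap/VAF window width (bp)
#' @param out_dir optional directory for the serialized report
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(callsets = NULL, snvs = NULL, depth_table = NULL,
                            fusion_candidates = NULL, fusion_panel = NULL,
                            truth = NULL,
                            consensus = consensus_config(),
                            filters = filter_config(),
                            fusion_filters = fusion_filter_config(),
                            window = 1e6, out_dir = NULL) {
  structure(list(callsets = callsets, snvs = snvs, depth_table = depth_table,
                 fusion_candidates = fusion_candidates,
                 fusion_panel = fusion_panel, truth = truth,
                 consensus = consensus, filters = filters,
                 fusion_filters = fusion_filters, window = window,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the characterization pipeline
#'
#' Stages run in order: callset normalization, consensus merging (with
#' combination counts, size strata, breakpoint heatmap, allele
#' fractions), per-callset candidate filtering (large-SV pre-filter then
#' support/coverage filter), karyotype profiling (copy states, LOH
#' segments), fusion screening (panel subtraction, tiered filter), and
#' evaluation against a truth set when one is supplied. Every number in
#' the report is the corresponding module's output; nothing is
#' recomputed.
#'
#' @param cfg a [pipeline_config()]
#' @return a `cellline_report` list; if `cfg$out_dir` is set, the report
#'   is also serialized as `report.json` there
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(stages = character(0))

  callsets <- cfg$callsets
  if (!is.null(callsets) && length(callsets) > 0 &&
      !inherits(callsets[[1]], "sv_callset")) {
    callsets <- lapply(callsets, function(x)
      parse_sv_vcf(x$path, caller = x$caller, technology = x$technology,
                   mean_depth = x$mean_depth,
                   name = if (is.null(x$name)) x$caller else x$name))
  }

  if (!is.null(callsets) && length(callsets) > 0) {
    report$callsets <- lapply(callsets, function(cs)
      list(name = cs$name, caller = cs$caller, technology = cs$technology,
           mean_depth = cs$mean_depth, n_records = nrow(cs$records)))
    cons <- merge_callsets(callsets, cfg$consensus)
    crec <- consensus_records(cons)
    report$consensus <- list(
      n_groups = length(cons$groups),
      n_excluded_min_size = cons$n_excluded_min_size,
      n_excluded_blacklist = cons$n_excluded_blacklist,
      combination_counts = combination_counts(cons),
      size_strata = stratify_sizes(crec, cfg$filters)$counts,
      heatmap = heatmap_bins(crec, cfg$window),
      allele_fractions = as.numeric(sv_allele_fractions(cons)))
    report$filtered <- lapply(callsets, function(cs) {
      pre <- prefilter_large(cs, cfg$filters)
      sc <- support_coverage_filter(pre$retained, cfg$filters)
      list(name = cs$name,
           n_input = nrow(cs$records),
           n_prefilter_discarded = pre$discarded_count,
           n_retained = nrow(sc$retained$records),
           rejected_reasons = table(sc$rejected$reason),
           retained = sc$retained$records)
    })
    report$stages <- c(report$stages, "consensus", "filters")
    if (!is.null(cfg$truth) && !is.null(cfg$truth$sv)) {
      report$sv_eval <- do.call(rbind, lapply(callsets, function(cs) {
        compute_sv_metrics(
          match_sv_truth(cs, cfg$truth$sv, cfg$consensus$max_distance),
          caller = cs$name)
      }))
      report$stages <- c(report$stages, "sv_eval")
    }
  }

  if (!is.null(cfg$snvs) && !is.null(cfg$depth_table)) {
    snvs <- if (is.character(cfg$snvs)) parse_snv_vcf(cfg$snvs) else cfg$snvs
    dt <- if (is.character(cfg$depth_table))
      utils::read.delim(cfg$depth_table, stringsAsFactors = FALSE)
    else cfg$depth_table
    states <- call_copy_states(dt)
    windows <- vaf_windows(snvs, window = cfg$window)
    report$karyotype <- list(
      copy_states = states,
      baseline_depth = attr(states, "baseline"),
      loh_segments = detect_loh(windows, states),
      n_vaf_windows = nrow(windows))
    report$stages <- c(report$stages, "karyoprofile")
  }

  if (!is.null(cfg$fusion_candidates) && nrow(cfg$fusion_candidates) > 0) {
    agg <- aggregate_fusion_candidates(cfg$fusion_candidates)
    sub <- subtract_panel(agg, cfg$fusion_panel)
    tf <- tiered_filter(sub$retained, cfg$fusion_filters)
    report$fusions <- list(
      n_candidates = nrow(agg),
      n_panel_removed = sub$removed_count,
      n_self_pair = tf$n_self_pair,
      n_no_tier = tf$n_no_tier,
      retained = tf$retained)
    report$stages <- c(report$stages, "fusionscreen")
    if (!is.null(cfg$truth) && !is.null(cfg$truth$fusions)) {
      per_caller <- split(cfg$fusion_candidates,
                          cfg$fusion_candidates$caller)
      report$fusion_eval <- do.call(rbind, lapply(names(per_caller),
        function(nm) compute_fusion_metrics(per_caller[[nm]],
                                            cfg$truth$fusions,
                                            panel = cfg$fusion_panel,
                                            caller = nm)))
      report$stages <- c(report$stages, "fusion_eval")
    }
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("svkaryo")),
    config = list(consensus = unclass(cfg$consensus)[
      setdiff(names(cfg$consensus), "blacklist")],
      filters = unclass(cfg$filters), window = cfg$window))
  class(report) <- "cellline_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.report_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.report_json <- function(report) {
  rapply(unclass(report), function(x) {
    if (is.table(x)) as.list(x) else x
  }, how = "replace")
}

#' Render a cell-line report as text
#'
#' Deterministic plain-text tables; rendering the same report twice
#' yields byte-identical output.
#'
#' @param report a `cellline_report` from [run_pipeline()]
#' @return character vector of lines, invisibly; also printed
#' @export
render_summary <- function(report) {
  stopifnot(inherits(report, "cellline_report"))
  out <- c("== cell line report ==")
  if (is.null(report$consensus) || report$consensus$n_groups == 0) {
    out <- c(out, "no variants")
  } else {
    cc <- report$consensus$combination_counts
    out <- c(out, sprintf("consensus groups: %d", report$consensus$n_groups),
             sprintf("  %-30s %6d", cc$combination, cc$count),
             "size strata:",
             sprintf("  %-8s %6d", names(report$consensus$size_strata),
                     as.integer(report$consensus$size_strata)))
  }
  if (!is.null(report$karyotype)) {
    ks <- report$karyotype$copy_states
    out <- c(out, "copy states:",
             sprintf("  %-8s ratio=%.2f %s", ks$chrom, ks$ratio, ks$state))
    ls <- report$karyotype$loh_segments
    if (nrow(ls) > 0)
      out <- c(out, "LOH segments:",
               sprintf("  %-8s %d-%d %s", ls$chrom, as.integer(ls$start),
                       as.integer(ls$end), ls$kind))
  }
  if (!is.null(report$fusions)) {
    rf <- report$fusions$retained
    out <- c(out, sprintf("fusions retained: %d", nrow(rf)))
    if (nrow(rf) > 0)
      out <- c(out, sprintf("  %s::%s [%s]", rf$gene5, rf$gene3, rf$tiers))
  }
  if (!is.null(report$sv_eval)) {
    ev <- report$sv_eval
    out <- c(out, "SV caller evaluation:",
             sprintf("  %-10s tp=%d fp=%d fn=%d sens=%.2f%% fpr=%.2f%%",
                     ev$caller, ev$tp, ev$fp, ev$fn, ev$sensitivity, ev$fpr))
  }
  cat(out, sep = "\n")
  invisible(out)
}
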