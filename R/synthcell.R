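# Synthetic cell-line generator.
#
# Emits a truth karyotype (SVs, translocations, fusions, copy states, LOH
# segments) and caller-like observations of it (per-technology SV
# callsets, an SNV table with binomial allele fractions, a depth table,
# per-caller fusion candidate tables), with the statistical structure the
# downstream analysis assumes. Deterministic given the seed.

#' Technology profile for the SV callset simulator
#'
#' @param name callset/caller name
#' @param technology `"short_read"` or `"long_read"`
#' @param sensitivity probability a truth SV is emitted
#' @param fp_rate expected false positives per Mb of genome
#' @param jitter_sd breakpoint jitter standard deviation (bp)
#' @param support_model mean support as a fraction of `mean_depth`
#' @param mean_depth dataset mean depth of coverage (reads)
#' @param quality_fail_rate probability an emitted record fails the
#'   caller's quality filters
#' @return a `tech_profile` list
#' @export
tech_profile <- function(name, technology = c("short_read", "long_read"),
                         sensitivity = 0.9, fp_rate = 0.2, jitter_sd = 30,
                         support_model = 0.5, mean_depth = 30,
                         quality_fail_rate = 0.02) {
  technology <- match.arg(technology)
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, jitter_sd >= 0,
            quality_fail_rate >= 0, quality_fail_rate <= 1, mean_depth > 0)
  structure(list(name = name, technology = technology,
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, support_model = support_model,
                 mean_depth = mean_depth,
                 quality_fail_rate = quality_fail_rate),
            class = "tech_profile")
}

#' Fusion caller profile
#'
#' @param name caller name
#' @param class `"short_read"` or `"long_read"`
#' @param sensitivity probability a truth fusion is reported
#' @param fp_count_mean Poisson mean of false-positive candidates
#' @param panel_contamination_rate probability each panel-of-normals pair
#'   is also reported (shared-artifact contamination)
#' @param read_mean mean supporting reads for reported candidates
#' @return a `fusion_caller_profile` list
#' @export
fusion_caller_profile <- function(name, class = c("short_read", "long_read"),
                                  sensitivity = 0.5, fp_count_mean = 20,
                                  panel_contamination_rate = 0.2,
                                  read_mean = 20) {
  class <- match.arg(class)
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_count_mean >= 0,
            panel_contamination_rate >= 0, panel_contamination_rate <= 1)
  structure(list(name = name, class = class, sensitivity = sensitivity,
                 fp_count_mean = fp_count_mean,
                 panel_contamination_rate = panel_contamination_rate,
                 read_mean = read_mean),
            class = "fusion_caller_profile")
}

#' Simulation configuration
#'
#' The defaults emulate a hyperdiploid-adjacent leukemia cell line on a
#' desk-scale toy genome: five 20-Mb chromosomes (~100 Mb), one trisomic
#' and one monosomic chromosome, one 10-Mb copy-neutral LOH segment, ~450
#' intrachromosomal truth SVs plus 50 translocations, and three technology
#' profiles shaped like a 34x short-read, a 15x and an 18x long-read
#' dataset.
#'
#' @param seed integer seed; every generator call derives its randomness
#'   from it
#' @param chromosomes `data.frame` with `name` and `length` (bp)
#' @param diploid_depth depth of coverage of a disomic chromosome
#' @param copy_states named integer vector (1, 2 or 3) per chromosome;
#'   unnamed chromosomes are disomic
#' @param loh_segments `data.frame` with `chrom`, `start`, `end`, `kind`
#'   (`"LOH"` or `"cnLOH"`)
#' @param n_truth_sv named counts per intrachromosomal type
#' @param sv_size_range log-uniform size range (bp) for truth SVs
#' @param n_translocations number of interchromosomal truth breakends
#' @param tech_profiles list of [tech_profile()]s
#' @param n_truth_fusions number of truth fusion gene pairs
#' @param fusion_caller_profiles list of [fusion_caller_profile()]s
#' @param snv_density expected SNVs per bp
#' @param het_fraction fraction of SNV sites that are heterozygous
#' @param fp_min_distance minimum distance (bp) between simulated false
#'   positives and any truth breakpoint, so evaluation labels are
#'   unambiguous
#' @param gene_universe_size number of synthetic gene symbols
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = data.frame(
                         name = paste0("chr", 1:5),
                         length = rep(2e7, 5),
                         stringsAsFactors = FALSE),
                       diploid_depth = 30,
                       copy_states = c(chr4 = 3L, chr5 = 1L),
                       loh_segments = data.frame(
                         chrom = "chr2", start = 2e6, end = 12e6,
                         kind = "cnLOH", stringsAsFactors = FALSE),
                       n_truth_sv = c(DEL = 250L, DUP = 100L, INV = 100L),
                       sv_size_range = c(150, 20000),
                       n_translocations = 50L,
                       tech_profiles = list(
                         tech_profile("illumina", "short_read",
                                      sensitivity = 0.91, fp_rate = 0.47,
                                      jitter_sd = 30, support_model = 0.47,
                                      mean_depth = 34),
                         tech_profile("pacbio", "long_read",
                                      sensitivity = 0.91, fp_rate = 0.20,
                                      jitter_sd = 20, support_model = 0.64,
                                      mean_depth = 15),
                         tech_profile("ont", "long_read",
                                      sensitivity = 0.96, fp_rate = 0.04,
                                      jitter_sd = 20, support_model = 0.62,
                                      mean_depth = 18)),
                       n_truth_fusions = 7L,
                       fusion_caller_profiles = default_fusion_profiles(),
                       snv_density = 1 / 2000,
                       het_fraction = 0.6,
                       fp_min_distance = 2000L,
                       gene_universe_size = 500L) {
  stopifnot(all(chromosomes$length > 0), diploid_depth > 0,
            all(copy_states %in% 1:3), snv_density > 0,
            het_fraction >= 0, het_fraction <= 1)
  if (nrow(loh_segments) > 0) {
    len_of <- stats::setNames(chromosomes$length, chromosomes$name)
    stopifnot(all(loh_segments$chrom %in% chromosomes$name),
              all(loh_segments$start >= 1),
              all(loh_segments$end <= len_of[loh_segments$chrom]),
              all(loh_segments$end > loh_segments$start))
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 diploid_depth = diploid_depth, copy_states = copy_states,
                 loh_segments = loh_segments, n_truth_sv = n_truth_sv,
                 sv_size_range = sv_size_range,
                 n_translocations = as.integer(n_translocations),
                 tech_profiles = tech_profiles,
                 n_truth_fusions = as.integer(n_truth_fusions),
                 fusion_caller_profiles = fusion_caller_profiles,
                 snv_density = snv_density, het_fraction = het_fraction,
                 fp_min_distance = as.integer(fp_min_distance),
                 gene_universe_size = as.integer(gene_universe_size)),
            class = "sim_config")
}

#' Default seven-caller fusion simulation profiles
#'
#' Five short-read and two long-read caller profiles spanning the range
#' of sensitivity and false-positive load seen across published fusion
#' detection tools.
#'
#' @return list of [fusion_caller_profile()]s
#' @export
default_fusion_profiles <- function() {
  list(
    fusion_caller_profile("sr_precise", "short_read", sensitivity = 0.45,
                          fp_count_mean = 4, panel_contamination_rate = 0.1),
    fusion_caller_profile("sr_sensitive", "short_read", sensitivity = 1.0,
                          fp_count_mean = 25, panel_contamination_rate = 0.3),
    fusion_caller_profile("sr_mid1", "short_read", sensitivity = 0.45,
                          fp_count_mean = 60, panel_contamination_rate = 0.3),
    fusion_caller_profile("sr_mid2", "short_read", sensitivity = 0.45,
                          fp_count_mean = 300, panel_contamination_rate = 0.4),
    fusion_caller_profile("sr_noisy", "short_read", sensitivity = 0.15,
                          fp_count_mean = 350, panel_contamination_rate = 0.4),
    fusion_caller_profile("lr_clustered", "long_read", sensitivity = 0.45,
                          fp_count_mean = 30, panel_contamination_rate = 0.1),
    fusion_caller_profile("lr_pipeline", "long_read", sensitivity = 0.45,
                          fp_count_mean = 250, panel_contamination_rate = 0.2))
}

.gene_universe <- function(cfg) sprintf("GENE%04d", seq_len(cfg$gene_universe_size))

# place n non-overlapping intervals of the given sizes on the genome;
# uniform over chromosomes weighted by length, bounded retries
.place_intervals <- function(cfg, sizes, occupied = NULL, max_tries = 200L) {
  chroms <- cfg$chromosomes
  out_chrom <- character(length(sizes))
  out_start <- numeric(length(sizes))
  occ <- occupied  # list per chrom of matrix(start, end)
  if (is.null(occ)) occ <- stats::setNames(
    vector("list", nrow(chroms)), chroms$name)
  for (i in seq_along(sizes)) {
    placed <- FALSE
    for (tries in seq_len(max_tries)) {
      ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
      len <- chroms$length[ci]
      if (len <= sizes[i] + 2) next
      start <- floor(stats::runif(1, 1, len - sizes[i]))
      end <- start + sizes[i]
      prev <- occ[[chroms$name[ci]]]
      clash <- !is.null(prev) &&
        any(start <= prev[, 2] & end >= prev[, 1])
      if (!clash) {
        occ[[chroms$name[ci]]] <- rbind(prev, c(start, end))
        out_chrom[i] <- chroms$name[ci]
        out_start[i] <- start
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stopf("could not place interval %d (size %d) after %d tries",
             i, sizes[i], max_tries)
  }
  list(chrom = out_chrom, start = out_start, occupied = occ)
}

#' Generate the simulated truth
#'
#' Deterministic given `cfg$seed`. Intrachromosomal truth SVs are placed
#' uniformly without mutual overlap, with log-uniform sizes;
#' translocations link random positions on distinct chromosomes; truth
#' fusions are attached to translocation breakpoints. Each SV is
#' heterozygous (allele fraction 0.5) or homozygous (1.0).
#'
#' @param cfg a [sim_config()]
#' @return list with `sv` (an [sv_records()] table), `fusions`
#'   (`data.frame` of `gene5`, `gene3`, breakpoints), and `karyotype`
#'   (copy states, LOH segments, chromosomes, diploid depth)
#' @export
make_truth <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  types <- rep(names(cfg$n_truth_sv), cfg$n_truth_sv)
  n_intra <- length(types)
  sizes <- floor(exp(stats::runif(n_intra, log(cfg$sv_size_range[1]),
                                  log(cfg$sv_size_range[2]))))
  placed <- .place_intervals(cfg, sizes)
  het <- stats::runif(n_intra + cfg$n_translocations) < 0.7
  sv <- NULL
  if (n_intra > 0) {
    sv <- sv_records(
      id = sprintf("truth%04d", seq_len(n_intra)),
      svtype = types, chrom1 = placed$chrom,
      pos1 = as.integer(placed$start), size = as.integer(sizes),
      support = 0L,
      allele_fraction = ifelse(het[seq_len(n_intra)], 0.5, 1.0))
  }
  if (cfg$n_translocations > 0) {
    stopifnot(nrow(cfg$chromosomes) >= 2)
    pair <- replicate(cfg$n_translocations,
                      sample(cfg$chromosomes$name, 2, replace = FALSE))
    len_of <- stats::setNames(cfg$chromosomes$length, cfg$chromosomes$name)
    p1 <- floor(stats::runif(cfg$n_translocations, 1, len_of[pair[1, ]]))
    p2 <- floor(stats::runif(cfg$n_translocations, 1, len_of[pair[2, ]]))
    bnd <- sv_records(
      id = sprintf("truthT%03d", seq_len(cfg$n_translocations)),
      svtype = "BND", chrom1 = pair[1, ], pos1 = as.integer(p1),
      chrom2 = pair[2, ], pos2 = as.integer(p2), size = 0L, support = 0L,
      strand_pair = sample(STRAND_PAIRS, cfg$n_translocations, replace = TRUE),
      allele_fraction = ifelse(het[n_intra + seq_len(cfg$n_translocations)],
                               0.5, 1.0))
    bnd <- .orient_records(bnd)
    sv <- rbind(sv, bnd)
  }
  if (is.null(sv))
    sv <- sv_records(character(0), character(0), character(0), integer(0))

  fusions <- data.frame(gene5 = character(0), gene3 = character(0),
                        chrom5 = character(0), pos5 = numeric(0),
                        chrom3 = character(0), pos3 = numeric(0),
                        stringsAsFactors = FALSE)
  if (cfg$n_truth_fusions > 0) {
    genes <- sample(.gene_universe(cfg), 2 * cfg$n_truth_fusions)
    g5 <- genes[seq_len(cfg$n_truth_fusions)]
    g3 <- genes[cfg$n_truth_fusions + seq_len(cfg$n_truth_fusions)]
    bnd_rows <- which(sv$svtype == "BND")
    anchor <- if (length(bnd_rows))
      bnd_rows[(seq_len(cfg$n_truth_fusions) - 1L) %% length(bnd_rows) + 1L]
    else rep(NA_integer_, cfg$n_truth_fusions)
    fusions <- data.frame(
      gene5 = g5, gene3 = g3,
      chrom5 = ifelse(is.na(anchor), NA_character_, sv$chrom1[anchor]),
      pos5 = ifelse(is.na(anchor), NA_real_, sv$pos1[anchor]),
      chrom3 = ifelse(is.na(anchor), NA_character_, sv$chrom2[anchor]),
      pos3 = ifelse(is.na(anchor), NA_real_, sv$pos2[anchor]),
      stringsAsFactors = FALSE)
  }
  list(sv = sv, fusions = fusions,
       karyotype = list(copy_states = cfg$copy_states,
                        loh_segments = cfg$loh_segments,
                        chromosomes = cfg$chromosomes,
                        diploid_depth = cfg$diploid_depth))
}

#' Simulate a caller-like SV callset from the truth
#'
#' Each truth SV is emitted with probability `profile$sensitivity`;
#' emitted breakpoints are perturbed by rounded Gaussian jitter truncated
#' to chromosome bounds; support is Poisson with mean
#' `support_model * mean_depth` (minimum 1); records fail quality with
#' `quality_fail_rate`; breakpoint coverage is Gaussian around the mean
#' depth; the observed allele fraction is binomial around the truth
#' zygosity. False positives are added at `fp_rate` per Mb, placed by
#' rejection sampling at least `cfg$fp_min_distance` from any truth
#' breakpoint.
#'
#' @param truth output of [make_truth()]
#' @param profile a [tech_profile()]
#' @param cfg the [sim_config()] used to build the truth
#' @return an [sv_callset()]
#' @export
simulate_sv_callset <- function(truth, profile, cfg = sim_config()) {
  sv <- truth$sv
  len_of <- stats::setNames(cfg$chromosomes$length, cfg$chromosomes$name)
  det <- stats::runif(nrow(sv)) < profile$sensitivity
  obs <- sv[det, , drop = FALSE]
  n <- nrow(obs)
  if (n > 0) {
    j1 <- round(stats::rnorm(n, 0, profile$jitter_sd))
    j2 <- round(stats::rnorm(n, 0, profile$jitter_sd))
    obs$pos1 <- as.integer(pmin(pmax(obs$pos1 + j1, 1), len_of[obs$chrom1]))
    obs$pos2 <- as.integer(pmin(pmax(obs$pos2 + j2, 1), len_of[obs$chrom2]))
    intra <- obs$chrom1 == obs$chrom2
    flip <- intra & obs$pos2 < obs$pos1
    if (any(flip)) {
      tmp <- obs$pos1[flip]
      obs$pos1[flip] <- obs$pos2[flip]
      obs$pos2[flip] <- tmp
    }
    obs$size[intra] <- obs$pos2[intra] - obs$pos1[intra]
    obs$support <- pmax(1L, stats::rpois(
      n, profile$support_model * profile$mean_depth))
    obs$quality_pass <- stats::runif(n) >= profile$quality_fail_rate
    cov <- pmax(1, round(stats::rnorm(n, profile$mean_depth,
                                      0.15 * profile$mean_depth)))
    obs$position_coverage <- cov
    obs$allele_fraction <- stats::rbinom(n, cov, obs$allele_fraction) / cov
    obs$id <- paste0(profile$name, "_", obs$id)
  }

  genome_mb <- sum(cfg$chromosomes$length) / 1e6
  n_fp <- stats::rpois(1, profile$fp_rate * genome_mb)
  if (n_fp > 0) {
    fp_sizes <- floor(exp(stats::runif(n_fp, log(cfg$sv_size_range[1]),
                                       log(cfg$sv_size_range[2]))))
    fp <- NULL
    truth_pos <- rbind(
      data.frame(chrom = sv$chrom1, pos = sv$pos1),
      data.frame(chrom = sv$chrom2, pos = sv$pos2))
    for (i in seq_len(n_fp)) {
      for (tries in 1:100) {
        ci <- sample.int(nrow(cfg$chromosomes), 1,
                         prob = cfg$chromosomes$length)
        chrom <- cfg$chromosomes$name[ci]
        maxs <- cfg$chromosomes$length[ci] - fp_sizes[i]
        if (maxs <= 1) next
        start <- floor(stats::runif(1, 1, maxs))
        end <- start + fp_sizes[i]
        tp <- truth_pos$pos[truth_pos$chrom == chrom]
        if (length(tp) == 0 ||
            min(abs(tp - start), abs(tp - end)) >= cfg$fp_min_distance) {
          fp <- rbind(fp, data.frame(chrom = chrom, start = start,
                                     size = fp_sizes[i],
                                     stringsAsFactors = FALSE))
          break
        }
      }
    }
    if (!is.null(fp)) {
      m <- nrow(fp)
      fp_rec <- sv_records(
        id = sprintf("%s_fp%04d", profile$name, seq_len(m)),
        svtype = sample(c("DEL", "DUP", "INV"), m, replace = TRUE),
        chrom1 = fp$chrom, pos1 = as.integer(fp$start),
        size = as.integer(fp$size),
        support = pmax(1L, stats::rpois(
          m, profile$support_model * profile$mean_depth)),
        quality_pass = stats::runif(m) >= profile$quality_fail_rate,
        position_coverage = pmax(1, round(stats::rnorm(
          m, profile$mean_depth, 0.15 * profile$mean_depth))))
      obs <- rbind(obs, fp_rec)
    }
  }
  rownames(obs) <- NULL
  sv_callset(obs, name = profile$name, caller = profile$name,
             technology = profile$technology,
             mean_depth = profile$mean_depth)
}

#' Simulate an SNV table with karyotype structure
#'
#' Heterozygous sites draw their alternate depth binomially: around 0.5
#' under disomy, around 1/3 or 2/3 (random allele) on trisomic
#' chromosomes. Sites on monosomic chromosomes and inside copy-neutral
#' LOH segments are emitted homozygous; inside deletion-driven LOH
#' segments heterozygous sites are removed. Per-site depth is Poisson
#' with mean scaled by copy state / 2.
#'
#' @param cfg a [sim_config()]
#' @return an SNV table as in [parse_snv_vcf()]
#' @export
simulate_snv_table <- function(cfg = sim_config()) {
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(nrow(cfg$chromosomes)), function(ci) {
    chrom <- cfg$chromosomes$name[ci]
    len <- cfg$chromosomes$length[ci]
    n <- round(len * cfg$snv_density)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n))
    copy <- if (chrom %in% names(cfg$copy_states))
      cfg$copy_states[[chrom]] else 2L
    het <- stats::runif(n) < cfg$het_fraction
    if (copy == 1L) het[] <- FALSE
    loh <- cfg$loh_segments
    if (nrow(loh) > 0) {
      for (k in which(loh$chrom == chrom)) {
        inside <- pos >= loh$start[k] & pos <= loh$end[k]
        if (loh$kind[k] == "cnLOH") {
          het[inside] <- FALSE           # hets collapse to homozygous
        } else {
          drop <- inside & het           # hemizygous deletion: hets vanish
          pos <- pos[!drop]; het <- het[!drop]
          n <- length(pos)
        }
      }
    }
    depth <- stats::rpois(n, cfg$diploid_depth * copy / 2)
    keep <- depth > 0
    pos <- pos[keep]; het <- het[keep]; depth <- depth[keep]
    n <- length(pos)
    # homozygous sites sit at allele fraction 1.0; heterozygous sites are
    # binomial around 0.5 (disomy) or 1/3 and 2/3 (trisomy)
    p <- ifelse(het,
                if (copy == 3L) NA_real_ else 0.5,
                1.0)
    if (copy == 3L) {
      tri <- which(het)
      p[tri] <- sample(c(1 / 3, 2 / 3), length(tri), replace = TRUE)
    }
    alt <- stats::rbinom(n, depth, p)
    ref_b <- sample(bases, n, replace = TRUE)
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1),
                    character(1))
    data.frame(chrom = chrom, pos = pos, ref = ref_b, alt = alt_b,
               depth = depth, alt_depth = alt, vaf = alt / depth,
               population_af = NA_real_, consequence = NA_character_,
               affected_transcript_fraction = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .empty_snv_table()
  rownames(out) <- NULL
  out
}

#' Simulate a per-chromosome depth table
#'
#' Mean depth per chromosome is `diploid_depth * copy_state / 2` with
#' multiplicative Gaussian noise.
#'
#' @param cfg a [sim_config()]
#' @param noise_sd relative standard deviation of the per-chromosome mean
#' @return `data.frame` with `chrom` and `mean_depth`
#' @export
simulate_depth_table <- function(cfg = sim_config(), noise_sd = 0.02) {
  copy <- vapply(cfg$chromosomes$name, function(ch)
    if (ch %in% names(cfg$copy_states)) cfg$copy_states[[ch]] else 2L,
    integer(1))
  depth <- cfg$diploid_depth * copy / 2 *
    (1 + stats::rnorm(nrow(cfg$chromosomes), 0, noise_sd))
  data.frame(chrom = cfg$chromosomes$name, mean_depth = pmax(depth, 0),
             stringsAsFactors = FALSE)
}

#' Simulate per-caller fusion candidate tables
#'
#' Per caller: each truth fusion is reported with the profile's
#' sensitivity; false positives are Poisson-many random directed gene
#' pairs (never colliding with truth pairs); each panel-of-normals pair is
#' additionally reported with the contamination rate. Output rows are in
#' the normalized per-caller form accepted by
#' [aggregate_fusion_candidates()].
#'
#' @param truth_fusions `data.frame` with `gene5`, `gene3`
#' @param profiles list of [fusion_caller_profile()]s
#' @param panel optional panel of normals (two gene columns)
#' @param cfg a [sim_config()] (supplies the gene universe)
#' @return `data.frame` with `gene5`, `gene3`, `caller`, `class`, `reads`
#' @export
simulate_fusion_callsets <- function(truth_fusions, profiles, panel = NULL,
                                     cfg = sim_config()) {
  universe <- .gene_universe(cfg)
  tk <- paste(truth_fusions$gene5, truth_fusions$gene3, sep = "\r")
  out <- lapply(profiles, function(pr) {
    det <- stats::runif(nrow(truth_fusions)) < pr$sensitivity
    rows <- NULL
    if (any(det)) {
      rows <- data.frame(gene5 = truth_fusions$gene5[det],
                         gene3 = truth_fusions$gene3[det],
                         reads = 1L + stats::rpois(sum(det), pr$read_mean),
                         stringsAsFactors = FALSE)
    }
    n_fp <- stats::rpois(1, pr$fp_count_mean)
    if (n_fp > 0) {
      g5 <- sample(universe, n_fp, replace = TRUE)
      g3 <- sample(universe, n_fp, replace = TRUE)
      ok <- g5 != g3 & !paste(g5, g3, sep = "\r") %in% tk
      if (any(ok)) {
        rows <- rbind(rows, data.frame(
          gene5 = g5[ok], gene3 = g3[ok],
          reads = 1L + stats::rpois(sum(ok), pr$read_mean / 4),
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(panel) && nrow(panel) > 0) {
      contam <- stats::runif(nrow(panel)) < pr$panel_contamination_rate
      if (any(contam)) {
        rows <- rbind(rows, data.frame(
          gene5 = panel[[1]][contam], gene3 = panel[[2]][contam],
          reads = 1L + stats::rpois(sum(contam), pr$read_mean / 2),
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(rows)) return(NULL)
    agg <- stats::aggregate(reads ~ gene5 + gene3, data = rows, FUN = sum)
    agg$caller <- pr$name
    agg$class <- pr$class
    agg[, c("gene5", "gene3", "caller", "class", "reads")]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene5 = character(0), gene3 = character(0),
                      caller = character(0), class = character(0),
                      reads = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
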