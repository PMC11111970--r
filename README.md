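# svkaryo

Multi-technology structural-variant consensus and karyotype profiling for
cancer cell lines.

## The problem

Characterizing the genome of a cancer cell line from whole-genome
sequencing means reconciling several imperfect views of the same
karyotype: a short-read callset built from discordant read pairs and two
long-read callsets built from split reads, each with its own sensitivity,
false-positive load and breakpoint precision. `svkaryo` implements the
analysis layer of that reconciliation for users who already have caller
output (VCFs, coverage tables, fusion-caller candidate lists) and want a
reproducible, testable path from callsets to a cell-line report:

- **Consensus merging** — SV records from independent callsets are
  clustered into consensus groups when they agree on type and breakend
  orientation and both breakpoints lie within a distance tolerance
  *d* (default 1 kb), after excluding records shorter than 100 bp and
  records in blacklisted regions. Groups are tallied by their exact
  supporting-callset combination (the Venn counts of a technology
  comparison) and stratified by size into Small [100 bp, 1 kb],
  Medium (1–10 kb] and Large (>10 kb).
- **Candidate filtering** — the large-rearrangement screen: keep
  candidates with length > 100 kb or interchromosomal breakends, then
  require (1) the caller's quality filters passed, (2) support
  ≥ 5 reads *and* > 20% of the dataset's mean depth of coverage (DC),
  and (3) breakpoint coverage ≤ 150% of the mean DC. A pseudorandom
  short-read sample is drawn as the candidates with exactly 15
  supporting reads, and a deterministic cross-callset confirmation
  stands in for manual read inspection.
- **Karyotype profiling** — chromosome copy states from
  depth-of-coverage ratios against a self-bootstrapped diploid baseline
  (gain above 1.25, loss below 0.75), and loss-of-heterozygosity
  segmentation from SNV allele fractions: heterozygous sites are
  binomially spread around 0.5 under disomy, so runs of 1-Mb windows
  with (almost) no heterozygous calls mark LOH — copy-neutral when the
  depth ratio stays in [0.8, 1.2].
- **Fusion screening** — candidate tables from short- and long-read
  fusion callers are normalized, panel-of-normals pairs are subtracted,
  and candidates are retained through a four-tier rule (known
  disease-gene partner with ≥5 reads; both read classes; ≥3 short-read
  callers; ≥10 long reads).
- **Caller evaluation** — greedy one-to-one truth matching within the
  consensus tolerance, sensitivity = TP/(TP+FN), and the
  false-positive rate as used in this setting, FPR = FP/(FP+TP) (a
  false-discovery proportion; the reports also carry it under `fdr`).
- **A synthetic cell-line generator** — seeded truth karyotypes
  (non-overlapping SVs, translocations, trisomy/monosomy, LOH segments,
  fusion pairs) observed through configurable technology profiles
  (sensitivity, false positives per Mb, breakpoint jitter, Poisson read
  support), so the whole pipeline is exercisable and statistically
  testable without sequencing data.

The package ships the curated table of 23 confirmed large-scale
structural variants of the REH leukemia cell line
(`reh_confirmed_svs()`), the ETV6::RUNX1-positive B-ALL line whose
multi-platform characterization these methods come from; it doubles as
the built-in truth set and worked example.

## Worked example

A full synthetic run — truth generation, three technology callsets,
consensus, karyotype, evaluation:

```r
library(svkaryo)

cfg      <- sim_config(seed = 7)          # 100-Mb toy genome, 550 truth SVs
truth    <- make_truth(cfg)
callsets <- lapply(cfg$tech_profiles, function(p) simulate_sv_callset(truth, p, cfg))

report <- run_pipeline(pipeline_config(
  callsets    = callsets,
  snvs        = simulate_snv_table(cfg),
  depth_table = simulate_depth_table(cfg),
  truth       = truth))
render_summary(report)
```

```
== cell line report ==
consensus groups: 575
  illumina                           48
  illumina+ont                       43
  illumina+ont+pacbio               393
  illumina+pacbio                    13
  ont                                 9
  ont+pacbio                         45
  pacbio                             24
size strata:
  Small       189
  Medium      262
  Large        74
copy states:
  chr1     ratio=1.02 disomy
  chr2     ratio=0.99 disomy
  chr3     ratio=1.00 disomy
  chr4     ratio=1.47 gain
  chr5     ratio=0.50 loss
LOH segments:
  chr2     2000001-12000000 cnLOH
  chr5     1-20000000 LOH
SV caller evaluation:
  illumina   tp=451 fp=46 fn=49 sens=90.20% fpr=9.26%
  pacbio     tp=452 fp=24 fn=48 sens=90.40% fpr=5.04%
  ont        tp=485 fp=5 fn=15 sens=97.00% fpr=1.02%
```

Reading it: 393 consensus groups are supported by all three callsets;
the trisomic chromosome (chr4, depth ratio 1.47) and the monosomic one
(chr5, 0.50) are called from coverage alone; the simulated 10-Mb
copy-neutral LOH segment on chr2 is recovered exactly, while the
monosomic chr5 is (correctly) LOH over its whole length; and each
simulated caller's estimated sensitivity lands within sampling error of
its configured value (0.91/0.91/0.96).

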