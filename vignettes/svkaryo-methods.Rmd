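---
title: "Methods: consensus SV calling, karyotype profiling and caller evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SV calling, karyotype profiling and caller evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svkaryo)
```

This vignette is the package's account of its methods: the record model,
the consensus and filtering procedures, the karyotype callers, the
evaluation statistics, and — because every one of these is exercised
against simulated data — what the synthetic cell-line generator does and
does not emulate.

## The record model

Every structural variant, whatever its caller dialect, is reduced to one
flat record: a type (`DEL`, `DUP`, `INV`, `INS`, `BND`), two breakpoints,
a size, the caller-reported read support (split reads for long-read
data, discordant mate pairs for short-read data), a quality flag, and
optional breakpoint coverage and allele fraction. Three normalization
rules make downstream arithmetic uniform:

* **Breakpoint order.** Breakpoint 1 is always the lexicographically
  smaller `(chromosome, position)` end. Breakend mate pairs describe the
  same junction from both sides; after reordering they collapse onto one
  key, so a mate-complete VCF parses to exactly half its `BND` line
  count.
* **Size convention.** Intrachromosomal size is `pos2 - pos1`, not
  `end - start + 1`. This is the convention under which the curated REH
  coordinates reproduce their printed sizes exactly (e.g.
  61437807 − 35660443 = 25777364 for the 26-Mb deletion on 3p), so it is
  applied everywhere. Interchromosomal breakends carry size 0.
* **Insertions.** VCF insertion records conventionally have `END = POS`
  while their length lives in `SVLEN`. They are normalized to
  `pos2 = pos1 + size` so the single size invariant holds for all
  intrachromosomal types. Records with neither `END` nor `SVLEN` are
  rejected with an error naming the record — guessing a size would
  silently corrupt the size strata.

Breakend orientation is read from bracket notation
(`t[p[` → `+-`, `t]p]` → `++`, `[p[t` → `--`, `]p]t` → `-+`); swapping
breakpoint order reverses the pair. Symmetric types carry no orientation
and are treated as strand-compatible with everything.

Blacklist intervals are standard 0-based half-open BED. A 1-based
breakpoint `pos` falls in `[start, end)` iff `start ≤ pos − 1 < end`;
hence the last covered 1-based position of a `100–200` interval is 200,
and 201 is outside.

## Consensus merging

The merge is greedy single-linkage in a deterministic order: records are
pooled across callsets, records below the minimum size (default 100 bp;
breakends are exempt, having no length) and records with either
breakpoint in a blacklisted interval are excluded and counted, and the
remainder is sorted by `(chrom1, pos1, chrom2, pos2, id)`. Each record
joins an existing group if the group representative (the first member)
has the same chromosome pair, the same type (configurable), a compatible
orientation (equal, or either missing), and both breakpoint distances at
most `max_distance` (default 1000 bp, the tolerance at which independent
callsets of the same genome agree on large events). When several groups
match, the record joins the one with the smallest summed breakpoint
distance, the earliest-seeded group on ties; otherwise it seeds a new
group. This deterministic variant of distance-based merging gives the
properties the analysis relies on: permutation invariance of the
combination counts, nesting of consensus subsets (the three-way
consensus is contained in every pairwise one), idempotence when a merged
representative set is merged again, and conservation
(members + size-excluded + blacklisted = input).

The minimum number of supporting callsets is deliberately 1: consensus
is defined *post hoc* by `consensus_subset`, so one merge serves every
combination query.

## Candidate filtering

The large-rearrangement screen keeps candidates with length strictly
greater than 100 kb, or interchromosomal breakends. The three-criterion
filter then requires, in order: (1) the caller's own quality filters
passed; (2) support of at least 5 reads *and* strictly more than 20% of
the dataset's mean depth of coverage — an absolute floor plus a
depth-relative floor, so a 5-read event is credible at 18× but not at
35×; (3) breakpoint coverage at most 150% of the mean depth (inclusive),
suppressing collapsed-repeat pileups. Rejections are labelled with the
first failed criterion; a missing coverage value is its own label
(`no-coverage`) rather than a silent pass. Strictness follows the
wording of each rule ("a minimum of", "more than", "no greater than")
read literally.

Two desk-scale proxies replace manual steps. The pseudorandom short-read
sample is the set of candidates with exactly 15 supporting reads — in a
high-false-positive callset an arbitrary exact support count selects an
effectively random subset, and it is perfectly reproducible.
Cross-callset confirmation replaces visual read inspection: a candidate
is confirmed iff a same-type record within the tolerance on both ends
exists in at least one other callset, i.e. the event is seen at least
twice overall.

Size strata are Small [100, 1000], Medium (1000, 10000], Large
(10000, ∞) bp. The prose convention "100 bp–1 kb / 1–10 kb / >10 kb" is
boundary-ambiguous; contiguous right-closed bins were chosen (1000 is
Small, 1001 is Medium) and the boundaries are configurable. Records
under 100 bp are excluded and counted; breakends are never stratified.

The SNV impact filter retains variants that are rare in the population
(allele frequency missing or ≤ 1e-4), predicted loss-of-function or
nonsense-mediated-decay, and affecting at least 25% of the gene's
transcripts ("at least" — the 1-of-4-transcripts case passes). SnpEff
writes that fraction in its `LOF=(gene|id|n|fraction)` annotation, which
the SNV parser reads directly.

## Karyotype profiling

Copy states come from depth ratios. The diploid baseline must be
self-bootstrapped (a cell line has no matched normal): first the median
mean depth over autosomes, then one refinement pass that drops
chromosomes whose ratio falls outside [0.75, 1.25] and recomputes the
median. A trisomy sits near ratio 1.5 and a monosomy near 0.5, both far
from the default thresholds (gain > 1.25, loss < 0.75); with
per-chromosome sampling noise under 10% of the baseline, the calls are
deterministic, which the tests verify across seeds.

LOH detection works on fixed 1-Mb windows of SNV allele fractions. A
site is heterozygous when its allele fraction lies in [0.2, 0.8]; under
disomy heterozygous fractions are binomial around 0.5, so genuine LOH
produces long runs of windows with essentially no heterozygous calls.
Maximal runs of at least 5 consecutive windows with heterozygous
fraction ≤ 0.05 become segments; a segment is copy-neutral LOH when the
chromosome's depth ratio lies in [0.8, 1.2] and deletion-driven LOH
otherwise. The 1-Mb default resolves multi-Mb events (the scale of a
chromosome-arm cnLOH) with a one-window boundary error, which is the
recovery guarantee the tests assert; smaller events need a smaller
window and correspondingly more SNVs per window to keep the
heterozygous fraction stable. The trisomy allele-fraction signature
(heterozygous clusters near 1/3 and 2/3) is visible in the windowed
summaries but is deliberately not used for calling — depth is the
caller, allele fractions are the cross-check.

## Fusion screening

Per-caller candidate tables are column-mapped into a common form, rows
of the same directional pair collapsed (reads summed), and aggregated
per pair across callers with per-class caller counts. Panel-of-normals
subtraction is *unordered* — an artifact pair is an artifact in either
orientation — while truth matching in evaluation is *ordered*, because a
real fusion is directional (5′ partner → 3′ partner). The tier rule
retains a candidate satisfying any of: (T1) a known
leukemia-gene partner and ≥ 5 total reads across platforms (the read
threshold is read as cross-platform total, since per-platform
attribution varies by caller); (T2) at least one short-read and one
long-read caller; (T3) at least three short-read callers; (T4) at least
10 long reads. Self-pairs are dropped unconditionally. Retention is
monotone in added evidence, and panel subtraction commutes with the
filter — both properties are tested. A default B-ALL gene list ships in
`extdata` and is user-replaceable.

## Evaluation statistics

Truth matching is greedy one-to-one: compatible pairs (same type, same
chromosome pair, both ends within the tolerance, default the consensus
1 kb) are assigned in order of increasing summed breakpoint distance,
ties by candidate input order. Each truth event absorbs at most one
candidate, so two near-duplicates at one truth event score 1 TP + 1 FP.

Sensitivity is TP/(TP+FN). The false-positive rate follows the
operational definition used in this comparison setting:
**FPR = FP/(FP+TP)**, which is arithmetically a false-discovery
proportion — the three published (FP, TP) pairs for this analysis,
(128, 22), (606, 21) and (1469, 21), reproduce their printed
percentages 85.33 / 96.65 / 98.59 only under this definition, which the
tests pin down. To prevent downstream confusion the result tables carry
the same number under `fdr` as well. Percentages round half-up to two
decimals and mean read support to one decimal, matching how such values
are conventionally printed; base R's banker's rounding would differ on
exact ties.

## The synthetic cell line

The generator's defaults are the study conditions in miniature: a
100-Mb toy genome of five 20-Mb chromosomes; 450 intrachromosomal truth
SVs (250 DEL, 100 DUP, 100 INV) with log-uniform sizes in
[150, 20000] bp, placed uniformly without mutual overlap; 50
translocations; a trisomic and a monosomic chromosome; one 10-Mb
copy-neutral LOH segment; seven truth fusion pairs anchored to
translocation breakpoints; and three technology profiles shaped like the
real datasets — a 34× short-read profile (sensitivity 0.91, 0.47 FP/Mb,
30-bp jitter) and 15× / 18× long-read profiles (0.91 and 0.96
sensitivity, 0.20 and 0.04 FP/Mb, 20-bp jitter), with Poisson read
support whose means (~16, ~10, ~11 reads) match the observed support
regimes. Depths, sensitivities and false-positive loads are taken from
the published three-technology comparison; jitter and the 70%
heterozygous SV fraction are field-typical choices fixed once.

Design choices that make the generator a usable oracle:

* one seeded stream per run (`make_truth` seeds; the observation
  functions consume the stream), so every output is reproducible and
  cross-implementation bit-identity is not promised — statistical
  contracts are;
* false positives are rejection-placed at least 2 kb from any truth
  breakpoint, so TP/FP labels are unambiguous at the 1-kb matching
  tolerance and the detected-truth count is exactly binomial in the
  configured sensitivity — this is what lets the recovery tests use
  exact binomial confidence bounds rather than loose heuristics;
* jitter is truncated at chromosome bounds; homozygous SNV sites sit at
  allele fraction 1.0 while heterozygous sites are binomial, matching
  the bimodal allele-fraction picture the karyotype methods assume.

What it does **not** emulate — and hence what passing tests do not show
about real data: sequence context (no repeats, so no locus-dependent
caller failure), breakpoint microhomology, support that depends on
event size or type, subclonal mixtures (all events are clonal at 0.5 or
1.0), technology-specific error modes (indel-driven mismapping,
collapsed segmental duplications), and read-level artifacts. Recovery
within binomial bounds validates the pipeline's bookkeeping and
statistics, not any caller's behavior on a real genome.

Sensitivity recovery is measured on the simulated callsets *before* the
support/coverage filter: the filter intentionally removes
quality-failed and under-supported records, so applying it first would
estimate the product of sensitivity and filter pass-rate rather than
the generator parameter. The filter's own contract is tested
separately as a no-silent-loss property: every truth observation whose
simulated support and coverage meet the stated thresholds is in the
retained set.

## Problem sizes and determinism

The test suite runs the full parameter-recovery study at 200 seeded
replicates of the 100-Mb genome (3 × 100,000 pooled detection trials),
with karyotype and LOH recovery checked on 25 replicates; the
acceptance script uses 60 replicates and reports the pooled recovered
sensitivities. These sizes give exact-binomial tests enough resolution
to catch a one-point sensitivity bias while keeping a full run in tens
of seconds. All randomness flows from explicit seeds; reported
percentages are deterministic for a given seed.

## Known limitations

* The consensus representative is the first member in sort order, not a
  centroid; a pathological chain of records each within tolerance of
  the representative but not of each other is still one group
  (single-linkage behavior, shared with the established merging tools).
* `cross_callset_confirm` is a proxy for expert read review; it cannot
  distinguish a shared artifact present in two callsets from a true
  event.
* Copy-state calling assumes most autosomes are diploid; a genome where
  more than half the autosomes are aneuploid would corrupt the
  bootstrapped baseline.
* LOH segmentation is run-length-based, not an HMM/CBS segmentation; it
  trades boundary precision (one window) for having no tunable
  smoothing parameters.
* Fusion evaluation matches gene symbols exactly; paralog mismapping
  (two symbols for one locus) is not corrected.
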