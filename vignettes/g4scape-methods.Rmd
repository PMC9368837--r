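---
title: "Methods: cation-favorable G-quadruplex landscape analysis with g4scape"
author: "g4scape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cation-favorable G-quadruplex landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

DNA G-quadruplexes (G4s) fold from guanine-rich sequence, and their
formation in vitro depends strongly on the stabilizing monovalent
cation: K+ generally supports folding better than Na+, and crowding
agents such as PEG shift the balance further. BG4-antibody DNA
immunoprecipitation followed by sequencing yields genome-wide peak
calls of folded G4s under each ionic condition; comparing the K+- and
Na+-condition peak landscapes then becomes a question of downstream
peak analysis. `g4scape` implements that downstream analysis as a
reusable, tested pipeline:

1. **PQS scanning** (`scan_pqs`): putative quadruplex sequences are
   matches of G{t,}(N{1,12}G{t,}){3,} with t = 3 (G3 classes) or t = 2
   (G2 classes), on both strands (minus-strand PQSs are C-patterns on
   the forward sequence). Subtypes follow the loop-length scheme:
   GxL1-7 when every loop is at most 7 nt, GxL8-12 when at least one
   loop is 8-12 nt.
2. **Peak-set operations** (`reproducible_peaks`,
   `classify_conditions`): replicate reproducibility by >= 1 bp
   intersection, and the three-way split into common and
   condition-specific peaks.
3. **Subgenomic annotation** (`build_partition`, `assign_peaks`):
   a seven-category partition (promoter, 5'UTR, 3'UTR, exon, intron,
   downstream-of-TES, intergenic) that tiles the genome exactly.
4. **Shuffle-null enrichment** (`shuffle_intervals`,
   `subgenomic_fold`, `pqs_fold`): observed statistics divided by the
   mean over length-preserving random re-placements of the peaks
   (3 randomizations for subgenomic categories, 100 for PQS subtypes,
   both configurable), with Wilcoxon rank-sum comparisons
   (`rank_sum`).
5. **Sequence composition** (`composition_profile`): GC content,
   GC skew = (G - C)/(G + C) and AT skew = (A - T)/(A + T) in a
   scaled-region scheme: 50 equal body bins plus 1 kb flanks in 20 bp
   windows (150 bins).
6. **Signal and methylation metaprofiles** (`center_profile`,
   `methylation_profile`, `matched_random_regions`, `region_fold`,
   `metagene_profile`): peak-center-anchored +/-1 kb windows in 20 bp
   bins for quantitative tracks and for CG/CHG/CHH methylation
   (level = sum(meth)/sum(total), the pooled C/(C+T) of bisulfite
   calls), C-content-matched random controls, and TSS-to-TES metagene
   profiles by expression class.
7. **Expression association** (`classify_expression`,
   `expression_by_peak_class`): genes split into non-expressed
   (FPKM = 0) and low/medium/high tertiles of expressed FPKM,
   intersected with peak classes at promoters and gene bodies, with
   TE-gene / non-TE-gene stratification.
8. **Synthetic data** (`sim_config`, `generate_dataset`, `plant_pqs`):
   a generator that emits a complete consistent bundle (FASTA, GFF3,
   narrowPeak x 4, cytosine report, bedGraph, expression table) with a
   truth manifest, so every stage is testable against planted ground
   truth without any external download.

The package is the analysis layer only: read cleaning, alignment and
peak calling are upstream (peaks arrive as narrowPeak/BED), and motif
discovery and GO enrichment are external (the package exports MEME
input windows with `export_meme_windows`).

# Conventions and numerical choices

**Coordinates.** All interval logic runs on `GRanges` (1-based,
closed), the native currency of the Bioconductor stack; BED-family
inputs (0-based, half-open) are converted at the I/O boundary and
converted back on write, and writers invert readers byte-identically
for files the package emits. GFF3 is read with `rtracklayer` and kept
1-based.

**Scanner policy.** Matching is leftmost-longest and non-overlapping
per strand and tract class. Maximal guanine runs are absorbed whole
into tracts — a run of 7 Gs is one tract, never split into two tracts
and a G-loop — which makes counts deterministic and subtypes
well-defined. A G2-class match overlapping a G3-class match on the
same strand is suppressed, so the four subtypes are disjoint and their
percentages can be summed. Loops may contain any base except N; an N
breaks the candidate silently. Lowercase (soft-masked) sequence is
treated as normal sequence. PQSs on opposite strands are counted
separately; whether a C-pattern "duplicate" of a G-pattern should be
deduplicated is scientifically open, and keeping both is the
documented choice.

**Peak-set rules.** Overlap means >= 1 bp everywhere (bedtools
`intersect` default). Reproducible peaks keep replicate-1 coordinates.
Common peaks are the merged union of each cross-condition overlapping
cluster, so one common interval can absorb several peaks; specific
peaks keep their original coordinates. The merge rule means
common + specific counts need not sum to the reproducible count — the
conservation law is |specific| + |absorbed| = |input|, and it is
tested.

**Partition.** Promoter and downstream widths default to 1 kb
(consistent with the +/-1 kb flank used throughout the profiling
stages; the category widths are configurable). Overlaps between raw
territories resolve by the fixed priority promoter > 5'UTR > 3'UTR >
exon > intron > downstream, the residue is intergenic, and a property
test asserts the partition tiles every chromosome exactly. Peaks are
assigned to the category of their midpoint base, so each peak counts
once and percentages sum to 100.

**Enrichment null.** `shuffle_intervals` re-places each interval
uniformly (chromosome weighted by length, start uniform where the
interval fits), preserving lengths, with mutual non-overlap by
rejection sampling. Fold = observed / mean(random). When no
randomization hits a stratum the fold is reported as Inf with a
degenerate flag (0/0 is NaN). Randomization seeds derive
deterministically from one master seed.

**Profiles.** Composition statistics are computed from forward-strand
base counts; the reverse-strand profile complements the counts, which
flips skew signs. Bins with a zero denominator (e.g. G + C = 0 for GC
skew) are missing and excluded from cross-region means. Regions
shorter than 50 bp still produce 50 body bins by assigning each base
to the bin containing its midpoint. Methylation is pooled
coverage-weighted (sum meth / sum total) rather than a mean of
per-site levels — robust at low coverage, and additive under record
splitting (tested). Signal tracks are consumed as given ("normalized
read counts"); bin values are overlap-length-weighted means of track
runs, and uncovered bins are missing rather than zero.

**Rank-sum test.** `stats::wilcox.test` supplies the engine: exact
p-values for untied samples with both n <= 20, otherwise the normal
approximation with tie and continuity correction. Two samples with all
values identical return p = 1 by convention. An exact-enumeration
oracle in the test suite cross-checks small-sample p-values, and a
2,000-replicate null simulation checks the empirical size at
alpha = 0.05.

# The synthetic study conditions

The generator's defaults are the fixed study conditions under which
the pipeline is validated, chosen once:

- genome: 2 chromosomes x 2.5 Mb. The background base model forbids
  GG and CC dinucleotides, so the background PQS false-positive rate
  is structurally zero and recall/precision assertions are exact. (A
  smaller 2 x 1 Mb genome cannot hold the ~3,840 mutually disjoint
  anchor peaks that constructive overlap realization requires, which
  is why 2.5 Mb per chromosome is the default problem size.)
- 300 genes with 1-4 exons, edge UTRs, ~50% flagged as TE genes.
- 100 planted PQSs per subtype, with A/T-only loops and 15 bp
  sanitized A/T flanks so planted sites never merge.
- peaks: 2,000 per condition and replicate, lengths ~ Normal(250, 40)
  truncated at 50 bp; replicate overlap 0.80 and cross-condition
  overlap 0.60 realized *constructively* (peaks are copied and
  jittered by <= 20 bp between files, and all distinct anchors are
  mutually disjoint with >= 60 bp spacing), so classification tests
  can assert exact counts rather than statistical tolerances.
- methylation: CG 0.8 inside peaks / 0.2 background (CHG 0.6/0.15,
  CHH 0.15/0.05, following the usual plant-methylome ordering),
  per-site Beta(level, concentration 50) with Poisson(20) coverage.
- one signal track: background 1, Gaussian bumps of amplitude 5 and
  sigma 150 bp at condition-A-specific peak centers.
- expression: log-normal FPKM (meanlog 1, sdlog 1.2), 25%
  non-expressed, 2x boost for genes whose promoter holds a
  condition-A-specific peak.

What the generator deliberately does **not** emulate: realistic rice
base composition or repeat structure, read-level noise, peak-caller
artifacts, or correlated epigenomic layers. Passing tests therefore
demonstrate the correctness of the computations, not biological
effect sizes on real data.

Targeted experiments use variants of the defaults, fixed in the test
code: the planted-enrichment experiment uses a 2 x 4 Mb genome, one
condition and a 3x promoter placement bias (larger genome so that
promoter territory is not saturated; each anchor's compartment is
drawn once and only its position is resampled on collision, so
placement retries cannot distort the planted compartment
distribution); the
methylation-recovery experiment uses 2 x 2 Mb, one condition and 500
peaks (peak density low enough that +/-1 kb flanks are mostly
background). The end-to-end determinism check runs the default
conditions twice and compares reports byte for byte.

# Worked example

```{r example}
library(g4scape)

out <- file.path(tempdir(), "g4run")
res <- run_g4_pipeline(out, seed = 1)
str(res$report$peaks)

# or stage by stage:
sim <- generate_dataset(sim_config(), file.path(tempdir(), "sim"),
                        seed = 1)
genome <- read_fasta(sim$paths$fasta)
pqs <- scan_pqs(genome)
rep_k <- reproducible_peaks(
  read_intervals(sim$paths$a_rep1, "narrowPeak"),
  read_intervals(sim$paths$a_rep2, "narrowPeak"))
rep_k$overlap_ratio
```

# Known limitations

- The shuffle null is plain (length-preserving, genome-wide); GC- or
  annotation-matched randomization is out of scope, except for the
  C-content-matched controls used by the methylation profiles.
- Common-peak coordinates depend on the documented merge rule; other
  conventions (pairing, intersection spans) would give different
  common counts on real data, where the construction is not uniquely
  determined by the published counts.
- The per-stratum significance reported alongside fold enrichments
  compares a single observed value against the randomization
  distribution; with the default 3 subgenomic randomizations it is
  descriptive, not inferential — raise `n` for hypothesis tests.
- Gene models use the longest mRNA per gene; isoform-aware annotation
  is not attempted.
- TE status is whatever the annotation attribute says; the package
  does not classify transposable elements.
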