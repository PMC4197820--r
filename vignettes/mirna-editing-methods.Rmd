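---
title: "Detecting and quantifying conserved A-to-I miRNA editing"
author: "mirededit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying conserved A-to-I miRNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirededit)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Inosine base-pairs like guanosine, so an edited position inside a mature
miRNA appears in small-RNA sequencing data as an A-to-G mismatch between
reads and the genome. Editing inside the seed (nucleotides 2–7/8 from the
miRNA 5' end) redirects the miRNA to a different target set, which makes
site-specific miRNA editing a mechanism for generating regulatory
diversity — and makes distinguishing genuine editing from sequencing
error, SNPs and alignment artifacts the central methodological problem.

`mirededit` implements the full analysis chain: read filtering,
mismatch-tolerant alignment, per-site mismatch tallying with a battery of
candidate-site filters, cross-species conservation calling over miRNA
family alignments, remapping-based frequency estimation with a
fake-editing control, and the downstream statistics for tissue,
developmental and matched tumor/normal comparisons. A synthetic data
generator with per-read truth tables makes every stage testable offline.

## Detection model and filters

Reads are kept when they are 15–28 nt long after adapter removal and
every position has Phred quality ≥ 30 (an error probability of 0.1%).
Alignment allows at most one mismatch and keeps a read only if its best
stratum (fewest mismatches) contains a single alignment; reads unmapped
at full length are retried with one and then two bases removed from the
3' end, accommodating non-templated 3' additions. The aligner is exact
seed-and-extend: with one mismatch, a read splits into two exact
stretches of which the longer is at least ⌈(L−1)/2⌉ ≥ 7 nt for L ≥ 15,
so two non-overlapping 7-mer seeds guarantee that no valid alignment is
missed. (A 12-mer seed, natural for longer reads, silently loses 15-nt
reads with a central mismatch — which is why the default seed length is
7.) A brute-force sliding-window aligner with the identical contract
serves as an independent oracle in the tests.

A candidate site is a position inside an annotated mature or star miRNA
where aligned reads on the annotation's strand disagree with the genome,
counted in miRNA-sense orientation. Sites are then filtered:

* mismatches in the first base or last two bases of a read, or the first
  base or last two bases of the annotated sequence, are treated as 5'/3'
  modification artifacts and carry no weight;
* the site must be covered by at least one perfectly mapping read;
* at most one mismatch type may exceed the sequencing error rate (0.1%).
  The type frequency is measured against the site's total read coverage
  pooled over all tissues of the species: the tier thresholds below are
  explicitly tissue-specific, but nothing ties the error filter to a
  single tissue, and pooling gives the frequency estimate its maximal
  denominator so that single stray error reads at moderate coverage do
  not masquerade as a systematic second variant;
* positions coinciding with a known SNP of the same species are
  rejected.

Surviving sites are tiered per tissue: **high** when the mismatch and the
perfectly matching variant each have ≥ 5 reads and the mismatch reads are
≥ 5% of the miRNA's read total in that tissue; **relaxed** when both
variants have ≥ 1 read and the site-level mismatch frequency is ≥ 1%;
**trace** below 1%. The 5% rule is interpreted as a condition on the
mismatch variant (the headline description of the high set is "mismatch
frequency above 5%"); the per-site frequency reported to users uses reads
overlapping the site as denominator, the miRNA total entering only the 5%
threshold.

## Conservation calling

miRNAs are grouped into families and their sequences aligned. Mature
miRNA sequences are ~22 nt and near-identical within a family, so the
package uses a unit-cost Needleman–Wunsch pairwise aligner merged
progressively over a star topology ("once a gap, always a gap"); an
independent dynamic-programming cost oracle (`utils::adist`) guards the
optimum in the tests. When one species contributes several orthologs,
the one with the fewest mismatches to the reference mature sequence is
kept (ties break lexicographically, with a warning — the tie rule is a
package decision, since no convention is established).

Site calls are projected onto alignment columns. An event is *conserved*
when the column carries a non-gap A in every claiming species (a
non-conserved site is more likely to hide a SNP) and at least two species
reach the relaxed tier, with the run mode deciding whether the pair must
be at the high tier (high-confidence set) or the relaxed tier (extended
set) — both modes are exposed because the boundary between the two
published set definitions is not fully explicit. For additional species
with sparser data, a relaxed scan locates the ortholog by mapping the
reference mature/star sequence with up to two mismatches (up to five
locations, best stratum), requires read-wide quality ≥ 20 and site
quality ≥ 30, and tiers the site at ≥ 1% (relaxed), < 1% (trace), no
edited reads (none) or no spanning reads (no-data).

## Remapping-based frequency estimation

Detection treats edited and unedited reads asymmetrically (an edited read
with one extra error is lost, an unedited one is kept), so frequencies
are estimated separately: each event's annotated sequence is extracted
with 10 nt of genomic context on either side in an unedited, an edited
(G at the site) and a fake-edited version (G at the nearest other A; a
5' tie-break, logged, where the distance ties). A read counts for a
version iff it matches it exactly — no mismatches, any start/end inside
the reference — and spans that version's variant site; reads consistent
with more than one version or spanning no site are discarded, and a read
whose 1–2 nt 3' trim removed the site does not count as spanning. The
frequency is edited/(edited + unedited); the fake count estimates the
error-driven background of the estimator. A cross-mapping check remaps
counted reads against the genome and reports the fraction with perfect
matches outside the variant loci. The 5' start offset of each counted
read supports the isomiR-by-editing breakdown: a 2×2 table of start
offset (annotated vs −1) × edited status, tested with a 1-df χ² without
continuity correction (a continuity correction is deliberately not
applied; an expected-count-below-5 warning is attached instead).

## Downstream statistics

All standard tests are delegated to base R: exact two-sided binomial
tests (`binom.test`, minimum-likelihood two-sided, which at p₀ = 0.5
equals the doubled tail), per-pair 2×2 χ² without continuity correction,
Spearman correlations of editing frequency (and expression) with age,
Mann–Whitney/Wilcoxon group comparisons, Benjamini–Hochberg correction
(`p.adjust`), and classic Ward clustering (`hclust(method = "ward.D")`
on squared Euclidean distances, deterministic with index tie-breaks).
Coverage rules gate the analyses: ≥ 10 edited reads per miRNA for the
age correlations (replicates merged first), ≥ 100 reads per sample for
each tumor/normal pair. Neural tissues are brain and cerebellum;
non-neural are heart, kidney and testis. The seed span defaults to
[2, 8] inclusive and can be set to [2, 7]; the published site table
contains no position-8 event, so the two conventions agree there.

## What the simulator emulates — and what it does not

The generator builds per-species contigs containing hairpin-style
precursors (mature + loop + reverse-complement star), family membership
with bounded ortholog divergence (pairwise ≤ 3 substitutions by
default), and SNP tables. Reads are drawn from mature arms with:

* site-specific A→G edits at programmed per-sample frequencies;
* a 5' cleavage offset over {−1, 0, +1} (default 10/80/10%), optionally
  switched to a different distribution for edited transcripts to couple
  cleavage with editing;
* 1–2 nt random non-templated 3' additions (default probability 0.15 —
  the true per-transcript distribution of 3' additions is not
  established, so it is exposed as a parameter rather than asserted);
* per-base substitution errors (default 0.001, i.e. Q30) with constant
  per-run quality strings. Quality is constant because every filter in
  the pipeline thresholds on quality rather than using its shape;
  errors are substitutions only because the mapping model allows one
  mismatch and no gaps.

Read identifiers encode sample, miRNA, edited status and offset, and a
truth table accompanies every simulation, so false positives and
negatives can be accounted exactly. The simulator does **not** model
hairpin thermodynamics, ligation or amplification biases, platform error
profiles, or adapter read-through beyond a fixed adapter — passing tests
demonstrate the pipeline's behavior under its stated error model, not
robustness to every artifact of real libraries.

## Calibration experiments and problem sizes

The test suite runs the following simulation studies (sizes chosen to
mirror the study design at a desk-reproducible scale):

* **False-positive control** — 50 miRNAs, coverage 1000, error 0.1%, no
  planted editing: zero high-tier calls over 20 seeds. High tier is
  effectively unreachable by errors because 5% of a 1000-read total
  demands 50 mismatch reads where errors supply ~0.3.
* **Sensitivity** — one site at frequency 0.10, five tissues at coverage
  1000 (the core-data design of five tissues per species): high-tier
  detection in ≥ 95% of 50 seeds.
* **Estimator consistency** — frequencies 0.05/0.2/0.5/0.8 at ≥ 1000
  spanning reads, 50 seeds each: the edited count is compared with the
  exact binomial 99% interval around truth; the run is judged against
  the 99.9th percentile of the implied Binomial(200, 0.01) miss count
  (a nominal 1% miss rate cannot be asserted as zero misses).
* **Oracle equivalence** — ~1000 simulated reads over an ~10-kb genome,
  field-by-field agreement between the seed-and-extend aligner and the
  brute-force oracle.
* **Pattern recoveries** — age-trend (12 ages, slope 0.5 over the age
  range from base frequency 0.1, coverage 120), isomiR×editing coupling
  (offset distributions 45/55 vs 68/32, mirroring the published
  proportions, coverage 2500), tumor/normal downregulation (10
  patients, shift −0.15, coverage 1000) and clustering by miRNA
  identity (5 miRNAs × 3 species, profile noise SD 0.03, adjusted Rand
  index against miRNA labels): each succeeds in ≥ 90–95% of the seeded
  runs.

The published tissue/age/cancer p-values (0.012, 0.79, 0.001, 0.0003)
depend on the study's own frequency tables and unreleased expression
data; they calibrate these Monte-Carlo properties and are not asserted
as numbers.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in interval files;
  all user-facing reports are 1-based within the annotated miRNA.
* Trim retry prefers the longest alignment (untrimmed, then trim 1,
  then 2), maximizing evidence per read; trimmed-away bases do not
  exist for mismatch purposes.
* Suppressed multimappers are returned as an explicit state and logged,
  never silently dropped.
* A site with two equally frequent mismatch types is flagged and
  classified non-canonical with a warning rather than guessed.
* Degenerate rank tests (all observations tied) report p = 1: an
  all-tied comparison carries no evidence of a difference.
* Editing frequencies with a zero denominator are NA and flagged, never
  0.

## Known limitations

The aligner is exact and exhaustive but designed for miRNA-scale
references (tens of kilobases), not whole genomes. The conservation
caller assumes family membership is given, as it is in the annotation
sets the pipeline consumes; it does not infer families de novo. Clade
labels and divergence ages, where reported, are configuration metadata,
never computed. Expression matrices are consumed as already normalized,
and editing quantifications are deliberately not normalized across
samples.
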