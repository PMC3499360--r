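---
title: "Methods: metagene profiling and promoter-peak persistence of heterochromatin ChIP signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metagene profiling and promoter-peak persistence of heterochromatin ChIP signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachip)
```

## The scientific setting

In *Drosophila melanogaster*, Heterochromatin protein 1a (HP1a) and the
histone marks it reads (H3K9me2/me3) blanket the pericentromeric regions,
the small 4th chromosome and the interior cytological block 2L:31. Three
methyltransferases divide the labor of writing H3K9me: Su(var)3-9 serves
the pericentromeric blocks, Setdb1 serves chromosome 4 and 2L:31 (on
chromosome 4 together with the chromosome-specific protein POF), and G9a
has no detectable regional role. Comparing ChIP tiling profiles of HP1a
across wild type and null mutants of these enzymes reveals a two-component
binding pattern on active genes: enrichment across gene bodies that
collapses when the region's methyltransferase (or POF, for chromosome-4
bodies) is lost, and a sharp promoter peak that persists in every mutant.
These *methylation-independent* promoter peaks sit in A/T-rich, DNase
accessible promoters and are co-occupied by heterochromatin protein 2
(HP2).

`metachip` implements the analysis layer of that study design as a tested,
reproducible pipeline: region-stratified 8-feature average gene
("metagene") profiles, promoter-peak detection and persistence
classification across genotypes, peak-centered co-factor profiles,
promoter sequence statistics with Mann-Whitney group comparisons, binary
chromatin-factor co-occupancy with a prevalence filter, and sliding-window
DNase cleavage density. A seeded generator synthesizes genomes and signal
tracks with exactly this structure, so the whole pipeline runs, and is
validated, without any external download.

## The metagene model

Every gene is represented by one transcript: the most strongly expressed
one, with ties broken by longer span and then lexicographically smaller
transcript id. Eight features are derived from it:

* **P** (promoter): up to 500 bp upstream of the TSS, truncated at the
  nearest neighboring transcript boundary (TSS or transcription stop,
  treated as half-open cut points) when that is closer.
* **IG** (intergenic): from the next boundary upstream of the promoter to
  the promoter start. If no boundary exists upstream (first gene on a
  chromosome), IG is empty rather than extended to the chromosome end —
  the definition is anchored on the *next* boundary, and an unbounded
  stretch would dominate the region average.
* **E1–E5**: five equal bins over the *concatenated exons* of the selected
  transcript, in transcript (5′→3′) order. With concatenated length
  `L`, bin `k` covers concatenated positions `[floor((k−1)L/5),
  floor(kL/5))` and is mapped back to genomic intervals; a bin may split
  across an exon junction. The alternative reading — five bins over the
  genomic span — is not used because introns are reported as their own
  feature (**IN** = span minus exons), which only makes sense if the body
  bins exclude them.

A feature's per-gene value is the mean of all probe values whose midpoint
falls in the feature (per-base means for base-resolution tracks such as
DNase density); features with no covered position are missing for that
gene. The region profile averages per-gene values with equal gene weights
— duplicating a gene's probes at double density does not move the region
mean — restricted to *active* genes (selected-transcript expression above
a threshold, default 0). Region membership is decided by the TSS alone.

Bidirectional or tail-to-head gene arrangements can place one gene's
promoter inside another gene's intergenic interval; both genes keep their
own features, so IG region means sit above the noise floor wherever
promoters are shared. This is a property of the definitions, not an
artifact.

## Signal model

Tracks are log2 ChIP/input ratios at probe midpoints (`log2_ratio()`
forms them from paired intensity tracks with a pseudocount). Interval
tracks read from bedGraph or fixed-step WIG place each interval's value at
`floor((start+end)/2)`; the tiling platform's own probe-coordinate
convention is not documented, and midpoints make bin assignment
unambiguous.

Smoothing is an unweighted sliding-window mean with a 200 bp default
bandwidth (window `±bandwidth/2`, both ends inclusive). The tiling-array
software used upstream of the original profiles applies a pseudo-median
(Hodges–Lehmann) estimator at the same bandwidth; the package deliberately
uses the plain mean because it is transparent, exactly testable against a
brute-force oracle, and linear (the smoothed track of a sum is the sum of
smoothed tracks). Replicates are averaged probe-wise after the log2
transform; smoothing before averaging and averaging before smoothing
commute for this estimator, so the order exposed by the pipeline
(smooth, then average) is a presentation choice, not a modeling one.

## Promoter peaks and persistence classification

Peak detection scans each gene's promoter extended by ±100 bp in the
smoothed track and reports the maximal probe as the gene's peak if it
reaches `min_height` (default 0.75 log2 units — half the generator's
promoter effect, about 4.3 noise standard deviations after smoothing) and
is a local maximum of the full track; ties resolve to the leftmost probe,
and a gene has at most one peak. The original study annotated such peaks
manually; an explicit, parameterized rule is used here because
reproducibility requires one.

Persistence is classified per peak against the mutant lacking the
region's methyltransferase (Setdb1 for chromosome 4 and 2L:31, Su(var)3-9
for pericentromeric; configurable):

* **methylation independent** — mutant height at the wild-type center
  (maximum within ±100 bp) is at least `retention_ratio` (default 0.5)
  of the wild-type height *and* the mutant gene-body mean (over E1–E5) is
  at most `body_loss` (default 0.5) of the wild-type body mean;
* **methylation dependent** — mutant height below the retention
  threshold;
* **ambiguous** — anything else, including genes whose region has no
  mutant track.

On the synthetic genome the genes that retain gene-body enrichment in the
mutant (the silenced HP1a-target pair, see below) are deliberately
*ambiguous* under this rule: their peak persists but their body is not
lost, which is exactly what the rule should say.

## Sequence statistics

A/T content is `(#A + #T) / (#A + #C + #G + #T)` with `N` excluded from
both counts. Motif scores are maximum log2-odds over all windows on both
strands (`sum_i log2(p_i(b)/bg(b))`, in bits); windows containing `N` are
skipped. Both-strand scanning is used because motif occurrences in
double-stranded DNA are strand-agnostic; a sum-over-windows aggregate is
available as an option. Motif *discovery* is out of scope — any position
weight matrix can be supplied, and the generator's planted matrix ships as
the default.

Group comparisons (each heterochromatic region against the euchromatic
control) use the two-sided Mann-Whitney U test with midrank ties: exact by
full enumeration when `n1 + n2 ≤ 16` without ties, otherwise the normal
approximation with tie and continuity corrections. Following the original
presentation, no multiple-testing correction is applied by default; a
Bonferroni option exists. The exact two-sided p doubles the smaller tail
probability, capped at 1 — the same convention the enumeration oracle in
the test suite derives independently.

## Occupancy and accessibility

A promoter counts as bound by a factor when any factor interval overlaps
it by at least 1 bp (half-open; abutting intervals do not overlap). The
binding data this emulates come pre-classified by an external consortium
whose rule is not restated in the literature this package follows, so the
minimal overlap rule is an explicit surrogate with a `min_overlap`
parameter. A factor passes the prevalence filter when it is bound to
*strictly more than* 50% of active-gene promoters in the prevalence
region (chromosome 4); a factor at exactly one half fails.

DNase cleavage density sums per-base counts in a 150 bp window centered on
each covered base (left-heavy by one base for even windows — the window
`[p − 75, p + 74]` for the default). Density is computed only where
counts are defined and windows truncate at the edges of covered runs. The
accessibility metagene is the same 8-feature procedure computed on the
per-base density track. Counts are used raw; a per-million scaling is a
presentation concern left to the caller since all contrasts reported here
are ratios within one track.

## The synthetic generator

`synthetic_config()` fixes the study conditions; `generate_genome()` and
the track generators are deterministic functions of its single seed (each
generated object draws from a sub-seed derived from the seed and the
object's name, so adding a track never perturbs another).

* **Layout** — a chromosome-4-like chromosome and a 2L-like chromosome
  carrying a pericentromeric block, interior 2L:31-like block and
  euchromatin. Genes occupy non-overlapping 4 kb slots (lengths uniform
  800–2200 bp, 1–5 exons with a 30 bp segment floor, random strands),
  leaving every promoter its full 500 bp and a non-empty intergenic
  stretch for interior genes.
* **Expression** — log-normal for active genes; a configurable fraction
  (default 0.2) is silent. A quarter of genes get a second, shorter and
  more weakly expressed transcript so transcript selection is actually
  exercised. Two chromosome-4 genes (configurable) are silenced yet carry
  HP1a promoter and body enrichment in *every* genotype, emulating the
  silent HP1a-bound domain pair observed in the middle of the real
  chromosome 4.
* **ChIP tracks** — i.i.d. Gaussian noise (sd `sigma`, default 0.3 log2
  units) plus additive effects: promoter peaks of height `h_p` (default
  1.5) on HP1a tracks wherever the genotype map retains them, and
  gene-body enrichment `h_b` (default 1.0) over exonic probes of active
  genes wherever bodies are retained. H3K9me tracks never receive
  promoter peaks — the promoters detectably lack the mark — and
  euchromatin never receives any enrichment. The genotype map encodes the
  methyltransferase division of labor described above; pericentromeric
  behavior keys on Su(var)3-9, chromosome 4 and 2L:31 on Setdb1, and the
  Pof genotype removes chromosome-4 bodies only.
* **Bump shape** — the default promoter bump is *rectangular*: `h_p`
  across the defined promoter. A Gaussian shape (sd 150 bp) is available,
  but a Gaussian of that width centered in a 500 bp promoter attenuates
  the promoter *feature mean* to about 0.68 of its height, which would
  defeat the package's own calibration contract that feature means
  recover the configured effect sizes exactly. The peaked shape is kept
  for the HP2 co-factor track (Gaussian, sd 150 bp, co-centered with
  every wild-type HP1a promoter peak), where a maximum at offset zero is
  the property of interest.
* **Sequence** — i.i.d. bases at background A/T 0.50 with promoter A/T
  raised per region (defaults 0.65 on chromosome 4, 0.62 in 2L:31 and
  pericentromeric blocks, 0.55 in euchromatin) and one planted motif
  instance per promoter with a region-specific probability.
* **Factors and DNase** — per-promoter Bernoulli binding intervals per
  factor with region-specific probabilities, and per-base Poisson
  cleavage counts over each gene's territory with promoter rates raised
  (chromosome 4 most) and chromosome-4 body rates lowered relative to
  euchromatin, reproducing the promoter-open / body-closed contrast.

The effect sizes `h_p = 1.5`, `h_b = 1.0`, `sigma = 0.3` are calibration
choices, not literature values — the original profiles are published as
figures, not effect sizes. They give a promoter peak that is clearly
resolvable (5 noise SDs per probe) without being trivial, and a realistic
peak-to-body ratio of 1.5.

What the generator does **not** emulate: real sequence composition
(repeats, transposons, codon structure), array hybridization artifacts,
probe-level GC effects, replicate batch structure, copy-number variation,
or biologically correlated noise. Passing tests therefore demonstrate
that the *analysis* is correct and well-calibrated under the stated
signal model; they do not certify performance on real tiling arrays,
where the noise is neither independent nor Gaussian.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package; GFF3
  converts at the boundary (read and write), BED/bedGraph pass through.
  The TSS of a minus-strand transcript is `span_end − 1`.
* A transcript shorter than 5 bp still defines all five bins; some are
  empty and simply contribute nothing. An empty probe track smooths to an
  empty track. A gene with an empty promoter is skipped by peak
  detection. Two all-identical samples give a degenerate Mann-Whitney
  result with `p = 1`.
* Peak-detection ties go to the leftmost probe; transcript-selection ties
  go to the longer span, then the lexicographically smaller id. Both are
  arbitrary but deterministic.
* Writers emit floating values at fixed precision and a version header
  without timestamps, so identical configurations produce byte-identical
  files; the pipeline manifest records MD5 content hashes.

## Problem sizes

The shipped validation uses genomes of 20–200 genes: per-base enumeration
oracles on 20 random toy genomes, a 200-gene calibration genome (100
chromosome-4, 100 euchromatic) for parameter recovery and classification
operating characteristics, 200-replicate simulations for the prevalence
filter and the A/T power check, and a 120-gene demo genome for the
end-to-end determinism check. These sizes put every Monte-Carlo check's
sampling error well inside its acceptance band while the full suite runs
in a few minutes on one CPU.

## A worked sketch

```{r example, eval = FALSE}
library(metachip)

cfg <- synthetic_config(seed = 1)
genome <- generate_genome(cfg)

wt <- generate_chip_track(genome, "wildtype", "HP1a")
mut <- generate_chip_track(genome, "Setdb1", "HP1a")

mg <- region_metagene(wt, genome$annotation, genome$regions)
autoplot(mg)

sel <- assign_regions(define_promoters(select_transcripts(genome$annotation)),
                      genome$regions)
fm <- build_feature_map(sel)
peaks <- detect_promoter_peaks(smooth_track(wt, 200), fm, min_height = 0.75)
classified <- classify_peak_persistence(peaks, smooth_track(wt, 200),
                                        list(Setdb1 = smooth_track(mut, 200)),
                                        fm, sel)
table(classified$classification)

# or the whole thing in one call:
res <- run_demo(seed = 7)
```

## Known limitations

* The smoothing estimator is a mean, not the pseudo-median the original
  array software used; profiles from heavy-tailed raw data will differ.
* The peak rule and the persistence thresholds (`r = 0.5`, `b = 0.5`) are
  surrogates for manual annotation; the published count of 34 manually
  annotated peaks is not a quantity this package reproduces.
* The occupancy "bound" rule is a 1 bp overlap surrogate for an external
  consortium's classification.
* Real-data ingestion is limited to the text formats listed in the IO
  layer (GFF3, BED, bedGraph, fixed-step WIG, FASTA, TSV); bigWig, BAM
  and raw array intensity files are out of scope.
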