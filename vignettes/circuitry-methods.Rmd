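---
title: "Methods: super-enhancer calling and core regulatory circuitry mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer calling and core regulatory circuitry mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`crcmapr`, in the spirit of a methods section: what each stage computes,
which parameters matter, what the synthetic data emulate, and where the
package had to make a call that the underlying procedure leaves open.

## Coordinates and interval algebra

All genomic spans are 0-based half-open (the BED convention); conversion
happens only at parse/serialize boundaries. Two consequences follow and
are deliberate:

* **Adjacent intervals merge at gap 0** in `merge_intervals()`: with
  half-open coordinates, `end == next start` means zero intervening
  bases.
* **Distances are gap counts**: `nearest_distance()` returns 0 for any
  overlap and otherwise the number of bases strictly between the closest
  ends. Every distance rule in the package (active-gene window, TSS
  exclusion, proximal assignment, Promoter/Enhancer/Distal bins) uses
  this one definition.

Strand is carried through readers and writers but ignored by interval
arithmetic; only motif scanning is strand-aware.

## Read densities

`region_density()` implements rpm/bp: reads are extended 3′-ward from
their 5′ start to `max(native length, 200)` bases (unstranded fragments
extend rightward — the extension length is specified by the procedure,
the direction for unstranded input is our convention), per-base coverage
is summed over the region as exact integer counts, then divided by region
length and by millions of mapped reads. The total mapped count is
supplied by the caller (sidecar file or argument); whether it is pre- or
post-deduplication is the caller's responsibility and is echoed in run
logs. Coverage accumulation before normalization is integer-exact, so
identical inputs give bit-identical densities.

`summit_matrix()` evaluates the same density in 10 bp bins across a
10 kb window centered on peak summits (1,000 columns); bins running off a
chromosome end are zero-filled rather than dropped so rows stay aligned.

## Super-enhancers

Stitching pools H3K27ac peaks from **all** cell lines, removes peaks
lying entirely within ±2,500 bp of any TSS (whole-peak removal, no
truncation of partial overlaps — the simplest reading of the exclusion
rule; the logged peak counts make the choice auditable) and merges
survivors at 1,638 bp. Regions are scored on the **pooled** fragment
track (fragments concatenated, totals summed): since the stitched
peakset itself pools all lines, scoring against the pooled library is
the consistent choice. An optional control track is subtracted with a
floor at zero. The score is total signal (density × length), the
quantity the rank-ordering approach ranks on; `score_mode = "mean"` is
available.

The cutoff: order regions by ascending signal, scale rank and signal
each to [0, 1], and find the first point whose outgoing discrete slope
exceeds 1. That point and everything above it are super-enhancers. Two
properties follow:

* the SE set is always an upward-closed prefix of the signal ranking;
* the cutoff point itself is included. On a sharp hockey stick whose
  first steep segment starts at the strongest "body" region, that
  boundary region is flagged along with the true tail — visible on the
  synthetic fixture, where the called set is the 10 planted SEs plus one
  boundary region (base-level Jaccard ≈ 0.97). This is inherent to the
  tangent-slope-1 geometry, not a bug; the manual override
  (`super_cutoff` on a pre-filtered table, or `score_mode`) is available
  when a different convention is wanted.

If all signals are equal no cutoff exists; the function warns and flags
nothing.

Gene assignment gives each SE its overlapping-TSS genes, genes within a
50 kb proximal window (the cited tooling's convention; the procedure
itself does not define "proximal"), and always the single closest gene.
Duplicates collapse to the strongest relation. Nucleosome-free regions
are merged ATAC peaks **fully contained** in an SE assigned to at least
one active gene — containment, not overlap, so a peak straddling an SE
boundary is excluded.

## Motif scanning with exact p-values

PWMs are log2-odds matrices built from count matrices with a
background-scaled pseudocount (default 0.1). The null score distribution
is computed exactly by column-wise convolution on a rounded score grid
(granularity 1e−3 bits, configurable): the rounding bounds the dynamic
programming table at the cost of at most L·g/2 bits of score slack, and
the resulting tail probabilities match full 4^L enumeration to numerical
precision for any motif the enumeration can reach (the test suite checks
L ≤ 8 under uniform and skewed backgrounds).

Scanning evaluates every window on both strands (reverse strand via the
reverse-complemented matrix, coordinates reported on the forward
system); windows containing N are skipped. The background is estimated
from the pooled mononucleotide composition of the scanned NFR sequences
(overridable), matching scanner-default behavior. Benjamini–Hochberg
control is applied over **all scanned windows**, not just emitted hits —
the q-value of a hit depends on the full family size — with one family
per motif by default (`fdr_scope = "per-tf"`); a single global family is
available since the original analysis does not record which was used.
Hits are kept at q ≤ 1e−5.

## The circuitry

Candidate TFs are genes that are active, assigned a super-enhancer, and
present in the motif database (exact, case-insensitive symbol match;
unmatched motifs are reported, never silently dropped). An edge A → B
requires at least one q-passing hit of A's motif in an NFR contained in
an SE assigned to B; evidence is aggregated per ordered pair. Total
degree is |unique in-set| + |unique out-set|; a self-loop contributes
its TF once to each set (autoregulation is the hallmark of these
circuits, so it is counted by default; `exclude_self` removes it).
Ranking is by descending total degree, ties by out-degree then name, so
reports are deterministic.

## Chromatin states

The consensus peakset keeps transitive overlap groups supported by ≥ 3
distinct cell lines; the representative summit is the summit of the
highest-signal member (the least arbitrary single choice — the
underlying description centers on "cell line specific" summits without
naming the line). Summit matrices for H3K27ac, H3K4me1 and H3K4me3 are
averaged across lines, z-scaled per mark (so no mark dominates the
Euclidean metric; `scale = FALSE` reproduces clustering on raw
densities, since the original description does not state whether
features were scaled), concatenated, and clustered with Ward-D2 linkage;
the tree is cut at k = 3. Labels are renumbered by decreasing mean raw
H3K27ac so "state 1" is stable across runs.

## Regulated-gene categories

The DE filter keeps |log2FC| > 0.6 with adjusted p < 1e−10 (both
strict). One quoted description of this filter prints the adjusted-p
inequality with the opposite sign; selecting the *null* genes for
downstream analysis is not coherent, so the package implements `<` and
documents the discrepancy here. Distance bins: Promoter d < 10 kb,
Enhancer 10 kb ≤ d ≤ 400 kb, Distal d > 400 kb. The printed bin
definitions leave both boundary points ambiguous; the package follows
the strict `<` at 10 kb and closes 400 kb on the Enhancer side so the
partition is total. Genes with no consensus peak on their chromosome are
`Unassigned`. Category effect sizes are compared with Welch's unequal
variance t-test (`stats::t.test`), reported pairwise.

## The synthetic data

`generate_bundle()` writes a complete input set — genome FASTA, TSS
table, JASPAR motifs, per-line narrowPeak files and fragment BEDs with
total-mapped sidecars for five tracks, a DE table — plus machine-readable
ground truth. It emulates the *structure* the analysis assumes:

* a planted TF network (one master regulating every TF including
  itself, every TF regulating the master, plus a chain) whose every edge
  is realized as a high-information motif instance (18 bp,
  near-deterministic columns, ≈ 34 bits) written into an NFR of the
  target's planted SE;
* hockey-stick enhancer signal: ~22 low-signal single-peak "body"
  regions (Poisson fragment counts, mean 25 per line per peak) against
  10 planted SEs of three constituents each (mean 150), an
  order-of-magnitude signal separation;
* three chromatin-state archetypes (H3K27ac+H3K4me1, H3K27ac+H3K4me3,
  low) at 150 TF binding sites, plus low-support decoy sites that the
  3-of-4 rule must drop;
* negative-control structure throughout: promoter-proximal peaks that
  the TSS exclusion must remove, ATAC peaks straddling SE boundaries
  that containment must drop, inactive genes, null DE genes with
  uniform p-values.

Fragment counts are Poisson in the configured rate, so expected
densities scale linearly with the generator's signal parameters. One
random stream is derived per (seed, file) pair, so adding a track never
perturbs another file, and a fixed seed yields byte-identical
directories. DE effects are Normal(−1.0/−1.5/−2.0, 0.3) for
promoter/distal/enhancer-category targets with adjusted p = 1e−15, and
Normal(0, 0.15) with uniform p for nulls — clean separation at the
default thresholds, with the enhancer-vs-promoter gap sized so the
Welch comparison is decisively significant at the fixture's group sizes.

What the generator does **not** emulate: realistic nucleosome
positioning, fragment-length mixtures, mappability or GC biases,
correlated noise between marks, or motif occurrences arising from
sequence context. Passing the planted-recovery tests therefore
demonstrates the correctness of the inference machinery, not its
robustness to the full noise structure of real chromatin data.

Problem sizes: the `small` fixture (2 Mb, 40 genes, 8 TFs, 150 sites)
runs each pipeline in a few seconds and is what the test suite and the
acceptance script use, with the planted-recovery check repeated over ten
seeds; `medium` (10 Mb, 300 genes, 25 candidate TFs — the scale of a
real circuitry run) is provided for heavier exercises.

## Numerical and degenerate-input conventions

* Score grid granularity 1e−3 bits; coverage sums integer-exact before
  normalization; written numbers use fixed notation with trailing-zero
  trimming so reruns are byte-identical.
* Ties: ranking breaks signal ties by longer region then coordinates;
  nearest-gene ties by smaller TSS position then input order; consensus
  summit ties by leftmost summit; TF ranking ties by out-degree then
  name.
* Degenerate inputs: empty peak lists and empty DE tables return empty
  results (with a warning where a stage becomes vacuous); all-equal SE
  signals produce zero SEs with a warning; a `total_mapped` of zero, a
  motif column summing to zero, an NFR outside the genome, or a hit in
  an NFR that maps to no SE are hard errors naming the offending record.

## Known limitations

* Input-DNA normalization is plain subtraction with a zero floor; no
  scaling model.
* One genome-wide background per scan; no per-region or dinucleotide
  background models.
* The gene-collapsing step implied by per-gene SE counts in published
  analyses (one "best" SE per gene) is not standardized; the package
  reports the full many-to-many assignment.
* `read_bundle()` loads everything into memory; the package targets
  desk-scale reanalysis and planted-data validation, not
  whole-genome-scale production runs.
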