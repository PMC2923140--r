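---
title: "Subpeak calling and gene annotation of enrichment regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subpeak calling and gene annotation of enrichment regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaktools)
```

## The problem

Peak-calling programs for ChIP-seq and ChIP-chip report contiguous
regions of signal enrichment. Two properties of these regions complicate
downstream analysis. First, callers merge adjacent areas of enrichment,
so one reported peak often covers several distinct binding events; motif
discovery and binding-site counting both degrade when composite regions
are treated as single sites. Second, interpreting tens of thousands of
loci requires relating each one to the annotated gene models around it —
which gene lies downstream on each strand, which transcription start
site (TSS) is closest, whether a within-gene hit falls in an exon,
intron or untranslated region — and doing so naively by scanning the
whole annotation per peak is quadratic.

`peaktools` addresses both: a *splitter* that subdivides multimodal
regions into subpeaks at signal valleys, and an *annotator* built on a
nested containment list (NCL) index that answers downstream-gene,
nearest-TSS and dataset-overlap queries in logarithmic time per locus,
with a Monte-Carlo enrichment P-value for inter-dataset overlap.

## Coordinates

Internally every interval is 0-based and half-open, `[start, end)`. The
parsers convert at the boundary: BED and bedGraph records are taken
verbatim; GTF (1-based, inclusive) becomes `(start - 1, end)`; WIG
`fixedStep`/`variableStep` positions (1-based) shift down by one. A
single internal convention removes the most common class of interval
arithmetic error; the round-trip tests verify the conversion per record.

## The splitting rule

For a peak with depth profile $d$, local maxima are located by a
relative-height scan: a position is a maximum when its depth is at least
both flanking non-equal depths (boundary positions compare inward), and
every maximal plateau is represented once at its leftmost base. For each
adjacent pair of maxima with heights $h_i$ and $h_{i+1}$, the division
threshold is

$$ t = f \cdot \min(h_i, h_{i+1}), $$

where $f$ is the *valley factor*. If the minimum depth on the open
interval between the two maxima falls below $t$, the peak is cut at that
minimum and the two maxima seed separate subpeaks; otherwise the maxima
merge. Subpeaks tile the parent exactly before any filtering, and a
`min_height` filter then removes subpeaks whose summit depth is too low.

Three decisions here were genuinely open and are fixed as follows:

* **Cut position.** The cut is placed at the valley minimum, not midway
  between the maxima; the leftmost deepest base wins ties, and the
  valley base joins the right-hand subpeak. Cutting at the minimum keeps
  each subpeak's flanks monotone toward its own summit; the leftmost
  conventions make output deterministic.
* **Valley factor default 0.6.** The multiplier is inherently a
  user-facing sensitivity dial; 0.6 separates clearly distinct summits
  (valley below 60 % of the lower summit) without fragmenting noisy
  plateaus, and is exposed as `--valley` so any published setting can be
  matched. Subpeak counts are non-decreasing in this parameter, which
  the acceptance suite asserts over a grid.
* **`min_height` defaults to 0** (no filtering) and `summit_flank` to
  100 bases per side for sequence windows; both are plain knobs with no
  privileged value.

Depth is carried as a float so that fluorescence tracks from tiling
arrays work unchanged, even though sequencing read counts are integral.
Peaks whose signal coverage is entirely zero yield no subpeaks and a
warning rather than an error, since peak and signal files can come from
different runs.

## The nested containment list

Gene annotations of higher eukaryotes contain transcripts nested inside
the introns of others, so a start-sorted list does not have sorted ends
and plain binary search breaks. The NCL repairs this by moving every
interval contained in another into the *sublist* of its smallest
container, recursively. What remains at each level is sorted by both
boundaries, so:

* `first_start_after` is a strict binary search over the primary list;
* an overlap query locates a contiguous run at each level by binary
  search on ends and recurses into the sublists of the run's members;
* `containers_of` walks the parent chain, innermost first.

Construction sorts by (start ascending, end descending, input order) and
assigns parents in one stack pass, $O(n \log n)$ overall. Two
conventions keep every interval in exactly one home: identical spans
nest by input order (the first encountered is the container of later
duplicates), and strand is payload rather than index key — one index per
chromosome carries both strands because the downstream-gene query needs
interleaved access to them.

A useful structural fact the implementation exploits: depth-first
pre-order of the containment forest coincides with the build's sort
order, so flattening the index is a constant-time view of the arrays,
and the flatten-is-a-permutation invariant is cheap to test at scale.

## Downstream genes, TSS, and components

**Downstream semantics.** A gene is downstream of a peak when the peak
lies upstream of the gene's TSS in the gene's own reading direction:
forward-strand genes with `tx_start >= peak_end`, reverse-strand genes
with `tx_end <= peak_start`. The reported distance is the gap between
the facing boundaries (peak end to `tx_start` for forward genes,
`tx_end` to peak start for reverse genes); zero means direct adjacency,
and transcripts overlapping the peak are never candidates — they are
reported separately with a component classification.

**Search strategy.** On the forward strand the answer minimises
`tx_start` among genes starting at or after the peak end. Primaries
starting after the peak form a suffix of the primary list; the walk
scans it left to right, descending into sublists, and stops as soon as
the next primary's start cannot beat the best candidate. Sublists of
primaries that *overlap* the peak are searched too: a small gene can sit
wholly downstream of the peak inside a host gene that spans the peak
itself. The reverse strand is the mirror image, maximising `tx_end`
over the prefix of primaries ending at or before the peak start — here
the containment sublists are essential, because a reverse gene ending
near the peak may be nested inside a forward gene whose own end is far
away. The tests assert exact agreement with a quadratic linear scan
across hundreds of randomized annotation sets, and a strand-reflection
property (mirroring all coordinates and strands swaps the forward and
reverse answers).

**Bidirectional promoters** are flagged when non-overlapping downstream
genes exist on both strands within a window, 1000 bases by default. The
window is a configurable convention, not an inference.

**Nearest TSS.** The peak's centre is `floor((start + end - 1) / 2)`
(the left-of-centre base for even lengths). Candidate TSSs are probed in
both directions around the centre's insertion point in a per-chromosome
start-sorted TSS table built once per index, which by construction
returns the global minimiser of `|TSS - centre|`; equidistant
transcripts tie-break to the lexicographically smallest `transcript_id`
and all ties are reported. The signed distance is positive when the
centre lies downstream of the TSS in the gene's transcription direction.

**Component classification** is by the peak centre, matching the
convention of profiling binding-site central positions. The centre maps
into the transcript in transcription order: 5'/3' UTR calls require an
annotated CDS (exon hits without CDS report as `exon_cds`); intron ranks
are 1-based in transcription order, so rank 1 abuts the first
transcribed exon on either strand. The classification is total: every
centre position receives exactly one class per transcript. Profile
summaries group introns into first / higher rank-order / last, a
transcript's only intron counting as first.

## Dataset overlap and the enrichment P-value

`overlap_pairs` reports all pairs of loci intersecting by at least one
nucleotide, strand ignored, driven by the NCL overlap query on the
second set; the containment recursion is what finds a small interval
nested deep inside a much larger one. `merge_union` produces the
non-redundant union of several datasets with per-dataset membership
flags, merging strictly on intersection (touching intervals stay
separate).

The enrichment test conditions on the observed data: each null draw
replaces the first-named set `s1` with artificial loci having the same
per-chromosome counts and the same lengths, starts uniform on
`[0, chrom_length - length]`. Placements are independent and may
overlap one another; imposing self-avoidance would bias the placement of
long intervals. The statistic is the count of `s1` loci with at least
one partner (a site count, matching how overlap between binding-site
datasets is conventionally reported), and the estimator is add-one:

$$ p = \frac{1 + \#\{i : n_i \ge n_{\text{obs}}\}}{N + 1}, $$

never zero, with smallest reportable value $1/(N+1)$ — about
$10^{-3}$ at the default $N = 1000$ iterations. The null loop uses a
base-interval hit counter over the reduced union of `s2`; its agreement
with `overlap_pairs` is itself a test. Calibration is checked by
generating `s1` from the randomization null and confirming the
empirical fraction of $p \le 0.05$ over 200 repetitions at 500
iterations each lies in $[0.02, 0.08]$.

## The synthetic generator

The generator exists so every algorithm is testable hermetically with
known ground truth. `make_annotation` places stranded multi-exon
transcripts with optional CDS; a `p_nested` fraction is placed strictly
inside earlier transcripts to exercise the containment sublists, and
non-nested placements are rejection-sampled so that *unintended*
containment never occurs — sublist structure is controlled by the one
parameter. `make_signal` plants $k$ triangular bumps per peak with
valleys at an exact fraction of the lower flanking summit; because the
bumps are piecewise linear rather than Gaussian, summit heights and
valley depths are exact and separability at a given valley factor is an
analytic fact recorded in the truth table, not an empirical outcome. A
valley fraction of 0.25 against the default valley factor 0.6 makes all
planted pairs separable; 0.9 makes none.

Defaults describe a deliberately small study: two chromosomes of 200 kb
and 150 kb, 40 transcripts (20 % nested), 30 peaks of one to four
summits with heights 10–60 over background 1 — enough to exercise every
code path while keeping the full test suite fast. What the generator
does *not* emulate: read-level noise, mappability and assembly gaps,
non-uniform genomic background, and realistic gene density. Passing
tests demonstrate algorithmic correctness against the stated rules, not
robustness to those artefacts of real data.

## Problem sizes and numerical choices

The oracle-equivalence suites run 200 randomized annotation sets of up
to ~500 transcripts with 6 peaks each for the annotator, 200 random set
pairs (with forced containment chains) for the overlap module, and 1000
random index builds of up to 2000 intervals for the structural
invariants; these sizes give broad case coverage while keeping the
default test run in a few minutes on one CPU. Depth comparisons use
exact float equality only where the values are produced by identical
arithmetic (planted fixtures); statistical checks (uniformity of random
placement, calibration band) use fixed seeds and significance levels
stated in the tests. WIG value collisions resolve last-writer-wins with
a warning; BED scores are parsed as floats and deliberately not
range-checked, since real caller output ignores the nominal 0–1000
convention.

## Limitations

* Annotation is per-transcript, not per-gene: every transcript is an
  independent index entry, and all transcripts overlapping a location
  are reported. Collapsing to genes is left to the caller.
* The randomization model is uniform per chromosome; it does not mask
  assembly gaps or blacklisted regions, and the P-value should be read
  accordingly.
* Peak strand is parsed but ignored by all annotation operations;
  overlap is computed on either strand.
* Binary formats (bigWig/bigBed, BAM) and GFF3 are out of scope; inputs
  are BED, GTF, WIG/bedGraph, FASTA and a two-column chrom.sizes table.
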