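---
title: "Calling and characterizing Pol II termination windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing Pol II termination windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termwin)
library(GenomicRanges)
```

## The problem

RNA polymerase II does not stop at the polyadenylation site (PAS): it
transcribes past it and terminates within a downstream region, pausing
terminally as it does so. A CTD modification concentrated in that region —
threonine-4 phosphorylation measured by strand-specific, single-nucleotide
mNET-seq — marks where termination happens. `termwin` turns such coverage
into discrete *termination windows*, distinguishing normal gene-end
termination from premature termination inside gene bodies, and provides
the profile metrics used to characterize them.

## The procedure and its assumptions

**Gene preselection.** Termination signal downstream of a gene is only
attributable to that gene if no tandem neighbour contributes signal there.
`select_genes()` therefore keeps genes that (a) match the biotype filter
(default protein-coding), (b) overlap no other annotated gene on the same
strand, and (c) have the next same-strand gene start at least
`isolation_bp` (default 6000, inclusive) past their PAS. The overlap and
isolation filters deliberately consider *all* annotated genes, not only
those passing the biotype filter; `selection_params(overlap_all_biotypes =
FALSE)` restricts them. Isolation is measured to the downstream gene's
strand-aware start (its 5′ end), one of two defensible readings; it is the
stricter one for genes pointing toward the candidate. Gene-level records
define TSS and PAS; isoform-resolved PAS catalogs are out of scope.

**Averaging and extension.** Replicates within a study are averaged
per base, treating absent positions as zero (the union of covered regions
is averaged, as `wiggletools mean` does). Each recorded position — the
polymerase position given by the nascent RNA 3′ end — is then expanded to
a read-sized interval of `length_bp = 150`, contributing its value to
every base of the interval. The recorded position is taken as the 5′
anchor, extending 3′-ward in strand orientation; since the assay records
the polymerase position, the read body lies behind it, but the choice is
not forced, so `anchor = "center"` is provided as the alternative. The sum
of an extended track is exactly `length_bp` times the raw sum away from
contig edges, a property the tests assert.

**Two-tier broad calling.** On the averaged, extended track,
`call_broad_regions()` finds: (1) *strong* runs of bases strictly above
`cutoff_peak`, closing internal gaps up to `max_gap_within` (30 bp); (2)
*weak* runs strictly above `cutoff_link`; (3) strong regions bridged by
weak signal with interruptions up to `max_gap_link` (800 bp) are linked,
the emitted region spanning the linked strong regions; (4) regions shorter
than `min_length` (200 bp) are dropped. Comparisons are strictly-greater.
These defaults mirror the documented defaults of the MACS-style
`bdgbroadcall` utility this reimplements. An independent per-base
brute-force implementation of the same rules lives in the test suite and
the caller must match it region-for-region on hundreds of randomized
tracks.

Cutoffs are *scale-bound*: they live on the scale of the input track. The
2/1 defaults suit tracks whose enriched level is a few counts per base.
For other depths the cutoffs must be placed between the body-level and
window-level signal; `suggest_call_params()` does this in closed form for
simulated scenarios (peak cutoff at the geometric midpoint of the expected
extended body and window levels, link cutoff at half the peak, preserving
the 2:1 ratio of the reference defaults).

**Consensus.** Only enriched regions that overlap (≥ 1 bp) a region from
the other study's averaged file are kept; the retained pool is merged into
maximal disjoint windows. Book-ended ranges coalesce (half-open adjacency),
matching the reduce semantics of the underlying ranges machinery. With
more than two studies, a region must overlap a region from at least one
other study — all-way overlap would be stricter; the defining requirement
is support in two files, which the ≥ 1-other-set rule generalizes.

**Classification.** Each window gets exactly one category, in priority
order: *gene-end* if it overlaps any preselected gene's
`[PAS, PAS + 6 kb)` on the same strand; else *premature* if fully
contained in a preselected gene's body; else *other* (intergenic, or
belonging to genes the preselection excluded). Priority matters because a
window can satisfy both predicates across two genes; gene-end is assigned
first, consistent with defining the premature class as windows excluded
from the other categories. Among same-category candidate genes, the gene
whose PAS (gene-end) or TSS (premature) is nearest the window midpoint
assigns, with exact ties broken by `gene_id` — classification is therefore
invariant to input order. Length medians use the lower-median convention
for even counts; quartiles are type-7.

## Profile metrics

`metagene()` computes scale-regions matrices: fixed-width flanks binned at
`bin_bp`, bodies rescaled to `n_body_bins` equal bins, minus-strand rows
reversed so every row reads 5′→3′. Bins may be fractional: a bin's mean is
the exact average of the piecewise-constant per-base signal over its real
interval, so short regions are handled without special cases (the tests
pin this to a per-base oracle at 1e-12). Unit-max scaling follows the
two-pass convention: the factor is 1/max of the *averaged* profile, then
applied to the signal and the matrix recomputed; because binning is
linear, this equals multiplying the matrix, and scaling is idempotent. A
signal-free profile has no defined factor and errors rather than returning
infinities.

`pas_tss_ratio()` sums signal in 200-bp windows ending at the PAS and
starting at the TSS and reports log₂(PAS/TSS); genes with an empty window
are excluded (count reported) rather than pseudocounted, since an
arbitrary pseudocount would place those genes at an arbitrary point of the
distribution — a `pseudocount` argument exists for sensitivity checks.
`activity_groups()` ranks genes by mean signal over the body + 5 kb and
splits them into `n_groups` *exactly equal* groups by dropping the
`n mod n_groups` least-active genes first, the remainder scheme under
which, for example, 10 387 genes split five ways give exactly equal groups
of 2077 with the 2 least-active genes set aside. Ties order stably by
`gene_id`.

## What the simulator emulates — and what it does not

`simulate_tracks()` generates per-base Poisson counts with rate
background + body + window boost + TSS bump:

| parameter | default | meaning |
|---|---|---|
| `lambda_background` | 0.01 /base | pervasive background |
| `lambda_body` | 0.2 /base | gene-body nascent signal, TSS through the planted window's end |
| `lambda_window` | 2.0 /base | additive boost inside planted windows |
| `window_offset_*` | U(500, 2000) bp | gene-end window start downstream of the PAS |
| `window_length_*` | logN(log 2000, 0.4) | gene-end window length |
| `premature_fraction` | 0.3 | genes carrying a premature window |
| `n_replicates` | A = 3, B = 2 | the two-study replicate design |
| `tss_peak_rate/width` | 0.3 /base, 150 bp | small 5′ initiation bump |

The gene-end geometry mirrors the observed enrichment maximum 500–2000
nucleotides downstream of the PAS; body-level signal continues *through*
the window (the polymerase is still on the template while pausing) and
falls to background after it. Premature windows are kept ≥ 200 bp from the
TSS and ≥ 1 kb from the PAS: premature termination occurs at intronic
sites away from gene ends, and the margin also prevents a planted
premature block from fusing with the gene-end block through the caller's
800-bp linking gap. The TSS bump is small (extended level ≈ 77, below the
depth-matched peak cutoff ≈ 102) because a terminal-pausing mark has low
TSS signal. Minus-strand layouts are mirrored plus-strand layouts, so both
orientations exercise identical geometry.

Scenario S1 (the default: 200 genes, two 0.8-Mb contigs, seconds to
simulate) is used by the test suite and the acceptance script; S2 is a
larger variant (500 genes, four 1-Mb contigs). Problem sizes were chosen
so the complete suite runs in about two minutes while every planted
structure class appears dozens of times per strand. Layout and every
replicate draw from fixed, independent substreams of the master seed, so
results are byte-reproducible and adding replicates never perturbs
existing ones.

What passing on simulated data does **not** show: the simulator has no
mappability artifacts, no fragmentation of windows by coverage dropouts,
no splicing or antisense signal, and — deliberately — no rise of the
terminal mark *before* the PAS. One visible consequence: the median
log₂(PAS/TSS) on simulated tracks is slightly negative (the planted
enrichment sits wholly downstream of the PAS, outside the PAS-ending
window, while the TSS window catches the initiation bump), whereas real
terminal-pausing marks give positive ratios because pausing signal rises
already at the gene 3′ end. The metric's sign behavior is therefore tested
on purpose-built tracks with 3′-end-heavy versus TSS-heavy signal.

## Numerical and degenerate-input choices

Internally coordinates are 1-based closed ranges (`GenomicRanges`); BED
and bedGraph io converts to and from 0-based half-open at the boundary.
Coverage is run-length encoded; absent contigs and positions are zero.
Track values are doubles; bedGraph is written with six significant digits.
Empty inputs propagate as empty outputs (empty track → no regions; empty
gene set → no selection) rather than errors; fewer than two replicate sets
is an error naming the consensus requirement; negative coverage is an
error. Without contig sizes, extension and derived regions are emitted
unclipped on the 3′ side and truncated at the coordinate origin on the 5′
side; supplying `seqlens` clips both. Chromosome-name dialects are not
normalized: tracks and annotation must agree.

## Known limitations

Single-nucleotide refinement of window boundaries is not attempted — the
150-bp extension means called edges overshoot the underlying signal by up
to the read length, and no de-fragmentation rule beyond the caller's gap
parameters is applied. Windows overlapping the downstream regions of two
genes remain one window. Liftover between assemblies, BAM/FASTQ
processing, and statistical significance models for windows (the
procedure is threshold-based by design) are out of scope.
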