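# termwin

Genome-wide definition and characterization of RNA polymerase II
transcription-**termin**ation **win**dows from strand-specific,
single-nucleotide nascent-transcription coverage (mNET-seq-style tracks of
the CTD threonine-4-phosphorylation mark of terminally pausing Pol II).

After Pol II transcribes past the polyadenylation site (PAS) it pauses and
terminates within a region typically 0.5–6 kb downstream; a CTD-T4ph-like
mark concentrated in that region can be used to map where termination
happens, both at gene ends and prematurely inside gene bodies. `termwin`
implements that mapping as a reusable, fully tested pipeline:

1. **Gene preselection** — keep protein-coding genes that overlap no other
   annotated gene on the same strand and whose 3′ end is isolated by at
   least 6 kb from the next same-strand gene (`select_genes()`), so
   downstream signal is attributable to one gene.
2. **Replicate averaging** per study (`mean_tracks()`), then **extension**
   of each recorded single-nucleotide position to a 150-bp read-sized
   interval in strand orientation (`extend_signal()`).
3. **Two-tier broad-enrichment calling** (`call_broad_regions()`): strong
   runs above a peak cutoff *c₁* (internal gaps ≤ 30 bp closed) are linked
   through weak signal above *c₂* with interruptions ≤ 800 bp; emitted
   regions shorter than 200 bp are dropped.
4. **Cross-study consensus** (`consensus()`): regions supported by both
   averaged files are retained and merged into disjoint termination
   windows.
5. **Classification** (`classify_windows()`): *gene-end* (overlapping the
   6-kb PAS-downstream region of a preselected gene), *premature* (fully
   inside a gene body), *other*; with per-category counts and length
   medians (`window_stats()`).
6. **Characterization** — scale-regions metagene matrices with unit-max
   scaling (`metagene()`, `unit_max_scale()`), per-gene log₂(PAS/TSS)
   signal ratios (`pas_tss_ratio()`), and activity-quintile-stratified
   profiles (`activity_groups()`, `group_profiles()`).

A calibrated Poisson simulator (`simulate_tracks()`) plants termination
structure with known truth, so the whole pipeline is testable without any
downloads; `evaluate_recovery()` scores called windows against the planted
truth by interval Jaccard.

## Worked example

The `analysis/` scripts run the full study on simulated data
(`scratch/sim/` holds the intermediates, `results/` the tables):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_call_windows.R
Rscript analysis/03_classify_windows.R
Rscript analysis/04_profile_metrics.R
```

which prints, stage by stage:

```
Simulated 200 genes over 2 contigs (seed 1)
Planted 200 gene-end and 54 premature termination windows
Caller cutoffs matched to depth: peak 102.2, link 51.1
Called 254 consensus termination windows (124 on +, 130 on -)
Median window length: 1995 bp
  category   n median_length_bp q1_length_bp q3_length_bp
  gene_end 200             2124      1686.25      2682.25
 premature  54             1587      1324.00      1845.25
     other   0               NA           NA           NA
Recovery at Jaccard >= 0.5: 100.0% overall (gene-end 100.0%, premature 100.0%)
Category accuracy on matched windows: 100.0%; precision 100.0%
Metagene over 100 forward-strand gene-end windows; scale factor 0.4448 (profile max now 1.000)
log2(PAS/TSS) over 100 genes: median -1.09 (0 excluded for empty windows)
Mean signal per activity quintile (1 = least active):
group1 group2 group3 group4 group5
 0.438  0.568  0.677  0.769  1.036
```

Reading the numbers: every planted gene-end window is recovered as a
consensus window at Jaccard ≥ 0.5 and classified correctly; gene-end
windows are longer than premature ones (medians 2124 vs 1587 bp); unit-max
scaling pins the averaged metagene at 1; and mean terminal-mark signal
rises monotonically with gene activity. The PAS/TSS median is slightly
negative on simulated data because the planted enrichment sits wholly
downstream of the PAS (see the methods vignette).

The same pipeline runs from files: point `pipeline_config()` at per-strand
bedGraph/bigWig replicates and a GTF, and `run_pipeline()` writes selected
genes, windows, classifications, statistics and a provenance-bearing
`summary.json`.

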