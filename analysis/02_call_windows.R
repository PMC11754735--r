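#!/usr/bin/env Rscript
# Stage 2: define termination windows from the coverage files.
#
# Reads the simulated replicates back from disk (exercising the bedGraph
# path), then per strand: averages each replicate set, extends the
# single-nucleotide signal to 150 bp, calls broadly enriched regions with
# the two-tier caller at cutoffs matched to the simulated depth, and keeps
# the merged cross-study consensus. Writes windows.bed and provenance.

suppressPackageStartupMessages({library(termwin); library(GenomicRanges)})

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

sim_dir <- "scratch/sim"
scenario <- read_scenario(file.path(sim_dir, "scenario.yaml"))
params <- suggest_call_params(scenario)
cat(sprintf("Caller cutoffs matched to depth: peak %.1f, link %.1f\n",
            params$cutoff_peak, params$cutoff_link))

sets <- lapply(setNames(nm = names(scenario$n_replicates)), function(set)
  lapply(seq_len(scenario$n_replicates[[set]]), function(r)
    list(fwd = file.path(sim_dir, sprintf("%s_rep%d_fwd.bedgraph", set, r)),
         rev = file.path(sim_dir, sprintf("%s_rep%d_rev.bedgraph", set, r)))))

windows <- do.call(c, lapply(c("+", "-"), function(strd) {
  key <- if (strd == "+") "fwd" else "rev"
  tracks <- lapply(sets, function(set)
    lapply(set, function(rep_) read_track(rep_[[key]], strand = strd)))
  call_termination_windows(tracks, params = params, labels = names(sets))
}))

bed <- granges(windows)
bed$name <- windows$window_id
bed$score <- 0L
rtracklayer::export(bed, "results/windows.bed", format = "BED")
write.table(data.frame(window_id = windows$window_id,
                       provenance = vapply(windows$provenance, paste,
                                           character(1), collapse = ",")),
            "results/windows_provenance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Called %d consensus termination windows (%d on +, %d on -)\n",
            length(windows), sum(strand(windows) == "+"),
            sum(strand(windows) == "-")))
cat(sprintf("Median window length: %d bp\n",
            as.integer(median(width(windows)))))
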