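#!/usr/bin/env Rscript
# Stage 1: generate the study inputs.
#
# Simulates the default scenario S1: a two-contig genome with 200 isolated
# protein-coding genes per the preselection rules, strand-specific
# single-nucleotide Poisson coverage in two replicate sets (3 + 2), planted
# gene-end termination windows 0.5-2 kb downstream of each PAS and
# premature windows inside 30% of gene bodies. Writes GTF annotation,
# per-replicate bedGraphs and the planted truth under results/sim/.

suppressPackageStartupMessages(library(termwin))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

scenario <- scenario_s1(seed = seed)
sim <- simulate_tracks(scenario)
out <- "scratch/sim"
write_simulation(sim, out)

cat(sprintf("Simulated %d genes over %d contigs (seed %d)\n",
            length(sim$genes), scenario$n_contigs, seed))
cat(sprintf("Planted %d gene-end and %d premature termination windows\n",
            sum(sim$truth$category == "gene_end"),
            sum(sim$truth$category == "premature")))
cat(sprintf("Wrote annotation, %d bedGraph tracks and truth to %s/\n",
            2 * sum(scenario$n_replicates), out))
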