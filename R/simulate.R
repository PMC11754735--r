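#' Simulation scenario for planted termination structure
#'
#' Describes a synthetic genome and coverage model that emulates
#' strand-specific, single-nucleotide nascent-transcription signal of a
#' terminal-pausing CTD mark: low pervasive background, elevated gene-body
#' signal, a strong enrichment block beginning 0.5-2 kb downstream of the
#' annotated PAS (continuing body-level signal runs through the block, after
#' which signal falls back to background), optional premature-termination
#' blocks inside gene bodies, a small 5' TSS bump, and independent Poisson
#' replicate noise in two replicate sets (3 + 2 replicates, the two-study
#' design the consensus caller expects). Genes are placed so that the
#' preselection filters hold by construction: no same-strand overlap and
#' inter-gene gaps of at least `isolation_bp`.
#'
#' @param seed Master seed; layout and every replicate draw from fixed,
#'   independent substreams, so outputs are reproducible and adding
#'   replicates never perturbs existing ones.
#' @param n_contigs,contig_length_bp Genome shape.
#' @param n_genes Total genes, split evenly over contigs and strands.
#' @param gene_length_min,gene_length_max Uniform gene-length range (bp).
#' @param isolation_bp Minimum inter-gene gap on a strand.
#' @param lambda_background,lambda_body,lambda_window Poisson rates per base
#'   per replicate: pervasive background, gene body, and the additive boost
#'   inside planted windows.
#' @param window_offset_min,window_offset_max Uniform range of the gene-end
#'   window's start downstream of the PAS (bp).
#' @param window_length_meanlog,window_length_sdlog Log-normal gene-end
#'   window length.
#' @param premature_fraction Fraction of genes carrying a premature window.
#' @param premature_length_meanlog,premature_length_sdlog Log-normal
#'   premature window length.
#' @param premature_margin_tss,premature_margin_pas Minimum distance of a
#'   premature window from the TSS and the PAS (premature termination at
#'   intronic sites, away from gene ends).
#' @param n_replicates Named integer vector: replicates per set.
#' @param tss_peak_rate,tss_peak_width Additive rate and width of the 5'
#'   bump.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(seed = 1L,
                         n_contigs = 2L, contig_length_bp = 800000L,
                         n_genes = 200L,
                         gene_length_min = 2000L, gene_length_max = 8000L,
                         isolation_bp = 6000L,
                         lambda_background = 0.01, lambda_body = 0.2,
                         lambda_window = 2.0,
                         window_offset_min = 500L, window_offset_max = 2000L,
                         window_length_meanlog = log(2000),
                         window_length_sdlog = 0.4,
                         premature_fraction = 0.3,
                         premature_length_meanlog = log(1500),
                         premature_length_sdlog = 0.4,
                         premature_margin_tss = 200L,
                         premature_margin_pas = 1000L,
                         n_replicates = c(A = 3L, B = 2L),
                         tss_peak_rate = 0.3, tss_peak_width = 150L) {
  sc <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
             contig_length_bp = as.integer(contig_length_bp),
             n_genes = as.integer(n_genes),
             gene_length_min = as.integer(gene_length_min),
             gene_length_max = as.integer(gene_length_max),
             isolation_bp = as.integer(isolation_bp),
             lambda_background = lambda_background,
             lambda_body = lambda_body, lambda_window = lambda_window,
             window_offset_min = as.integer(window_offset_min),
             window_offset_max = as.integer(window_offset_max),
             window_length_meanlog = window_length_meanlog,
             window_length_sdlog = window_length_sdlog,
             premature_fraction = premature_fraction,
             premature_length_meanlog = premature_length_meanlog,
             premature_length_sdlog = premature_length_sdlog,
             premature_margin_tss = as.integer(premature_margin_tss),
             premature_margin_pas = as.integer(premature_margin_pas),
             n_replicates = n_replicates,
             tss_peak_rate = tss_peak_rate,
             tss_peak_width = as.integer(tss_peak_width))
  stopifnot(sc$lambda_background >= 0, sc$lambda_body >= 0,
            sc$lambda_window >= 0, sc$tss_peak_rate >= 0,
            sc$premature_fraction >= 0, sc$premature_fraction <= 1,
            sc$n_genes >= 1, length(sc$n_replicates) >= 1)
  structure(sc, class = "sim_scenario")
}

#' Shipped scenarios
#'
#' `scenario_s1()` is the small default scenario used throughout the test
#' suite (200 genes on two 0.8-Mb contigs, seconds to simulate);
#' `scenario_s2()` is a larger variant (500 genes on four 1-Mb contigs).
#'
#' @param seed Master seed.
#' @return A [sim_scenario()].
#' @export
scenario_s1 <- function(seed = 1L) sim_scenario(seed = seed)

#' @rdname scenario_s1
#' @export
scenario_s2 <- function(seed = 1L)
  sim_scenario(seed = seed, n_contigs = 4L, contig_length_bp = 1000000L,
               n_genes = 500L)

#' Read / write a scenario as YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [sim_scenario()].
#'
#' @param path YAML file.
#' @return [read_scenario()]: a `sim_scenario`; [write_scenario()]: `path`,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_scenario))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$n_replicates))
    vals$n_replicates <- unlist(vals$n_replicates)
  do.call(sim_scenario, vals)
}

#' @rdname read_scenario
#' @param scenario A `sim_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(lapply(unclass(scenario), function(x)
    if (length(names(x))) as.list(x) else x), path)
  invisible(path)
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

# lay out genes and planted windows for one (contig, strand); returns a list
# of data.frames. Coordinates 1-based closed.
layout_strand <- function(sc, n_genes, contig_len, rng_seed) {
  for (attempt in 0:4) {
    set.seed(sub_seed(rng_seed, attempt * 7))
    genes <- windows <- NULL
    cur_end <- 0L  # end of previously placed gene
    prev_reserve <- 0L
    g <- list(); w <- list()
    ok <- TRUE
    for (i in seq_len(n_genes)) {
      len <- round(runif(1, sc$gene_length_min, sc$gene_length_max))
      offset <- round(runif(1, sc$window_offset_min, sc$window_offset_max))
      wlen <- max(300, round(rlnorm(1, sc$window_length_meanlog,
                                    sc$window_length_sdlog)))
      reserve_this <- offset + wlen + 500L
      gap <- max(sc$isolation_bp, prev_reserve, reserve_this) +
        round(runif(1, 0, 2000))
      s <- cur_end + gap + 1L
      e <- s + len - 1L
      win <- c(e + offset, e + offset + wlen - 1L)  # +-strand geometry;
      # mirrored below for the minus strand
      prem <- NULL
      if (runif(1) < sc$premature_fraction) {
        plen <- max(300, round(rlnorm(1, sc$premature_length_meanlog,
                                      sc$premature_length_sdlog)))
        avail <- len - sc$premature_margin_tss - sc$premature_margin_pas -
          plen + 1
        if (avail >= 1) {
          ps <- s + sc$premature_margin_tss + floor(runif(1, 0, avail))
          prem <- c(ps, ps + plen - 1L)
        }
      }
      if (max(e, win[2]) > contig_len - 200L) { ok <- i > 1; break }
      g[[i]] <- c(start = s, end = e, offset = offset, wlen = wlen)
      w[[i]] <- list(win = win, prem = prem)
      cur_end <- e
      prev_reserve <- reserve_this
    }
    if (ok && length(g) == n_genes)
      return(list(genes = do.call(rbind, g), windows = w))
  }
  stop("could not place ", n_genes, " genes on a ", contig_len,
       " bp contig; increase contig_length_bp or reduce n_genes")
}

mirror_interval <- function(iv, contig_len) {
  c(contig_len - iv[2] + 1L, contig_len - iv[1] + 1L)
}

#' Simulate annotation, coverage replicates and planted truth
#'
#' Per replicate and base, counts are Poisson with rate background + body
#' (inside the gene and continuing at body level through the planted
#' gene-end window) + window boost inside planted windows + TSS bump.
#' Minus-strand layouts are mirrored plus-strand layouts, so both strands
#' exercise identical geometry in opposite orientations.
#'
#' @param scenario A [sim_scenario()].
#' @return A `sim_result` list: `scenario`; `genes` (annotation `GRanges`
#'   with `gene_id`, `biotype`, `tss`, `pas`); `truth` (planted windows
#'   `GRanges` with `category`, `gene_id`); `tracks` (nested list:
#'   set, then replicate, then strand, of `CoverageTrack`); `seqlens`.
#' @export
simulate_tracks <- function(scenario) {
  sc <- scenario
  stopifnot(is(sc, "sim_scenario"))
  contigs <- sprintf("sim%d", seq_len(sc$n_contigs))
  seqlens <- setNames(rep(sc$contig_length_bp, sc$n_contigs), contigs)
  per_cell <- sc$n_genes / (sc$n_contigs * 2)
  if (per_cell != floor(per_cell))
    stop("n_genes must be divisible by 2 * n_contigs")
  gene_rows <- list(); truth_rows <- list()
  rates <- list(`+` = list(), `-` = list())
  gi <- 0L
  for (ci in seq_along(contigs)) {
    for (st in c("+", "-")) {
      lay <- layout_strand(sc, per_cell, sc$contig_length_bp,
                           sub_seed(sc$seed, ci * 20 + (st == "-")))
      rate <- rep(sc$lambda_background, sc$contig_length_bp)
      for (i in seq_len(nrow(lay$genes))) {
        gi <- gi + 1L
        id <- sprintf("SIMG%04d", gi)
        gr <- lay$genes[i, ]
        body <- c(gr[["start"]], gr[["end"]])
        win <- lay$windows[[i]]$win
        prem <- lay$windows[[i]]$prem
        tssb <- c(body[1], min(body[2], body[1] + sc$tss_peak_width - 1L))
        if (st == "-") {
          body <- mirror_interval(body, sc$contig_length_bp)
          win <- mirror_interval(win, sc$contig_length_bp)
          if (!is.null(prem)) prem <- mirror_interval(prem, sc$contig_length_bp)
          tssb <- mirror_interval(tssb, sc$contig_length_bp)
        }
        # body-level signal continues through the gene-end window
        through <- range(c(body, win))
        rate[through[1]:through[2]] <- rate[through[1]:through[2]] +
          sc$lambda_body
        rate[win[1]:win[2]] <- rate[win[1]:win[2]] + sc$lambda_window
        if (!is.null(prem))
          rate[prem[1]:prem[2]] <- rate[prem[1]:prem[2]] + sc$lambda_window
        rate[tssb[1]:tssb[2]] <- rate[tssb[1]:tssb[2]] + sc$tss_peak_rate
        gene_rows[[gi]] <- data.frame(contig = contigs[ci], start = body[1],
                                      end = body[2], strand = st,
                                      gene_id = id)
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(contig = contigs[ci], start = win[1], end = win[2],
                     strand = st, category = "gene_end", gene_id = id)
        if (!is.null(prem))
          truth_rows[[length(truth_rows) + 1L]] <-
            data.frame(contig = contigs[ci], start = prem[1], end = prem[2],
                       strand = st, category = "premature", gene_id = id)
      }
      rates[[st]][[contigs[ci]]] <- rate
    }
  }
  gdf <- do.call(rbind, gene_rows)
  genes <- GRanges(gdf$contig, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id,
                   biotype = "protein_coding",
                   seqlengths = seqlens)
  genes <- set_tss_pas(genes)
  tdf <- do.call(rbind, truth_rows)
  truth <- GRanges(tdf$contig, IRanges(tdf$start, tdf$end),
                   strand = tdf$strand, category = tdf$category,
                   gene_id = tdf$gene_id, seqlengths = seqlens)
  tracks <- list()
  for (si in seq_along(sc$n_replicates)) {
    set_name <- names(sc$n_replicates)[si]
    tracks[[set_name]] <- lapply(seq_len(sc$n_replicates[[si]]), function(ri) {
      out <- lapply(c(`+` = "+", `-` = "-"), function(st) {
        cov <- lapply(seq_along(contigs), function(ci) {
          set.seed(sub_seed(sc$seed,
                            1000000L + si * 10000L + ri * 100L +
                              ci * 2L + (st == "-")))
          Rle(rpois(sc$contig_length_bp, rates[[st]][[contigs[ci]]]))
        })
        names(cov) <- contigs
        coverage_track(as(cov, "RleList"), st, assembly = "sim")
      })
      out
    })
  }
  structure(list(scenario = sc, genes = genes, truth = truth,
                 tracks = tracks, seqlens = seqlens),
            class = "sim_result")
}

#' Caller parameters matched to a scenario's signal depth
#'
#' Threshold cutoffs live on the scale of the called track. After replicate
#' averaging and `extension_bp` expansion, the expected level is
#' `extension_bp * (background + body)` in gene bodies and
#' `extension_bp * (background + body + window)` inside planted windows.
#' The peak cutoff is placed at the geometric midpoint of those two levels
#' and the link cutoff at half of it (preserving the 2:1 peak:link ratio of
#' the caller's documented defaults); length and gap parameters are the
#' defaults.
#'
#' @param scenario A [sim_scenario()].
#' @param extension_bp Extension used by the pipeline (default 150).
#' @return A [broad_call_params()].
#' @export
suggest_call_params <- function(scenario, extension_bp = 150L) {
  body_level <- extension_bp * (scenario$lambda_background +
                                  scenario$lambda_body)
  window_level <- extension_bp * (scenario$lambda_background +
                                    scenario$lambda_body +
                                    scenario$lambda_window)
  peak <- sqrt(body_level * window_level)
  broad_call_params(cutoff_peak = peak, cutoff_link = peak / 2)
}

#' Write a simulation to disk
#'
#' Writes the annotation as GTF, each replicate as one bedGraph per strand,
#' the planted truth as BED6 and TSV, and the scenario as YAML.
#'
#' @param sim A [simulate_tracks()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- granges(sim$genes)
  ann$source <- "termwin_sim"
  ann$type <- "gene"
  ann$gene_id <- sim$genes$gene_id
  ann$gene_type <- sim$genes$biotype
  rtracklayer::export(ann, file.path(dir, "annotation.gtf"), format = "gtf")
  for (set_name in names(sim$tracks))
    for (ri in seq_along(sim$tracks[[set_name]]))
      for (st in c("+", "-"))
        write_track(sim$tracks[[set_name]][[ri]][[st]],
                    file.path(dir, sprintf("%s_rep%d_%s.bedgraph", set_name,
                                           ri, if (st == "+") "fwd" else "rev")))
  bed <- granges(sim$truth)
  bed$name <- paste(sim$truth$gene_id, sim$truth$category, sep = "|")
  bed$score <- 0L
  rtracklayer::export(bed, file.path(dir, "truth.bed"), format = "BED")
  write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_scenario(sim$scenario, file.path(dir, "scenario.yaml"))
  writeLines(sprintf("%s\t%d", names(sim$seqlens), sim$seqlens),
             file.path(dir, "chrom.sizes"))
  invisible(dir)
}

pairwise_jaccard <- function(a, b) {
  hits <- findOverlaps(a, b, ignore.strand = FALSE)
  inter <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)]))
  uni <- width(a)[queryHits(hits)] + width(b)[subjectHits(hits)] - inter
  data.frame(q = queryHits(hits), s = subjectHits(hits),
             jaccard = inter / uni)
}

#' Recovery of planted windows by called windows
#'
#' A truth window is recovered when some called window on the same strand
#' has interval Jaccard at least `min_jaccard` with it. Category accuracy is
#' computed over matched pairs (each recovered truth window against its
#' best-Jaccard called window); precision is the fraction of called windows
#' matching some truth window at the same Jaccard bound.
#'
#' @param called Called (and, for category accuracy, classified) window
#'   `GRanges`; a `category` column is used when present.
#' @param truth Planted truth `GRanges` with `category`, `gene_id`.
#' @param min_jaccard Matching threshold (default 0.5).
#' @return List: `sensitivity`, per-category sensitivities, `precision`,
#'   `category_accuracy` (`NA` without categories), `n_truth`, `n_called`,
#'   and the per-truth match table.
#' @export
evaluate_recovery <- function(called, truth, min_jaccard = 0.5) {
  pj <- pairwise_jaccard(truth, called)
  best <- rep(NA_integer_, length(truth))
  bestj <- rep(0, length(truth))
  if (nrow(pj)) {
    pj <- pj[order(pj$q, -pj$jaccard), ]
    first <- !duplicated(pj$q)
    best[pj$q[first]] <- pj$s[first]
    bestj[pj$q[first]] <- pj$jaccard[first]
  }
  recovered <- bestj >= min_jaccard
  cat_t <- as.character(truth$category)
  sens_by_cat <- vapply(unique(cat_t), function(cc)
    mean(recovered[cat_t == cc]), numeric(1))
  called_best <- rep(0, length(called))
  if (nrow(pj)) {
    byc <- tapply(pj$jaccard, pj$s, max)
    called_best[as.integer(names(byc))] <- byc
  }
  acc <- NA_real_
  if (!is.null(called$category) && any(recovered)) {
    m <- which(recovered)
    acc <- mean(as.character(called$category)[best[m]] == cat_t[m])
  }
  list(sensitivity = mean(recovered),
       sensitivity_by_category = sens_by_cat,
       precision = if (length(called)) mean(called_best >= min_jaccard)
                   else NA_real_,
       category_accuracy = acc,
       n_truth = length(truth), n_called = length(called),
       matches = data.frame(truth_idx = seq_along(truth),
                            category = cat_t, gene_id = truth$gene_id,
                            best_called = best, jaccard = bestj,
                            recovered = recovered))
}
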