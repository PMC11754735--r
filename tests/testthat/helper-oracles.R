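# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package: they work on plain
# numeric vectors / coordinate matrices and scan bases or pairs directly.

# maximal runs of TRUE in a logical vector, as a [start, end] matrix (1-based)
runs_of_mask <- function(mask) {
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  cbind(s[r$values], e[r$values])
}

# merge consecutive runs separated by a gap of at most g bases
close_gaps_runs <- function(m, g) {
  if (nrow(m) < 2) return(m)
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    gap <- m[i, 1] - out[nrow(out), 2] - 1L
    if (gap <= g) out[nrow(out), 2] <- m[i, 2]
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

# reference two-tier broad caller on a per-base value vector
oracle_broad_call <- function(v, cutoff_peak = 2, cutoff_link = 1,
                              min_length = 200, max_gap_within = 30,
                              max_gap_link = 800) {
  strong <- close_gaps_runs(runs_of_mask(v > cutoff_peak), max_gap_within)
  if (nrow(strong) == 0) return(matrix(integer(0), 0, 2))
  weak <- close_gaps_runs(runs_of_mask(v > cutoff_link), max_gap_link)
  res <- NULL
  for (j in seq_len(nrow(weak))) {
    inside <- which(strong[, 1] <= weak[j, 2] & strong[, 2] >= weak[j, 1])
    if (length(inside))
      res <- rbind(res, c(min(strong[inside, 1]), max(strong[inside, 2])))
  }
  res <- res[res[, 2] - res[, 1] + 1 >= min_length, , drop = FALSE]
  res[order(res[, 1]), , drop = FALSE]
}

# reference consensus: pairwise overlap retention then per-base set union
oracle_consensus <- function(a, b, n) {
  overlaps_any <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i)
      any(y[, 1] <= x[i, 2] & y[, 2] >= x[i, 1]), logical(1))
  }
  keep <- rbind(a[overlaps_any(a, b), , drop = FALSE],
                b[overlaps_any(b, a), , drop = FALSE])
  covered <- logical(n)
  for (i in seq_len(nrow(keep)))
    covered[keep[i, 1]:keep[i, 2]] <- TRUE
  runs_of_mask(covered)
}

# reference gene preselection by all-pairs scanning over a data.frame with
# columns contig, start, end, strand, gene_id, biotype
oracle_select <- function(df, biotypes = "protein_coding",
                          isolation_bp = 6000) {
  keep <- character(0)
  for (i in seq_len(nrow(df))) {
    if (!(df$biotype[i] %in% biotypes)) next
    same <- df[df$contig == df$contig[i] & df$strand == df$strand[i] &
                 df$gene_id != df$gene_id[i], , drop = FALSE]
    if (any(same$start <= df$end[i] & same$end >= df$start[i])) next
    d <- if (df$strand[i] == "+") same$start - df$end[i] - 1
         else df$start[i] - same$end - 1
    d <- d[d >= 0]
    if (length(d) && min(d) < isolation_bp) next
    keep <- c(keep, df$gene_id[i])
  }
  keep
}

# reference fractional binning: per-base overlap weights with each bin
oracle_bin_means <- function(v, n_bins) {
  L <- length(v)
  bw <- L / n_bins
  out <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    lo <- (i - 1) * bw; hi <- i * bw
    s <- 0
    for (b in seq_len(L)) {
      ov <- min(hi, b) - max(lo, b - 1)
      if (ov > 0) s <- s + ov * v[b]
    }
    out[i] <- s / bw
  }
  out
}

# blocky random coverage vector: run-length segments with mostly-low values
random_track_vec <- function(len, values = c(0, 0, 0, 0, 1, 1, 2, 3, 4, 5),
                             max_run = 400) {
  v <- numeric(0)
  while (length(v) < len) {
    v <- c(v, rep(sample(values, 1), sample.int(max_run, 1)))
  }
  v[seq_len(len)]
}

make_track <- function(v, strand = "+", contig = "chrT") {
  cov <- setNames(list(v), contig)
  coverage_track(cov, strand = strand)
}

granges_matrix <- function(gr) {
  cbind(GenomicRanges::start(gr), GenomicRanges::end(gr))
}
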