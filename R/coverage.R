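#' Strand-specific run-length coverage track
#'
#' A `CoverageTrack` wraps a per-contig run-length encoded, base-resolution,
#' non-negative signal (an [S4Vectors::RleList]) together with the strand it
#' was measured on and a free-text assembly tag. Positions beyond the encoded
#' length, or on contigs not present, are implicitly zero.
#'
#' @param cov Named `RleList` (or a named list of numeric vectors / `Rle`s,
#'   coerced) of per-contig signal, one element per contig.
#' @param strand `"+"` or `"-"`.
#' @param assembly Free-text assembly tag; tracks entering a joint operation
#'   must agree.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, strand = c("+", "-"), assembly = "unspecified") {
  strand <- match.arg(strand)
  if (is.list(cov) && !is(cov, "RleList")) {
    cov <- as(lapply(cov, function(x) if (is(x, "Rle")) x else Rle(as.numeric(x))),
              "RleList")
  }
  if (!is(cov, "RleList")) stop("'cov' must be an RleList or a named list")
  if (length(cov) > 0 &&
      (is.null(names(cov)) || anyNA(names(cov)) || any(names(cov) == "")))
    stop("coverage contigs must be named")
  if (any(vapply(cov, function(x) length(x) > 0 && min(runValue(x)) < 0, logical(1))))
    stop("coverage values must be non-negative")
  structure(list(cov = cov, strand = strand, assembly = assembly),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  tot <- sum(vapply(x$cov, function(r) sum(as.numeric(runValue(r)) *
                                             runLength(r)), numeric(1)))
  cat(sprintf("CoverageTrack [%s] strand=%s assembly=%s\n",
              paste(names(x$cov), collapse = ","), x$strand, x$assembly))
  cat(sprintf("  total signal: %g over %d contig(s)\n", tot, length(x$cov)))
  invisible(x)
}

#' Total signal of a track
#' @param track A `CoverageTrack`.
#' @return Sum of per-base values over all contigs.
#' @export
track_total <- function(track) {
  sum(vapply(track$cov, function(r) sum(as.numeric(runValue(r)) * runLength(r)),
             numeric(1)))
}

contig_lengths <- function(track) vapply(track$cov, length, integer(1))

#' Read a coverage track from bedGraph or bigWig
#'
#' Imports a per-strand coverage file into the run-length representation.
#' Unsorted input is accepted (and sorted internally with a warning);
#' negative values are an error, since nascent-transcription coverage is a
#' count signal.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`, optionally gzipped) or bigWig file.
#' @param strand Strand label to attach (`"+"` or `"-"`).
#' @param assembly Assembly tag to attach.
#' @return A [coverage_track()].
#' @export
read_track <- function(path, strand = c("+", "-"), assembly = "unspecified") {
  strand <- match.arg(strand)
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "BigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0)
    return(coverage_track(RleList(compress = FALSE), strand, assembly))
  if (any(gr$score < 0)) stop("negative coverage values in ", path)
  if (is.unsorted(order(as.integer(seqnames(gr)), start(gr)))) {
    warning("unsorted intervals in ", path, "; sorting internally")
    gr <- sort(gr)
  }
  cov <- coverage(gr, weight = "score")
  coverage_track(cov, strand, assembly)
}

#' Write a coverage track as bedGraph or bigWig
#'
#' Zero-valued runs are omitted (absent positions mean zero). Values are
#' written with up to `digits` significant digits. Paths ending in
#' `.bw`/`.bigwig` are written as bigWig, which requires `seqlens`.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param digits Significant digits for values (bedGraph only).
#' @param seqlens Named contig lengths, required for bigWig output.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, digits = 6, seqlens = NULL) {
  gr <- as(track$cov, "GRanges")
  gr <- gr[gr$score != 0]
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    if (is.null(seqlens)) stop("bigWig output requires contig sizes")
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, path, format = "BigWig")
  } else {
    gr$score <- signif(gr$score, digits)
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

pad_rle <- function(r, len) {
  if (length(r) < len) c(r, Rle(0, len - length(r))) else r
}

#' Average replicate coverage tracks
#'
#' Per-base arithmetic mean over a list of tracks; positions absent from a
#' track count as zero (the union of covered regions is averaged, mirroring
#' `wiggletools mean` behaviour). All tracks must share strand and assembly.
#'
#' @param tracks List of `CoverageTrack`s (length >= 1).
#' @return A `CoverageTrack` with the mean signal.
#' @export
mean_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (length(unique(vapply(tracks, `[[`, character(1), "strand"))) != 1)
    stop("cannot average tracks from different strands")
  if (length(unique(vapply(tracks, `[[`, character(1), "assembly"))) != 1)
    stop("cannot average tracks from different assemblies")
  contigs <- unique(unlist(lapply(tracks, function(t) names(t$cov))))
  out <- lapply(contigs, function(ctg) {
    lens <- vapply(tracks, function(t)
      if (ctg %in% names(t$cov)) length(t$cov[[ctg]]) else 0L, integer(1))
    n <- max(lens)
    acc <- Rle(0, n)
    for (t in tracks)
      if (ctg %in% names(t$cov)) acc <- acc + pad_rle(t$cov[[ctg]], n)
    acc / length(tracks)
  })
  names(out) <- contigs
  coverage_track(as(out, "RleList"), tracks[[1]]$strand, tracks[[1]]$assembly)
}

#' Extend single-nucleotide signal to read-sized intervals
#'
#' Each base position carrying value v contributes v to every base of a
#' `length_bp` interval anchored at that position: with the default
#' `"five_prime"` anchor the recorded position is the 5' end and the interval
#' extends 3'-ward in strand orientation (on `+`, `[p, p + length_bp)`; on
#' `-`, `(p - length_bp, p]`); with `"center"` the interval is centred on the
#' position. This is the value-weighted coverage expansion corresponding to
#' resizing single-nucleotide reads to `length_bp`.
#'
#' Without contig sizes the track grows past the original contig length on
#' the 3' side; on the 5' side intervals are truncated at position 1 (the
#' coordinate origin), which loses signal only when reads sit within
#' `length_bp` of a contig start.
#'
#' @param track A `CoverageTrack` at base resolution.
#' @param length_bp Extension length in bp (default 150, a typical read size).
#' @param anchor `"five_prime"` (default) or `"center"`.
#' @return A `CoverageTrack` with the expanded signal.
#' @export
extend_signal <- function(track, length_bp = 150L,
                          anchor = c("five_prime", "center")) {
  anchor <- match.arg(anchor)
  length_bp <- as.integer(length_bp)
  stopifnot(length_bp >= 1L)
  # window for a value at base p is [p + off, p + off + length_bp - 1]
  off <- switch(anchor,
    five_prime = if (track$strand == "+") 0L else -(length_bp - 1L),
    center     = -(length_bp %/% 2L))
  out <- lapply(track$cov, function(r) {
    n <- length(r)
    if (n == 0L || all(runValue(r) == 0)) return(Rle(0, n))
    v <- as.numeric(r)
    C <- c(0, cumsum(v))
    m <- n + max(0L, off + length_bp - 1L)       # new 3'-most position
    x <- seq_len(m)
    hi <- pmin(pmax(x - off, 0L), n)
    lo <- pmin(pmax(x - off - length_bp, 0L), n)
    Rle(C[hi + 1L] - C[lo + 1L])
  })
  coverage_track(as(out, "RleList"), track$strand, track$assembly)
}

# per-base values over [start, end] (1-based closed) on one contig,
# zero-padded outside the encoded track
region_values <- function(track, contig, start, end) {
  w <- end - start + 1L
  if (!(contig %in% names(track$cov))) return(numeric(w))
  r <- track$cov[[contig]]
  n <- length(r)
  lo <- max(start, 1L); hi <- min(end, n)
  out <- numeric(w)
  if (lo <= hi)
    out[(lo - start + 1L):(hi - start + 1L)] <- as.numeric(r[lo:hi])
  out
}

#' Sum of signal over genomic intervals
#'
#' @param track A `CoverageTrack`.
#' @param regions A `GRanges` (strand is not checked here; callers pass
#'   regions belonging to the track's strand or unstranded regions).
#' @return Numeric vector of per-region sums; regions on contigs the track
#'   does not declare contribute 0 with a warning.
#' @export
window_sum <- function(track, regions) {
  stopifnot(is(regions, "GRanges"))
  off <- !(as.character(seqnames(regions)) %in% names(track$cov))
  if (any(off))
    warning(sum(off), " region(s) on contigs absent from the track; sum = 0")
  vapply(seq_along(regions), function(i) {
    sum(region_values(track, as.character(seqnames(regions))[i],
                      start(regions)[i], end(regions)[i]))
  }, numeric(1))
}

# mean per-base value in each of n_bins equal subdivisions of v, allowing
# fractional (non-integer-width) bins: v is piecewise-constant per base and
# bin i averages the exact real interval [ (i-1)L/n, iL/n ).
bin_means <- function(v, n_bins) {
  L <- length(v)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  if (L == 0L) return(numeric(n_bins))
  C <- c(0, cumsum(as.numeric(v)))
  e <- seq(0, L, length.out = n_bins + 1L)
  i <- pmin(floor(e), L - 1)
  S <- C[i + 1] + (e - i) * v[i + 1]
  S[n_bins + 1L] <- C[L + 1L]
  (S[-1L] - S[-(n_bins + 1L)]) / (L / n_bins)
}

#' Binned profile of a track over one interval
#'
#' Splits the interval into `n_bins` equal (possibly fractional) subdivisions
#' and returns the mean per-base value of each, oriented 5' to 3': for
#' minus-strand regions the vector is reversed so index 1 is the 5' bin.
#'
#' @param track A `CoverageTrack`.
#' @param region A length-1 `GRanges`.
#' @param n_bins Number of bins.
#' @return Numeric vector of length `n_bins`.
#' @export
binned_profile <- function(track, region, n_bins) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  v <- region_values(track, as.character(seqnames(region)),
                     start(region), end(region))
  if (as.character(strand(region)) == "-") v <- rev(v)
  bin_means(v, n_bins)
}
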