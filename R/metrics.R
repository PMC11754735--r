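#' Metagene profile over anchored or scaled regions
#'
#' Builds a regions-by-bins matrix of mean per-base signal. In
#' `"scale_regions"` mode each row is: upstream flank binned at `bin_bp`,
#' the region body rescaled to `n_body_bins` equal (possibly fractional)
#' bins, then the downstream flank; in `"reference_point"` mode the bins
#' cover `[anchor - flank_bp, anchor + flank_bp)` around each region's 5'
#' end. Rows of minus-strand regions are oriented 5' to 3'. The averaged
#' profile (column means) summarizes the matrix.
#'
#' @param tracks A `CoverageTrack`, or a list of them from which the track
#'   matching each region's strand is chosen (unstranded regions use `+`).
#' @param regions Non-empty `GRanges`.
#' @param anchor_mode `"scale_regions"` (default) or `"reference_point"`.
#' @param n_body_bins Number of body bins (scale_regions).
#' @param flank_bp Flank length in bp.
#' @param bin_bp Flank bin width in bp.
#' @return A `MetageneProfile`: list with `matrix`, `profile` (column
#'   means), `settings`, and `scale_factor` (`NULL` until
#'   [unit_max_scale()]).
#' @export
metagene <- function(tracks, regions, anchor_mode = c("scale_regions",
                                                      "reference_point"),
                     n_body_bins = 100L, flank_bp = 5000L, bin_bp = 10L) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(is(regions, "GRanges"), length(regions) > 0, flank_bp >= 0,
            bin_bp >= 1)
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  by_strand <- setNames(tracks, vapply(tracks, `[[`, character(1), "strand"))
  n_flank_bins <- as.integer(round(flank_bp / bin_bp))
  if (anchor_mode == "scale_regions") {
    if (any(width(regions) < n_body_bins))
      warning("region(s) shorter than one bin per body bin; ",
              "fractional bins used")
    ncol_out <- 2L * n_flank_bins + n_body_bins
  } else {
    ncol_out <- 2L * n_flank_bins
  }
  mat <- matrix(NA_real_, nrow = length(regions), ncol = ncol_out)
  for (i in seq_along(regions)) {
    st <- as.character(strand(regions))[i]
    if (st == "*") st <- "+"
    track <- by_strand[[st]]
    if (is.null(track)) stop("no track supplied for strand ", st)
    ctg <- as.character(seqnames(regions))[i]
    s <- start(regions)[i]; e <- end(regions)[i]
    minus <- st == "-"
    if (anchor_mode == "scale_regions") {
      up <- region_values(track, ctg,
                          if (minus) e + 1L else s - flank_bp,
                          if (minus) e + flank_bp else s - 1L)
      body <- region_values(track, ctg, s, e)
      down <- region_values(track, ctg,
                            if (minus) s - flank_bp else e + 1L,
                            if (minus) s - 1L else e + flank_bp)
      if (minus) { up <- rev(up); body <- rev(body); down <- rev(down) }
      row <- c(if (n_flank_bins) bin_means(up, n_flank_bins),
               bin_means(body, n_body_bins),
               if (n_flank_bins) bin_means(down, n_flank_bins))
    } else {
      anchor <- if (minus) e else s
      v <- region_values(track, ctg, anchor - flank_bp,
                         anchor + flank_bp - 1L)
      if (minus) v <- rev(v)
      row <- bin_means(v, 2L * n_flank_bins)
    }
    mat[i, ] <- row
  }
  rownames(mat) <- if (!is.null(regions$gene_id)) regions$gene_id
                   else if (!is.null(regions$window_id)) regions$window_id
                   else NULL
  structure(list(matrix = mat, profile = colMeans(mat),
                 settings = list(anchor_mode = anchor_mode,
                                 n_body_bins = n_body_bins,
                                 flank_bp = flank_bp, bin_bp = bin_bp),
                 scale_factor = NULL),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile (%s): %d regions x %d bins, max profile %g\n",
              x$settings$anchor_mode, nrow(x$matrix), ncol(x$matrix),
              max(x$profile)))
  invisible(x)
}

#' Unit-max scaling of metagene profiles
#'
#' For each profile the scale factor is 1 / (maximum of its averaged profile
#' within the plotted window); the factor is applied to the underlying
#' values and the matrix recomputed. Binning and averaging are linear in the
#' signal, so recomputation multiplies the matrix by the factor. Scaling is
#' idempotent: a scaled profile has maximum 1 and rescales by factor 1.
#'
#' @param profiles A `MetageneProfile` or a list of them.
#' @return Same shape as the input, with `matrix`/`profile` scaled and
#'   `scale_factor` set.
#' @export
unit_max_scale <- function(profiles) {
  single <- is(profiles, "MetageneProfile")
  if (single) profiles <- list(profiles)
  out <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    m <- max(p$profile)
    if (!is.finite(m) || m <= 0)
      stop("cannot unit-max scale profile ", i, ": max of averaged profile is ",
           m)
    f <- 1 / m
    p$matrix <- p$matrix * f
    p$profile <- colMeans(p$matrix)
    p$scale_factor <- f
    p
  })
  names(out) <- names(profiles)
  if (single) out[[1]] else out
}

#' Per-gene log2 PAS/TSS signal ratio
#'
#' Sums the signal in fixed-width windows ending at the annotated PAS and
#' starting at the annotated TSS of each preselected gene and returns
#' log2(PAS sum / TSS sum). Genes with a zero sum in either window are
#' excluded (reported via the `n_excluded` attribute), unless a pseudocount
#' is supplied. Marks of terminal pausing give positive ratios; initiation
#' marks give negative ones.
#'
#' @param track A `CoverageTrack` (regions on its strand are used; pass the
#'   genes matching the track's strand, or both strands' tracks via two
#'   calls).
#' @param genes Preselected gene `GRanges`.
#' @param window_bp Window width (default 200).
#' @param pseudocount Added to both sums when > 0 (default 0 = excluded).
#' @return `data.frame` with `gene_id`, `pas_sum`, `tss_sum`, `log2_ratio`,
#'   and attribute `n_excluded`.
#' @export
pas_tss_ratio <- function(track, genes, window_bp = 200L, pseudocount = 0) {
  pw <- pas_window(genes, window_bp)
  tw <- tss_window(genes, window_bp)
  s_pas <- window_sum(track, pw) + pseudocount
  s_tss <- window_sum(track, tw) + pseudocount
  keep <- s_pas > 0 & s_tss > 0
  df <- data.frame(gene_id = genes$gene_id[keep],
                   pas_sum = s_pas[keep], tss_sum = s_tss[keep],
                   log2_ratio = log2(s_pas[keep] / s_tss[keep]))
  attr(df, "n_excluded") <- sum(!keep)
  df
}

#' Rank genes into equal-size activity groups
#'
#' Computes each gene's mean per-base signal over its body extended
#' `body_extension_bp` past the PAS, ranks genes ascending, drops the
#' `n %% n_groups` least-active genes so groups are exactly equal, and
#' assigns group ranks 1 (least active) to `n_groups` (most active). Ties
#' are ordered stably by `gene_id`, so assignment is deterministic.
#'
#' @param total_track A `CoverageTrack` of modification-independent (total)
#'   polymerase signal.
#' @param genes Preselected gene `GRanges` (length >= `n_groups`).
#' @param body_extension_bp Downstream extension of the body (default 5000).
#' @param n_groups Number of groups (default 5).
#' @return An `ActivityGroups` list: `assignment` (`data.frame` with
#'   `gene_id`, `mean_signal`, `rank`, `group`), `dropped_ids`, `n_groups`.
#' @export
activity_groups <- function(total_track, genes, body_extension_bp = 5000L,
                            n_groups = 5L) {
  n <- length(genes)
  if (n < n_groups)
    stop("need at least ", n_groups, " genes, got ", n)
  regions <- body_plus_extension(genes, body_extension_bp)
  mean_signal <- window_sum(total_track, regions) / width(regions)
  ord <- order(mean_signal, genes$gene_id)
  r <- n %% n_groups
  dropped <- ord[seq_len(r)]
  kept <- ord[setdiff(seq_len(n), seq_len(r))]
  per <- (n - r) %/% n_groups
  assignment <- data.frame(gene_id = genes$gene_id[kept],
                           mean_signal = mean_signal[kept],
                           rank = seq_along(kept),
                           group = rep(seq_len(n_groups), each = per))
  structure(list(assignment = assignment,
                 dropped_ids = genes$gene_id[dropped],
                 n_groups = as.integer(n_groups)),
            class = "ActivityGroups")
}

#' Metagene profiles stratified by activity group
#'
#' @param mark_track `CoverageTrack` of the modification of interest (e.g.
#'   the terminal-pausing mark).
#' @param groups An [activity_groups()] result.
#' @param genes The gene `GRanges` the groups were computed from.
#' @param body_extension_bp Regions profiled are bodies extended this far
#'   past the PAS.
#' @inheritParams metagene
#' @return Named list of `MetageneProfile`, `group1` (least active) to
#'   `groupK` (most active).
#' @export
group_profiles <- function(mark_track, groups, genes,
                           body_extension_bp = 5000L, n_body_bins = 100L,
                           flank_bp = 0L, bin_bp = 10L) {
  stopifnot(is(groups, "ActivityGroups"))
  regions <- body_plus_extension(genes, body_extension_bp)
  names(regions) <- genes$gene_id
  out <- lapply(seq_len(groups$n_groups), function(k) {
    ids <- groups$assignment$gene_id[groups$assignment$group == k]
    if (length(ids) == 0) stop("activity group ", k, " is empty")
    metagene(mark_track, regions[names(regions) %in% ids],
             n_body_bins = n_body_bins, flank_bp = flank_bp, bin_bp = bin_bp)
  })
  names(out) <- paste0("group", seq_len(groups$n_groups))
  out
}

#' Write a metagene profile (and optionally its matrix) as TSV
#'
#' The matrix file carries a single JSON header line (prefixed `#`) with
#' the settings and region count.
#'
#' @param profile A `MetageneProfile`.
#' @param profile_path TSV of bin index and averaged profile value.
#' @param matrix_path Optional gzip TSV of the full matrix.
#' @return Invisibly, the paths written.
#' @export
write_profile <- function(profile, profile_path, matrix_path = NULL) {
  write.table(data.frame(bin = seq_along(profile$profile),
                         mean_signal = profile$profile),
              profile_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    con <- gzfile(matrix_path, "w")
    on.exit(close(con))
    header <- jsonlite::toJSON(c(profile$settings,
                                 list(n_regions = nrow(profile$matrix),
                                      scale_factor = profile$scale_factor)),
                               auto_unbox = TRUE, null = "null")
    writeLines(paste0("#", header), con)
    write.table(profile$matrix, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(profile = profile_path, matrix = matrix_path))
}
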