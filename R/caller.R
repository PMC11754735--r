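#' Parameters of the two-tier broad-enrichment caller
#'
#' Defaults mirror the documented defaults of the MACS-style broad bedGraph
#' caller this reimplements: a high "peak" cutoff defining strong runs, a
#' low "link" cutoff defining weak signal allowed to bridge them, small-gap
#' closing within strong regions, a maximum linking gap, and a minimum
#' emitted length. Cutoffs are on the scale of the input track, so analyses
#' of tracks with different depth should scale them accordingly (see
#' [suggest_call_params()] for simulated data).
#'
#' @param cutoff_peak High threshold; bases with value strictly greater are
#'   "strong".
#' @param cutoff_link Low threshold for "weak" signal; must satisfy
#'   `cutoff_peak >= cutoff_link > 0`.
#' @param min_length Minimum emitted region length (bp).
#' @param max_gap_within Gaps up to this length inside strong regions are
#'   closed.
#' @param max_gap_link Strong regions bridged by weak signal with
#'   interruptions up to this length are linked; must be
#'   `>= max_gap_within`.
#' @return A `broad_call_params` list.
#' @export
broad_call_params <- function(cutoff_peak = 2, cutoff_link = 1,
                              min_length = 200L, max_gap_within = 30L,
                              max_gap_link = 800L) {
  stopifnot(cutoff_peak >= cutoff_link, cutoff_link > 0,
            min_length >= 1, max_gap_link >= max_gap_within,
            max_gap_within >= 0)
  structure(list(cutoff_peak = cutoff_peak, cutoff_link = cutoff_link,
                 min_length = as.integer(min_length),
                 max_gap_within = as.integer(max_gap_within),
                 max_gap_link = as.integer(max_gap_link)),
            class = "broad_call_params")
}

# two-tier calling on one contig's Rle; returns IRanges
call_broad_contig <- function(x, params) {
  strong <- reduce(as(slice(x, lower = params$cutoff_peak,
                            includeLower = FALSE), "IRanges"),
                   min.gapwidth = params$max_gap_within + 1L)
  if (length(strong) == 0) return(IRanges())
  weak <- reduce(as(slice(x, lower = params$cutoff_link,
                          includeLower = FALSE), "IRanges"),
                 min.gapwidth = params$max_gap_link + 1L)
  # every gap-closed strong region lies inside exactly one weak super-region
  # (strong bases are weak bases and the closing gap is smaller)
  grp <- findOverlaps(strong, weak, select = "first")
  sp <- vapply(split(seq_along(strong), grp), function(i)
    c(min(start(strong)[i]), max(end(strong)[i])), numeric(2))
  out <- IRanges(sp[1, ], sp[2, ])
  out <- out[width(out) >= params$min_length]
  sort(out)
}

#' Call broadly enriched regions on a coverage track
#'
#' Two-tier threshold calling: (1) maximal runs of bases with value strictly
#' above `cutoff_peak`, with internal gaps up to `max_gap_within` closed, are
#' strong regions; (2) maximal runs strictly above `cutoff_link` are weak
#' regions; (3) strong regions whose intervening gap is bridged by weak
#' signal (with interruptions up to `max_gap_link`) are linked, and the
#' emitted region spans the linked strong regions; (4) emitted regions
#' shorter than `min_length` are discarded.
#'
#' @param track A `CoverageTrack` (typically a replicate-averaged, extended
#'   signal).
#' @param params A [broad_call_params()].
#' @param source_label Label recorded on every emitted region (which
#'   averaged track produced it).
#' @return Sorted `GRanges` of enriched regions on the track's strand, with
#'   a `source_label` metadata column.
#' @export
call_broad_regions <- function(track, params = broad_call_params(),
                               source_label = "track") {
  stopifnot(is(params, "broad_call_params"))
  per <- lapply(names(track$cov), function(ctg) {
    ir <- call_broad_contig(track$cov[[ctg]], params)
    GRanges(factor(rep(ctg, length(ir)), levels = names(track$cov)), ir,
            strand = rep(track$strand, length(ir)))
  })
  out <- if (length(per)) sort(do.call(c, per), ignore.strand = TRUE)
         else GRanges()
  out$source_label <- if (length(out)) source_label else character(0)
  out
}

#' Consensus of enriched regions from two sources
#'
#' Retains every region from either list that overlaps (by at least 1 bp) a
#' region from the other list, pools the retained regions, and merges
#' overlapping or book-ended ranges into maximal disjoint windows. Requiring
#' support in both averaged files guards against study-specific artifacts.
#'
#' @param regions_a,regions_b `GRanges` of enriched regions on the same
#'   strand and assembly.
#' @return Sorted, pairwise-disjoint `GRanges` of consensus windows with
#'   metadata columns `window_id` and `provenance` (a `CharacterList` of the
#'   contributing source regions as `label:contig:start-end`).
#' @export
consensus <- function(regions_a, regions_b) {
  ka <- regions_a[countOverlaps(regions_a, regions_b) > 0]
  kb <- regions_b[countOverlaps(regions_b, regions_a) > 0]
  merge_with_provenance(c(granges(ka), granges(kb)),
                        c(source_labels(ka), source_labels(kb)))
}

source_labels <- function(gr) {
  if (length(gr) == 0) character(0)
  else if (!is.null(gr$source_label)) as.character(gr$source_label)
  else rep("unknown", length(gr))
}

merge_with_provenance <- function(pooled, lab) {
  merged <- sort(reduce(sort(pooled, ignore.strand = TRUE)),
                 ignore.strand = TRUE)
  tags <- sprintf("%s:%s:%d-%d", lab, as.character(seqnames(pooled)),
                  start(pooled), end(pooled))
  hits <- findOverlaps(merged, pooled)
  prov <- unname(splitAsList(tags[subjectHits(hits)],
                             factor(queryHits(hits),
                                    levels = seq_along(merged))))
  merged$window_id <- if (length(merged))
    sprintf("tw_%s_%05d", as.character(strand(merged)), seq_along(merged))
    else character(0)
  merged$provenance <- prov
  merged
}

#' Call termination windows from replicate sets
#'
#' Full window-calling composition for one strand: each replicate set (one
#' study) is averaged ([mean_tracks()]), extended ([extend_signal()]) and
#' called ([call_broad_regions()]); windows are then the cross-set
#' [consensus()]. With more than two sets, regions overlapping a region from
#' at least one other set are retained and merged.
#'
#' @param replicate_sets List (length >= 2) of lists of `CoverageTrack`s,
#'   all on the same strand; one inner list per study.
#' @param params A [broad_call_params()].
#' @param extension_bp,anchor Passed to [extend_signal()].
#' @param labels Optional labels for the sets (defaults `set1`, `set2`, ...).
#' @return Consensus windows as from [consensus()].
#' @export
call_termination_windows <- function(replicate_sets,
                                     params = broad_call_params(),
                                     extension_bp = 150L,
                                     anchor = "five_prime",
                                     labels = NULL) {
  if (length(replicate_sets) < 2)
    stop("consensus window calling requires at least two replicate sets ",
         "(one per study); got ", length(replicate_sets))
  if (is.null(labels)) labels <- paste0("set", seq_along(replicate_sets))
  called <- lapply(seq_along(replicate_sets), function(i) {
    avg <- mean_tracks(replicate_sets[[i]])
    ext <- extend_signal(avg, length_bp = extension_bp, anchor = anchor)
    call_broad_regions(ext, params, source_label = labels[i])
  })
  if (length(called) == 2) return(consensus(called[[1]], called[[2]]))
  keep <- lapply(seq_along(called), function(i) {
    others <- do.call(c, called[-i])
    called[[i]][countOverlaps(called[[i]], others) > 0]
  })
  pooled <- do.call(c, keep)
  merge_with_provenance(granges(pooled), source_labels(pooled))
}
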