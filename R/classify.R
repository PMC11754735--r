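#' Window-classification parameters
#'
#' @param downstream_bp Length of the PAS-downstream region defining
#'   gene-end windows (default 6000, the region where most human genes
#'   terminate).
#' @param priority Order in which the two gene-linked categories are tried
#'   when both predicates hold.
#' @return A `class_params` list.
#' @export
class_params <- function(downstream_bp = 6000L,
                         priority = c("gene_end", "premature")) {
  stopifnot(downstream_bp > 0,
            setequal(priority, c("gene_end", "premature")))
  structure(list(downstream_bp = as.integer(downstream_bp),
                 priority = priority),
            class = "class_params")
}

# among candidate genes (indices into `genes`), pick the one whose anchor
# is nearest the window midpoint; exact ties resolved by gene_id
pick_gene <- function(genes, idx, anchors, mid) {
  d <- abs(anchors[idx] - mid)
  idx <- idx[order(d, genes$gene_id[idx])]
  idx[1]
}

#' Classify termination windows against preselected genes
#'
#' Each window receives exactly one category: `gene_end` if it overlaps (by
#' at least 1 bp) the PAS-downstream region of any preselected gene on the
#' same strand; otherwise `premature` if it falls fully inside the body of
#' any preselected gene on the same strand; otherwise `other` (intergenic,
#' or belonging to genes excluded from preselection). When several genes
#' assign the same category, the gene whose PAS (gene-end) or TSS
#' (premature) lies nearest the window midpoint wins, with exact ties broken
#' by `gene_id`.
#'
#' @param windows `GRanges` of termination windows (stranded).
#' @param genes Preselected gene `GRanges` (from [select_genes()]).
#' @param params A [class_params()].
#' @return `GRanges` parallel to `windows` with metadata columns
#'   `window_id`, `category` (factor gene_end/premature/other), `gene_id`
#'   (`NA` for other) and `length_bp`.
#' @export
classify_windows <- function(windows, genes, params = class_params()) {
  out <- granges(windows)
  n <- length(out)
  out$window_id <- if (!is.null(windows$window_id)) windows$window_id
                   else sprintf("tw_%05d", seq_len(n))
  category <- rep("other", n)
  gene_id <- rep(NA_character_, n)
  if (n > 0 && length(genes) > 0) {
    ge_regions <- pas_downstream(genes, params$downstream_bp)
    mid <- (start(out) + end(out)) / 2
    hits_ge <- findOverlaps(out, ge_regions, ignore.strand = FALSE)
    hits_pm <- findOverlaps(out, granges(genes), type = "within",
                            ignore.strand = FALSE)
    ge_by_w <- split(subjectHits(hits_ge), queryHits(hits_ge))
    pm_by_w <- split(subjectHits(hits_pm), queryHits(hits_pm))
    for (cat in params$priority) {
      by_w <- if (cat == "gene_end") ge_by_w else pm_by_w
      anchors <- if (cat == "gene_end") genes$pas else genes$tss
      for (w in as.integer(names(by_w))) {
        if (category[w] != "other") next
        category[w] <- cat
        gene_id[w] <- genes$gene_id[pick_gene(genes, by_w[[as.character(w)]],
                                              anchors, mid[w])]
      }
    }
  }
  out$category <- factor(category,
                         levels = c("gene_end", "premature", "other"))
  out$gene_id <- gene_id
  out$length_bp <- width(out)
  out
}

# lower median: for even n the smaller of the two central order statistics
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[(n + 1L) %/% 2L]
}

#' Per-category summary of classified windows
#'
#' Counts and length summaries per category. The median uses the
#' lower-median convention for even counts; quartiles use the default
#' (type 7) quantile definition.
#'
#' @param classified Output of [classify_windows()].
#' @return `data.frame` with one row per category (`gene_end`, `premature`,
#'   `other`): `n`, `median_length_bp`, `q1_length_bp`, `q3_length_bp`
#'   (`NA` for empty categories).
#' @export
window_stats <- function(classified) {
  cats <- c("gene_end", "premature", "other")
  rows <- lapply(cats, function(cat) {
    len <- classified$length_bp[classified$category == cat]
    if (length(len) == 0)
      data.frame(category = cat, n = 0L, median_length_bp = NA_real_,
                 q1_length_bp = NA_real_, q3_length_bp = NA_real_)
    else
      data.frame(category = cat, n = length(len),
                 median_length_bp = lower_median(len),
                 q1_length_bp = unname(stats::quantile(len, 0.25)),
                 q3_length_bp = unname(stats::quantile(len, 0.75)))
  })
  do.call(rbind, rows)
}

#' Write classified windows as BED6 and TSV
#'
#' BED names carry the category (`window_id|category`); scores are 0.
#'
#' @param classified Output of [classify_windows()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_classified <- function(classified, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- granges(classified)
    bed$name <- paste(classified$window_id, classified$category, sep = "|")
    bed$score <- 0L
    rtracklayer::export(bed, bed_path, format = "BED")
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(window_id = classified$window_id,
                     contig = as.character(seqnames(classified)),
                     start = start(classified), end = end(classified),
                     strand = as.character(strand(classified)),
                     category = as.character(classified$category),
                     gene_id = classified$gene_id,
                     length_bp = classified$length_bp)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
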