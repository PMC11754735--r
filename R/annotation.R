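#' Load gene models from a GTF annotation
#'
#' Reads gene-level records from a (GENCODE-style) GTF and returns them as a
#' `GRanges` with `gene_id`, `biotype` and strand-aware `tss`/`pas` position
#' columns. `tss` is the first transcribed base and `pas` the last (the
#' annotated polyadenylation site), so on `+` genes `tss = start`,
#' `pas = end` and on `-` genes `tss = end`, `pas = start`. Records without
#' a strand are skipped with a warning giving their count.
#'
#' @param gtf_path GTF file (optionally gzipped). Records with
#'   `type == "gene"` are used; if the file carries no `type` column every
#'   record is treated as a gene.
#' @return `GRanges`, one range per gene, in file order, with metadata
#'   columns `gene_id`, `biotype`, `tss`, `pas`.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("no such file: ", gtf_path)
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e)
                   stop("failed to parse GTF ", gtf_path, ": ",
                        conditionMessage(e)))
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "gene"]
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes: ", gtf_path)
  unstranded <- as.character(strand(gr)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " gene record(s) without strand skipped")
    gr <- gr[!unstranded]
  }
  biotype <- if (!is.null(gr$gene_type)) as.character(gr$gene_type)
             else if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
             else rep(NA_character_, length(gr))
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = as.character(gr$gene_id),
                          biotype = biotype)
  out <- set_tss_pas(out)
  out
}

set_tss_pas <- function(genes) {
  plus <- as.character(strand(genes)) == "+"
  genes$tss <- ifelse(plus, start(genes), end(genes))
  genes$pas <- ifelse(plus, end(genes), start(genes))
  genes
}

#' Gene-preselection parameters
#'
#' @param biotypes Biotypes to retain (applies to the retained gene only;
#'   the overlap and isolation filters consider every annotated gene).
#' @param isolation_bp Minimum strand-aware distance (bp between the PAS and
#'   the start of the next same-strand gene) required downstream of the 3'
#'   end; the bound is inclusive.
#' @param overlap_all_biotypes If `FALSE`, the same-strand overlap filter
#'   only considers genes passing the biotype filter.
#' @return A `selection_params` list.
#' @export
selection_params <- function(biotypes = "protein_coding",
                             isolation_bp = 6000L,
                             overlap_all_biotypes = TRUE) {
  stopifnot(isolation_bp >= 0)
  structure(list(biotypes = biotypes,
                 isolation_bp = as.integer(isolation_bp),
                 overlap_all_biotypes = isTRUE(overlap_all_biotypes)),
            class = "selection_params")
}

# strand-aware gap (bp) from each candidate's PAS to the start (5' end) of
# the nearest same-strand gene lying strictly downstream; Inf when none
downstream_isolation <- function(candidates, genes) {
  vapply(seq_along(candidates), function(i) {
    g <- candidates[i]
    same <- genes[as.character(strand(genes)) == as.character(strand(g)) &
                  as.character(seqnames(genes)) == as.character(seqnames(g))]
    if (as.character(strand(g)) == "+") {
      d <- start(same) - end(g) - 1L
    } else {
      d <- start(g) - end(same) - 1L
    }
    d <- d[d >= 0]
    if (length(d)) min(d) else Inf
  }, numeric(1))
}

#' Preselect non-overlapping genes with isolated 3' ends
#'
#' Retains genes that (a) match the biotype filter, (b) overlap no other
#' annotated gene on the same strand, and (c) have their 3' end isolated:
#' the nearest same-strand gene starting downstream of the PAS begins at
#' least `isolation_bp` past it (inclusive). Quantifying termination signal
#' downstream of a gene is only meaningful when no tandem neighbour
#' contributes signal there, which is what (b) and (c) guarantee.
#'
#' @param genes `GRanges` from [load_annotation()].
#' @param params A [selection_params()].
#' @return The retained genes, sorted by (contig, start).
#' @export
select_genes <- function(genes, params = selection_params()) {
  if (length(genes) == 0) return(genes)
  pool <- if (params$overlap_all_biotypes) genes
          else genes[genes$biotype %in% params$biotypes]
  cand <- genes[genes$biotype %in% params$biotypes]
  # (b) same-strand overlap with any other annotated gene
  hits <- findOverlaps(cand, pool, ignore.strand = FALSE)
  self <- cand$gene_id[queryHits(hits)] == pool$gene_id[subjectHits(hits)]
  cand <- cand[!(seq_along(cand) %in% queryHits(hits)[!self])]
  if (length(cand) == 0) return(cand)
  # (c) 3'-end isolation against same-strand genes
  iso <- downstream_isolation(cand, pool)
  cand <- cand[iso >= params$isolation_bp]
  sort(cand, ignore.strand = TRUE)
}

strand_is_plus <- function(gr) as.character(strand(gr)) == "+"

clip_regions <- function(gr, seqlens = NULL) {
  under <- start(gr) < 1L
  if (any(under)) start(gr)[under] <- 1L
  if (!is.null(seqlens)) {
    ctg <- as.character(seqnames(gr))
    lim <- unname(seqlens[ctg])
    over <- !is.na(lim) & end(gr) > lim
    if (any(over)) end(gr)[over] <- lim[over]
  }
  gr
}

#' Region downstream of the PAS, in transcription direction
#' @param genes Gene `GRanges`.
#' @param bp Region length in bp.
#' @param seqlens Optional named vector of contig lengths for clipping.
#' @return `GRanges` parallel to `genes`, carrying `gene_id`.
#' @export
pas_downstream <- function(genes, bp = 6000L, seqlens = NULL) {
  plus <- strand_is_plus(genes)
  s <- ifelse(plus, end(genes) + 1L, start(genes) - bp)
  out <- GRanges(seqnames(genes), IRanges(s, width = bp), strand = strand(genes),
                 gene_id = genes$gene_id)
  clip_regions(out, seqlens)
}

#' Window of given width starting at the TSS
#' @inheritParams pas_downstream
#' @export
tss_window <- function(genes, bp = 200L, seqlens = NULL) {
  plus <- strand_is_plus(genes)
  s <- ifelse(plus, start(genes), end(genes) - bp + 1L)
  out <- GRanges(seqnames(genes), IRanges(s, width = bp), strand = strand(genes),
                 gene_id = genes$gene_id)
  clip_regions(out, seqlens)
}

#' Window of given width ending at the PAS
#' @inheritParams pas_downstream
#' @export
pas_window <- function(genes, bp = 200L, seqlens = NULL) {
  plus <- strand_is_plus(genes)
  s <- ifelse(plus, end(genes) - bp + 1L, start(genes))
  out <- GRanges(seqnames(genes), IRanges(s, width = bp), strand = strand(genes),
                 gene_id = genes$gene_id)
  clip_regions(out, seqlens)
}

#' Gene body extended downstream past the PAS
#' @inheritParams pas_downstream
#' @export
body_plus_extension <- function(genes, bp = 5000L, seqlens = NULL) {
  plus <- strand_is_plus(genes)
  s <- ifelse(plus, start(genes), start(genes) - bp)
  e <- ifelse(plus, end(genes) + bp, end(genes))
  out <- GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes),
                 gene_id = genes$gene_id)
  clip_regions(out, seqlens)
}

#' Bundle of derived regions for genes
#'
#' Convenience wrapper returning the four strand-aware region sets used by
#' the pipeline: the PAS-downstream region, fixed-width TSS and PAS windows,
#' and the gene body extended past the PAS.
#'
#' @param genes Gene `GRanges`.
#' @param downstream_bp Length of the PAS-downstream region.
#' @param window_bp Width of the TSS/PAS windows.
#' @param body_extension_bp Extension of the body past the PAS.
#' @param seqlens Optional contig lengths; without them regions extending
#'   past the (unknown) contig end are emitted unclipped.
#' @return Named list of `GRanges`: `pas_downstream`, `tss_window`,
#'   `pas_window`, `body_plus_extension`.
#' @export
derive_regions <- function(genes, downstream_bp = 6000L, window_bp = 200L,
                           body_extension_bp = 5000L, seqlens = NULL) {
  stopifnot(downstream_bp > 0, window_bp > 0, body_extension_bp > 0)
  list(pas_downstream = pas_downstream(genes, downstream_bp, seqlens),
       tss_window = tss_window(genes, window_bp, seqlens),
       pas_window = pas_window(genes, window_bp, seqlens),
       body_plus_extension = body_plus_extension(genes, body_extension_bp,
                                                 seqlens))
}

#' Write selected genes as BED6 and TSV
#'
#' @param genes Gene `GRanges` with `gene_id`, `tss`, `pas`.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_genes <- function(genes, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- granges(genes)
    bed$name <- genes$gene_id
    bed$score <- 0L
    rtracklayer::export(bed, bed_path, format = "BED")
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(contig = as.character(seqnames(genes)),
                     start = start(genes), end = end(genes),
                     strand = as.character(strand(genes)),
                     gene_id = genes$gene_id, biotype = genes$biotype,
                     tss = genes$tss, pas = genes$pas)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
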