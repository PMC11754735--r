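toy_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(contig, start, end, strand, id, biotype = "protein_coding") {
  sprintf('%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
          contig, start, end, strand, id, biotype)
}

test_that("GTF gene records parse with strand-aware TSS and PAS", {
  g <- load_annotation(toy_gtf(gtf_line("chr1", 1001, 2000, "+", "G1")))
  expect_equal(start(g), 1001)
  expect_equal(end(g), 2000)
  expect_equal(g$tss, 1001)
  expect_equal(g$pas, 2000)
  m <- load_annotation(toy_gtf(gtf_line("chr1", 1001, 2000, "-", "G1")))
  expect_equal(m$tss, 2000)
  expect_equal(m$pas, 1001)
  expect_equal(m$biotype, "protein_coding")
})

test_that("the shipped five-gene fixture parses in file order", {
  g <- load_annotation(test_path("fixtures", "toy5.gtf"))
  expect_length(g, 5)
  expect_equal(g$gene_id, paste0("TG", 1:5))
  expect_equal(as.character(seqnames(g)),
               c("chr1", "chr1", "chr1", "chr2", "chr2"))
  expect_equal(g$biotype[3], "lincRNA")
  expect_equal(g$tss, c(1001, 15000, 30001, 501, 22000))
  expect_equal(g$pas, c(2000, 12001, 31000, 4000, 20001))
})

test_that("unstranded gene records are skipped with a warning", {
  path <- toy_gtf(c(gtf_line("chr1", 1001, 2000, "+", "G1"),
                    gtf_line("chr1", 9001, 9500, ".", "G2")))
  expect_warning(g <- load_annotation(path), "without strand")
  expect_equal(g$gene_id, "G1")
})

test_that("mutually overlapping same-strand genes are both rejected", {
  path <- toy_gtf(c(gtf_line("chr1", 1001, 2000, "+", "G1"),
                    gtf_line("chr1", 2000, 3000, "+", "G2")))
  g <- load_annotation(path)
  expect_length(select_genes(g), 0)
})

test_that("the 6-kb isolation bound is inclusive", {
  # downstream gene starting exactly isolation_bp past the PAS is allowed
  at_bound <- c(gtf_line("chr1", 1001, 2000, "+", "G1"),
                gtf_line("chr1", 8001, 9000, "+", "G2"))
  g <- load_annotation(toy_gtf(at_bound))
  expect_true("G1" %in% select_genes(g)$gene_id)
  inside <- c(gtf_line("chr1", 1001, 2000, "+", "G1"),
              gtf_line("chr1", 8000, 9000, "+", "G2"))
  g2 <- load_annotation(toy_gtf(inside))
  expect_false("G1" %in% select_genes(g2)$gene_id)
})

test_that("preselection on a four-gene toy keeps only isolated genes", {
  path <- toy_gtf(c(gtf_line("chr1", 1, 1000, "+", "A"),
                    gtf_line("chr1", 1501, 2000, "+", "B"),
                    gtf_line("chr1", 1201, 1800, "-", "C"),
                    gtf_line("chr1", 9001, 9500, "+", "D")))
  sel <- select_genes(load_annotation(path))
  # A's downstream neighbour B starts 500 bp past its PAS; B, C, D isolated
  expect_setequal(sel$gene_id, c("B", "C", "D"))
  expect_equal(sel$gene_id, c("C", "B", "D"))  # sorted by (contig, start)
})

test_that("empty input selects nothing without error", {
  g <- GRanges()
  g$gene_id <- character(0); g$biotype <- character(0)
  expect_length(select_genes(g), 0)
})

random_gene_df <- function(n) {
  start <- sample.int(50000, n)
  data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
             start = start,
             end = start + sample(200:4000, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             gene_id = sprintf("R%03d", seq_len(n)),
             biotype = sample(c("protein_coding", "lincRNA"), n,
                              replace = TRUE, prob = c(0.8, 0.2)))
}

df_to_granges <- function(df) {
  g <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand,
               gene_id = df$gene_id, biotype = df$biotype)
  termwin:::set_tss_pas(g)
}

test_that("preselection matches the all-pairs oracle on random gene sets", {
  set.seed(42)
  for (rep in 1:40) {
    df <- random_gene_df(sample(5:60, 1))
    sel <- select_genes(df_to_granges(df),
                        selection_params(isolation_bp = 3000))
    expect_setequal(sel$gene_id, oracle_select(df, isolation_bp = 3000))
    # retained genes form an antichain under same-strand overlap
    if (length(sel) > 1) {
      hits <- findOverlaps(sel, sel, ignore.strand = FALSE)
      expect_true(all(queryHits(hits) == subjectHits(hits)))
    }
  }
})

test_that("derived regions follow strand-aware geometry", {
  gp <- df_to_granges(data.frame(contig = "chr1", start = 1001, end = 5000,
                                 strand = "+", gene_id = "G",
                                 biotype = "protein_coding"))
  r <- derive_regions(gp, downstream_bp = 6000, window_bp = 200,
                      body_extension_bp = 5000)
  expect_equal(granges_matrix(r$pas_downstream), cbind(5001, 11000))
  expect_equal(granges_matrix(r$tss_window), cbind(1001, 1200))
  expect_equal(granges_matrix(r$pas_window), cbind(4801, 5000))
  expect_equal(granges_matrix(r$body_plus_extension), cbind(1001, 10000))
  gm <- df_to_granges(data.frame(contig = "chr1", start = 1001, end = 5000,
                                 strand = "-", gene_id = "G",
                                 biotype = "protein_coding"))
  rm_ <- derive_regions(gm, downstream_bp = 6000, window_bp = 200,
                        body_extension_bp = 5000)
  expect_equal(granges_matrix(rm_$tss_window), cbind(4801, 5000))
  expect_equal(granges_matrix(rm_$pas_window), cbind(1001, 1200))
  expect_equal(granges_matrix(rm_$body_plus_extension), cbind(1, 5000))
})

test_that("mirror-image genes produce mirror-image regions", {
  L <- 100000
  gp <- df_to_granges(data.frame(contig = "c", start = 20001, end = 30000,
                                 strand = "+", gene_id = "G",
                                 biotype = "protein_coding"))
  gm <- df_to_granges(data.frame(contig = "c", start = L - 30000 + 1,
                                 end = L - 20001 + 1, strand = "-",
                                 gene_id = "G", biotype = "protein_coding"))
  rp <- derive_regions(gp)
  rm_ <- derive_regions(gm)
  mirror <- function(m) cbind(L - m[, 2] + 1, L - m[, 1] + 1)
  for (nm in names(rp))
    expect_equal(granges_matrix(rm_[[nm]]),
                 mirror(granges_matrix(rp[[nm]])), info = nm)
})

test_that("region clipping respects supplied contig sizes", {
  g <- df_to_granges(data.frame(contig = "chr1", start = 1001, end = 5000,
                                strand = "+", gene_id = "G",
                                biotype = "protein_coding"))
  r <- pas_downstream(g, 6000, seqlens = c(chr1 = 8000))
  expect_equal(granges_matrix(r), cbind(5001, 8000))
})
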