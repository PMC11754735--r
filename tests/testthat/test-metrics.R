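mk_genes2 <- function(df) {
  g <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand,
               gene_id = df$gene_id, biotype = "protein_coding")
  termwin:::set_tss_pas(g)
}

test_that("scale-regions metagene rows are oriented bin means", {
  cst <- make_track(rep(2.5, 3000))
  regions <- GRanges("chrT", IRanges(c(501, 1501), c(900, 2200)),
                     strand = "+")
  p <- metagene(cst, regions, n_body_bins = 20, flank_bp = 100, bin_bp = 10)
  expect_equal(dim(p$matrix), c(2, 20 + 2 * 10))
  expect_true(all(abs(p$matrix - 2.5) < 1e-12))
  expect_true(all(abs(p$profile - 2.5) < 1e-12))
  # single region, no flanks: the row is the region's binned profile
  v <- numeric(1000); v[101:200] <- rpois(100, 5)
  t <- make_track(v)
  r1 <- GRanges("chrT", IRanges(101, 200), strand = "+")
  p1 <- metagene(t, r1, n_body_bins = 10, flank_bp = 0)
  expect_equal(as.numeric(p1$matrix[1, ]), binned_profile(t, r1, 10))
})

test_that("mirror-image regions on opposite strands give identical rows", {
  L <- 2000
  set.seed(12)
  v <- rpois(L, 2)
  tp <- make_track(v, "+")
  tm <- make_track(rev(v), "-")
  rp <- GRanges("chrT", IRanges(301, 420), strand = "+")
  rm_ <- GRanges("chrT", IRanges(L - 420 + 1, L - 301 + 1), strand = "-")
  pp <- metagene(tp, rp, n_body_bins = 12, flank_bp = 50, bin_bp = 10)
  pm <- metagene(tm, rm_, n_body_bins = 12, flank_bp = 50, bin_bp = 10)
  expect_equal(pp$matrix, pm$matrix, tolerance = 1e-12)
})

test_that("metagene matches the per-base binning oracle", {
  set.seed(21)
  for (i in 1:8) {
    L <- sample(200:1000, 1)
    v <- rpois(3000, 2)
    t <- make_track(v)
    s <- sample(1100:1500, 1)
    r <- GRanges("chrT", IRanges(s, s + L - 1), strand = "+")
    p <- metagene(t, r, n_body_bins = 30, flank_bp = 100, bin_bp = 10)
    want <- c(oracle_bin_means(v[(s - 100):(s - 1)], 10),
              oracle_bin_means(v[s:(s + L - 1)], 30),
              oracle_bin_means(v[(s + L):(s + L + 99)], 10))
    expect_equal(as.numeric(p$matrix[1, ]), want, tolerance = 1e-12)
  }
})

test_that("reference-point metagene anchors at the 5' end", {
  v <- numeric(1000); v[500] <- 10
  t <- make_track(v)
  r <- GRanges("chrT", IRanges(500, 700), strand = "+")
  p <- metagene(t, r, anchor_mode = "reference_point", flank_bp = 50,
                bin_bp = 10)
  expect_equal(ncol(p$matrix), 10)
  expect_equal(as.numeric(p$matrix[1, ]), c(rep(0, 5), 1, rep(0, 4)))
})

test_that("unit-max scaling normalizes the averaged profile to one", {
  v <- numeric(1000); v[401:500] <- 4
  t <- make_track(v)
  r <- GRanges("chrT", IRanges(301, 600), strand = "+")
  p <- metagene(t, r, n_body_bins = 30, flank_bp = 0)
  ps <- unit_max_scale(p)
  expect_equal(max(ps$profile), 1, tolerance = 1e-9)
  expect_equal(ps$scale_factor, 1 / 4)
  # two profiles with maxima 2 and 8 get factors 0.5 and 0.125
  p2 <- metagene(make_track(c(numeric(300), rep(2, 100), numeric(600))), r,
                 n_body_bins = 30, flank_bp = 0)
  p8 <- metagene(make_track(c(numeric(300), rep(8, 100), numeric(600))), r,
                 n_body_bins = 30, flank_bp = 0)
  sc <- unit_max_scale(list(p2, p8))
  expect_equal(vapply(sc, `[[`, numeric(1), "scale_factor"), c(0.5, 0.125))
  # idempotence
  ps2 <- unit_max_scale(ps)
  expect_equal(ps2$matrix, ps$matrix, tolerance = 1e-12)
  # a signal-free profile cannot be scaled
  p0 <- metagene(make_track(numeric(1000)), r, n_body_bins = 10,
                 flank_bp = 0)
  expect_error(unit_max_scale(p0), "cannot unit-max scale")
})

ratio_genes <- mk_genes2(data.frame(contig = "chrT",
                                    start = c(1001, 11001),
                                    end = c(3000, 13000),
                                    strand = "+", gene_id = c("G1", "G2")))

test_that("PAS/TSS ratios follow the window sums", {
  v <- numeric(20000)
  v[1001:1200] <- 1; v[2801:3000] <- 1          # G1: equal sums -> 0
  v[11001:11200] <- 1; v[12801:13000] <- 4      # G2: 4x -> 2
  df <- pas_tss_ratio(make_track(v), ratio_genes)
  expect_equal(df$log2_ratio[df$gene_id == "G1"], 0)
  expect_equal(df$log2_ratio[df$gene_id == "G2"], 2)
  expect_equal(attr(df, "n_excluded"), 0)
})

test_that("genes with an empty window are excluded unless pseudocounted", {
  v <- numeric(20000)
  v[1001:1200] <- 1                              # G1 has no PAS signal
  v[11001:11200] <- 1; v[12801:13000] <- 2
  df <- pas_tss_ratio(make_track(v), ratio_genes)
  expect_equal(df$gene_id, "G2")
  expect_equal(attr(df, "n_excluded"), 1)
  dfp <- pas_tss_ratio(make_track(v), ratio_genes, pseudocount = 1)
  expect_equal(nrow(dfp), 2)
})

test_that("swapping the two windows negates every ratio", {
  set.seed(31)
  v <- rpois(20000, 1) + 1
  t <- make_track(v)
  fwd <- pas_tss_ratio(t, ratio_genes)
  flipped <- ratio_genes
  strand(flipped) <- "-"   # flips which end is TSS/PAS, i.e. swaps windows
  flipped <- termwin:::set_tss_pas(flipped)
  rev_ <- pas_tss_ratio(t, flipped)
  expect_equal(rev_$log2_ratio, -fwd$log2_ratio)
})

test_that("ratio sign tracks where the signal sits along the gene", {
  set.seed(32)
  n <- 10
  starts <- seq(1001, by = 15000, length.out = n)
  genes <- mk_genes2(data.frame(contig = "chrT", start = starts,
                                end = starts + 4000, strand = "+",
                                gene_id = sprintf("G%02d", 1:n)))
  end_heavy <- numeric(160000); tss_heavy <- numeric(160000)
  for (s in starts) {
    body <- rpois(4001, 0.2)
    end_heavy[s:(s + 4000)] <- body
    tss_heavy[s:(s + 4000)] <- body
    end_heavy[(s + 3801):(s + 4000)] <- rpois(200, 3)   # 3' -end block
    tss_heavy[s:(s + 199)] <- rpois(200, 3)             # 5' peak
  }
  expect_gt(median(pas_tss_ratio(make_track(end_heavy), genes)$log2_ratio), 0)
  expect_lt(median(pas_tss_ratio(make_track(tss_heavy), genes)$log2_ratio), 0)
})

test_that("activity grouping is equal-sized, monotone and deterministic", {
  n <- 12
  starts <- seq(1001, by = 15000, length.out = n)
  genes <- mk_genes2(data.frame(contig = "chrT", start = starts,
                                end = starts + 2000, strand = "+",
                                gene_id = sprintf("G%02d", 1:n)))
  v <- numeric(200000)
  for (i in seq_len(n)) v[starts[i]:(starts[i] + 2000)] <- i  # activity = i
  g <- activity_groups(make_track(v), genes, n_groups = 5)
  expect_equal(length(g$dropped_ids), 2)          # 12 mod 5
  expect_equal(g$dropped_ids, c("G01", "G02"))    # least active dropped
  expect_equal(as.vector(table(g$assignment$group)), rep(2L, 5))
  # monotone: each group's signals dominate the previous group's
  agg <- tapply(g$assignment$mean_signal, g$assignment$group, max)
  agg_min <- tapply(g$assignment$mean_signal, g$assignment$group, min)
  expect_true(all(agg_min[-1] >= agg[-5]))
  # 10 genes in 5 groups: none dropped
  g10 <- activity_groups(make_track(v), genes[1:10], n_groups = 5)
  expect_length(g10$dropped_ids, 0)
  expect_error(activity_groups(make_track(v), genes[1:3], n_groups = 5),
               "at least 5")
})

test_that("tied activities resolve stably by gene id across runs", {
  n <- 10
  starts <- seq(1001, by = 15000, length.out = n)
  genes <- mk_genes2(data.frame(contig = "chrT", start = starts,
                                end = starts + 2000, strand = "+",
                                gene_id = sprintf("G%02d", 1:n)))
  t <- make_track(rep(1, 160000))   # every gene identical
  g1 <- activity_groups(t, genes, n_groups = 5)
  g2 <- activity_groups(t, genes, n_groups = 5)
  expect_identical(g1$assignment, g2$assignment)
  expect_equal(g1$assignment$gene_id, sort(genes$gene_id))
})

test_that("group profiles order by activity and respect identical input", {
  n <- 10
  starts <- seq(1001, by = 20000, length.out = n)
  genes <- mk_genes2(data.frame(contig = "chrT", start = starts,
                                end = starts + 2000, strand = "+",
                                gene_id = sprintf("G%02d", 1:n)))
  v <- numeric(250000)
  for (i in seq_len(n)) v[starts[i]:(starts[i] + 7000)] <- i
  t <- make_track(v)
  g <- activity_groups(t, genes, n_groups = 5)
  profs <- group_profiles(t, g, genes, n_body_bins = 20, flank_bp = 0)
  integrals <- vapply(profs, function(p) sum(p$profile), numeric(1))
  expect_equal(which.max(integrals), 5L, ignore_attr = TRUE)
  expect_true(all(diff(integrals) > 0))
  # identical signal for every gene: identical group profiles
  tflat <- make_track(rep(2, 250000))
  gflat <- activity_groups(tflat, genes, n_groups = 5)
  pflat <- group_profiles(tflat, gflat, genes, n_body_bins = 20,
                          flank_bp = 0)
  for (k in 2:5) expect_equal(pflat[[k]]$profile, pflat[[1]]$profile)
})
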