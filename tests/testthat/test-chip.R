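# two-gene toy genome at 1 bp bins: a + strand gene and its mirror
# image on the - strand, with a 5' promoter block of elevated coverage
toy_tracks <- function(promoter_height = 8, background = 2,
                       chrom_len = 3000, gene_start = 1000,
                       gene_len = 1000) {
  v <- rep(background, chrom_len)
  v[(gene_start - 500):(gene_start - 1) + 1] <- promoter_height
  plus <- coverage_track(list(chr1 = v), 1, total_mapped_reads = sum(v))
  minus <- coverage_track(list(chr1 = rev(v)), 1,
                          total_mapped_reads = sum(v))
  flat <- coverage_track(list(chr1 = rep(background, chrom_len)), 1,
                         total_mapped_reads = background * chrom_len)
  ann_plus <- gene_annotation(data.frame(
    gene_id = "g1", chrom = "chr1", tss = gene_start,
    tes = gene_start + gene_len, strand = "+",
    class_label = "class_II"))
  ann_minus <- gene_annotation(data.frame(
    gene_id = "g1", chrom = "chr1", tss = chrom_len - gene_start,
    tes = chrom_len - gene_start - gene_len, strand = "-",
    class_label = "class_II"))
  list(plus = plus, minus = minus, flat = flat,
       ann_plus = ann_plus, ann_minus = ann_minus)
}

test_that("rpkm is definitional and scale invariant", {
  tr <- coverage_track(list(chr1 = rep(1, 1000)), 1,
                       total_mapped_reads = 1e6)
  # 100 reads in a 1 kb interval at 1e6 depth -> RPKM 100
  expect_equal(rpkm(coverage_track(list(chr1 = rep(0.1, 1000)), 1,
                                   total_mapped_reads = 1e6),
                    "chr1", 0, 1000), 100)
  # empty interval -> 0
  tr0 <- coverage_track(list(chr1 = c(rep(0, 500), rep(2, 500))), 1,
                        total_mapped_reads = 1000)
  expect_equal(rpkm(tr0, "chr1", 0, 500), 0)
  # doubling counts and total leaves RPKM unchanged
  tr2 <- coverage_track(list(chr1 = rep(2, 1000)), 1,
                        total_mapped_reads = 2e6)
  expect_equal(rpkm(tr, "chr1", 100, 600), rpkm(tr2, "chr1", 100, 600))
  expect_warning(rpkm(tr, "chr1", -50, 100), "clipped")
})

test_that("normalized density is 1 for identical tracks and guards zeros", {
  a <- coverage_track(list(chr1 = rep(3, 500)), 1, 1500)
  expect_equal(normalized_density(a, a, "chr1", 0, 500)$ratio, 1)
  zin <- coverage_track(list(chr1 = rep(0, 500)), 1, 1500)
  expect_error(normalized_density(a, zin, "chr1", 0, 500), "pseudocount")
  nd <- normalized_density(a, zin, "chr1", 0, 500, pseudocount = 0.5)
  expect_true(is.finite(nd$ratio))
  expect_true(nd$degenerate)
  b <- coverage_track(list(chr1 = rep(3, 400)), 1, 1200)
  expect_error(normalized_density(a, b, "chr1", 0, 100), "grids")
})

test_that("pseudocount vanishes in the limit for positive counts", {
  a <- coverage_track(list(chr1 = rep(6, 500)), 1, 3000)
  b <- coverage_track(list(chr1 = rep(2, 500)), 1, 1000)
  raw <- normalized_density(a, b, "chr1", 0, 500)$ratio
  for (pc in c(0.5, 0.05, 0.005)) {
    shrunk <- normalized_density(a, b, "chr1", 0, 500, pseudocount = pc)
    expect_lt(abs(shrunk$ratio - raw), abs(
      normalized_density(a, b, "chr1", 0, 500,
                         pseudocount = pc * 10)$ratio - raw) + 1e-12)
  }
  expect_equal(normalized_density(a, b, "chr1", 0, 500,
                                  pseudocount = 1e-9)$ratio,
               raw, tolerance = 1e-6)
})

test_that("metagene is flat for uniform coverage and strand symmetric", {
  toy <- toy_tracks(promoter_height = 2)   # uniform everywhere
  mg <- metagene(toy$plus, control = NULL, toy$ann_plus,
                 body_bins = 100, flank_bin_bp = 10)
  prof <- mg$matrix[1L, ]
  expect_equal(ncol(mg$matrix), 50 + 100 + 50)
  expect_true(all(abs(prof - prof[1L]) < 1e-9))

  # mirrored genome with flipped strand gives the identical profile
  toy8 <- toy_tracks(promoter_height = 8)
  mp <- metagene(toy8$plus, NULL, toy8$ann_plus)$matrix[1L, ]
  mm <- metagene(toy8$minus, NULL, toy8$ann_minus)$matrix[1L, ]
  expect_equal(unname(mp), unname(mm))
  # the promoter block sits in the upstream segment on both strands
  expect_gt(mean(mp[1:50]) / mean(mp[51:150]), 3.9)
})

test_that("metagene ratio mode recovers configured promoter enrichment", {
  g <- gen_genome_coverage(generator_config(seed = 7, depth = 1e6),
                           c(class_II = 8))
  ann2 <- g$annotations[g$annotations$class_label == "class_II", ]
  mg <- metagene(g$target, g$control, ann2)
  s <- mg$summary$mean
  up <- mean(s[1:50])
  body <- mean(s[51:150])
  expect_equal(log2(up), 3, tolerance = 0.15 / 3)   # promoter peak ~8x
  expect_equal(body, 1, tolerance = 0.1)
  expect_true(which.max(s) <= 50)                   # peak before the TSS

  short <- gene_annotation(data.frame(
    gene_id = "tiny", chrom = "chr1", tss = 1000, tes = 1050,
    strand = "+", class_label = "other"))
  expect_error(suppressWarnings(metagene(g$target, g$control, short)),
               "filtered out")
})

test_that("promoter enrichment is zero for equal tracks and flags clipping", {
  toy <- toy_tracks()
  pe <- promoter_enrichment(toy$plus, toy$plus, toy$ann_plus,
                            pseudocount = 0.5)
  expect_equal(pe$log2_ratio, 0)
  expect_false(pe$clipped)

  near_edge <- gene_annotation(data.frame(
    gene_id = "edge", chrom = "chr1", tss = 200, tes = 900,
    strand = "+", class_label = "other"))
  pe2 <- promoter_enrichment(toy$flat, toy$flat, near_edge)
  expect_true(pe2$clipped)
})

test_that("promoter enrichment recovers class truth and survives rescaling", {
  g <- gen_genome_coverage(generator_config(seed = 11, depth = 1e6),
                           c(class_II = 4))
  pe <- promoter_enrichment(g$target, g$control, g$annotations)
  m2 <- mean(pe$log2_ratio[pe$class_label == "class_II"])
  m_other <- mean(pe$log2_ratio[pe$class_label != "class_II"])
  expect_equal(m2, 2, tolerance = 0.1 / 2)
  expect_lt(abs(m_other), 0.1)

  # library-size invariance: scale the control track by 3
  scaled <- coverage_track(lapply(g$control$counts, function(v) v * 3),
                           g$control$bin_size,
                           g$control$total_mapped_reads * 3)
  pe_s <- promoter_enrichment(g$target, scaled, g$annotations)
  expect_equal(pe$log2_ratio, pe_s$log2_ratio, tolerance = 1e-12)
})

test_that("class comparison separates shifted classes and needs n >= 2", {
  # analytic oracle: Welch t on known normals, mean 2 vs 0, sd 0.5, n 50
  set.seed(42)
  xa <- stats::rnorm(50, 2, 0.5)
  xb <- stats::rnorm(50, 0, 0.5)
  enr <- data.frame(
    gene_id = sprintf("g%02d", 1:100),
    log2_ratio = c(xa, xb),
    class_label = rep(c("class_II", "class_I"), each = 50))
  cc <- class_compare(enr, "class_II", "class_I")
  expect_lt(cc$p_value, 1e-10)
  expect_equal(cc$difference, 2, tolerance = 0.2 / 2)
  # hand-computed Welch statistic
  se <- sqrt(stats::var(xa) / 50 + stats::var(xb) / 50)
  expect_equal(cc$t_statistic, (mean(xa) - mean(xb)) / se,
               tolerance = 1e-12)
  expect_equal(nrow(cc$ecdf), 100)
  expect_equal(max(cc$ecdf$cum_fraction), 1)

  ident <- data.frame(gene_id = sprintf("g%d", 1:20),
                      log2_ratio = rep(c(0.1, 0.3, -0.2, 0.4, 0), 4),
                      class_label = rep(c("a", "b"), each = 10))
  cc2 <- class_compare(ident, "a", "b")
  expect_equal(cc2$difference, 0, tolerance = 1e-12)
  expect_gt(cc2$p_value, 0.99)

  single <- data.frame(gene_id = c("g1", "g2", "g3"),
                       log2_ratio = c(1, 0, 0.5),
                       class_label = c("a", "b", "b"))
  expect_error(class_compare(single, "a", "b"), ">= 2 genes")
})

test_that("bedGraph and BED6 round-trip through files", {
  g <- gen_genome_coverage(
    generator_config(seed = 5, depth = 2e4,
                     genome_spec = list(n_chroms = 1L, n_genes = 6L,
                                        gene_length = c(600L, 1200L),
                                        class_props = c(class_I = 0.5,
                                                        class_II = 0.5),
                                        bin_size = 10L)),
    c(class_II = 8))
  bg <- file.path(tempdir(), "target.bedGraph")
  write_bedgraph_track(g$target, bg)
  rt <- read_bedgraph_track(bg, total_mapped_reads =
                              g$target$total_mapped_reads)
  expect_equal(rt$bin_size, g$target$bin_size)
  n <- length(rt$counts$chr1)
  expect_equal(rt$counts$chr1, g$target$counts$chr1[seq_len(n)])
  # trailing zero bins are not written; all retained bins match
  expect_true(all(g$target$counts$chr1[-seq_len(n)] == 0))

  bed <- file.path(tempdir(), "genes.bed")
  cls <- file.path(tempdir(), "classes.tsv")
  write_bed6_annotation(g$annotations, bed)
  utils::write.table(g$annotations[, c("gene_id", "class_label")], cls,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_bed6_annotation(bed, class_table = cls)
  ord <- match(g$annotations$gene_id, ann$gene_id)
  expect_equal(ann$tss[ord], g$annotations$tss)
  expect_equal(ann$tes[ord], g$annotations$tes)
  expect_equal(ann$strand[ord], g$annotations$strand)
  expect_equal(ann$class_label[ord], g$annotations$class_label)
})
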