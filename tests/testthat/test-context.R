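# CpG island/shore/shelf/ocean and exon/intron/intergenic partitions,
# bp-level composition, chi-square, nearest genes and overlap fractions.

test_that("single-island partition follows the 2 kb shore/shelf rule", {
  chroms <- c(chr1 = 1e5)
  ctx <- build_cpg_context(intervals("chr1", 1000, 2000), chroms)
  expect_equal(ctx$island, intervals("chr1", 1000, 2000))
  # left shore truncated at the chromosome start
  expect_equal(ctx$shore, intervals("chr1", c(0, 2000), c(1000, 4000)))
  expect_equal(ctx$shelf, intervals("chr1", 4000, 6000))
  expect_equal(ctx$ocean, intervals("chr1", 6000, 1e5))
})

test_that("island precedence and degenerate island sets", {
  chroms <- c(chr1 = 1e5)
  # two islands 1000 bp apart: the gap is entirely shore
  ctx <- build_cpg_context(intervals("chr1", c(10000, 12000),
                                     c(11000, 13000)), chroms)
  gap <- intersect_intervals(intervals("chr1", 11000, 12000), ctx$shore)
  expect_equal(sum(gap$end - gap$start), 1000)
  # no islands: the whole genome is ocean
  ctx0 <- build_cpg_context(intervals(), chroms)
  expect_equal(ctx0$ocean, intervals("chr1", 0, 1e5))
  expect_equal(nrow(ctx0$shore), 0)
  # out-of-bounds island errors
  expect_error(build_cpg_context(intervals("chr1", 99000, 101000), chroms),
               "bounds")
})

test_that("context partitions cover every bp exactly once", {
  set.seed(5)
  chroms <- c(chr1 = 5e4, chr2 = 3e4)
  st <- sort(sample(0:45000, 6))
  islands <- intervals(c(rep("chr1", 4), "chr2", "chr2"),
                       st[c(1, 3, 5, 6, 2, 4)] %/% 2,
                       st[c(1, 3, 5, 6, 2, 4)] %/% 2 + 800)
  ctx <- build_cpg_context(islands, chroms)
  total <- sum(vapply(ctx, dmrevert:::interval_bp, 0))
  expect_equal(total, sum(chroms))
  for (a in 1:3) for (b in (a + 1):4)
    expect_equal(nrow(intersect_intervals(ctx[[a]], ctx[[b]])), 0)
})

test_that("bp composition matches the per-bp labeling oracle", {
  L <- 1e4
  chroms <- c(chr1 = L)
  islands <- intervals("chr1", c(1200, 4600), c(1700, 5100))
  ctx <- build_cpg_context(islands, chroms, flank = 2000)
  comp <- annotate_region_context(intervals("chr1", 0, L), ctx)
  lab <- oracle_cpg_labels(islands, L, flank = 2000)
  for (cat in comp$category)
    expect_equal(comp$bp[comp$category == cat], sum(lab == cat),
                 info = cat)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)

  genes <- data.frame(id = c("g1", "g2"), chrom = "chr1",
                      start = c(2000, 6000), end = c(4000, 9000))
  exons <- data.frame(chrom = "chr1", start = c(2000, 3500, 6000),
                      end = c(2500, 4000, 7000))
  gctx <- build_gene_context(genes, exons, chroms)
  gcomp <- annotate_region_context(intervals("chr1", 0, L), gctx)
  glab <- oracle_gene_labels(genes, exons, L)
  for (cat in gcomp$category)
    expect_equal(gcomp$bp[gcomp$category == cat], sum(glab == cat),
                 info = cat)
})

test_that("region composition resolves fractions and is additive", {
  chroms <- c(chr1 = 1e5)
  ctx <- build_cpg_context(intervals("chr1", 1000, 2000), chroms)
  inside <- annotate_region_context(intervals("chr1", 1200, 1800), ctx)
  expect_equal(inside$fraction[inside$category == "island"], 1)
  straddle <- annotate_region_context(intervals("chr1", 1500, 2500), ctx)
  expect_equal(straddle$fraction[straddle$category == "island"], 0.5)
  expect_equal(straddle$fraction[straddle$category == "shore"], 0.5)
  # composition of a union of disjoint regions = sum of compositions
  a <- intervals("chr1", 0, 3000); b <- intervals("chr1", 5000, 8000)
  ca <- annotate_region_context(a, ctx)
  cb <- annotate_region_context(b, ctx)
  cu <- annotate_region_context(rbind(a, b), ctx)
  expect_equal(cu$bp, ca$bp + cb$bp)
})

test_that("composition chi-square matches the closed form", {
  obs <- data.frame(category = c("a", "b"), bp = c(90, 10),
                    fraction = c(0.9, 0.1))
  bg <- data.frame(category = c("a", "b"), bp = c(500, 500),
                   fraction = c(0.5, 0.5))
  r <- composition_chisq(obs, bg)
  expect_equal(r$statistic, 64)
  expect_equal(r$df, 1)
  expect_equal(r$statistic,
               unname(stats::chisq.test(c(90, 10),
                                        p = c(0.5, 0.5))$statistic))
  # identical proportions: statistic 0, p = 1
  obs2 <- data.frame(category = c("a", "b"), bp = c(50, 50))
  r2 <- composition_chisq(obs2, bg)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(composition_chisq(
    data.frame(category = "a", bp = 0), bg), "zero")
})

test_that("nearest flanking genes by TSS with ties and edge cases", {
  genes <- data.frame(id = c("gL", "gR"), chrom = "chr1",
                      tss = c(9000, 15000))
  region <- intervals("chr1", 10000, 10001)
  nf <- nearest_flanking_genes(region, genes)
  expect_equal(nf$gene_id, c("gL", "gR"))
  expect_equal(nf$distance, c(1000, 5000))
  # TSS inside the region: distance 0
  nf2 <- nearest_flanking_genes(intervals("chr1", 8000, 9500), genes)
  expect_equal(nf2$distance[1], 0)
  expect_equal(nf2$gene_id[1], "gL")
  # single-gene chromosome: one side empty-flagged
  nf3 <- nearest_flanking_genes(intervals("chr1", 100, 200),
                                genes[1, , drop = FALSE])
  expect_false(nf3$empty[2]); expect_true(is.na(nf3$gene_id[1]))
  # no genes on the chromosome at all
  nf4 <- nearest_flanking_genes(intervals("chr2", 100, 200), genes)
  expect_true(all(nf4$empty))
  # tie-break: two TSS at equal distance -> lower coordinate first
  g2 <- data.frame(id = c("b", "a"), chrom = "chr1", tss = c(500, 500))
  nf5 <- nearest_flanking_genes(intervals("chr1", 1000, 1100), g2)
  expect_equal(nf5$gene_id[1], "a")
})

test_that("expression-change labels use strict threshold inequalities", {
  expect_equal(label_expression_change(1.5), "up")
  expect_equal(label_expression_change(-2), "down")
  expect_equal(label_expression_change(0.99), "neutral")
  expect_equal(label_expression_change(c(1, -1)), c("neutral", "neutral"))
})

test_that("overlap fraction counts each region once, half-open", {
  feats <- intervals("chr1", c(100, 500), c(200, 600))
  inside <- intervals("chr1", c(120, 510, 150), c(180, 590, 160))
  expect_equal(overlap_fraction(inside, feats), 1)
  expect_equal(overlap_fraction(inside, intervals()), 0)
  # shared endpoint is not an overlap
  expect_equal(overlap_fraction(intervals("chr1", 200, 300), feats), 0)
  set.seed(9)
  regions <- intervals(sample(c("chr1", "chr2"), 40, TRUE),
                       s <- sample(0:5000, 40), s + sample(50:500, 40, TRUE))
  f2 <- intervals(sample(c("chr1", "chr2"), 15, TRUE),
                  fs <- sample(0:5000, 15), fs + sample(50:400, 15, TRUE))
  expect_equal(overlap_fraction(regions, f2),
               oracle_overlap_fraction(regions, f2))
})
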