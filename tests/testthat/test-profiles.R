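# One-gene annotation helper with a configurable span and strand.
one_gene_ann <- function(start, end, strand = "+", clen = 100000) {
  genome_annotation(
    data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
               start = start, end = end),
    data.frame(gene_id = "g1", chrom = "chr1", start = start, end = end),
    c(chr1 = clen))
}

test_that("constant track gives a constant metagene row", {
  ann <- one_gene_ann(10001, 12000)
  tr <- data.frame(chrom = "chr1", start = 0, end = 100000, value = 1)
  m <- metagene_matrix(tr, ann, body = 1000, flank = 500, bin_size = 50)
  expect_equal(ncol(m), 40L)
  expect_true(all(m == 1))
})

test_that("body scaling follows the per-base pre-image rule (hand oracle)", {
  # gene of 4 bp with per-base values {1,1,3,3}, body scaled to 4 with
  # 2-bp bins and 2-bp flanks of zero signal -> body bins {1, 3}
  ann <- one_gene_ann(11, 14, clen = 1000)
  tr <- data.frame(chrom = "chr1", start = c(10, 12), end = c(12, 14),
                   value = c(1, 3))
  m <- metagene_matrix(tr, ann, body = 4, flank = 2, bin_size = 2)
  expect_equal(as.vector(m), c(0, 1, 3, 0))
})

test_that("reversing strand and mirroring the signal leaves the profile row unchanged", {
  start <- 5001; end <- 6404   # length 1404, not a bin multiple
  ann_p <- one_gene_ann(start, end, "+")
  set.seed(31)
  # random step track over the window, then its mirror image
  s <- seq(2000, 9400, by = 100)
  v <- runif(length(s), 0, 5)
  tr <- data.frame(chrom = "chr1", start = s, end = s + 100, value = v)
  centre <- start - 1 + end    # mirror: pos' = centre - pos (0-based)
  trm <- data.frame(chrom = "chr1", start = centre - (s + 100),
                    end = centre - s, value = v)
  trm <- trm[order(trm$start), ]
  ann_m <- one_gene_ann(start, end, "-")
  mp <- metagene_matrix(tr, ann_p, body = 1000, flank = 500, bin_size = 50)
  mm <- metagene_matrix(trm, ann_m, body = 1000, flank = 500, bin_size = 50)
  expect_equal(as.vector(mm), as.vector(mp), tolerance = 1e-12)
})

test_that("metagene body bins are invariant to uniform translation", {
  set.seed(33)
  s <- seq(0, 30000, by = 200)
  v <- runif(length(s), 0, 3)
  tr <- data.frame(chrom = "chr1", start = s, end = s + 200, value = v)
  shift <- 10000
  tr2 <- data.frame(chrom = "chr1", start = s + shift, end = s + 200 + shift, value = v)
  a1 <- one_gene_ann(8001, 9500)
  a2 <- one_gene_ann(8001 + shift, 9500 + shift)
  m1 <- metagene_matrix(tr, a1, body = 1000, flank = 500, bin_size = 50)
  m2 <- metagene_matrix(tr2, a2, body = 1000, flank = 500, bin_size = 50)
  expect_equal(as.vector(m1), as.vector(m2))
})

test_that("methylation metagene averages covered CpGs per bin, NA when none", {
  ann <- one_gene_ann(1001, 2000, clen = 10000)
  calls <- toy_calls(c(1010, 1020, 1950, 510), c(10, 30, 80, 5))
  m <- metagene_matrix(calls, ann, body = 1000, flank = 500, bin_size = 100)
  # upstream: CpG at 510 sits in the first flank bin (window starts at 501)
  expect_equal(unname(m[1, 1]), 5)
  # first body bin holds CpGs 1010 and 1020
  expect_equal(unname(m[1, 6]), 20)
  expect_equal(unname(m[1, 15]), 80)
  expect_true(is.na(m[1, 2]))
})

test_that("anchored profiles are strand-aware and flag off-chromosome bins", {
  ann <- one_gene_ann(2001, 4000)
  tr <- data.frame(chrom = "chr1", start = 1900, end = 2100, value = 2)
  m <- anchored_profile(tr, ann, anchor = "TSS", flank = 500, bin_size = 100)
  expect_equal(ncol(m), 10L)
  # symmetric bump around the TSS gives a symmetric profile
  expect_equal(as.vector(m), rev(as.vector(m)))
  expect_gt(m[1, 5], m[1, 2])

  # minus-strand gene: TSS is the genomic end; same window, mirrored
  ann_m <- one_gene_ann(2001, 4000, "-")
  trm <- data.frame(chrom = "chr1", start = 3900, end = 4100, value = 2)
  mm <- anchored_profile(trm, ann_m, anchor = "TSS", flank = 500, bin_size = 100)
  expect_equal(as.vector(mm), as.vector(m))

  # anchor close to the chromosome start: left bins missing
  ann_edge <- one_gene_ann(201, 1200)
  me <- anchored_profile(tr, ann_edge, anchor = "TSS", flank = 500, bin_size = 100)
  expect_true(all(is.na(me[1, 1:3])))
  expect_false(anyNA(me[1, 4:10]))
})

test_that("set mean profile averages rows, ignoring missing cells", {
  mat <- rbind(g1 = c(1, 2, NA), g2 = c(3, -2, 4))
  pr <- set_mean_profile(mat)
  expect_equal(pr$mean, c(2, 0, 4))
  expect_equal(pr$n, c(2L, 2L, 1L))
  # one gene: its own row
  pr1 <- set_mean_profile(mat, "g1")
  expect_equal(pr1$mean, c(1, 2, NA))
  expect_equal(pr1$n, c(1L, 1L, 0L))
})

test_that("segment profile indexes exons/introns in transcription order", {
  ann <- toy_annotation()
  # gB is minus strand: E1 = [1401,1500]; plant E1 low, E2/E3 high
  calls <- toy_calls(c(1410, 1450, 1490,   1210, 1250, 1290,  1010, 1050, 1090,
                       1320, 1350, 1380,   1110, 1150, 1190),
                     c(0, 0, 0,            40, 40, 40,          40, 40, 40,
                       20, 20, 20,         30, 30, 30))
  sp <- segment_profile(calls, ann, gene_set = "gB", flank = 500, min_cpgs = 3)
  expect_equal(sp$mean_level[sp$segment == "E1"], 0)
  expect_equal(sp$mean_level[sp$segment == "E2"], 40)
  expect_equal(sp$mean_level[sp$segment == "E3"], 40)
  # introns in transcription order: I1 = [1301,1400] on the minus strand
  expect_equal(sp$mean_level[sp$segment == "I1"], 20)
  expect_equal(sp$mean_level[sp$segment == "I2"], 30)
  # segments beyond the gene's structure contribute nothing
  expect_equal(sp$n_genes[sp$segment == "E4"], 0L)
  sp3 <- segment_profile(calls, ann, gene_set = "gC", flank = 500)
  expect_equal(sp3$n_genes[sp3$segment == "E2"], 0L)
})
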