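test_that("per-CpG calling applies the coverage filter and level formula", {
  rec <- cpg_records(c(10, 20, 30), c(3, 1, 0), c(2, 3, 50))
  calls <- call_cpg_levels(rec, min_coverage = 5)
  # (3,2) -> 60% at coverage 5; (1,3) dropped at coverage 4; (0,50) -> 0%
  expect_equal(calls$pos, c(10, 30))
  expect_equal(calls$level, c(60, 0))
  expect_equal(calls$coverage, c(5, 50))
  expect_error(call_cpg_levels(cpg_records(1, -1, 3)), "negative")
})

test_that("raising min_coverage never increases the number of calls", {
  set.seed(42)
  rec <- cpg_records(1:300, rpois(300, 4), rpois(300, 4))
  n_prev <- Inf
  for (mc in c(1, 3, 5, 8, 12)) {
    n <- nrow(call_cpg_levels(rec, mc))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("conversion efficiency pools control cytosines", {
  expect_equal(conversion_efficiency(cpg_records(1:10, 0, rep(100, 10))), 100)
  # 77 methylated calls in 10,000 reads -> 99.23
  expect_equal(conversion_efficiency(cpg_records(1:2, c(50, 27), c(4950, 4973))),
               99.23)
  expect_equal(conversion_efficiency(cpg_records(1, 10, 0)), 0)
  expect_true(is.na(conversion_efficiency(cpg_records(1, 0, 0))))
})

test_that("feature methylation averages covered CpGs with the >=3 support rule", {
  feats <- data.frame(feature_id = c("f1", "f2", "f3"), chrom = "chr1",
                      start = c(1, 100, 200), end = c(50, 150, 250))
  calls <- toy_calls(c(10, 20, 30, 110, 120), c(0, 50, 100, 10, 20))
  fm <- feature_methylation(calls, feats, min_cpgs = 3)
  expect_equal(fm$mean_level[1], 50)          # {0,50,100}
  expect_true(is.na(fm$mean_level[2]))        # 2 CpGs < 3
  expect_false(fm$defined[2])
  expect_true(is.na(fm$mean_level[3]))        # empty feature
  expect_equal(fm$n_cpgs, c(3L, 2L, 0L))
})

test_that("feature mean is permutation-invariant and satisfies the partition identity", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(6:30, 1)
    pos <- sort(sample(1:1000, n))
    lv <- runif(n, 0, 100)
    feat <- data.frame(feature_id = "f", chrom = "chr1", start = 1, end = 1000)
    fm1 <- feature_methylation(toy_calls(pos, lv), feat)
    shuf <- sample(n)
    fm2 <- feature_methylation(toy_calls(pos[shuf], lv[shuf]), feat)
    expect_equal(fm1$mean_level, fm2$mean_level)

    # split the feature at a random point: CpG-count-weighted mean of the
    # part means equals the whole-feature mean
    cut <- sample(pos[-n], 1)
    parts <- data.frame(feature_id = c("l", "r"), chrom = "chr1",
                        start = c(1, cut + 1), end = c(cut, 1000))
    pm <- feature_methylation(toy_calls(pos, lv), parts, min_cpgs = 0)
    expect_equal(sum(pm$n_cpgs * pm$mean_level) / sum(pm$n_cpgs),
                 fm1$mean_level)
  }
})

test_that("consolidated gene set requires definition in every sample", {
  make_tab <- function(n_cpgs) {
    data.frame(feature_id = c("g1", "g2", "g3"), n_cpgs = n_cpgs,
               mean_level = ifelse(n_cpgs >= 3, 10, NA), defined = n_cpgs >= 3)
  }
  tabs <- list(make_tab(c(5, 2, 4)), make_tab(c(3, 6, 4)))
  expect_equal(consolidated_gene_set(tabs), c("g1", "g3"))
  # all defined -> identity on the universe
  tabs2 <- list(make_tab(c(5, 5, 4)), make_tab(c(3, 6, 4)))
  expect_equal(consolidated_gene_set(tabs2), c("g1", "g2", "g3"))
  # mismatched universes rejected
  bad <- make_tab(c(3, 3, 3)); bad$feature_id <- c("g1", "g2", "gX")
  expect_error(consolidated_gene_set(list(tabs[[1]], bad)), "mismatched")
})

test_that("methylation status uses a strict below-threshold rule", {
  expect_equal(methylation_status(c(9.99, 10, 70.1, NA)),
               c("not methylated", "methylated", "methylated", NA))
})

test_that("region class summary partitions the genome with exon priority", {
  ann <- toy_annotation()
  # hand toy: exon CpGs {20,40}, intron {10}, intergenic {0,0}
  calls <- toy_calls(c(110, 320, 250, 700, 900), c(20, 40, 10, 0, 0))
  rs <- region_class_summary(calls, ann)
  cl <- rs$classes
  expect_equal(cl$mean_level[cl$class == "exon"], 30)
  expect_equal(cl$mean_level[cl$class == "intron"], 10)
  expect_equal(cl$mean_level[cl$class == "intergenic"], 0)
  expect_equal(cl$n_cpgs, c(2L, 1L, 2L))
  expect_equal(sum(cl$genome_fraction), 100)
  # exon bp: gA 100+100, gB 100+100+100, gC 300 = 800 of 5000
  expect_equal(cl$genome_fraction[cl$class == "exon"], 16)

  # genome-wide summaries: mean level and thresholded fraction
  expect_equal(unname(rs$genome["mean_cpg_level"]), mean(c(20, 40, 10, 0, 0)))
  expect_equal(unname(rs$genome["pct_cpgs_methylated"]), 60)  # {20,40,10} >= 10

  # all CpGs level zero -> all class means zero
  rs0 <- region_class_summary(toy_calls(c(110, 250, 700), c(0, 0, 0)), ann)
  expect_true(all(rs0$classes$mean_level[rs0$classes$n_cpgs > 0] == 0))
})

test_that("repeat overlay class reports its own mean and genome fraction", {
  ann <- toy_annotation()
  calls <- toy_calls(c(110, 700), c(30, 10))
  reps <- data.frame(chrom = "chr1", start = 600, end = 1099)
  rs <- region_class_summary(calls, ann, repeats = reps)
  rc <- rs$classes[rs$classes$class == "repeat", ]
  expect_equal(rc$mean_level, 10)
  expect_equal(rc$genome_fraction, 10)
})
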