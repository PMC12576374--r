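# Build a dmr_input directly for segmentation tests: sites at regular
# spacing with prescribed group means and no replicate noise.
make_input <- function(diffs, spacing = 50, base = 50, n_rep = 3) {
  n <- length(diffs)
  pos <- seq(100, by = spacing, length.out = n)
  samples <- c(lapply(seq_len(n_rep), function(r)
    cpg_records(pos, round(base / 10), round((100 - base) / 10))),
    lapply(seq_len(n_rep), function(r)
      cpg_records(pos, round((base + diffs) / 10), round((100 - base - diffs) / 10))))
  names(samples) <- c(paste0("embryo_", seq_len(n_rep)), paste0("adult_", seq_len(n_rep)))
  dmr_input_filter(samples, rep(c("embryo", "adult"), each = n_rep),
                   min_cov = 5, max_cov = 100)
}

test_that("input filter applies the inclusive coverage window in every sample", {
  s <- list(e1 = cpg_records(c(10, 20, 30), c(5, 50, 2), c(5, 51, 3)),
            e2 = cpg_records(c(10, 20, 30), c(3, 40, 4), c(2, 40, 4)),
            a1 = cpg_records(c(10, 20, 30), c(0, 60, 3), c(9, 40, 2)),
            a2 = cpg_records(c(10, 20, 30), c(1, 50, 5), c(4, 50, 0)))
  di <- dmr_input_filter(s, c("embryo", "embryo", "adult", "adult"))
  # pos 20: coverage 101 in e1 -> excluded; pos 30: coverage 5 kept
  expect_equal(di$sites$pos, c(10, 30))
  # coverage exactly 100 everywhere is retained
  s2 <- lapply(s, function(x) cpg_records(1, 50, 50))
  di2 <- dmr_input_filter(s2, c("embryo", "embryo", "adult", "adult"))
  expect_equal(nrow(di2$sites), 1L)
  expect_error(dmr_input_filter(s, rep("embryo", 4)), "two groups")
  # reference is the first-appearing group, not alphabetical order
  expect_equal(levels(di$groups), c("embryo", "adult"))
})

test_that("segmentation isolates uniform runs and splits at change points", {
  # uniform -30 over 15 CpGs: one candidate, no split improves
  di <- make_input(rep(-30, 15))
  cand <- segment_candidates(di)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_cpgs, 15L)
  expect_equal(cand$mean_diff, -30)

  # 15 x -30 then 15 x 0: split exactly at the boundary, one candidate
  di2 <- make_input(c(rep(-30, 15), rep(0, 15)))
  cand2 <- segment_candidates(di2)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$n_cpgs, 15L)
  expect_equal(cand2$mean_diff, -30)
  expect_equal(cand2$start, di2$sites$pos[1])
  expect_equal(cand2$end, di2$sites$pos[15])

  # exhaustive split-point oracle agrees on the chosen boundary
  d <- c(rep(-30, 15), rep(0, 15))
  best <- which.max(vapply(10:20, function(k)
    abs(mean(d[1:k]) - mean(d[(k + 1):30])), 0))
  expect_equal((10:20)[best], 15L)

  # a 9-CpG run yields no candidate
  expect_equal(nrow(segment_candidates(make_input(rep(-30, 9)))), 0L)

  # runs break at gaps > max_gap
  di3 <- make_input(rep(-30, 20), spacing = 400)
  expect_equal(nrow(segment_candidates(di3, max_gap = 300)), 0L)
})

test_that("DMR calls respect the region criteria and direction convention", {
  set.seed(5)
  n <- 40
  pos <- seq(100, by = 40, length.out = n)
  lv_e <- c(rep(50, 20), rep(50, 20))
  lv_a <- c(rep(20, 20), rep(50, 20))     # adult lower in first half
  noise <- function(lv) pmin(100, pmax(0, lv + rnorm(n, 0, 2)))
  samples <- c(lapply(1:3, function(r) {m <- round(noise(lv_e)); cpg_records(pos, m, 100 - m)}),
               lapply(1:3, function(r) {m <- round(noise(lv_a)); cpg_records(pos, m, 100 - m)}))
  names(samples) <- c(paste0("e", 1:3), paste0("a", 1:3))
  di <- dmr_input_filter(samples, rep(c("embryo", "adult"), each = 3))
  dmrs <- test_dmrs(segment_candidates(di), di)
  expect_gte(nrow(dmrs), 1L)
  expect_true(all(dmrs$n_cpgs >= 10))
  expect_true(all(abs(dmrs$mean_diff) >= 10))
  expect_true(all(dmrs$q_bh < 0.05))
  expect_true(all(dmrs$direction == ifelse(dmrs$mean_diff < 0, "hypo", "hyper")))
  expect_true(all(dmrs$direction == "hypo"))

  # swapping the reference group flips every sign and direction, p unchanged
  di_sw <- dmr_input_filter(samples[c(4:6, 1:3)],
                            rep(c("adult", "embryo"), each = 3))
  dmrs_sw <- test_dmrs(segment_candidates(di_sw), di_sw)
  expect_equal(dmrs_sw$mean_diff, -dmrs$mean_diff)
  expect_true(all(dmrs_sw$direction == "hyper"))
  expect_equal(dmrs_sw$p_raw, dmrs$p_raw, tolerance = 1e-12)
})

test_that("identical groups produce no DMRs and constant data gives p = 1", {
  di <- make_input(rep(0, 30))
  expect_equal(nrow(test_dmrs(segment_candidates(di), di)), 0L)
  # force a constant candidate through the tester
  cand <- data.frame(chrom = "chr1", start = 100, end = 200, n_cpgs = 10,
                     mean_diff = 0, i_from = 1, i_to = 10)
  di0 <- make_input(rep(0, 10))
  expect_equal(test_dmrs(cand, di0, alpha = 1.1, min_diff = 0)$p_raw, 1)
})

test_that("BH adjustment matches the brute-force formula", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("DMR feature annotation distinguishes the four classes", {
  ann <- toy_annotation()
  dmrs <- data.frame(
    chrom = "chr1",
    start = c(110, 210, 180, 700),
    end = c(150, 290, 250, 900),
    n_cpgs = 12, mean_diff = c(-20, -15, -30, 25),
    p_raw = 0.001, q_bh = 0.01,
    direction = c("hypo", "hypo", "hypo", "hyper"))
  res <- annotate_dmrs(dmrs, ann)
  expect_equal(res$dmrs$feature_class,
               c("exon_only", "intron_only", "exon_intron", "intergenic"))
  expect_equal(res$fractions["hypo", "pct_genic"], 100)
  expect_equal(res$fractions["hyper", "pct_intergenic"], 100)
  expect_equal(unname(dmr_accounting(dmrs)), c(4, 3, 1))
})
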