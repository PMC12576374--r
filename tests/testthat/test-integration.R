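test_that("four-way classification crosses the two binary statuses at their boundaries", {
  expect_equal(classify_four_sets(methylation_status(10.0), expression_status(1.01)),
               "methylated/expressed")
  expect_equal(classify_four_sets(methylation_status(9.9), expression_status(1.0)),
               "not methylated/not expressed")
  expect_true(is.na(classify_four_sets(NA, "expressed")))
})

test_that("transition accounting reconciles marginals and handles identity", {
  set.seed(3)
  n <- 500
  mk_status <- function() {
    gene_status_table(paste0("g", 1:n), runif(n, 0, 50), rlnorm(n, 0, 1))
  }
  for (i in 1:5) {
    e <- mk_status(); a <- mk_status()
    tr <- transition_counts(e, a)
    m <- tr$marginals
    expect_equal(sum(tr$flows), m[["n"]])
    expect_equal(sum(tr$flows_long$count), m[["n"]])
    # activations - inactivations = change in expressed count
    expect_equal(m[["expressed_adult"]] - m[["expressed_embryo"]],
                 m[["become_active"]] - m[["become_inactive"]])
    # same identity for methylation
    meth_e <- sum(e$meth_status == "methylated")
    meth_a <- sum(a$meth_status[match(e$gene_id, a$gene_id)] == "methylated")
    expect_equal(meth_a - meth_e, m[["gain_methylation"]] - m[["lose_methylation"]])
  }
  e <- mk_status()
  tr_id <- transition_counts(e, e)
  expect_equal(tr_id$marginals[["changers"]], 0)
  expect_equal(tr_id$percent[["maintain_methylation"]], 100)
})

test_that("genes with undefined status are excluded and reported", {
  e <- gene_status_table(c("g1", "g2", "g3"), c(20, NA, 5), c(2, 3, 0.5))
  a <- gene_status_table(c("g1", "g2", "g3"), c(20, 15, 5), c(2, 3, 2))
  tr <- transition_counts(e, a)
  expect_equal(tr$n_excluded, 1L)
  expect_equal(tr$marginals[["n"]], 2L)
})

test_that("category statistics report counts and length moments", {
  ann <- toy_annotation()   # lengths: gA 300, gB 500, gC 300
  st <- gene_status_table(c("gA", "gB", "gC"),
                          c(30, 30, 2), c(5, 8, 0.1))
  cs <- category_stats(st, ann)
  me <- cs[cs$category == "methylated/expressed", ]
  expect_equal(me$n_genes, 2L)
  expect_equal(me$mean_length, 400)
  expect_equal(me$sd_length, sd(c(300, 500)))
  single <- cs[cs$category == "not methylated/not expressed", ]
  expect_equal(single$mean_length, 300)
  expect_true(is.na(single$sd_length))
  empty <- cs[cs$category == "methylated/not expressed", ]
  expect_equal(empty$n_genes, 0L)
  expect_true(is.na(empty$mean_length))
})

test_that("methylation-expression regression: collinear, null and recovery cases", {
  # exactly collinear points give r^2 = 1
  lv <- seq(15, 60, length.out = 20)
  st <- gene_status_table(paste0("g", 1:20), lv, 10^(0.5 + 0.02 * lv))
  fit <- suppressWarnings(gbm_expression_regression(st))  # exact fit warns
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.02)
  expect_equal(fit$intercept, 0.5)

  # permuted response: slope ~ 0 at large n
  set.seed(9)
  n <- 4000
  lv <- runif(n, 12, 70)
  f <- 10^(1 + 0.015 * lv + rnorm(n, 0, 0.3))
  st2 <- gene_status_table(paste0("g", 1:n), lv, sample(f))
  fit2 <- gbm_expression_regression(st2)
  expect_lt(abs(fit2$slope), 0.002)
  expect_gt(fit2$p_value, 1e-4)

  # generating slope recovered within its standard error envelope
  st3 <- gene_status_table(paste0("g", 1:n), lv, f)
  fit3 <- gbm_expression_regression(st3)
  expect_equal(fit3$slope, 0.015, tolerance = 0.05)
  expect_lt(fit3$p_value, 1e-10)
})

test_that("hypergeometric overlap equals exhaustive draw enumeration", {
  # literal enumeration: all choose(10,4) draws of B against a fixed A
  A <- 1:5
  draws <- combn(10, 4)
  frac <- mean(apply(draws, 2, function(b) length(intersect(A, b)) >= 4))
  expect_equal(frac, 5 / 210)
  expect_equal(hyper_overlap_p(4, 5, 4, 10), 5 / 210)

  # sweep every configuration with universe <= 15 against the formula oracle
  for (N in c(3, 7, 11, 15)) {
    for (K in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 3)) {
        for (k in 0:min(K, n)) {
          expect_equal(hyper_overlap_p(k, K, n, N),
                       hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
        }
      }
    }
  }

  # trivial anchors
  expect_equal(hyper_overlap_p(0, 3, 4, 10), 1)          # P(X >= 0) = 1
  expect_equal(hyper_overlap_p(4, 10, 4, 10), 1)         # A = universe
})

test_that("DMR x DEG overlap table covers all direction pairs", {
  universe <- paste0("g", 1:100)
  dmr <- list(hypo = paste0("g", 1:20), hyper = paste0("g", 90:95))
  deg <- list(up = paste0("g", 15:40), down = paste0("g", 1:10))
  ov <- dmr_deg_overlap(dmr, deg, universe)
  expect_equal(nrow(ov), 4L)
  hd <- ov[ov$dmr_set == "hypo" & ov$deg_set == "down", ]
  expect_equal(hd$overlap, 10L)
  expect_equal(hd$p_enrich, hyper_tail_oracle(10, 20, 100, 10))
  # disjoint sets: P(X >= 0) = 1
  dj <- ov[ov$dmr_set == "hyper" & ov$deg_set == "down", ]
  expect_equal(dj$overlap, 0L)
  expect_equal(dj$p_enrich, 1)
})

test_that("methylation change profile bins by embryonic level", {
  e <- c(5, 15, 25, 55, 95)
  expect_true(all(methylation_change_profile(e, e)$mean_change %in% c(0, NA)))
  pr <- methylation_change_profile(e, e - 10)
  expect_true(all(pr$mean_change[pr$n_genes > 0] == -10))
  expect_equal(sum(pr$n_genes), 5L)
  expect_equal(pr$bin_low, seq(0, 90, 10))
})
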