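test_that("genome generation is deterministic, flanked and validated", {
  g1 <- generate_genome(30, seed = 5)
  g2 <- generate_genome(30, seed = 5)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$cpg_sites, g2$cpg_sites)
  g3 <- generate_genome(30, seed = 6)
  expect_false(identical(g1$cpg_sites$pos, g3$cpg_sites$pos))

  expect_error(generate_genome(0), "n_genes")
  expect_error(generate_genome(50, chrom_length = 1000), "too short")

  # every gene flanked by >= 3000 gene-free bp
  gn <- g1$annotation$genes
  expect_true(all(gn$start[-1] - gn$end[-nrow(gn)] > 3000))
  expect_gte(gn$start[1], 3001)
  expect_lte(gn$end[nrow(gn)] + 3000, g1$annotation$chrom_lengths[["chr1"]])

  # exons have higher CpG density than intergenic space
  rs <- region_class_summary(
    toy_calls(g1$cpg_sites$pos, 0), g1$annotation)$classes
  dens <- rs$n_cpgs / rs$genome_fraction
  expect_gt(dens[rs$class == "exon"], 3 * dens[rs$class == "intergenic"])
})

test_that("truth is category-consistent and respects configured rates", {
  genome <- generate_genome(300, seed = 8)
  truth <- simulate_truth(genome, seed = 9)
  tg <- truth$genes
  # 'not methylated' truth means expected level strictly below 10
  expect_true(all(tg$expected_meth_embryo[tg$meth_status_embryo == "not methylated"] < 10))
  expect_true(all(tg$expected_meth_embryo[tg$meth_status_embryo == "methylated"] >= 10))
  expect_true(all(tg$category_embryo == paste(tg$meth_status_embryo,
                                              tg$expr_status_embryo, sep = "/")))
  # planted DMRs sit inside methylated host genes with the stated effect
  expect_true(all(truth$dmrs$direction == "hypo"))
  expect_true(all(truth$dmrs$gene_id %in% tg$gene_id[tg$meth_status_embryo == "methylated"]))
  # marginal expressed fraction near the configured 36.5%
  expect_equal(mean(tg$expr_status_embryo == "expressed"), 0.365, tolerance = 0.25)
})

test_that("spike-in controls carry their truth; conversion failure adds false calls", {
  genome <- generate_genome(20, seed = 2)
  truth0 <- simulate_truth(genome, seed = 3, conversion_failure = 0)
  meth0 <- simulate_methylome(genome, truth0, n_replicates = 1, seed = 4)
  lam <- meth0$embryo_1[meth0$embryo_1$chrom == "Lambda", ]
  expect_true(all(lam$count_meth == 0))
  puc <- meth0$embryo_1[meth0$embryo_1$chrom == "pUC19", ]
  expect_true(all(puc$count_unmeth == 0))
  expect_equal(conversion_efficiency(lam), 100)

  truth1 <- simulate_truth(genome, seed = 3, conversion_failure = 0.005)
  meth1 <- simulate_methylome(genome, truth1, n_replicates = 1,
                              mean_coverage = 50, seed = 4)
  lam1 <- meth1$embryo_1[meth1$embryo_1$chrom == "Lambda", ]
  expect_gt(sum(lam1$count_meth), 0)
  expect_equal(conversion_efficiency(lam1), 99.5, tolerance = 0.01)
})

test_that("noise-free methylome reproduces gene truth exactly", {
  genome <- generate_genome(40, seed = 12)
  truth <- simulate_truth(genome, seed = 13)
  # coverage 1000 makes rounding exact to 0.1 points
  meth <- simulate_methylome(genome, truth, n_replicates = 1,
                             mean_coverage = 1000, seed = 14, noise = "none")
  calls <- call_cpg_levels(meth$embryo_1[meth$embryo_1$chrom == "chr1", ])
  fm <- feature_methylation(calls, gene_feature_table(genome$annotation))
  i <- match(fm$feature_id, truth$genes$gene_id)
  ok <- fm$defined
  expect_true(all(abs(fm$mean_level[ok] - truth$genes$expected_meth_embryo[i][ok]) < 0.05))
})

test_that("expression and track simulation honours truth at zero noise", {
  genome <- generate_genome(40, seed = 15)
  truth <- simulate_truth(genome, seed = 16)
  sim <- simulate_expression_and_tracks(genome, truth, seed = 17,
                                        noise_sd = 0, track_noise = 0)
  tg <- truth$genes
  ne <- tg$expr_status_embryo == "not expressed"
  expect_true(all(sim$fpkm[ne, "embryo_1"] <= 1))
  expect_true(all(sim$fpkm[!ne, "embryo_1"] > 1))

  # H3K36me3 at the TES exceeds the TSS for every expressed gene
  tr <- sim$tracks$H3K36me3$rep1
  ti <- data.frame(chrom = tr$chrom, start1 = tr$start + 1, end1 = tr$end,
                   value = tr$value)
  gn <- genome$annotation$genes
  for (i in which(!ne)) {
    v <- gbmix:::.track_values_at(ti, c(gn$tss[i], gn$tes[i]))
    expect_gt(v[2], v[1])
  }

  # H3K27ac peaks at the TSS of expressed genes, absent for silent ones
  tr27 <- sim$tracks$H3K27ac$rep1
  t27 <- data.frame(chrom = tr27$chrom, start1 = tr27$start + 1,
                    end1 = tr27$end, value = tr27$value)
  v_tss <- gbmix:::.track_values_at(t27, gn$tss)
  expect_true(all(v_tss[!ne] > 3))
  expect_true(all(v_tss[ne] == 0))
})

test_that("methylome simulation is seed-deterministic and seed-sensitive", {
  genome <- generate_genome(15, seed = 1)
  truth <- simulate_truth(genome, seed = 2)
  m1 <- simulate_methylome(genome, truth, n_replicates = 1, seed = 5)
  m2 <- simulate_methylome(genome, truth, n_replicates = 1, seed = 5)
  m3 <- simulate_methylome(genome, truth, n_replicates = 1, seed = 6)
  expect_identical(m1, m2)
  expect_false(identical(m1$embryo_1$count_meth, m3$embryo_1$count_meth))
})
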