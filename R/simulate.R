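# Synthetic multiomics generator: a toy genome with CpG sites, a
# ground-truth record (stage-wise methylation and expression state,
# planted DMRs, histone-mark profile parameters, spike-in truths), and
# simulators for the methylome (with Lambda/pUC19 spike-in controls),
# expression tables and histone signal tracks. Everything is
# deterministic under a fixed seed.

#' Generate a toy annotated genome with CpG sites
#'
#' Places non-overlapping genes (1-8 exons, both strands) along one
#' chromosome with at least 3 kb of gene-free flank around every gene,
#' and scatters CpG sites with higher density in exons than in introns
#' or intergenic space.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length optional chromosome length; an error is raised
#'   when the requested genes do not fit. Default: sized to fit.
#' @param seed RNG seed.
#' @param min_flank minimum gene-free flank in bp (default 3000).
#' @param cpg_density per-bp CpG probabilities, named `exon`, `intron`,
#'   `intergenic`.
#' @return list `annotation` (a [genome_annotation]) and `cpg_sites`
#'   (data.frame `chrom`, `pos`, `strand`).
#' @export
generate_genome <- function(n_genes, chrom_length = NULL, seed = 1,
                            min_flank = 3000,
                            cpg_density = c(exon = 0.05, intron = 0.02,
                                            intergenic = 0.003)) {
  .assert(is.numeric(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  set.seed(seed)
  chrom <- "chr1"
  genes <- exons <- list()
  cursor <- min_flank + 1
  for (i in seq_len(n_genes)) {
    n_ex <- sample(1:8, 1)
    ex_len <- round(runif(n_ex, 150, 800))
    in_len <- if (n_ex > 1) round(runif(n_ex - 1, 80, 400)) else integer(0)
    g_start <- cursor
    ex_start <- g_start + cumsum(c(0, head(ex_len, -1) + in_len))
    ex_end <- ex_start + ex_len - 1
    g_end <- max(ex_end)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene%04d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = g_start, end = g_end)
    exons[[i]] <- data.frame(gene_id = gid, chrom = chrom,
                             start = ex_start, end = ex_end)
    cursor <- g_end + min_flank + 1 + round(runif(1, 0, 2000))
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  needed <- max(genes$end) + min_flank
  if (is.null(chrom_length)) chrom_length <- needed
  .assert(chrom_length >= needed,
          "chromosome too short: need %d bp for %d genes, got %d",
          needed, n_genes, chrom_length)
  ann <- genome_annotation(genes, exons, c(chr1 = chrom_length))

  # CpG placement: per-bp density by region class, exon > intron > rest
  dens <- rep(cpg_density[["intergenic"]], chrom_length)
  for (i in seq_len(nrow(genes))) {
    dens[genes$start[i]:genes$end[i]] <- cpg_density[["intron"]]
  }
  for (i in seq_len(nrow(exons))) {
    dens[exons$start[i]:exons$end[i]] <- cpg_density[["exon"]]
  }
  pos <- which(runif(chrom_length) < dens)
  list(annotation = ann,
       cpg_sites = data.frame(chrom = chrom, pos = pos, strand = "+",
                              stringsAsFactors = FALSE))
}

#' Ground truth for a synthetic multiomics study
#'
#' Draws a per-gene truth for two stages (embryo, adult): methylation
#' plateau levels (methylated genes uniform on 10-70 percent, with
#' longer genes more likely methylated; unmethylated genes below 8),
#' mostly-maintained methylation with small stage-specific loss/gain
#' rates and a mild adult-ward hypomethylation drift; expression states
#' with activation/inactivation rates and FPKM means tied to the
#' methylated/expressed regression slope; planted adult-stage DMRs over
#' contiguous CpG runs inside methylated genes; a TSS methylation dip
#' (level ~ 0 within +/- `dip_halfwidth` of the TSS) for
#' methylated/expressed genes only; spike-in truths (Lambda 0, pUC19
#' 100) and the conversion-failure rate.
#'
#' Per-site expected levels (including dip and planted DMRs) are stored
#' alongside the plateau levels; gene truth categories derive from the
#' expected gene-body site mean, so they are exactly what a perfect
#' pipeline would recover.
#'
#' @param genome output of [generate_genome()].
#' @param seed RNG seed.
#' @param p_methylated baseline probability a gene is methylated in the
#'   embryo (default 0.25).
#' @param p_expressed_embryo marginal embryo expressed fraction (default
#'   0.365); methylated genes are expressed with probability
#'   `p_expr_methylated` (default 0.7) and the unmethylated rate is
#'   solved to keep the marginal.
#' @param rate_activate,rate_inactivate stage-transition rates for
#'   expression (defaults 0.175 of embryo-silent, 0.093 of
#'   embryo-expressed).
#' @param rate_lose_meth,rate_gain_meth methylation transition rates
#'   (defaults 0.168 of methylated, 0.0067 of unmethylated).
#' @param drift_max upper bound (points) of the adult-ward
#'   hypomethylation drift of maintained methylated genes (default 6;
#'   0 disables, giving a stage-null methylome apart from the planted
#'   effects).
#' @param n_dmrs planted DMRs (default 8), `dmr_cpgs` CpGs each
#'   (default 15), additive `dmr_effect` in adult (default -30 points).
#' @param dip_halfwidth TSS dip half-width in bp (default 200).
#' @param gbm_slope,gbm_intercept,gbm_sd log10-FPKM ~ methylation
#'   relation for methylated/expressed genes (defaults 0.012, 0.9, 0.4).
#' @param conversion_failure false-methylated call rate on the
#'   unmethylated control (default 0.0045, i.e. 99.55 percent
#'   conversion efficiency).
#' @param dmr_cpgs,dmr_effect see `n_dmrs`.
#' @return object of class `sim_truth`.
#' @export
simulate_truth <- function(genome, seed = 1,
                           p_methylated = 0.25,
                           p_expressed_embryo = 0.365,
                           p_expr_methylated = 0.7,
                           rate_activate = 0.175, rate_inactivate = 0.093,
                           rate_lose_meth = 0.168, rate_gain_meth = 0.0067,
                           drift_max = 6,
                           n_dmrs = 8, dmr_cpgs = 15, dmr_effect = -30,
                           dip_halfwidth = 200,
                           gbm_slope = 0.012, gbm_intercept = 0.9, gbm_sd = 0.4,
                           conversion_failure = 0.0045) {
  set.seed(seed)
  ann <- genome$annotation
  g <- ann$genes
  n <- nrow(g)
  len <- g$end - g$start + 1

  # longer genes more likely methylated (length-category association);
  # weighted sampling of a fixed count keeps the marginal at p_methylated
  z <- scale(log(len))[, 1]
  meth_e <- logical(n)
  meth_e[sample.int(n, round(p_methylated * n), prob = exp(1.2 * z))] <- TRUE
  level_e <- ifelse(meth_e, runif(n, 10, 70), runif(n, 0, 8))

  lose <- meth_e & runif(n) < rate_lose_meth
  gain <- !meth_e & runif(n) < rate_gain_meth
  level_a <- level_e
  keep_m <- meth_e & !lose
  if (drift_max > 0) {
    # mild adult-ward hypomethylation drift of maintained genes
    level_a[keep_m] <- pmax(10.2, level_e[keep_m] - runif(sum(keep_m), 0, drift_max))
  }
  level_a[lose] <- runif(sum(lose), 0, 8)
  level_a[gain] <- runif(sum(gain), 12, 40)

  # expression states; solve unmethylated rate for the stated marginal
  p_expr_unmeth <- max(0.01, (p_expressed_embryo -
                                p_methylated * p_expr_methylated) /
                         (1 - p_methylated))
  expr_e <- runif(n) < ifelse(meth_e, p_expr_methylated, p_expr_unmeth)
  activate <- !expr_e & runif(n) < rate_activate
  inactivate <- expr_e & runif(n) < rate_inactivate
  expr_a <- (expr_e & !inactivate) | activate

  draw_fpkm <- function(expressed, methylated, level) {
    f <- numeric(length(expressed))
    me <- expressed & methylated
    f[me] <- pmax(1.05, 10^(gbm_intercept + gbm_slope * level[me] +
                              rnorm(sum(me), 0, gbm_sd)))
    ue <- expressed & !methylated
    f[ue] <- pmax(1.05, rlnorm(sum(ue), log(15), 1.1))
    ne <- !expressed
    f[ne] <- pmin(1, rlnorm(sum(ne), log(0.2), 0.9))
    f
  }
  fpkm_e <- draw_fpkm(expr_e, meth_e, level_e)
  fpkm_a <- draw_fpkm(expr_a, level_a >= 10, level_a)
  # extra magnitude-only DE among always-expressed genes
  both_expr <- expr_e & expr_a
  mag_de <- both_expr & runif(n) < 0.15
  fpkm_a[mag_de] <- fpkm_e[mag_de] *
    2^(sample(c(-1, 1), sum(mag_de), replace = TRUE) * runif(sum(mag_de), 1.2, 3))
  is_de <- (expr_e != expr_a) | mag_de
  log2fc <- log2((fpkm_a + 1e-3) / (fpkm_e + 1e-3))

  # planted DMRs: contiguous CpG runs inside methylated embryo genes
  sites <- genome$cpg_sites
  site_gene <- rep(NA_integer_, nrow(sites))
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos)),
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end)))
  site_gene[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

  # hosts are stage-stable apart from the planted run, so the run is the
  # gene's only embryo-to-adult difference; the run is placed clear of
  # the TSS dip zone, where levels are pinned near zero in both stages
  eligible <- which(meth_e & !lose & level_e >= 25 & expr_e == expr_a &
                      tabulate(site_gene, n)[seq_len(n)] >= dmr_cpgs + 6)
  dmrs <- list()
  dmr_site_mask <- logical(nrow(sites))
  dmr_genes <- integer(0)
  for (gi in sample(eligible)) {
    if (length(dmr_genes) >= n_dmrs) break
    idx <- which(site_gene == gi)
    idx <- idx[order(sites$pos[idx])]
    clear <- abs(sites$pos[idx] - g$tss[gi]) > dip_halfwidth
    r <- rle(clear)
    ends <- cumsum(r$lengths)
    ok_runs <- which(r$values & r$lengths >= dmr_cpgs)
    if (!length(ok_runs)) next
    seg <- ok_runs[which.max(r$lengths[ok_runs])]
    seg_idx <- idx[(ends[seg] - r$lengths[seg] + 1):ends[seg]]
    start_i <- sample(seq_len(length(seg_idx) - dmr_cpgs + 1), 1)
    run <- seg_idx[start_i:(start_i + dmr_cpgs - 1)]
    dmr_site_mask[run] <- TRUE
    dmr_genes <- c(dmr_genes, gi)
    dmrs[[length(dmrs) + 1]] <- data.frame(
      chrom = sites$chrom[run[1]], start = sites$pos[run[1]],
      end = sites$pos[run[dmr_cpgs]], gene_id = g$gene_id[gi],
      n_cpgs = dmr_cpgs, effect = dmr_effect,
      direction = if (dmr_effect < 0) "hypo" else "hyper",
      stringsAsFactors = FALSE)
  }
  if (length(dmr_genes)) level_a[dmr_genes] <- level_e[dmr_genes]
  dmrs <- if (length(dmrs)) do.call(rbind, dmrs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               gene_id = character(), n_cpgs = integer(), effect = numeric(),
               direction = character(), stringsAsFactors = FALSE)

  # per-site expected levels per stage; introns carry attenuated
  # gene-body methylation (exon > intron, as gene-body data shows)
  in_exon <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos)),
    .as_granges(ann$exon_union)) > 0
  site_level <- function(gene_level, meth_status, expr_status) {
    lv <- rep(1, nrow(sites))                       # intergenic background
    genic <- !is.na(site_gene)
    lv[genic] <- gene_level[site_gene[genic]]
    lv[genic & !in_exon] <- 0.7 * lv[genic & !in_exon]
    # TSS dip for methylated & expressed genes only
    dip_g <- which(meth_status & expr_status)
    if (length(dip_g)) {
      near <- genic & site_gene %in% dip_g &
        abs(sites$pos - g$tss[site_gene]) <= dip_halfwidth
      lv[near] <- pmin(lv[near], 1)
    }
    lv
  }
  sl_e <- site_level(level_e, meth_e, expr_e)
  sl_a <- site_level(level_a, level_a >= 10, expr_a)
  sl_a[dmr_site_mask] <- pmax(0, sl_a[dmr_site_mask] + dmr_effect)

  expected_mean <- function(sl) {
    out <- rep(NA_real_, n)
    tg <- tapply(sl[!is.na(site_gene)], site_gene[!is.na(site_gene)], mean)
    out[as.integer(names(tg))] <- as.numeric(tg)
    out
  }
  exp_e <- expected_mean(sl_e)
  exp_a <- expected_mean(sl_a)

  genes_df <- data.frame(
    gene_id = g$gene_id, length = len,
    level_embryo = level_e, level_adult = level_a,
    expected_meth_embryo = exp_e, expected_meth_adult = exp_a,
    meth_status_embryo = methylation_status(exp_e),
    meth_status_adult = methylation_status(exp_a),
    expr_status_embryo = ifelse(expr_e, "expressed", "not expressed"),
    expr_status_adult = ifelse(expr_a, "expressed", "not expressed"),
    fpkm_embryo = fpkm_e, fpkm_adult = fpkm_a,
    is_de = is_de, log2fc = log2fc, stringsAsFactors = FALSE)
  genes_df$category_embryo <- classify_four_sets(genes_df$meth_status_embryo,
                                                 genes_df$expr_status_embryo)
  genes_df$category_adult <- classify_four_sets(genes_df$meth_status_adult,
                                                genes_df$expr_status_adult)

  structure(list(
    genes = genes_df, dmrs = dmrs,
    site_levels = list(embryo = sl_e, adult = sl_a),
    site_gene = site_gene,
    profile = list(k27_height = 8, k27_sigma = 150,
                   k36_min = 0.5, k36_max = 6, k36_decay = 600,
                   k36_silent_level = 3),
    spikein = c(Lambda = 0, pUC19 = 100),
    conversion_failure = conversion_failure,
    dip_halfwidth = dip_halfwidth, seed = seed), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes, %d planted DMRs, conversion failure %.4f\n",
              nrow(x$genes), nrow(x$dmrs), x$conversion_failure))
  print(table(embryo = x$genes$category_embryo))
  invisible(x)
}

# control-chromosome CpG records for one sample
.control_records <- function(truth, mean_coverage, noise) {
  specs <- list(Lambda = list(n = 400, p = truth$conversion_failure),
                pUC19 = list(n = 120, p = 1 - truth$conversion_failure))
  do.call(rbind, lapply(names(specs), function(ch) {
    s <- specs[[ch]]
    cov <- if (noise == "none") rep(mean_coverage, s$n) else rpois(s$n, mean_coverage)
    meth <- if (noise == "none") round(cov * s$p) else rbinom(s$n, cov, s$p)
    data.frame(chrom = ch, pos = seq(10, by = 37, length.out = s$n),
               strand = "+", count_meth = meth, count_unmeth = cov - meth,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate per-sample methylome reads
#'
#' Per-CpG coverage is Poisson(`mean_coverage`); methylated counts are
#' beta-binomial around the site's true level with overdispersion
#' `dispersion`. Spike-in control records (chromosomes `Lambda`,
#' `pUC19`) are appended per sample, with conversion failure adding
#' false methylated calls on Lambda. `noise = "none"` uses fixed
#' coverage and rounded expected counts (exact recovery whenever
#' coverage x level/100 is integral).
#'
#' @param genome [generate_genome()] output.
#' @param truth a [simulate_truth()] object.
#' @param n_replicates per stage (default 3).
#' @param mean_coverage default 30.
#' @param dispersion beta-binomial overdispersion in \[0, 1); default
#'   0.1.
#' @param seed RNG seed.
#' @param noise `"betabinom"` (default) or `"none"`.
#' @return named list of CpG record data.frames (`embryo_1`, ...,
#'   `adult_n`).
#' @export
simulate_methylome <- function(genome, truth, n_replicates = 3,
                               mean_coverage = 30, dispersion = 0.1,
                               seed = 1, noise = c("betabinom", "none")) {
  noise <- match.arg(noise)
  .assert(mean_coverage > 0, "mean_coverage must be > 0")
  set.seed(seed)
  sites <- genome$cpg_sites
  out <- list()
  for (stage in c("embryo", "adult")) {
    p <- truth$site_levels[[stage]] / 100
    for (r in seq_len(n_replicates)) {
      ns <- nrow(sites)
      if (noise == "none") {
        cov <- rep(mean_coverage, ns)
        meth <- round(cov * p)
      } else {
        cov <- rpois(ns, mean_coverage)
        meth <- rbetabinom(ns, cov, p, dispersion)
      }
      rec <- data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                        count_meth = meth, count_unmeth = cov - meth,
                        stringsAsFactors = FALSE)
      out[[paste0(stage, "_", r)]] <- rbind(rec, .control_records(truth, mean_coverage, noise))
    }
  }
  out
}

# evaluate mark signal contributions of one gene onto a grid (bp centers)
.mark_profile_values <- function(centers, g_row, mark, pr, scale_f) {
  v <- numeric(length(centers))
  tss <- g_row$tss; tes <- g_row$tes
  if (mark == "H3K27ac") {
    v <- v + scale_f * pr$k27_height * exp(-((centers - tss)^2) / (2 * pr$k27_sigma^2))
  } else {
    lo <- g_row$start; hi <- g_row$end
    inside <- centers >= lo & centers <= hi
    L <- hi - lo + 1
    frac <- if (g_row$strand == "+") (centers - lo) / L else (hi - centers) / L
    if (isTRUE(g_row$ramp)) {
      v[inside] <- v[inside] + scale_f *
        (pr$k36_min + (pr$k36_max - pr$k36_min) * frac[inside])
      # exponential decay past the TES into the 3' flank
      d <- if (g_row$strand == "+") centers - hi else lo - centers
      tail <- d > 0 & d <= 4 * pr$k36_decay
      v[tail] <- v[tail] + scale_f * pr$k36_max * exp(-d[tail] / pr$k36_decay)
    } else {
      v[inside] <- v[inside] + scale_f * pr$k36_silent_level
    }
  }
  v
}

#' Simulate expression tables, DE results and histone signal tracks
#'
#' FPKM replicate values are log-normal around each gene's true stage
#' mean (`noise_sd` on the log scale; 0 gives the exact means, so
#' not-expressed genes stay at or below FPKM 1). The DE table reflects
#' the truth's differential calls. Histone tracks (2 replicates per
#' mark, embryo stage) are built on a `track_bin` bp grid: H3K27ac adds
#' a Gaussian bump at the TSS of expressed genes; H3K36me3 adds a
#' linear 5'-to-3' ramp over the bodies of expressed genes with
#' exponential decay into the 3' flank, and uniform body enrichment for
#' methylated, not-expressed genes; sparse low random bumps form the
#' background, independent per replicate.
#'
#' @param genome [generate_genome()] output.
#' @param truth a [simulate_truth()] object.
#' @param n_replicates expression replicates per stage (default 3).
#' @param n_track_replicates per mark (default 2).
#' @param seed RNG seed.
#' @param noise_sd log-scale FPKM replicate noise (default 0.3).
#' @param track_noise multiplicative per-gene track jitter sd (default
#'   0.15); 0 disables background bumps too.
#' @param track_bin grid resolution in bp (default 25).
#' @return list `fpkm` (matrix genes x samples, columns `embryo_1`...),
#'   `deg` (data.frame `gene_id`, `log2fc`, `padj`), `tracks` (nested
#'   list mark -> replicate -> bedGraph data.frame).
#' @export
simulate_expression_and_tracks <- function(genome, truth, n_replicates = 3,
                                           n_track_replicates = 2, seed = 1,
                                           noise_sd = 0.3, track_noise = 0.15,
                                           track_bin = 25) {
  set.seed(seed)
  tg <- truth$genes
  n <- nrow(tg)
  samples <- c(paste0("embryo_", seq_len(n_replicates)),
               paste0("adult_", seq_len(n_replicates)))
  fpkm <- matrix(0, n, length(samples), dimnames = list(tg$gene_id, samples))
  for (r in seq_len(n_replicates)) {
    fpkm[, r] <- tg$fpkm_embryo * exp(rnorm(n, 0, noise_sd))
    fpkm[, n_replicates + r] <- tg$fpkm_adult * exp(rnorm(n, 0, noise_sd))
  }
  deg <- data.frame(gene_id = tg$gene_id, log2fc = tg$log2fc,
                    padj = ifelse(tg$is_de, runif(n, 1e-8, 0.01),
                                  runif(n, 0.2, 1)), stringsAsFactors = FALSE)

  ann <- genome$annotation
  g <- ann$genes
  chrom <- names(ann$chrom_lengths)[1]
  clen <- ann$chrom_lengths[[1]]
  nb <- clen %/% track_bin
  centers <- (seq_len(nb) - 0.5) * track_bin
  pr <- truth$profile
  expressed <- tg$expr_status_embryo == "expressed"
  meth_silent <- tg$meth_status_embryo == "methylated" & !expressed

  tracks <- list()
  for (mark in c("H3K27ac", "H3K36me3")) {
    tracks[[mark]] <- list()
    active <- if (mark == "H3K27ac") which(expressed)
              else which(expressed | meth_silent)
    for (r in seq_len(n_track_replicates)) {
      v <- numeric(nb)
      for (gi in active) {
        row <- g[gi, ]
        row$ramp <- expressed[gi]
        sf <- if (track_noise > 0) exp(rnorm(1, 0, track_noise)) else 1
        # restrict evaluation to the gene neighbourhood for speed
        lo <- max(1, (row$start - 4 * pr$k36_decay) %/% track_bin)
        hi <- min(nb, (row$end + 4 * pr$k36_decay) %/% track_bin + 1)
        idx <- lo:hi
        v[idx] <- v[idx] + .mark_profile_values(centers[idx], row, mark, pr, sf)
      }
      if (track_noise > 0) {
        # dense, narrow low-level background bumps: on a real genome the
        # sparse-enrichment caller sees thousands of small blocks, and the
        # top-2.5% rule only behaves like the study's when it does here too
        n_bumps <- max(1L, nrow(g) * 18L)
        bp_pos <- runif(n_bumps, 1, clen)
        bp_h <- runif(n_bumps, 0.3, 1.2)
        for (b in seq_len(n_bumps)) {
          lo <- max(1, (bp_pos[b] - 80) %/% track_bin)
          hi <- min(nb, (bp_pos[b] + 80) %/% track_bin + 1)
          idx <- lo:hi
          v[idx] <- v[idx] + bp_h[b] * exp(-((centers[idx] - bp_pos[b])^2) / (2 * 15^2))
        }
      }
      v[v < 0.05] <- 0
      keep <- v > 0
      tracks[[mark]][[paste0("rep", r)]] <- data.frame(
        chrom = chrom, start = (which(keep) - 1L) * track_bin,
        end = pmin(which(keep) * track_bin, clen), value = round(v[keep], 4),
        stringsAsFactors = FALSE)
    }
  }
  list(fpkm = fpkm, deg = deg, tracks = tracks)
}

#' Synthetic gene-to-GO assignments
#'
#' Random direct annotations with a configurable set of terms enriched
#' in the methylated/expressed embryo category, for exercising the
#' enrichment module end-to-end.
#'
#' @param truth a [simulate_truth()] object.
#' @param n_terms default 30 (the first 5 are category-enriched).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `term`.
#' @export
simulate_gene2go <- function(truth, n_terms = 30, seed = 1) {
  set.seed(seed)
  ids <- truth$genes$gene_id
  me <- ids[truth$genes$category_embryo == "methylated/expressed"]
  out <- list()
  for (t in seq_len(n_terms)) {
    size <- sample(5:40, 1)
    pool <- if (t <= 5 && length(me) >= 3) {
      k <- min(length(me), ceiling(size * 0.6))
      c(sample(me, k), sample(ids, size - k))
    } else sample(ids, size)
    out[[t]] <- data.frame(gene_id = unique(pool),
                           term = sprintf("GO:%07d", t), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
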