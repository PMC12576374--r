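# Configuration-driven end-to-end analysis: validated parameter set and
# an orchestrator that runs every stage in dependency order, writing
# all module tables to an output directory. A demo mode generates the
# synthetic dataset first (through the package's own writers) and then
# analyses it like real data.

#' Pipeline configuration
#'
#' Validated parameter set; every default equals the study value used
#' throughout the modules.
#'
#' @param min_coverage per-CpG calling coverage (5).
#' @param min_cpgs feature-level support (3).
#' @param meth_threshold percent for methylation status (10).
#' @param fpkm_threshold expression status (1).
#' @param dmr_min_cpgs,dmr_min_diff,dmr_alpha DMR criteria (10, 10,
#'   0.05).
#' @param dmr_cov_window inclusive coverage window (c(5, 100)).
#' @param dmr_max_gap segmentation run gap in bp (300).
#' @param peak_fraction top-AUC fraction (0.025).
#' @param profile_body,profile_flank,profile_bin metagene geometry
#'   (5000, 3000, 50).
#' @param anchored_flank TSS/TES half-window (500).
#' @param go_top_n reported GO terms (40).
#' @param qc_correlation_floor replicate flagging threshold (0.8).
#' @param excluded_replicates character vector of sample names dropped
#'   from stage summaries (config action, never automatic).
#' @param seed master RNG seed for demo mode.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 5, min_cpgs = 3, meth_threshold = 10,
                            fpkm_threshold = 1, dmr_min_cpgs = 10,
                            dmr_min_diff = 10, dmr_alpha = 0.05,
                            dmr_cov_window = c(5, 100), dmr_max_gap = 300,
                            peak_fraction = 0.025, profile_body = 5000,
                            profile_flank = 3000, profile_bin = 50,
                            anchored_flank = 500, go_top_n = 40,
                            qc_correlation_floor = 0.8,
                            excluded_replicates = character(), seed = 1) {
  cfg <- as.list(environment())
  num <- cfg[setdiff(names(cfg), "excluded_replicates")]
  .assert(all(vapply(num, is.numeric, TRUE)), "thresholds must be numeric")
  .assert(all(unlist(num) > 0 | names(unlist(num)) == "seed"),
          "all thresholds must be positive")
  .assert(peak_fraction > 0 && peak_fraction <= 1,
          "peak_fraction must be in (0, 1]")
  .assert(dmr_alpha > 0 && dmr_alpha < 1, "dmr_alpha must be in (0, 1)")
  .assert(length(dmr_cov_window) == 2 && dmr_cov_window[1] <= dmr_cov_window[2],
          "dmr_cov_window must be c(lo, hi)")
  .assert(profile_body %% profile_bin == 0 && profile_flank %% profile_bin == 0,
          "profile_bin must divide body and flank")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis
#'
#' Runs all stages in dependency order (methylome -> DMR; expression ->
#' integration; chromatin -> profiles -> enrichment) and writes every
#' module table as TSV/BED to `outdir`, plus a run log recording the
#' package version, seed and configuration. With `demo = TRUE` a
#' synthetic dataset is generated under `outdir/data` first (written
#' through the package's format writers, then read back), so the whole
#' pipeline runs without any external input.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @param demo generate and analyse a synthetic dataset (default TRUE;
#'   non-demo callers assemble stages from the module functions
#'   directly).
#' @param n_genes demo genome size (default 200).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config = pipeline_config(), outdir, demo = TRUE,
                    n_genes = 200) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  .assert(isTRUE(demo), "non-demo orchestration is composed from module functions")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(outdir, "data")
  dir.create(data_dir, showWarnings = FALSE)

  seed <- config$seed
  genome <- generate_genome(n_genes, seed = seed)
  truth <- simulate_truth(genome, seed = seed + 1)
  meth <- simulate_methylome(genome, truth, seed = seed + 2)
  expr <- simulate_expression_and_tracks(genome, truth, seed = seed + 3)
  gene2go <- simulate_gene2go(truth, seed = seed + 4)

  # ---- write the synthetic layer through the io writers, read it back
  write_annotation(genome$annotation, file.path(data_dir, "annotation.gff3"))
  for (s in names(meth)) {
    write_cytosine_report(meth[[s]], file.path(data_dir, paste0(s, ".CpG_report.txt")))
  }
  fpkm_df <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm)
  write_tsv_table(fpkm_df, file.path(data_dir, "fpkm.tsv"))
  write_tsv_table(expr$deg, file.path(data_dir, "deg.tsv"))
  for (mk in names(expr$tracks)) {
    for (r in names(expr$tracks[[mk]])) {
      write_bedgraph(expr$tracks[[mk]][[r]],
                     file.path(data_dir, paste0(mk, "_", r, ".bedgraph")))
    }
  }
  write_tsv_table(gene2go, file.path(data_dir, "gene2go.tsv"))
  jsonlite::write_json(list(genes = truth$genes, dmrs = truth$dmrs,
                            spikein = as.list(truth$spikein),
                            conversion_failure = truth$conversion_failure,
                            seed = truth$seed),
                       file.path(data_dir, "truth.json"), digits = NA)

  ann <- read_annotation(file.path(data_dir, "annotation.gff3"))
  samples <- lapply(names(meth), function(s)
    read_cytosine_report(file.path(data_dir, paste0(s, ".CpG_report.txt")), s))
  names(samples) <- names(meth)
  fpkm <- as.matrix(read_tsv_table(file.path(data_dir, "fpkm.tsv"))[-1])
  rownames(fpkm) <- fpkm_df$gene_id
  deg <- read_tsv_table(file.path(data_dir, "deg.tsv"))
  tracks <- lapply(names(expr$tracks), function(mk) {
    lapply(stats::setNames(names(expr$tracks[[mk]]), names(expr$tracks[[mk]])),
           function(r) read_bedgraph(file.path(data_dir, paste0(mk, "_", r, ".bedgraph"))))
  })
  names(tracks) <- names(expr$tracks)

  # ---- methylome stage
  control_chroms <- c("Lambda", "pUC19")
  conv <- vapply(samples, function(s)
    conversion_efficiency(s[s$chrom == "Lambda", ]), 0)
  write_tsv_table(data.frame(sample = names(conv), conversion_efficiency = conv),
                  file.path(outdir, "conversion_efficiency.tsv"))
  calls <- lapply(samples, function(s)
    call_cpg_levels(s[!s$chrom %in% control_chroms, ], config$min_coverage))
  feats <- gene_feature_table(ann)
  fm <- lapply(calls, feature_methylation, features = feats,
               min_cpgs = config$min_cpgs)
  consolidated <- consolidated_gene_set(fm)
  region <- region_class_summary(calls[[1]], ann,
                                 status_threshold = config$meth_threshold)
  write_tsv_table(region$classes, file.path(outdir, "region_summary.tsv"))

  stage_of <- sub("_[0-9]+$", "", names(samples))
  stage_mean <- function(stage) {
    keep <- stage_of == stage & !names(samples) %in% config$excluded_replicates
    rowMeans(do.call(cbind, lapply(fm[keep], function(tab)
      tab$mean_level[match(consolidated, tab$feature_id)])))
  }
  meth_e <- stage_mean("embryo"); meth_a <- stage_mean("adult")

  # ---- dmr stage
  samples_nc <- lapply(samples, function(s) s[!s$chrom %in% control_chroms, ])
  dinput <- dmr_input_filter(samples_nc, stage_of,
    min_cov = config$dmr_cov_window[1], max_cov = config$dmr_cov_window[2])
  cand <- segment_candidates(dinput, max_gap = config$dmr_max_gap,
                             min_cpgs = config$dmr_min_cpgs,
                             min_diff = config$dmr_min_diff)
  dmrs <- test_dmrs(cand, dinput, alpha = config$dmr_alpha,
                    min_cpgs = config$dmr_min_cpgs,
                    min_diff = config$dmr_min_diff)
  dmr_ann <- annotate_dmrs(dmrs, ann)
  write_tsv_table(dmr_ann$dmrs, file.path(outdir, "dmrs.tsv"))
  write_dmr_bed(dmrs, file.path(outdir, "dmrs.bed"))

  # ---- expression stage
  keep_cols <- !colnames(fpkm) %in% config$excluded_replicates
  qc <- replicate_qc(fpkm[, keep_cols, drop = FALSE],
                     groups = sub("_[0-9]+$", "", colnames(fpkm)[keep_cols]),
                     cor_floor = config$qc_correlation_floor)
  expr_stage <- function(stage) {
    cols <- grepl(paste0("^", stage, "_"), colnames(fpkm)) & keep_cols
    rowMeans(fpkm[consolidated, cols, drop = FALSE])
  }
  acct <- deg_accounting(deg, config$dmr_alpha)

  # ---- integration stage
  st_e <- gene_status_table(consolidated, meth_e, expr_stage("embryo"),
                            config$meth_threshold, config$fpkm_threshold)
  st_a <- gene_status_table(consolidated, meth_a, expr_stage("adult"),
                            config$meth_threshold, config$fpkm_threshold)
  write_tsv_table(st_e, file.path(outdir, "gene_status_embryo.tsv"))
  write_tsv_table(st_a, file.path(outdir, "gene_status_adult.tsv"))
  trans <- transition_counts(st_e, st_a)
  write_tsv_table(trans$flows_long, file.path(outdir, "transition_flows.tsv"))
  cstats <- category_stats(st_e, ann)
  write_tsv_table(cstats, file.path(outdir, "category_stats_embryo.tsv"))
  reg <- tryCatch(gbm_expression_regression(st_e), error = function(e) NULL)
  dmr_gene_sets <- .dmr_gene_sets(dmrs, ann)
  ov <- dmr_deg_overlap(dmr_gene_sets, deg_gene_sets(deg, config$dmr_alpha),
                        consolidated)
  write_tsv_table(ov, file.path(outdir, "dmr_deg_overlap.tsv"))
  chg <- methylation_change_profile(st_e$mean_level, st_a$mean_level)
  write_tsv_table(chg, file.path(outdir, "methylation_change.tsv"))

  # ---- chromatin stage
  highconf <- list()
  for (mk in names(tracks)) {
    peak_sets <- lapply(tracks[[mk]], function(tr)
      select_top_fraction(signal_blocks(tr), config$peak_fraction))
    highconf[[mk]] <- consolidate_replicates(peak_sets)
    write_bed(highconf[[mk]], file.path(outdir, paste0("peaks_", mk, ".bed")))
  }
  assign1 <- assign_peaks(highconf[[1]], ann)
  marks_ov <- gene_mark_overlap(ann, highconf,
                                gene_groups = setNames(st_e$expr_status, st_e$gene_id))
  write_tsv_table(marks_ov$summary, file.path(outdir, "gene_mark_summary.tsv"))
  cat_sets <- split(st_e$gene_id, st_e$category)
  enr <- do.call(rbind, lapply(names(highconf), function(mk) {
    marked <- marks_ov$per_gene$gene_id[marks_ov$per_gene[[mk]]]
    cbind(mark = mk, category_mark_enrichment(cat_sets, marked, consolidated))
  }))
  write_tsv_table(enr, file.path(outdir, "category_mark_enrichment.tsv"))

  # ---- profiles stage
  me_set <- st_e$gene_id[st_e$category == "methylated/expressed"]
  prof_meth <- metagene_matrix(calls[[1]], ann, genes = consolidated,
                               body = config$profile_body,
                               flank = config$profile_flank,
                               bin_size = config$profile_bin)
  write_tsv_table(cbind(gene_id = rownames(prof_meth), as.data.frame(prof_meth)),
                  file.path(outdir, "metagene_methylation_embryo1.tsv"))
  prof_sets <- list(methylation = set_mean_profile(prof_meth, me_set))
  for (mk in names(tracks)) {
    pm <- metagene_matrix(tracks[[mk]][[1]], ann, genes = consolidated,
                          body = config$profile_body,
                          flank = config$profile_flank,
                          bin_size = config$profile_bin)
    prof_sets[[mk]] <- set_mean_profile(
      pm, st_e$gene_id[st_e$expr_status == "expressed"])
    write_tsv_table(prof_sets[[mk]],
                    file.path(outdir, paste0("metagene_", mk, "_expressed.tsv")))
  }
  segs <- segment_profile(calls[[1]], ann, gene_set = me_set,
                          flank = config$profile_flank,
                          min_cpgs = config$min_cpgs)
  write_tsv_table(segs, file.path(outdir, "segment_profile_me.tsv"))

  # ---- enrichment stage
  go <- go_fisher(me_set, consolidated, gene2go)
  write_tsv_table(top_terms(go, config$go_top_n), file.path(outdir, "go_top.tsv"))

  writeLines(c(sprintf("gbmix %s", as.character(utils::packageVersion("gbmix"))),
               sprintf("seed: %d", seed),
               sprintf("genes: %d, consolidated: %d", n_genes, length(consolidated)),
               "config:", paste0("  ", names(config), " = ",
                                 vapply(config, function(x) paste(format(x), collapse = ","), ""))),
             file.path(outdir, "run_log.txt"))

  invisible(list(annotation = ann, truth = truth, consolidated = consolidated,
                 conversion = conv, status_embryo = st_e, status_adult = st_a,
                 transitions = trans, dmrs = dmrs, dmr_annotation = dmr_ann,
                 deg_accounting = acct, overlap = ov, region = region,
                 peaks = highconf, peak_assignment = assign1,
                 gene_marks = marks_ov, mark_enrichment = enr,
                 profiles = prof_sets, segments = segs, go = go, qc = qc,
                 regression = reg))
}

# gene sets hit by DMRs, split by direction
.dmr_gene_sets <- function(dmrs, annotation) {
  g <- annotation$genes
  if (nrow(dmrs) == 0) return(list(hypo = character(), hyper = character()))
  dgr <- .as_granges(dmrs)
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  hits <- GenomicRanges::findOverlaps(dgr, ggr)
  df <- data.frame(direction = dmrs$direction[S4Vectors::queryHits(hits)],
                   gene_id = g$gene_id[S4Vectors::subjectHits(hits)])
  list(hypo = unique(df$gene_id[df$direction == "hypo"]),
       hyper = unique(df$gene_id[df$direction == "hyper"]))
}
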