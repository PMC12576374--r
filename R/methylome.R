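# Per-CpG methylation calling, spike-in QC, feature aggregation and
# genome/feature summaries.

#' Call per-CpG methylation levels
#'
#' A CpG is called when its read coverage (methylated + unmethylated)
#' reaches `min_coverage`; its level is the percent of reads methylated.
#' Spike-in control chromosomes should be excluded before calling (see
#' [conversion_efficiency()]).
#'
#' @param records CpG records from one sample ([read_cytosine_report()]).
#' @param min_coverage minimum read coverage; default 5.
#' @return data.frame `chrom`, `pos`, `strand`, `level` (percent,
#'   0–100), `coverage`.
#' @export
call_cpg_levels <- function(records, min_coverage = 5) {
  .assert(all(records$count_meth >= 0 & records$count_unmeth >= 0),
          "negative read counts")
  cov <- records$count_meth + records$count_unmeth
  keep <- cov >= min_coverage
  out <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                    strand = if (!is.null(records$strand)) records$strand[keep] else "+",
                    level = 100 * records$count_meth[keep] / cov[keep],
                    coverage = cov[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Conversion efficiency from the unmethylated spike-in
#'
#' For an enzymatic (or bisulfite) conversion assay, the unmethylated
#' Lambda control should read fully unmethylated; residual methylated
#' calls measure conversion failure. Efficiency is 100 minus the pooled
#' percent of methylated cytosine calls over all control positions.
#'
#' @param control_records CpG records restricted to the unmethylated
#'   control chromosome.
#' @return percent in \[0, 100\], or `NA` when the control has zero
#'   coverage.
#' @export
conversion_efficiency <- function(control_records) {
  tot <- sum(control_records$count_meth) + sum(control_records$count_unmeth)
  if (tot == 0) return(NA_real_)
  100 - 100 * sum(control_records$count_meth) / tot
}

#' Mean methylation per genomic feature
#'
#' The feature's level is the unweighted mean of per-CpG levels over
#' covered CpGs inside it, defined if and only if at least `min_cpgs`
#' covered CpGs fall within the feature.
#'
#' @param calls output of [call_cpg_levels()].
#' @param features data.frame `feature_id`, `chrom`, `start`, `end`
#'   (1-based closed), e.g. [gene_feature_table()].
#' @param min_cpgs support threshold; default 3.
#' @return data.frame `feature_id`, `n_cpgs`, `mean_level` (`NA` when
#'   undefined), `defined`.
#' @export
feature_methylation <- function(calls, features, min_cpgs = 3) {
  n <- integer(nrow(features))
  m <- rep(NA_real_, nrow(features))
  if (nrow(calls) > 0 && nrow(features) > 0) {
    fgr <- .as_granges(features)
    cgr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
    hits <- GenomicRanges::findOverlaps(fgr, cgr)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      lv <- calls$level[S4Vectors::subjectHits(hits)]
      n_t <- tapply(lv, qh, length)
      m_t <- tapply(lv, qh, mean)
      idx <- as.integer(names(n_t))
      n[idx] <- as.integer(n_t)
      m[idx] <- as.numeric(m_t)
    }
  }
  defined <- n >= min_cpgs
  m[!defined] <- NA_real_
  data.frame(feature_id = features$feature_id, n_cpgs = n,
             mean_level = m, defined = defined, stringsAsFactors = FALSE)
}

#' Consolidated gene set across samples
#'
#' Genes whose methylation level is defined (at least `min_cpgs` covered
#' CpGs) in every sample. This set is the universe for all categorical
#' analyses.
#'
#' @param per_sample list of [feature_methylation()] tables, one per
#'   sample, over a common gene universe.
#' @return character vector of retained gene ids.
#' @export
consolidated_gene_set <- function(per_sample) {
  .assert(length(per_sample) >= 1, "need at least one sample")
  ids <- per_sample[[1]]$feature_id
  for (tab in per_sample) {
    .assert(identical(sort(tab$feature_id), sort(ids)),
            "samples have mismatched gene universes")
  }
  def <- Reduce(`&`, lapply(per_sample, function(tab)
    tab$defined[match(ids, tab$feature_id)]))
  ids[def]
}

#' Binary methylation status of a gene
#'
#' "not methylated" means a mean level strictly below the threshold
#' (default 10 percent); at or above is "methylated".
#'
#' @param mean_level percent in \[0, 100\] (vectorised; `NA` passes
#'   through).
#' @param threshold percent; default 10.
#' @return character vector, `"methylated"` / `"not methylated"`.
#' @export
methylation_status <- function(mean_level, threshold = 10) {
  ifelse(is.na(mean_level), NA_character_,
         ifelse(mean_level < threshold, "not methylated", "methylated"))
}

#' Genome-wide methylation summary per region class
#'
#' Classifies the genome into exon, intron and intergenic space (plus an
#' optional repeat class from a BED annotation), with exon taking
#' priority over intron for positions covered by both (overlapping
#' isoforms). Reports, per class, the mean of per-CpG levels of CpGs in
#' the class, the CpG count, and the class's fraction of the genome in
#' bp. Also reports two genome-wide methylated-CpG summaries: the mean
#' per-CpG level and the fraction of covered CpGs at or above
#' `status_threshold` percent.
#'
#' @param calls [call_cpg_levels()] output, all chromosomes of one
#'   sample.
#' @param annotation a [genome_annotation].
#' @param repeats optional data.frame `chrom`, `start`, `end` (1-based
#'   closed) of repeat intervals; reported as an additional overlay
#'   class (not part of the exon/intron/intergenic partition).
#' @param status_threshold percent used for the thresholded genome-wide
#'   fraction; default 10.
#' @return list with `classes` (data.frame `class`, `mean_level`,
#'   `n_cpgs`, `genome_fraction`) and `genome` (named numeric:
#'   `mean_cpg_level`, `pct_cpgs_methylated`).
#' @export
region_class_summary <- function(calls, annotation, repeats = NULL,
                                 status_threshold = 10) {
  sl <- annotation$chrom_lengths
  genome_bp <- sum(as.numeric(sl))
  exon_gr <- GenomicRanges::reduce(.as_granges(annotation$exon_union))
  gene_gr <- GenomicRanges::reduce(.as_granges(
    data.frame(chrom = annotation$genes$chrom, start = annotation$genes$start,
               end = annotation$genes$end)))
  intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)
  cgr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))

  in_exon <- GenomicRanges::countOverlaps(cgr, exon_gr) > 0
  in_intron <- !in_exon & GenomicRanges::countOverlaps(cgr, intron_gr) > 0
  cls <- ifelse(in_exon, "exon", ifelse(in_intron, "intron", "intergenic"))

  bp <- c(exon = sum(GenomicRanges::width(exon_gr)),
          intron = sum(GenomicRanges::width(intron_gr)))
  bp["intergenic"] <- genome_bp - bp[["exon"]] - bp[["intron"]]
  classes <- data.frame(
    class = c("exon", "intron", "intergenic"),
    mean_level = vapply(c("exon", "intron", "intergenic"), function(k) {
      v <- calls$level[cls == k]
      if (length(v)) mean(v) else NA_real_
    }, 0),
    n_cpgs = vapply(c("exon", "intron", "intergenic"),
                    function(k) sum(cls == k), 0L),
    genome_fraction = 100 * as.numeric(bp[c("exon", "intron", "intergenic")]) / genome_bp,
    stringsAsFactors = FALSE)

  if (!is.null(repeats) && nrow(repeats) > 0) {
    rep_gr <- GenomicRanges::reduce(.as_granges(repeats))
    in_rep <- GenomicRanges::countOverlaps(cgr, rep_gr) > 0
    classes <- rbind(classes, data.frame(
      class = "repeat",
      mean_level = if (any(in_rep)) mean(calls$level[in_rep]) else NA_real_,
      n_cpgs = sum(in_rep),
      genome_fraction = 100 * sum(GenomicRanges::width(rep_gr)) / genome_bp))
  }
  rownames(classes) <- NULL
  genome <- c(mean_cpg_level = if (nrow(calls)) mean(calls$level) else NA_real_,
              pct_cpgs_methylated = if (nrow(calls))
                100 * mean(calls$level >= status_threshold) else NA_real_)
  list(classes = classes, genome = genome)
}
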