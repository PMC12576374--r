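# Sparse-enrichment peak calling from coverage tracks: signal blocks,
# top-fraction selection by AUC, cross-replicate consolidation, feature
# assignment and gene-mark overlap statistics.

#' Signal blocks from a coverage track
#'
#' Maximal runs of adjacent (book-ended) intervals with value > 0 become
#' blocks; each records its area under the curve (sum of value x width)
#' and maximum value.
#'
#' @param track bedGraph data.frame ([read_bedgraph()] layout, 0-based
#'   half-open).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `auc`, `max_value`.
#' @export
signal_blocks <- function(track) {
  t2 <- track[track$value > 0, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      auc = numeric(), max_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(t2) == 0) return(empty)
  t2 <- t2[order(t2$chrom, t2$start), , drop = FALSE]
  new_block <- c(TRUE, t2$chrom[-1] != t2$chrom[-nrow(t2)] |
                   t2$start[-1] > t2$end[-nrow(t2)])
  bid <- cumsum(new_block)
  w <- t2$end - t2$start
  out <- data.frame(
    chrom = tapply(t2$chrom, bid, `[`, 1),
    start = as.integer(tapply(t2$start, bid, min)),
    end = as.integer(tapply(t2$end, bid, max)),
    auc = as.numeric(tapply(t2$value * w, bid, sum)),
    max_value = as.numeric(tapply(t2$value, bid, max)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top fraction of blocks by AUC
#'
#' Blocks are ranked by AUC descending; the top `ceiling(fraction * n)`
#' are retained. Ties at the cutoff are broken by maximum value, then
#' genomic order, so the selection is deterministic and invariant to
#' input shuffling.
#'
#' @param blocks [signal_blocks()] output.
#' @param fraction in (0, 1\]; default 0.025 (the 2.5 percent of highest
#'   peaks).
#' @return the retained blocks, in genomic order.
#' @export
select_top_fraction <- function(blocks, fraction = 0.025) {
  .assert(is.numeric(fraction) && length(fraction) == 1 &&
            fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  n <- nrow(blocks)
  if (n == 0) return(blocks)
  k <- ceiling(fraction * n)
  o <- order(-blocks$auc, -blocks$max_value, blocks$chrom, blocks$start)
  sel <- blocks[o[seq_len(k)], , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Consolidate peak sets across replicates
#'
#' The high-confidence set: genomic space covered by at least one peak
#' in every replicate (the n-way intersection, >= 1 bp), with
#' overlapping intersection fragments merged into maximal intervals.
#' Equivalent to the pairwise intersect-then-merge construction for two
#' replicates.
#'
#' @param peak_sets list (length >= 2) of peak data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return data.frame `chrom`, `start`, `end` of consolidated peaks.
#' @export
consolidate_replicates <- function(peak_sets) {
  .assert(length(peak_sets) >= 2, "need >= 2 replicate peak sets")
  grs <- lapply(peak_sets, function(p)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      p$chrom, IRanges::IRanges(p$start + 1L, p$end))))
  common <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), grs)
  common <- GenomicRanges::reduce(common)
  data.frame(chrom = as.character(GenomicRanges::seqnames(common)),
             start = GenomicRanges::start(common) - 1L,
             end = GenomicRanges::end(common), stringsAsFactors = FALSE)
}

#' Assign peaks to genic or intergenic space
#'
#' A peak is genic iff it overlaps any gene span by at least 1 bp.
#'
#' @param peaks data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param annotation a [genome_annotation].
#' @return list `peaks` (input plus `class` column), `fractions` (named
#'   percent `genic` / `intergenic`, summing to 100).
#' @export
assign_peaks <- function(peaks, annotation) {
  gene_gr <- GenomicRanges::reduce(.as_granges(
    data.frame(chrom = annotation$genes$chrom, start = annotation$genes$start,
               end = annotation$genes$end)))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end))
  genic <- GenomicRanges::countOverlaps(pgr, gene_gr) > 0
  peaks$class <- ifelse(genic, "genic", "intergenic")
  list(peaks = peaks,
       fractions = c(genic = 100 * mean(genic), intergenic = 100 * mean(!genic)))
}

#' Gene x histone-mark overlap booleans and summaries
#'
#' For each gene and mark, whether the gene span overlaps (>= 1 bp) any
#' high-confidence peak of that mark; plus either-mark and both-marks
#' summaries, optionally stratified by a gene grouping (e.g. expression
#' status or four-way category).
#'
#' @param annotation a [genome_annotation].
#' @param peaks_by_mark named list of peak data.frames (`chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param gene_groups optional named character vector (gene id ->
#'   group).
#' @return list `per_gene` (data.frame gene_id + one logical column per
#'   mark + `either`, `both`), `summary` (per group when given, else
#'   overall: percent either / both / per mark).
#' @export
gene_mark_overlap <- function(annotation, peaks_by_mark, gene_groups = NULL) {
  g <- annotation$genes
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  per <- data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE)
  for (mk in names(peaks_by_mark)) {
    p <- peaks_by_mark[[mk]]
    pgr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
    per[[mk]] <- GenomicRanges::countOverlaps(ggr, pgr) > 0
  }
  mk_cols <- names(peaks_by_mark)
  per$either <- Reduce(`|`, per[mk_cols])
  per$both <- Reduce(`&`, per[mk_cols])
  grp <- if (is.null(gene_groups)) rep("all", nrow(per)) else
    unname(gene_groups[per$gene_id])
  ok <- !is.na(grp)
  summary <- do.call(rbind, lapply(split(which(ok), grp[ok]), function(idx) {
    row <- data.frame(group = grp[idx[1]], n_genes = length(idx),
                      pct_either = 100 * mean(per$either[idx]),
                      pct_both = 100 * mean(per$both[idx]),
                      stringsAsFactors = FALSE)
    for (mk in mk_cols) row[[paste0("pct_", mk)]] <- 100 * mean(per[[mk]][idx])
    row
  }))
  rownames(summary) <- NULL
  list(per_gene = per, summary = summary)
}

#' Category x mark enrichment tests
#'
#' Upper-tail hypergeometric probability that a gene category overlaps
#' the marked gene set at least as strongly as observed, per category.
#'
#' @param category_sets named list of gene-id vectors (the four-way
#'   categories).
#' @param marked_gene_set gene ids overlapping the mark's
#'   high-confidence peaks.
#' @param universe gene-id universe.
#' @return data.frame `category`, `n_category`, `n_marked`, `overlap`,
#'   `p_enrich`.
#' @export
category_mark_enrichment <- function(category_sets, marked_gene_set, universe) {
  universe <- unique(universe)
  marked <- base::intersect(marked_gene_set, universe)
  do.call(rbind, lapply(names(category_sets), function(k) {
    a <- base::intersect(category_sets[[k]], universe)
    ov <- length(base::intersect(a, marked))
    data.frame(category = k, n_category = length(a), n_marked = length(marked),
               overlap = ov,
               p_enrich = hyper_overlap_p(ov, length(a), length(marked),
                                          length(universe)),
               stringsAsFactors = FALSE)
  }))
}
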