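#' Genome annotation container
#'
#' Holds chromosome lengths and a gene model in 1-based inclusive
#' coordinates: gene spans, the ordered exons of each gene's longest
#' transcript (E1 is always the 5'-most exon in transcription order),
#' the introns derived as gaps between consecutive exons, and the union
#' of exons across all transcripts (the exonic space used for region
#' classification).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`; rows in transcription order per gene (rank assigned here).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param exon_union optional data.frame (`gene_id`, `chrom`, `start`,
#'   `end`) of merged exonic intervals over all transcripts; defaults to
#'   the union of `exons`.
#'
#' @return An object of class `genome_annotation` with elements `genes`
#'   (gains `tss`/`tes` columns), `exons`, `introns`, `exon_union`,
#'   `chrom_lengths`.
#' @export
genome_annotation <- function(genes, exons, chrom_lengths, exon_union = NULL) {
  .assert(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
          "genes must have gene_id, chrom, strand, start, end")
  .assert(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(genes$end >= genes$start), "zero/negative-length gene feature")
  .assert(all(exons$end >= exons$start), "zero/negative-length exon feature")
  .assert(all(exons$gene_id %in% genes$gene_id), "exon without parent gene")

  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  rownames(genes) <- NULL

  # order exons in transcription direction and derive introns per gene
  ex_list <- split(exons, exons$gene_id)
  ord_exons <- vector("list", length(ex_list))
  introns <- vector("list", length(ex_list))
  for (i in seq_along(ex_list)) {
    ex <- ex_list[[i]]
    g <- genes[match(ex$gene_id[1], genes$gene_id), ]
    .assert(all(ex$start >= g$start & ex$end <= g$end),
            "exon outside gene span for gene %s", g$gene_id)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      .assert(all(ex$start[-1] > ex$end[-nrow(ex)]),
              "overlapping exons within transcript of gene %s", g$gene_id)
    }
    if (g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    ex$rank <- seq_len(nrow(ex))
    ord_exons[[i]] <- ex
    if (nrow(ex) > 1) {
      # gap between consecutive exons in transcription order
      if (g$strand == "+") {
        in_start <- ex$end[-nrow(ex)] + 1
        in_end <- ex$start[-1] - 1
      } else {
        in_start <- ex$end[-1] + 1
        in_end <- ex$start[-nrow(ex)] - 1
      }
      introns[[i]] <- data.frame(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
                                 start = in_start, end = in_end,
                                 rank = seq_len(nrow(ex) - 1))
    }
  }
  exons <- do.call(rbind, ord_exons)
  introns <- if (length(introns) && any(!vapply(introns, is.null, TRUE))) {
    do.call(rbind, introns[!vapply(introns, is.null, TRUE)])
  } else {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), rank = integer())
  }
  rownames(exons) <- rownames(introns) <- NULL

  if (is.null(exon_union)) {
    gr <- .as_granges(exons)
    red <- GenomicRanges::reduce(S4Vectors::splitAsList(gr, exons$gene_id))
    ul <- lapply(names(red), function(g) {
      r <- red[[g]]
      if (length(r) == 0) return(NULL)
      data.frame(gene_id = g,
                 chrom = exons$chrom[match(g, exons$gene_id)],
                 start = GenomicRanges::start(r), end = GenomicRanges::end(r))
    })
    exon_union <- do.call(rbind, ul)
  }

  structure(list(genes = genes, exons = exons, introns = introns,
                 exon_union = exon_union, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s), %d exons, %d introns\n",
              nrow(x$genes), length(x$chrom_lengths), nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Parses gene/mRNA/exon features from a GFF3 file. For multi-transcript
#' genes, the transcript with the largest summed exon length defines the
#' ordered exon chain E1..En (and hence the introns), while the union of
#' exons over all transcripts defines the gene's exonic space. Exons
#' parented directly by a gene (no mRNA level) are accepted.
#'
#' @param path GFF3 file. Chromosome lengths are taken from
#'   `##sequence-region` pragmas when present, else from the maximum
#'   annotated coordinate per chromosome.
#' @return A [genome_annotation] object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  .assert(length(gr) > 0, "empty annotation file: %s", path)
  .assert(all(GenomicRanges::width(gr) >= 1), "zero-length feature in %s", path)
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")

  gi <- which(type == "gene")
  .assert(length(gi) > 0, "no gene features in %s", path)
  genes <- data.frame(gene_id = ids[gi],
                      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
                      strand = as.character(GenomicRanges::strand(gr))[gi],
                      start = GenomicRanges::start(gr)[gi],
                      end = GenomicRanges::end(gr)[gi])
  .assert(all(genes$strand %in% c("+", "-")), "gene without strand in %s", path)

  ti <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- setNames(parent[ti], ids[ti])
  ei <- which(type == "exon")
  .assert(!any(is.na(parent[ei])), "exon without parent")
  # resolve exon parent: transcript id or gene id
  ex_parent <- parent[ei]
  ex_tx <- ifelse(ex_parent %in% names(tx2gene), ex_parent, NA_character_)
  ex_gene <- ifelse(is.na(ex_tx), ex_parent, unname(tx2gene[ex_tx]))
  .assert(all(ex_gene %in% genes$gene_id), "exon without parent gene")
  ex <- data.frame(gene_id = ex_gene, tx = ifelse(is.na(ex_tx), ex_gene, ex_tx),
                   chrom = as.character(GenomicRanges::seqnames(gr))[ei],
                   start = GenomicRanges::start(gr)[ei],
                   end = GenomicRanges::end(gr)[ei])

  # longest transcript (summed exon width) per gene defines E1..En
  ex$w <- ex$end - ex$start + 1
  txw <- tapply(ex$w, ex$tx, sum)
  best <- tapply(seq_len(nrow(ex)), ex$gene_id, function(idx) {
    txs <- unique(ex$tx[idx])
    txs[which.max(txw[txs])]
  })
  main_ex <- ex[ex$tx %in% unlist(best), c("gene_id", "chrom", "start", "end")]

  # exonic union over all transcripts
  gru <- .as_granges(ex)
  red <- GenomicRanges::reduce(S4Vectors::splitAsList(gru, ex$gene_id))
  exon_union <- do.call(rbind, lapply(names(red), function(g) {
    r <- red[[g]]
    data.frame(gene_id = g, chrom = ex$chrom[match(g, ex$gene_id)],
               start = GenomicRanges::start(r), end = GenomicRanges::end(r))
  }))

  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) {
    # fall back to ##sequence-region pragmas, then to the annotation extent
    prag <- grep("^##sequence-region", readLines(path, n = 500L), value = TRUE)
    if (length(prag)) {
      parts <- strsplit(trimws(prag), "\\s+")
      sl <- setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                     vapply(parts, `[`, "", 2))
    } else {
      sl <- tapply(GenomicRanges::end(gr), as.character(GenomicRanges::seqnames(gr)), max)
      sl <- setNames(as.numeric(sl), names(sl))
    }
  }
  genome_annotation(genes, main_ex, sl, exon_union = exon_union)
}

#' Write a genome annotation as GFF3
#'
#' Emits gene, mRNA and exon features (one transcript per gene, the
#' stored E1..En chain) with `##sequence-region` pragmas, readable by
#' [read_annotation()].
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  rows <- list()
  rows$gene <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                      strand = g$strand, type = "gene", ID = g$gene_id,
                                      Parent = NA_character_)
  rows$mrna <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                      strand = g$strand, type = "mRNA",
                                      ID = paste0(g$gene_id, ".t1"), Parent = g$gene_id)
  est <- g$strand[match(e$gene_id, g$gene_id)]
  rows$exon <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                      strand = est, type = "exon",
                                      ID = paste0(e$gene_id, ".e", e$rank),
                                      Parent = paste0(e$gene_id, ".t1"))
  gr <- c(rows$gene, rows$mrna, rows$exon)
  sl <- annotation$chrom_lengths
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- as.integer(sl)
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit sequence-region pragmas; add them so the
  # round-trip preserves chromosome lengths
  lines <- readLines(path)
  prag <- sprintf("##sequence-region %s 1 %d", names(sl), as.integer(sl))
  writeLines(c(lines[1], prag, lines[-1]), path)
  invisible(path)
}

#' Feature table of gene spans
#'
#' Gene spans as a `feature_id`/`chrom`/`start`/`end` table, the input
#' shape [feature_methylation()] expects.
#'
#' @param annotation a [genome_annotation].
#' @return data.frame with one row per gene.
#' @export
gene_feature_table <- function(annotation) {
  data.frame(feature_id = annotation$genes$gene_id,
             chrom = annotation$genes$chrom,
             start = annotation$genes$start,
             end = annotation$genes$end)
}
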