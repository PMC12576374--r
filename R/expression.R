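# Expression quantification ingestion, expressed/not-expressed calling,
# DEG table accounting and replicate QC.

#' FPKM from raw counts
#'
#' fpkm = count / (gene length in kb x library size in millions).
#'
#' @param counts numeric matrix genes x samples (or vector).
#' @param gene_lengths bp, recycled over genes; all > 0.
#' @param library_sizes total mapped fragments per sample.
#' @return matrix (or vector) of FPKM values.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes) {
  .assert(all(gene_lengths > 0), "zero gene length")
  .assert(all(library_sizes > 0), "zero library size")
  if (is.matrix(counts)) {
    sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, `/`)
  } else {
    counts / (gene_lengths / 1e3) / (library_sizes / 1e6)
  }
}

#' Binary expression status
#'
#' "not expressed" means a summary FPKM of 1 or below; strictly above
#' the threshold is "expressed".
#'
#' @param summary_fpkm numeric (vectorised; `NA` passes through).
#' @param threshold default 1.
#' @return character vector `"expressed"` / `"not expressed"`.
#' @export
expression_status <- function(summary_fpkm, threshold = 1) {
  ifelse(is.na(summary_fpkm), NA_character_,
         ifelse(summary_fpkm > threshold, "expressed", "not expressed"))
}

#' Replicate quality control
#'
#' Pearson correlations and PCA on log2(FPKM + 1); a replicate is
#' flagged when its median correlation with the other members of its
#' group falls below `cor_floor`. Flagging is advisory: exclusion is a
#' configuration action, never automatic.
#'
#' @param expr matrix genes x replicates of FPKM.
#' @param groups group label per replicate (stage); default one group.
#' @param cor_floor flagging threshold; default 0.8.
#' @return list `correlations` (replicate x replicate), `pca` (replicate
#'   scores, PC1/PC2), `flagged` (named logical); `NULL` with a warning
#'   when fewer than 2 replicates.
#' @export
replicate_qc <- function(expr, groups = rep("all", ncol(expr)), cor_floor = 0.8) {
  if (ncol(expr) < 2) {
    warning("fewer than 2 replicates; QC skipped")
    return(NULL)
  }
  lx <- log2(expr + 1)
  cc <- cor(lx, method = "pearson")
  keep <- apply(lx, 1, stats::var) > 0
  scores <- if (any(keep)) {
    pc <- prcomp(t(lx[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  } else NULL                      # identical replicates: no variation to project
  flagged <- vapply(seq_len(ncol(expr)), function(j) {
    mates <- which(groups == groups[j] & seq_len(ncol(expr)) != j)
    if (!length(mates)) return(FALSE)
    median(cc[j, mates]) < cor_floor
  }, TRUE)
  names(flagged) <- colnames(expr) %||% paste0("rep", seq_len(ncol(expr)))
  list(correlations = cc, pca = scores, flagged = flagged)
}

#' Differential-expression accounting
#'
#' Counts significant genes (adjusted p < `alpha`) and splits them by
#' direction: `up` means higher expression in the comparison stage
#' (adult, log2FC > 0), `down` means higher in the reference (embryo).
#'
#' @param deg_table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param alpha default 0.05.
#' @return named numeric `total`, `up`, `down` (total = up + down).
#' @export
deg_accounting <- function(deg_table, alpha = 0.05) {
  sig <- !is.na(deg_table$padj) & deg_table$padj < alpha
  up <- sum(sig & deg_table$log2fc > 0)
  down <- sum(sig & deg_table$log2fc < 0)
  c(total = up + down, up = up, down = down)
}

#' Significant DEG gene sets by direction
#' @param deg_table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param alpha default 0.05.
#' @return list `up`, `down` of gene-id vectors.
#' @export
deg_gene_sets <- function(deg_table, alpha = 0.05) {
  sig <- !is.na(deg_table$padj) & deg_table$padj < alpha
  list(up = deg_table$gene_id[sig & deg_table$log2fc > 0],
       down = deg_table$gene_id[sig & deg_table$log2fc < 0])
}
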