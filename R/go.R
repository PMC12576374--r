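# Classic Fisher GO-term enrichment with Benjamini-Hochberg correction
# and a gene-ratio summary per term.

#' GO term enrichment by one-sided Fisher's exact test
#'
#' For every term annotated to at least one subset gene, tests
#' enrichment of the term in the subset against the universe via the
#' one-sided (upper-tail) hypergeometric probability of the 2x2 table
#' (in/out of subset x with/without term); p-values are BH-adjusted
#' across tested terms. Gene ratio is the percent of all universe genes
#' carrying the term that fall inside the subset.
#'
#' @param subset gene ids, a subset of `universe`.
#' @param universe all annotated genes under consideration.
#' @param gene2go data.frame with columns `gene_id`, `term` (direct
#'   annotations; one row per pair).
#' @return data.frame `term`, `n_subset` (subset genes with term),
#'   `n_universe` (universe genes with term), `p_fisher`, `q_bh`,
#'   `gene_ratio` (percent), sorted by `q_bh`, `p_fisher`, `term`.
#' @export
go_fisher <- function(subset, universe, gene2go) {
  universe <- unique(universe)
  subset <- unique(subset)
  .assert(all(subset %in% universe), "subset is not contained in universe")
  g2g <- gene2go[gene2go$gene_id %in% universe, , drop = FALSE]
  term_genes <- split(g2g$gene_id, g2g$term)
  N <- length(universe)
  n <- length(subset)
  rows <- lapply(names(term_genes), function(tm) {
    tg <- unique(term_genes[[tm]])
    k <- length(base::intersect(tg, subset))
    if (k == 0) return(NULL)   # terms absent from the subset are not tested
    K <- length(tg)
    data.frame(term = tm, n_subset = k, n_universe = K,
               p_fisher = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               gene_ratio = 100 * k / K, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term = character(), n_subset = integer(),
                      n_universe = integer(), p_fisher = numeric(),
                      q_bh = numeric(), gene_ratio = numeric()))
  }
  res <- do.call(rbind, rows)
  res$q_bh <- p.adjust(res$p_fisher, method = "BH")
  res <- res[order(res$q_bh, res$p_fisher, res$term),
             c("term", "n_subset", "n_universe", "p_fisher", "q_bh", "gene_ratio")]
  rownames(res) <- NULL
  res
}

#' Most significant GO terms
#'
#' @param results a [go_fisher()] table.
#' @param n number of terms to keep; default 40.
#' @return the first `n` rows after sorting by `q_bh`, then `p_fisher`,
#'   then term id (deterministic under ties).
#' @export
top_terms <- function(results, n = 40) {
  o <- order(results$q_bh, results$p_fisher, results$term)
  head(results[o, , drop = FALSE], n)
}
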