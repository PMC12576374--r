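# Four-way methylation x expression classification, stage-transition
# accounting, per-category summaries, methylation-expression regression
# and hypergeometric set-overlap tests.

#' Four-way gene category
#'
#' Crosses binary methylation status with binary expression status into
#' the four mutually exclusive categories, e.g. `"methylated/expressed"`.
#'
#' @param meth_status `"methylated"` / `"not methylated"` (vectorised).
#' @param expr_status `"expressed"` / `"not expressed"`.
#' @return character vector of categories; `NA` where either status is
#'   `NA`.
#' @export
classify_four_sets <- function(meth_status, expr_status) {
  ifelse(is.na(meth_status) | is.na(expr_status), NA_character_,
         paste(meth_status, expr_status, sep = "/"))
}

#' Build a per-gene status table for one stage
#'
#' @param gene_ids consolidated gene ids.
#' @param mean_level per-gene mean methylation (percent), aligned.
#' @param summary_fpkm per-gene summary FPKM, aligned.
#' @param meth_threshold,fpkm_threshold status thresholds (10, 1).
#' @return data.frame `gene_id`, `mean_level`, `summary_fpkm`,
#'   `meth_status`, `expr_status`, `category`.
#' @export
gene_status_table <- function(gene_ids, mean_level, summary_fpkm,
                              meth_threshold = 10, fpkm_threshold = 1) {
  ms <- methylation_status(mean_level, meth_threshold)
  es <- expression_status(summary_fpkm, fpkm_threshold)
  data.frame(gene_id = gene_ids, mean_level = mean_level,
             summary_fpkm = summary_fpkm, meth_status = ms, expr_status = es,
             category = classify_four_sets(ms, es), stringsAsFactors = FALSE)
}

#' Stage-transition accounting
#'
#' Cross-tabulates the four-way categories between two stages (all 16
#' flows) and derives the marginal story: genes becoming active or
#' inactive, gaining or losing methylation, and maintaining methylation
#' status. Genes with an undefined status in either stage are excluded
#' and reported.
#'
#' @param status_embryo,status_adult [gene_status_table()] outputs over
#'   the same gene universe.
#' @return list of class `transition_summary`: `flows` (4x4 count
#'   matrix), `flows_long` (source, target, count), `marginals` (named
#'   counts incl. `n`, `become_active`, `become_inactive`,
#'   `gain_methylation`, `lose_methylation`, `maintain_methylation`,
#'   `expressed_embryo`, `expressed_adult`, `changers`), `percent`
#'   (marginals as percent of the universe), `n_excluded`.
#' @export
transition_counts <- function(status_embryo, status_adult) {
  m <- match(status_embryo$gene_id, status_adult$gene_id)
  .assert(!any(is.na(m)), "stage tables cover different gene sets")
  a <- status_adult[m, ]
  e <- status_embryo
  ok <- !is.na(e$category) & !is.na(a$category)
  n_excl <- sum(!ok)
  e <- e[ok, ]; a <- a[ok, ]
  lev <- c("not methylated/not expressed", "not methylated/expressed",
           "methylated/not expressed", "methylated/expressed")
  flows <- table(factor(e$category, levels = lev), factor(a$category, levels = lev))
  fl <- as.data.frame(flows, stringsAsFactors = FALSE)
  names(fl) <- c("source", "target", "count")
  n <- nrow(e)
  marg <- c(
    n = n,
    expressed_embryo = sum(e$expr_status == "expressed"),
    expressed_adult = sum(a$expr_status == "expressed"),
    become_active = sum(e$expr_status == "not expressed" & a$expr_status == "expressed"),
    become_inactive = sum(e$expr_status == "expressed" & a$expr_status == "not expressed"),
    gain_methylation = sum(e$meth_status == "not methylated" & a$meth_status == "methylated"),
    lose_methylation = sum(e$meth_status == "methylated" & a$meth_status == "not methylated"),
    maintain_methylation = sum(e$meth_status == a$meth_status))
  marg["changers"] <- marg[["become_active"]] + marg[["become_inactive"]]
  pct <- 100 * marg / n
  pct["n"] <- 100
  structure(list(flows = unclass(flows), flows_long = fl, marginals = marg,
                 percent = pct, n_excluded = n_excl),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  m <- x$marginals
  cat(sprintf("transition_summary over %d genes\n", m[["n"]]))
  cat(sprintf("  expressed: %d (%.1f%%) embryo -> %d (%.1f%%) adult\n",
              m[["expressed_embryo"]], x$percent[["expressed_embryo"]],
              m[["expressed_adult"]], x$percent[["expressed_adult"]]))
  cat(sprintf("  %d change expression status (%d become active, %d inactive)\n",
              m[["changers"]], m[["become_active"]], m[["become_inactive"]]))
  cat(sprintf("  methylation: %.1f%% lose, %.1f%% gain, %.1f%% maintain\n",
              x$percent[["lose_methylation"]], x$percent[["gain_methylation"]],
              x$percent[["maintain_methylation"]]))
  invisible(x)
}

#' Per-category gene counts and length statistics
#'
#' @param status a [gene_status_table()].
#' @param annotation a [genome_annotation] providing gene spans.
#' @return data.frame `category`, `n_genes`, `mean_length`, `sd_length`
#'   (bp; `NA` for empty categories, `sd` `NA` for singletons).
#' @export
category_stats <- function(status, annotation) {
  len <- with(annotation$genes, end - start + 1)[match(status$gene_id,
                                                       annotation$genes$gene_id)]
  lev <- c("not methylated/not expressed", "not methylated/expressed",
           "methylated/not expressed", "methylated/expressed")
  do.call(rbind, lapply(lev, function(k) {
    v <- len[!is.na(status$category) & status$category == k]
    data.frame(category = k, n_genes = length(v),
               mean_length = if (length(v)) mean(v) else NA_real_,
               sd_length = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Gene-body methylation vs expression regression
#'
#' Ordinary least squares of log10(FPKM) on mean gene-body methylation
#' over the methylated/expressed subset; zero FPKM or zero methylation
#' values are removed before the log transform.
#'
#' @param status a [gene_status_table()] (any stage); rows outside the
#'   methylated/expressed category are dropped.
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
gbm_expression_regression <- function(status) {
  d <- status[!is.na(status$category) &
                status$category == "methylated/expressed" &
                status$summary_fpkm > 0 & status$mean_level > 0, ]
  .assert(nrow(d) >= 3, "need >= 3 methylated/expressed genes with nonzero values")
  fit <- lm(log10(summary_fpkm) ~ mean_level, data = d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = sm$coefficients[2, 4], n = nrow(d))
}

#' Upper-tail hypergeometric overlap probability
#'
#' P(X >= k) for the overlap of two gene sets of sizes |A| and |B| drawn
#' from a universe of size N (the `phyper` upper-tail convention used
#' for enrichment overlap tests).
#'
#' @param k observed overlap.
#' @param size_a,size_b set sizes.
#' @param n_universe universe size.
#' @return probability in (0, 1\].
#' @export
hyper_overlap_p <- function(k, size_a, size_b, n_universe) {
  .assert(size_a <= n_universe && size_b <= n_universe, "set larger than universe")
  phyper(k - 1, size_a, n_universe - size_a, size_b, lower.tail = FALSE)
}

#' DMR x DEG direction-pair overlap tests
#'
#' For each pairing of differentially methylated gene sets (hypo/hyper)
#' with differentially expressed sets (up/down), the enrichment
#' (upper-tail hypergeometric) probability of at least the observed
#' overlap given the universe. Depletion is reported descriptively via
#' the expected overlap.
#'
#' @param dmr_gene_sets named list (e.g. `hypo`, `hyper`) of gene-id
#'   vectors.
#' @param deg_gene_sets named list (e.g. `up`, `down`).
#' @param universe gene-id vector containing all sets.
#' @return data.frame `dmr_set`, `deg_set`, `n_a`, `n_b`, `overlap`,
#'   `expected`, `p_enrich`.
#' @export
dmr_deg_overlap <- function(dmr_gene_sets, deg_gene_sets, universe) {
  universe <- unique(universe)
  n <- length(universe)
  combos <- expand.grid(dmr_set = names(dmr_gene_sets),
                        deg_set = names(deg_gene_sets),
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    a <- base::intersect(dmr_gene_sets[[combos$dmr_set[i]]], universe)
    b <- base::intersect(deg_gene_sets[[combos$deg_set[i]]], universe)
    k <- length(base::intersect(a, b))
    data.frame(dmr_set = combos$dmr_set[i], deg_set = combos$deg_set[i],
               n_a = length(a), n_b = length(b), overlap = k,
               expected = length(a) * length(b) / n,
               p_enrich = hyper_overlap_p(k, length(a), length(b), n),
               stringsAsFactors = FALSE)
  }))
}

#' Methylation change vs embryonic level
#'
#' Per-gene change (adult minus embryo, percentage points) binned by the
#' embryonic level into `n_bins` equal-width bins over \[0, 100\].
#'
#' @param embryo_levels,adult_levels aligned per-gene mean levels.
#' @param n_bins default 10.
#' @return data.frame `bin_low`, `bin_high`, `mean_change`, `n_genes`.
#' @export
methylation_change_profile <- function(embryo_levels, adult_levels, n_bins = 10) {
  ok <- !is.na(embryo_levels) & !is.na(adult_levels)
  e <- embryo_levels[ok]; d <- adult_levels[ok] - e
  br <- seq(0, 100, length.out = n_bins + 1)
  bin <- pmin(findInterval(e, br, rightmost.closed = TRUE), n_bins)
  data.frame(bin_low = br[-length(br)], bin_high = br[-1],
             mean_change = vapply(seq_len(n_bins), function(b) {
               v <- d[bin == b]
               if (length(v)) mean(v) else NA_real_
             }, 0),
             n_genes = vapply(seq_len(n_bins), function(b) sum(bin == b), 0L))
}
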