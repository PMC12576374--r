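# Differentially methylated region calling between two developmental
# stages: coverage-window input filter, recursive mean-difference
# segmentation, Mann-Whitney testing with Benjamini-Hochberg control,
# and genic-feature annotation of the calls.

#' Build the DMR input matrix
#'
#' Restricts to CpGs whose coverage lies in `[min_cov, max_cov]`
#' (inclusive) in every sample of both groups, and assembles per-CpG
#' methylation levels (percent) as a sites-by-samples matrix.
#'
#' @param samples named list of per-sample CpG record data.frames
#'   ([read_cytosine_report()] layout).
#' @param groups character/factor of length `length(samples)` assigning
#'   each sample to one of exactly two groups; the first level is the
#'   reference (embryo) and the second the comparison (adult) so that
#'   differences read comparison minus reference.
#' @param min_cov,max_cov inclusive coverage window; defaults 5 and 100.
#' @return list of class `dmr_input`: `sites` (data.frame `chrom`,
#'   `pos`, genomic order), `levels` (matrix sites x samples), `groups`.
#' @export
dmr_input_filter <- function(samples, groups, min_cov = 5, max_cov = 100) {
  # first-appearing group is the reference; do not let factor() re-sort
  groups <- factor(groups, levels = unique(as.character(groups)))
  .assert(nlevels(groups) == 2, "exactly two groups required")
  .assert(all(table(groups) >= 1), "each group needs at least one replicate")
  .assert(length(samples) == length(groups), "one group label per sample")

  keys <- lapply(samples, function(s) paste(s$chrom, s$pos))
  common <- Reduce(intersect, keys)
  lev <- cov_ok <- NULL
  levels_m <- matrix(NA_real_, nrow = length(common), ncol = length(samples))
  ok <- rep(TRUE, length(common))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    idx <- match(common, keys[[j]])
    cv <- s$count_meth[idx] + s$count_unmeth[idx]
    ok <- ok & cv >= min_cov & cv <= max_cov
    levels_m[, j] <- 100 * s$count_meth[idx] / cv
  }
  first <- samples[[1]]
  idx1 <- match(common, keys[[1]])
  sites <- data.frame(chrom = first$chrom[idx1], pos = first$pos[idx1],
                      stringsAsFactors = FALSE)
  sites <- sites[ok, , drop = FALSE]
  levels_m <- levels_m[ok, , drop = FALSE]
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  levels_m <- levels_m[o, , drop = FALSE]
  rownames(sites) <- NULL
  colnames(levels_m) <- names(samples) %||% paste0("s", seq_along(samples))
  structure(list(sites = sites, levels = levels_m, groups = groups),
            class = "dmr_input")
}

# per-site group-mean difference, second group minus first
.site_diffs <- function(input) {
  g <- input$groups
  rowMeans(input$levels[, g == levels(g)[2], drop = FALSE]) -
    rowMeans(input$levels[, g == levels(g)[1], drop = FALSE])
}

#' Segment CpG runs into candidate differential regions
#'
#' CpGs are first broken into runs at inter-CpG gaps larger than
#' `max_gap` bp. Within each run, recursive binary splitting places a
#' breakpoint where the two children's mean differences diverge most
#' (maximising |m1 - m2|); a split is accepted while both children keep
#' at least `min_cpgs` CpGs and the larger child |mean difference|
#' exceeds the parent's. Leaves whose |mean difference| reaches
#' `min_diff` percentage points become candidates.
#'
#' @param input a `dmr_input` from [dmr_input_filter()].
#' @param max_gap run-breaking gap in bp; default 300.
#' @param min_cpgs minimum CpGs per candidate; default 10.
#' @param min_diff minimum |mean difference| in percentage points;
#'   default 10.
#' @return data.frame `chrom`, `start`, `end` (1-based closed span of
#'   member CpGs), `n_cpgs`, `mean_diff`, plus hidden site index bounds
#'   used by [test_dmrs()].
#' @export
segment_candidates <- function(input, max_gap = 300, min_cpgs = 10, min_diff = 10) {
  sites <- input$sites
  d <- .site_diffs(input)
  out <- list()
  if (nrow(sites) == 0) return(.empty_candidates())

  # runs: same chromosome, gaps <= max_gap
  new_run <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)] |
                 diff(sites$pos) > max_gap)
  run_id <- cumsum(new_run)

  for (r in split(seq_len(nrow(sites)), run_id)) {
    if (length(r) < min_cpgs) next
    stack <- list(c(r[1], r[length(r)]))
    while (length(stack)) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- seg[1]; b <- seg[2]
      n <- b - a + 1
      dv <- d[a:b]
      parent_md <- mean(dv)
      split_at <- NA_integer_
      if (n >= 2 * min_cpgs) {
        cs <- cumsum(dv)
        k <- min_cpgs:(n - min_cpgs)     # size of left child
        m1 <- cs[k] / k
        m2 <- (cs[n] - cs[k]) / (n - k)
        best <- which.max(abs(m1 - m2))
        if (max(abs(m1[best]), abs(m2[best])) > abs(parent_md) + 1e-12) {
          split_at <- a + k[best] - 1
        }
      }
      if (!is.na(split_at)) {
        stack[[length(stack) + 1]] <- c(a, split_at)
        stack[[length(stack) + 1]] <- c(split_at + 1, b)
      } else if (n >= min_cpgs && abs(parent_md) >= min_diff) {
        out[[length(out) + 1]] <- data.frame(
          chrom = sites$chrom[a], start = sites$pos[a], end = sites$pos[b],
          n_cpgs = n, mean_diff = parent_md, i_from = a, i_to = b,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_cpgs = integer(), mean_diff = numeric(),
             i_from = integer(), i_to = integer(), stringsAsFactors = FALSE)
}

#' Test candidate regions and call DMRs
#'
#' Each candidate is tested with a two-sided Mann-Whitney U comparing
#' the two groups' pooled per-CpG level observations (replicate x CpG)
#' within the region. Because candidates are segments selected for a
#' mean difference of at least `min_diff`, the test is taken against
#' the effect-threshold null that the groups differ by exactly
#' `min_diff` points (the comparison group is shifted by the signed
#' threshold before ranking); a plain no-difference null would be
#' selection-biased and lose type-I control over noise-born candidates.
#' P-values are Benjamini-Hochberg adjusted across all candidates. A
#' region is a DMR when q < `alpha` and it satisfies the region
#' criteria (at least `min_cpgs` CpGs, |mean difference| of at least
#' `min_diff` points). Direction is `hypo` when the comparison group
#' (adult) is lower, `hyper` when higher.
#'
#' @param candidates from [segment_candidates()].
#' @param input the matching `dmr_input` (needs >= 2 replicates per
#'   group).
#' @param alpha BH-adjusted significance level; default 0.05.
#' @param min_cpgs,min_diff region criteria re-asserted on output;
#'   defaults 10 and 10.
#' @return data.frame `chrom`, `start`, `end`, `n_cpgs`, `mean_diff`,
#'   `p_raw`, `q_bh`, `direction`, sorted by genomic position.
#' @export
test_dmrs <- function(candidates, input, alpha = 0.05, min_cpgs = 10, min_diff = 10) {
  g <- input$groups
  .assert(all(table(g) >= 2), "need >= 2 replicates per group for testing")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), mean_diff = numeric(), p_raw = numeric(),
                      q_bh = numeric(), direction = character(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) return(empty)
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  p <- vapply(seq_len(nrow(candidates)), function(i) {
    rows <- candidates$i_from[i]:candidates$i_to[i]
    x <- as.vector(input$levels[rows, i1])
    y <- as.vector(input$levels[rows, i2])
    if (all(c(x, y) == c(x, y)[1])) return(1)    # constant data: no evidence
    # effect-threshold null: undo a min_diff-point shift before ranking
    y0 <- y - sign(candidates$mean_diff[i]) * min_diff
    suppressWarnings(wilcox.test(x, y0, exact = FALSE)$p.value)
  }, 0)
  # deterministic order before adjustment; BH itself is order-invariant
  q <- p.adjust(p, method = "BH")
  keep <- q < alpha & candidates$n_cpgs >= min_cpgs &
    abs(candidates$mean_diff) >= min_diff
  res <- data.frame(chrom = candidates$chrom, start = candidates$start,
                    end = candidates$end, n_cpgs = candidates$n_cpgs,
                    mean_diff = candidates$mean_diff, p_raw = p, q_bh = q,
                    direction = ifelse(candidates$mean_diff < 0, "hypo", "hyper"),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate DMRs by genic feature class
#'
#' Classifies each region as `exon_only`, `intron_only`, `exon_intron`
#' (overlapping both feature types) or `intergenic` (no gene overlap),
#' and summarises counts per class and direction plus the genic vs
#' intergenic fractions.
#'
#' @param dmrs [test_dmrs()] output.
#' @param annotation a [genome_annotation].
#' @return list: `dmrs` (input with a `feature_class` column), `counts`
#'   (class x direction), `fractions` (per direction, percent genic /
#'   intergenic).
#' @export
annotate_dmrs <- function(dmrs, annotation) {
  if (nrow(dmrs) == 0) {
    return(list(dmrs = cbind(dmrs, feature_class = character(0)),
                counts = data.frame(), fractions = data.frame()))
  }
  dgr <- .as_granges(dmrs)
  exon_gr <- GenomicRanges::reduce(.as_granges(annotation$exon_union))
  gene_gr <- GenomicRanges::reduce(.as_granges(
    data.frame(chrom = annotation$genes$chrom, start = annotation$genes$start,
               end = annotation$genes$end)))
  intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)
  has_ex <- GenomicRanges::countOverlaps(dgr, exon_gr) > 0
  has_in <- GenomicRanges::countOverlaps(dgr, intron_gr) > 0
  genic <- GenomicRanges::countOverlaps(dgr, gene_gr) > 0
  cls <- ifelse(!genic, "intergenic",
                ifelse(has_ex & has_in, "exon_intron",
                       ifelse(has_ex, "exon_only", "intron_only")))
  dmrs$feature_class <- cls
  counts <- as.data.frame.matrix(table(factor(cls, levels = c("exon_only",
    "intron_only", "exon_intron", "intergenic")), dmrs$direction))
  fr <- do.call(rbind, lapply(split(genic, dmrs$direction), function(gv) {
    data.frame(pct_genic = 100 * mean(gv), pct_intergenic = 100 * mean(!gv))
  }))
  list(dmrs = dmrs, counts = counts, fractions = fr)
}

#' Tally DMRs by direction
#'
#' @param dmrs [test_dmrs()] output (needs a `direction` column).
#' @return named numeric: `total`, `hypo`, `hyper`.
#' @export
dmr_accounting <- function(dmrs) {
  c(total = nrow(dmrs),
    hypo = sum(dmrs$direction == "hypo"),
    hyper = sum(dmrs$direction == "hyper"))
}

#' Write DMRs as BED6 (name = direction, score = -log10 q)
#' @param dmrs [test_dmrs()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                       end = dmrs$end, name = dmrs$direction,
                       score = round(-log10(pmax(dmrs$q_bh, 1e-300)), 4),
                       strand = "."), path)
}
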