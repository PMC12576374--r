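# Metagene (scale-regions), anchored and genic-segment profiles of
# methylation level or histone signal over gene sets.

# Transcription-ordered per-base genomic positions of a gene window:
# `flank` native bases upstream, `body` scaled bases over the gene
# (scaled base j takes the value of its pre-image base, mirrored on the
# minus strand), `flank` native bases downstream.
.gene_window_positions <- function(start, end, strand, body, flank) {
  L <- end - start + 1
  j <- seq_len(body)
  if (strand == "+") {
    c(seq(start - flank, start - 1),
      start + floor((j - 1) * L / body),
      seq(end + 1, end + flank))
  } else {
    c(seq(end + flank, end + 1),
      end - floor((j - 1) * L / body),
      seq(start - 1, start - flank))
  }
}

# scaled bin offset (1-based within body grid) of an original base index
# i0 (0-based, transcription direction) for gene length L
.scale_offset <- function(i0, L, body) floor((i0 + 0.5) * body / L) + 1

.is_track <- function(source) "value" %in% names(source)

#' Scaled metagene matrix
#'
#' deepTools-style scale-regions profile: each gene body is linearly
#' rescaled to `body` bp between fixed `flank` bp of native upstream and
#' downstream sequence, then averaged in `bin_size` bins. Rows are
#' transcription-oriented, so column 1 is always 5'-most. For a signal
#' track, bins hold the mean per-base value; for methylation calls,
#' bins hold the mean level of covered CpGs falling in the bin (`NA`
#' when none). Window bases beyond a chromosome end are `NA`.
#'
#' @param source a bedGraph-style track (`chrom,start,end,value`) or
#'   methylation calls (`chrom,pos,level`).
#' @param annotation a [genome_annotation].
#' @param genes gene ids to profile; default all.
#' @param body scaled body length in bp (default 5000).
#' @param flank flank length in bp (default 3000).
#' @param bin_size bp per bin (default 50); must divide `body` and
#'   `flank`.
#' @return numeric matrix genes x bins with gene-id rownames and a
#'   `regions` attribute giving each bin's segment (`upstream`, `body`,
#'   `downstream`).
#' @export
metagene_matrix <- function(source, annotation, genes = NULL,
                            body = 5000, flank = 3000, bin_size = 50) {
  .assert(body %% bin_size == 0 && flank %% bin_size == 0,
          "bin_size must divide body and flank")
  g <- annotation$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  .assert(nrow(g) > 0, "no genes to profile")
  .assert(all(g$end >= g$start), "zero-length gene")
  nb_f <- flank %/% bin_size; nb_b <- body %/% bin_size
  nbin <- 2 * nb_f + nb_b
  mat <- matrix(NA_real_, nrow(g), nbin, dimnames = list(g$gene_id, NULL))
  track <- .is_track(source)
  if (track) {
    ti <- .track_internal(source)
    by_chrom <- split(ti, ti$chrom)
  } else {
    by_chrom_calls <- split(source, source$chrom)
  }
  sl <- annotation$chrom_lengths
  for (i in seq_len(nrow(g))) {
    L <- g$end[i] - g$start[i] + 1
    chrom <- g$chrom[i]
    clen <- unname(sl[chrom])
    if (track) {
      pos <- .gene_window_positions(g$start[i], g$end[i], g$strand[i], body, flank)
      v <- numeric(length(pos))
      tc <- by_chrom[[chrom]]
      v <- if (is.null(tc)) numeric(length(pos)) else .track_values_at(tc, pos)
      v[pos < 1 | (!is.na(clen) & pos > clen)] <- NA_real_
      mat[i, ] <- colMeans(matrix(v, nrow = bin_size))
    } else {
      calls <- by_chrom_calls[[chrom]]
      if (is.null(calls)) next
      w_lo <- g$start[i] - flank; w_hi <- g$end[i] + flank
      cc <- calls[calls$pos >= w_lo & calls$pos <= w_hi, , drop = FALSE]
      if (nrow(cc) == 0) next
      if (g$strand[i] == "+") {
        up <- cc$pos < g$start[i]
        dn <- cc$pos > g$end[i]
        off <- integer(nrow(cc))
        off[up] <- cc$pos[up] - w_lo + 1
        bd <- !up & !dn
        off[bd] <- flank + .scale_offset(cc$pos[bd] - g$start[i], L, body)
        off[dn] <- flank + body + (cc$pos[dn] - g$end[i])
      } else {
        up <- cc$pos > g$end[i]
        dn <- cc$pos < g$start[i]
        off <- integer(nrow(cc))
        off[up] <- w_hi - cc$pos[up] + 1
        bd <- !up & !dn
        off[bd] <- flank + .scale_offset(g$end[i] - cc$pos[bd], L, body)
        off[dn] <- flank + body + (g$start[i] - cc$pos[dn])
      }
      bin <- ceiling(off / bin_size)
      mat[i, ] <- vapply(seq_len(nbin), function(b) {
        v <- cc$level[bin == b]
        if (length(v)) mean(v) else NA_real_
      }, 0)
    }
  }
  attr(mat, "regions") <- rep(c("upstream", "body", "downstream"),
                              c(nb_f, nb_b, nb_f))
  attr(mat, "bin_size") <- bin_size
  mat
}

#' Anchored profile around TSS or TES
#'
#' Fixed, unscaled window of `flank` bp either side of the strand-aware
#' anchor, binned at `bin_size`. Bins extending beyond a chromosome end
#' are `NA` (missing, flagged).
#'
#' @param source track or methylation calls (as in [metagene_matrix()]).
#' @param annotation a [genome_annotation].
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank half-window in bp (default 500).
#' @param bin_size default 50; must divide `flank`.
#' @param genes optional gene-id subset.
#' @return matrix genes x (2 * flank / bin_size) bins, transcription
#'   oriented (anchor sits between the two middle bins).
#' @export
anchored_profile <- function(source, annotation, anchor = c("TSS", "TES"),
                             flank = 500, bin_size = 50, genes = NULL) {
  anchor <- match.arg(anchor)
  .assert(flank %% bin_size == 0, "bin_size must divide flank")
  g <- annotation$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  .assert(nrow(g) > 0, "no genes to profile")
  apos <- if (anchor == "TSS") g$tss else g$tes
  nbin <- 2 * flank %/% bin_size
  mat <- matrix(NA_real_, nrow(g), nbin, dimnames = list(g$gene_id, NULL))
  track <- .is_track(source)
  if (track) {
    ti <- .track_internal(source)
    by_chrom <- split(ti, ti$chrom)
  } else {
    by_chrom_calls <- split(source, source$chrom)
  }
  sl <- annotation$chrom_lengths
  for (i in seq_len(nrow(g))) {
    chrom <- g$chrom[i]
    clen <- unname(sl[chrom])
    offsets <- seq_len(2 * flank)
    pos <- if (g$strand[i] == "+") apos[i] - flank + offsets - 1
           else apos[i] + flank - offsets + 1
    if (track) {
      tc <- by_chrom[[chrom]]
      v <- if (is.null(tc)) numeric(length(pos)) else .track_values_at(tc, pos)
      v[pos < 1 | (!is.na(clen) & pos > clen)] <- NA_real_
      mat[i, ] <- colMeans(matrix(v, nrow = bin_size))
    } else {
      calls <- by_chrom_calls[[chrom]]
      if (is.null(calls)) next
      cc <- calls[calls$pos >= min(pos) & calls$pos <= max(pos), , drop = FALSE]
      if (nrow(cc) == 0) next
      off <- if (g$strand[i] == "+") cc$pos - (apos[i] - flank) + 1
             else (apos[i] + flank) - cc$pos + 1
      bin <- ceiling(off / bin_size)
      mat[i, ] <- vapply(seq_len(nbin), function(b) {
        v <- cc$level[bin == b]
        if (length(v)) mean(v) else NA_real_
      }, 0)
    }
  }
  attr(mat, "anchor") <- anchor
  attr(mat, "bin_size") <- bin_size
  mat
}

#' Column-wise mean profile of a gene set
#'
#' @param mat a profile matrix ([metagene_matrix()] or
#'   [anchored_profile()]).
#' @param gene_set optional gene ids (default: all rows).
#' @return data.frame `bin`, `mean`, `se`, `n` (genes contributing per
#'   bin; missing cells ignored).
#' @export
set_mean_profile <- function(mat, gene_set = NULL) {
  m <- if (is.null(gene_set)) mat else mat[rownames(mat) %in% gene_set, , drop = FALSE]
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  s <- apply(m, 2, sd, na.rm = TRUE)
  data.frame(bin = seq_len(ncol(m)), mean = mu,
             se = ifelse(n > 1, s / sqrt(n), NA_real_), n = n)
}

#' Genic segment methylation profile
#'
#' Mean methylation of the upstream flank (U), the first `n_exons`
#' exons (E1..), the first `n_introns` introns (I1..) in transcription
#' order, and the downstream flank (D), per gene; segment means are
#' defined under the same >= `min_cpgs` covered-CpGs rule as
#' [feature_methylation()], and the set-level value averages genes where
#' the segment is defined (genes lacking a segment contribute nothing).
#'
#' @param calls [call_cpg_levels()] output.
#' @param annotation a [genome_annotation].
#' @param gene_set optional gene ids (default all).
#' @param flank U/D length in bp (default 3000).
#' @param n_exons,n_introns defaults 5 and 4.
#' @param min_cpgs default 3.
#' @return data.frame `segment`, `mean_level`, `n_genes` in the order
#'   U, E1, I1, E2, ..., D.
#' @export
segment_profile <- function(calls, annotation, gene_set = NULL, flank = 3000,
                            n_exons = 5, n_introns = 4, min_cpgs = 3) {
  g <- annotation$genes
  if (!is.null(gene_set)) g <- g[g$gene_id %in% gene_set, , drop = FALSE]
  .assert(nrow(g) > 0, "empty gene set")
  feats <- list()
  up_start <- ifelse(g$strand == "+", g$start - flank, g$end + 1)
  up_end <- ifelse(g$strand == "+", g$start - 1, g$end + flank)
  dn_start <- ifelse(g$strand == "+", g$end + 1, g$start - flank)
  dn_end <- ifelse(g$strand == "+", g$end + flank, g$start - 1)
  feats$U <- data.frame(feature_id = paste0(g$gene_id, "|U"), chrom = g$chrom,
                        start = pmax(1, up_start), end = up_end)
  feats$D <- data.frame(feature_id = paste0(g$gene_id, "|D"), chrom = g$chrom,
                        start = pmax(1, dn_start), end = dn_end)
  ex <- annotation$exons[annotation$exons$gene_id %in% g$gene_id &
                           annotation$exons$rank <= n_exons, ]
  feats$E <- data.frame(feature_id = paste0(ex$gene_id, "|E", ex$rank),
                        chrom = ex$chrom, start = ex$start, end = ex$end)
  intr <- annotation$introns[annotation$introns$gene_id %in% g$gene_id &
                               annotation$introns$rank <= n_introns, ]
  if (nrow(intr)) {
    feats$I <- data.frame(feature_id = paste0(intr$gene_id, "|I", intr$rank),
                          chrom = intr$chrom, start = intr$start, end = intr$end)
  }
  fm <- feature_methylation(calls, do.call(rbind, feats), min_cpgs = min_cpgs)
  seg <- sub("^.*\\|", "", fm$feature_id)
  seg_order <- c("U", as.vector(rbind(paste0("E", seq_len(n_exons)),
                                      c(paste0("I", seq_len(n_introns)),
                                        rep(NA, n_exons - n_introns)))), "D")
  seg_order <- seg_order[!is.na(seg_order)]
  do.call(rbind, lapply(seg_order, function(sname) {
    v <- fm$mean_level[seg == sname & fm$defined]
    data.frame(segment = sname,
               mean_level = if (length(v)) mean(v) else NA_real_,
               n_genes = length(v), stringsAsFactors = FALSE)
  }))
}
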