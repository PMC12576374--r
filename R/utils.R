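# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .stopf(fmt, ...)

# Beta-binomial draws parameterised by mean p and overdispersion rho in [0,1).
# rho = 0 collapses to the plain binomial; p = 0 or 1 is degenerate.
rbetabinom <- function(n, size, p, rho = 0) {
  p <- rep_len(p, n)
  size <- rep_len(size, n)
  out <- integer(n)
  degen <- rho <= 0 | p <= 0 | p >= 1
  degen <- rep_len(degen, n)
  if (any(degen)) {
    out[degen] <- rbinom(sum(degen), size[degen], p[degen])
  }
  if (any(!degen)) {
    a <- p[!degen] * (1 - rho) / rho
    b <- (1 - p[!degen]) * (1 - rho) / rho
    pp <- rbeta(sum(!degen), a, b)
    out[!degen] <- rbinom(sum(!degen), size[!degen], pp)
  }
  out
}

# GRanges from a 1-based closed data.frame with columns chrom, start, end.
.as_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(df[[chrom]], IRanges::IRanges(df[[start]], df[[end]]))
}

# Step-function lookup: value of a bedGraph-style track (1-based closed
# internal columns start1/end1) at 1-based positions on one chromosome.
# Positions not covered by any interval evaluate to 0.
.track_values_at <- function(track_chrom, pos) {
  if (nrow(track_chrom) == 0L) return(numeric(length(pos)))
  o <- order(track_chrom$start1)
  s <- track_chrom$start1[o]; e <- track_chrom$end1[o]; v <- track_chrom$value[o]
  i <- findInterval(pos, s)
  val <- numeric(length(pos))
  ok <- i > 0L
  ok[ok] <- pos[ok] <= e[i[ok]]
  val[ok] <- v[i[ok]]
  val
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
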