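# Shared in-code fixtures: a small hand-built annotation and record
# builders used across the unit tests.

toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(101, 1001, 2001),
    end = c(400, 1500, 2300))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gB", "gC"),
    chrom = "chr1",
    start = c(101, 301, 1001, 1201, 1401, 2001),
    end = c(200, 400, 1100, 1300, 1500, 2300))
  genome_annotation(genes, exons, c(chr1 = 5000))
}

toy_calls <- function(pos, level, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+",
             level = level, coverage = 10, stringsAsFactors = FALSE)
}

cpg_records <- function(pos, meth, unmeth, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+",
             count_meth = meth, count_unmeth = unmeth, stringsAsFactors = FALSE)
}

# upper-tail hypergeometric by direct summation of the sampling formula;
# independent of phyper
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg by the textbook formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  inter / ((a2 - a1 + 1) + (b2 - b1 + 1) - inter)
}
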