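---
title: "Methods: integrating gene-body methylation, expression and chromatin marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating gene-body methylation, expression and chromatin marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmix)
```

## The analysis in one paragraph

In many invertebrates, CpG methylation is concentrated in the bodies of
transcribed genes rather than acting as a silencing mark. gbmix implements a
complete desk-scale pipeline for studying this association across two
developmental stages: per-CpG methylation calling from enzymatic methyl-seq
(EM-seq) counts with spike-in conversion QC, aggregation to genes and genic
segments, a differentially-methylated-region (DMR) caller, expressed /
not-expressed calling from FPKM tables, a four-way methylation-by-expression
gene classification with stage-transition accounting, sparse-enrichment peak
consolidation for CUT&Tag histone tracks (H3K27ac, H3K36me3), metagene and
anchored profiles, and hypergeometric / Fisher gene-set tests. A synthetic
multiomics generator with a ground-truth sidecar makes every stage testable by
parameter recovery.

## Methylation model

A cytosine's methylation level is the percent of reads calling it methylated,
defined only at coverage >= 5 (`min_coverage`). A feature's level is the
*unweighted mean* of its covered CpGs, defined only with >= 3 CpGs
(`min_cpgs`); the consolidated gene set keeps genes defined in *every* sample
and is the universe for all categorical statements. Status thresholds are
strict on one side each: "not methylated" means a mean level strictly below
10%; "not expressed" means FPKM at or below 1. Conversion efficiency is 100
minus the pooled percent of methylated calls on the unmethylated Lambda
spike-in; reads on the control chromosomes never enter the analysis proper.

Genome-wide summaries report both readings of "percent of CpGs methylated" —
the mean per-CpG level and the fraction of covered CpGs at or above the 10%
status threshold — because the two differ and both are in circulation;
neither is privileged. Gene-level aggregation uses the full gene span
(exons + introns) by default: the TSS-dip and exon-versus-intron observations
both suggest span-level averaging, and per-segment means are available
separately through `segment_profile()`. CpG dyads are kept as separate
strand-wise sites (the Bismark convention); no dyad merging is performed.

## DMR calling

Input sites must have coverage in [5, 100] in all samples of both groups.
Sites are broken into runs at inter-CpG gaps above 300 bp (a standard
segmentation default, config-exposed), then recursively bisected: the split
point maximises the divergence |m1 - m2| of the children's mean adult-embryo
differences, and a split is accepted while both children keep >= 10 CpGs and
the larger child |mean difference| exceeds the parent's. Leaves with a mean
difference of at least 10 points become candidates.

Candidates are tested with a two-sided Mann-Whitney U on the pooled
replicate-by-CpG level observations. The null hypothesis is *not* "no
difference": candidates are selected precisely for |difference| >= 10 points,
so testing against zero difference with the same data is selection-biased —
in stage-null simulations virtually every noise-born candidate would survive
Benjamini-Hochberg. The test therefore takes the region criterion itself as
the null (groups differing by exactly the 10-point threshold, implemented by
shifting the comparison group by the signed threshold before ranking). With
this choice, measured null simulations call 0 of ~150 noise candidates while
planted 30-point regions are recovered with mean interval Jaccard ~0.93. A
region is reported when its BH-adjusted q is below 0.05 and it satisfies the
region criteria (>= 10 CpGs, >= 10-point difference); `hypo` means lower in
the adult. Ties in output ordering are broken by genomic position.

Regions are annotated as exon-only, intron-only, exon+intron, or intergenic
against the exon union over all transcripts; a region overlapping several
genic feature types counts only in the combined class.

## Expression, classification and association

FPKM is count / (kb x millions of mapped fragments). Stage status uses the
mean FPKM over retained replicates (median available by configuration);
replicate QC computes Pearson correlations and a PCA on log2(FPKM + 1) and
*flags* replicates whose median within-group correlation falls below 0.8 —
exclusion is always an explicit configuration action. Differential-expression
tables are consumed, not recomputed; "downregulated" means higher in the
embryo.

The four-way categories are the cross of the two binary statuses. Transition
accounting cross-tabulates all 16 embryo-to-adult flows; marginals
(activations, inactivations, methylation gain/loss/maintenance) reconcile by
construction and are also emitted as a long source/target/count table for
alluvial plotting. The methylation-expression association within
methylated/expressed genes is an ordinary least-squares fit of log10(FPKM) on
mean gene-body methylation after removing zeros. Set-overlap questions
(DMR-bearing x differentially expressed genes per direction pair; category x
histone-mark) use the upper-tail hypergeometric probability of at least the
observed overlap — enrichment only; depletion is reported descriptively via
the expected overlap.

## Peak consolidation and profiles

Coverage tracks are decomposed into maximal runs of positive signal
("blocks"), ranked by area under the curve, and the top 2.5% are retained per
replicate (ceiling rule; ties broken by maximum value then position). The
high-confidence set is the genomic space covered by at least one selected
peak in *every* replicate, merged — equivalent to pairwise
intersect-then-merge for two replicates, idempotent, and never outside the
input union. IgG-normalised thresholding is out of scope; the analysis layer
consumes only the top-fraction sets.

Metagene profiles rescale each gene body to 5 kb between fixed 3 kb flanks,
50 bp bins (220 columns); each scaled base takes the value of its pre-image
base, mirrored for minus-strand genes so column 1 is always 5'-most. Track
bins average per-base values; methylation bins average covered CpGs and stay
missing when none fall in a bin. Anchored profiles use an unscaled +/- 500 bp
window at the TSS or TES; window bases beyond a chromosome end are missing
and flagged. Segment profiles compute per-gene means for the upstream flank,
the first five exons and four introns in transcription order, and the
downstream flank, under the same >= 3-CpG rule; set means weight genes
equally (not by CpG count). Neighbouring genes are not masked from flanks.

## GO enrichment

Classic one-sided Fisher (hypergeometric) per term over direct annotations,
BH-adjusted across tested terms; terms absent from the subset are not tested.
The gene ratio is the percent of all universe genes carrying the term that
fall inside the subset. Parent-Child-style DAG weighting and ancestor
propagation are out of scope; the top-40 table is sorted by q, then p, then
term id.

## What the generator emulates — and what it does not

The synthetic dataset reproduces the *structure* the analysis assumes, at the
study's stated operating points: 2 stages x 3 methylome replicates (Poisson
coverage, default 30x; beta-binomial counts, overdispersion 0.1), 2 stages of
expression replicates, 2 CUT&Tag replicates x 2 marks, and Lambda/pUC19
spike-ins with a 0.45% conversion-failure rate (99.55% efficiency, middle of
the QC range such experiments report). Roughly 25% of genes are methylated
(uniform 10-70% plateau, longer genes more likely methylated), 36.5% are
expressed in the embryo with activation/inactivation rates chosen so ~44% are
expressed in the adult; 16.8% of methylated genes lose and 0.67% of
unmethylated genes gain methylation, plus a mild (<= 6-point) adult-ward
drift of maintained genes. Methylated/expressed genes carry a TSS dip (level
pinned near zero within +/- 200 bp); introns sit at 0.7x the exonic level.
H3K27ac is a Gaussian TSS bump on expressed genes; H3K36me3 ramps 5'-to-3'
over expressed bodies with exponential 3' decay (600 bp scale, sized to the
toy genome's ~3 kb intergenic gaps) and uniform enrichment on methylated
silent genes; a dense carpet of narrow low bumps emulates the block counts a
real genome feeds the top-fraction rule. Planted DMRs are 15-CpG, -30-point
adult shifts inside otherwise stage-stable methylated genes, placed clear of
the dip zone. Intergenic CpG density (0.003/bp) is low enough that
segmentation runs break between genes, as in CpG-poor intergenic space.

Not emulated: read-level artefacts (PCR duplicates, M-bias, mappability),
chromosome heterogeneity, repeat methylation classes, non-CpG contexts, and
any causal coupling between methylation change and expression change. Passing
recovery tests therefore demonstrates correctness of the estimators under the
assumed generative structure, not robustness to real-data artefacts.

## Numerical choices and degenerate inputs

All randomness flows from explicit seeds; fixed seeds give byte-identical
outputs. Coverage-zero spike-in controls yield a missing (not zero)
conversion efficiency. Constant data in a DMR candidate gives p = 1 by
convention. The segmentation tie-breaks at the first maximal split point;
top-fraction ties break by maximum value then genomic order; GO and BH ties
break by identifier and genomic order respectively, so every ranking is
deterministic. `simulate_methylome(noise = "none")` uses fixed coverage and
rounded expected counts, making gene means exactly recoverable whenever
coverage x level is integral — the basis of the exactness tests. Problem
sizes in the shipped tests (120-300 genes, ~1-2 Mb, 20-30k CpGs) keep the
full suite and the acceptance script within a few minutes on one core while
leaving every per-gene estimate well identified.

## Known limitations

The DMR caller is criteria-equivalent to, but not bit-compatible with,
segmentation tools built around circular binary segmentation; its
effect-threshold test trades sensitivity to sub-threshold differences (true
differences between 10 and ~20 points are conservatively missed at 3v3
replication) for honest type-I control after selection. Boundary resolution
of recovered regions is limited to roughly min_cpgs/2 CpGs on either side.
The expression layer consumes DE tables rather than refitting a count model.
Peak calling has no input-control normalisation, and the four-way
classification inherits every threshold's edge behaviour — genes sitting at
10% methylation or FPKM 1 flip categories under resampling noise.
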