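# gbmkit

Gene body methylation (GBM) — CpG methylation within the transcribed region
of a gene — is the dominant DNA methylation mode in most insects, and its
loss after knockdown of a maintenance DNA methyltransferase disrupts the
maternal-zygotic transition (MZT) of the early embryo. `gbmkit` is an R
package for the joint analysis of whole-genome bisulfite sequencing (WGBS)
and stage-resolved RNA-seq from such experiments. It is aimed at
epigenomics groups working on invertebrate methylomes who need the full
chain from per-CpG counts to methylome–transcriptome integration in one
tested, seedable toolkit — including a synthetic-data generator so every
stage can be exercised and calibrated without external data.

## What it computes

**Methylation calling.** At a CpG covered by `n` reads of which `k` read
methylated, the caller tests `k` against the bisulfite non-conversion rate
`e` (the probability an unmethylated C fails conversion and reads as
methylated) with an exact upper-tail binomial test,
`p = P(X >= k), X ~ Binomial(n, e)`. P-values are Benjamini–Hochberg
adjusted per sample, and sites with adjusted `p < 0.05` are methylated CpGs
(mCGs). Fractional methylation is `f = k/n`; a gene's value `F` is the mean
of `f` over its gene-body CpGs (exons and introns). Genes are classified
methylated by both conventions in use: at least one mCG, and `F >= 0.02`
(which exploits the strongly bimodal distribution of gene-level
methylation). Metagene profiles bin the first/last four exons and introns.

**Differential methylation.** Sites methylated in at least one control
sample are retained; per site a beta-binomial Wald test compares the two
conditions (method-of-moments dispersion, logit scale), falling back to a
two-sided Fisher exact test on pooled counts for degenerate sites; DM at
FDR 0.1. Per-mCG depletion `100 (f_ctrl − f_kd)/f_ctrl` and per-gene
relative GBM change `r_g = (F_kd − F_ctrl)/F_ctrl` summarise the loss.

**Differential expression.** Genes with maximum count ≤ 10 are filtered;
median-of-ratios size factors normalise libraries; each stage is tested as
a two-group negative-binomial Wald contrast (trend-shrunk method-of-moments
dispersions), DEGs at FDR 0.1; a 2-fold stage-transition analysis tracks
MZT dynamics.

**Integration.** DEGs are classified methylated/unmethylated, direction ×
methylation 2×2 tables are tested with an exact hypergeometric-enumeration
Fisher test, relative GBM change is rank-correlated (Spearman) with the
expression log2 fold change over methylated genes, group distributions are
compared by Welch's t, and mDEG trajectories are z-scored and
hierarchically clustered.

**Simulation.** `sim_config()` + `simulate_dataset()` generate gene models,
a bimodal true methylome with 5′-biased exon-enriched intragenic
methylation, binomial bisulfite read counts at ~15× Poisson coverage with
realistic non-conversion (~0.005), a mean 81.5% knockdown depletion, and a
four-stage NB expression course whose knockdown effects are coupled to
each gene's methylation loss.

## Worked example

The bundled demo config runs the whole pipeline on a synthetic knockdown
experiment (2,000 genes, ~40,000 CpGs, 4 stages × 2 conditions × 3
replicates) in well under a minute:

```r
library(gbmkit)
manifest <- run_all(system.file("extdata/demo_config.yaml", package = "gbmkit"),
                    out_dir = "demo_run")
res <- attr(manifest, "results")
print(res$gene_meth); print(res$depletion); print(res$report)
```

```
Gene-body methylation: 2000 genes (1997 with data); 642 methylated by F >= 0.02, 838 by >= 1 mCG
Mean per-mCG depletion: 80.2% (over 12030 sites); 95.2% of retained sites significantly reduced, 99.9% nominally reduced
Methylome-transcriptome integration report
  union DEGs: 760 (453 methylated / 305 unmethylated)
  egg: 0 DEGs; direction x methylation Fisher p = NA; rho(GBM change, log2FC) = -0.026 (p = 0.51, n = 641)
  early: 482 DEGs; direction x methylation Fisher p = 2.84e-130; rho(GBM change, log2FC) = 0.133 (p = 0.000711, n = 641)
  middle: 484 DEGs; direction x methylation Fisher p = 1.45e-120; rho(GBM change, log2FC) = 0.170 (p = 1.43e-05, n = 641)
  late: 420 DEGs; direction x methylation Fisher p = 7.53e-111; rho(GBM change, log2FC) = 0.111 (p = 0.00495, n = 641)
```

Reading the output: about a third of genes are gene-body methylated (the
0.02-threshold and ≥1-mCG rules bracket the class), knockdown strips ~80%
of methylation per mCG, the egg stage is untouched (the maternal transcript
pool predates zygotic transcription), and from the early blastoderm on,
down-regulated DEGs are overwhelmingly methylated while up-regulated ones
are unmethylated — with a positive rank correlation between how much
methylation a gene lost and how far its expression fell. Per-stage TSVs, a
metagene profile, size factors, a depletion summary and the integration
JSON are written to `demo_run/`, with a manifest recording seed, version
and file checksums.

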