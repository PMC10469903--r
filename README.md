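# metsig

Derivation, scoring and clinical stratification of an anchor-correlated
metabolic gene signature ("MetSig") from bulk RNA-seq cohorts, with
projection onto single-cell data.

## The problem

In rheumatoid arthritis, circulating CD14+ monocytes with high expression
of the Rho-GTPase gene *CDC42* carry a coordinated transcriptional program
of oxidative phosphorylation, proteasome and general-transcription-factor
genes. A compact gene signature summarizing that program tracks disease
activity (DAS28) in a subset of patients and marks a pathogenic synovial
macrophage population in single-cell data. `metsig` implements that whole
analysis as a reusable, tested pipeline for transcriptomics researchers:

1. **Signature derivation** from two cohorts: split samples by mean
   anchor-gene expression, call per-gene Welch tests on median-of-ratios
   log2 counts, intersect genes upregulated in anchor-high samples in both
   cohorts (nominal *p* < 0.05, concordant sign), keep targets of the
   regulators NFE2L1 / HOXA2 / NFRKB (a GMT file), and prune to genes
   whose Spearman correlation with the anchor and with each other stays
   above `rho_min`.
2. **Scoring**: per sample, `MetSig_i = sum_g z_g,i` over signature genes,
   where `z` is the row z-transform (mean 0, sd 1 with denominator n−1,
   per cohort); the z-scored anchor is kept alongside.
3. **Stratification**: the reference line through the componentwise
   extremes `(max x, max y)` and `(min x, min y)` of (MetSig, anchor-z);
   a sample is *inside* the model iff `|predicted − observed| < 1` (strict,
   one standard deviation on the z scale). The inside subset is tested for
   a MetSig–DAS28 Spearman association, and genes are screened for
   `|rho| > 0.5` correlation with DAS28.
4. **Single-cell projection**: QC filtering (500–4,500 detected features,
   ≤ 20% mitochondrial counts), per-cell log-normalization, PCA + K-means
   clustering, per-cluster aggregate signature scores (summed per-cell-mean
   expression), and Wilcoxon rank-sum marker calling with |log2FC| > 0.25
   and ≥ 25% detection.

The published six-gene signature (*ATP5BP*, *COX7A2*, *PSMB6*, *PSME3*,
*GTF3C6*, *GTF2E2*; anchor *CDC42*) ships as `builtinMetSig()`.

A synthetic-data module (`simulateBulkCohort()`, `simulateSCDataset()`,
`simulateTFTargets()`) generates negative-binomial cohorts and clustered
single-cell datasets with planted ground truth, so every stage can be
validated without downloading patient data.

## Worked example

```r
library(metsig)
simA <- simulateBulkCohort(bulkSimSpec(n_samples = 77, n_genes = 2000,
                                       tracked_fraction = 0.7,
                                       cohort = "BiO", seed = 11))
simB <- simulateBulkCohort(bulkSimSpec(n_samples = 59, n_genes = 2000,
                                       tracked_fraction = 0.7,
                                       cohort = "Neum", seed = 12))
tfmap <- simulateTFTargets(simA$truth$module_gene_ids,
                           decoy_pool = geneIds(simA$expr), seed = 13)
sig <- deriveSignature(simA$expr, simB$expr, anchor = "CDC42",
                       tfmap = tfmap, tfs = c("NFE2L1", "HOXA2", "NFRKB"))
sig
#> SignatureDefinition: anchor CDC42, 20 genes
#>   g0270, g0330, g1616, g1975, g1861, g0679, g0930, g0597, g0299, g1800 ...

scores <- metsigScore(simA$expr, sig)
model  <- fitMinMaxLine(scores, threshold = 1)
strat  <- classifyInside(scores, model)
strat
#> StratifiedSamples: 77 samples, 58 inside (threshold 1)
assoc  <- associateClinical(strat, scores, simA$annotation)
#> inside fraction: 0.753; MetSig-DAS28 Spearman rho = 0.72 (p = 2.1e-10)
```

The derived signature recovers the 20 planted module genes; 58 of 77
samples fall inside the line model, and their signature scores correlate
with the simulated disease-activity score at rho = 0.72.

On the single-cell side:

```r
ds <- simulateSCDataset(scSimSpec(n_cells = 300, k_clusters = 5,
                                  signature_fold = 3, seed = 14))
ds <- clusterCells(logNormalizeCells(qcFilter(ds)), k = 5, seed = 15)
clusterMetsig(ds, builtinMetSig())
#>   cluster n_cells   metsig anchor_mean   tie    hi
#> 1       1      60 10.89533    1.818333 FALSE FALSE
#> 2       2      58 17.02685    2.795782  TRUE  TRUE
#> ...
```

The cluster carrying the planted 3-fold signature elevation is flagged
`hi` (score 17.0 vs ~10.5 elsewhere) and `findMarkers()` profiles it
against all remaining cells.

`runPipeline(pipelineConfig(seed = 1, out_dir = "out"))` chains all stages
and writes per-stage artifacts plus a deterministic JSON report.

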