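## Single-cell stage: QC filtering, per-cell log-normalization, PCA +
## K-means clustering, per-cluster aggregate signature scoring and
## Wilcoxon marker calling.

#' Filter cells on detected features and mitochondrial fraction
#'
#' Retains cells with `min_features <= nFeatures <= max_features` and a
#' mitochondrial fraction of at most `max_mito`.  The defaults (500, 4500,
#' 20%) are the canonical QC cut-offs for droplet data.  Per-criterion
#' removal counts are recorded in `metadata(.)$qc_removed`.
#'
#' @param ds a [CellDataset-class].
#' @param min_features,max_features detected-feature bounds (inclusive).
#' @param max_mito maximum mitochondrial count fraction (inclusive).
#' @return the filtered [CellDataset-class]; removing every cell is an
#'   error.
#' @export
qcFilter <- function(ds, min_features = 500L, max_features = 4500L,
                     max_mito = 0.20) {
    stopifnot(is(ds, "CellDataset"))
    cd <- SummarizedExperiment::colData(ds)
    low <- cd$nFeatures < min_features
    high <- cd$nFeatures > max_features
    mito <- cd$mitoFraction > max_mito
    keep <- !(low | high | mito)
    if (!any(keep)) stop("QC filtering removed every cell")
    out <- ds[, keep]
    S4Vectors::metadata(out)$qc_removed <- c(
        low_features = sum(low), high_features = sum(high),
        high_mito = sum(mito), total = sum(!keep))
    out
}

#' Per-cell log-normalization
#'
#' Scales each cell to 10,000 total counts and applies the natural
#' `log1p`, storing the result as the `logcounts` assay.  A cell with zero
#' total counts is an error (it should have been removed by QC).
#'
#' @param ds a [CellDataset-class] with raw counts.
#' @return the dataset with an added `logcounts` assay.
#' @export
logNormalizeCells <- function(ds) {
    stopifnot(is(ds, "CellDataset"))
    cnt <- SummarizedExperiment::assay(ds, "counts")
    tot <- Matrix::colSums(cnt)
    if (any(tot == 0))
        stop(sprintf("cell(s) with zero total counts: %s",
             paste(colnames(ds)[tot == 0], collapse = ", ")))
    norm <- cnt %*% Matrix::Diagonal(x = 1e4 / tot)
    colnames(norm) <- colnames(cnt)
    SummarizedExperiment::assay(ds, "logcounts") <- log1p(norm)
    ds
}

#' Cluster cells by PCA + K-means
#'
#' Scales the log-normalized expression of the most variable genes (top
#' 2,000 by variance, or all genes if fewer), projects cells onto the top
#' principal components and runs K-means (25 restarts, best
#' within-cluster sum of squares kept), deterministic given the seed.
#' Labels are written to `colData(.)$cluster`.
#'
#' @param ds a [CellDataset-class] with a `logcounts` assay.
#' @param k number of clusters (>= 2; the reference analysis choice for
#'   synovial macrophages is 15).
#' @param n_pcs number of principal components (default 10).
#' @param seed integer random seed.
#' @param n_hvg number of highly variable genes (default 2000).
#' @return the dataset with cluster labels assigned.
#' @export
clusterCells <- function(ds, k = 15L, n_pcs = 10L, seed = 1L,
                         n_hvg = 2000L) {
    stopifnot(is(ds, "CellDataset"))
    if (k < 2L) stop("k must be at least 2")
    if (k > ncol(ds)) stop("k exceeds the number of cells")
    if (!"logcounts" %in% SummarizedExperiment::assayNames(ds))
        stop("run logNormalizeCells() first")
    lg <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
    vars <- rowSums((lg - rowMeans(lg))^2) / (ncol(lg) - 1L)
    hvg <- order(vars, decreasing = TRUE)[seq_len(min(n_hvg, nrow(lg)))]
    x <- .zscore_rows(lg[hvg, , drop = FALSE])
    set.seed(seed)
    pcs <- prcomp(t(x), center = FALSE, scale. = FALSE,
                  rank. = min(n_pcs, ncol(ds) - 1L, length(hvg)))$x
    fit <- kmeans(pcs, centers = k, nstart = 25L, iter.max = 100L)
    SummarizedExperiment::colData(ds)$cluster <- as.integer(fit$cluster)
    ds
}

#' Per-cluster aggregate signature score
#'
#' For each cluster the score is the sum over signature genes of the
#' cluster's aggregate expression divided by the number of cells in the
#' cluster, i.e. the summed per-cell-mean expression.  The cluster with
#' the maximal score carries the `hi` flag; clusters whose scores lie
#' within 1e-9 of the maximum are reported as ties.  The per-cell mean
#' anchor expression of each cluster is reported alongside, together with
#' whether the anchor-based and signature-based rankings agree on the top
#' cluster.
#'
#' @param ds a clustered [CellDataset-class].
#' @param sig a [SignatureDefinition-class]; all signature genes (and the
#'   anchor) must be present.
#' @param assay which assay to aggregate: `"logcounts"` (default) or
#'   `"counts"`.
#' @return a data.frame with columns `cluster`, `n_cells`, `metsig`,
#'   `anchor_mean`, `hi`, `tie`; the agreement flag is in
#'   `attr(., "anchor_agrees")`.
#' @export
clusterMetsig <- function(ds, sig, assay = c("logcounts", "counts")) {
    stopifnot(is(ds, "CellDataset"), is(sig, "SignatureDefinition"))
    assay <- match.arg(assay)
    cl <- cellClusters(ds)
    if (is.null(cl)) stop("the dataset has no cluster labels")
    if (!assay %in% SummarizedExperiment::assayNames(ds))
        stop(sprintf("assay '%s' not present", assay))
    need <- c(signatureGenes(sig), anchorGene(sig))
    missing <- setdiff(need, rownames(ds))
    if (length(missing))
        stop(sprintf("signature gene(s) missing from the dataset: %s",
                     paste(missing, collapse = ", ")))
    v <- SummarizedExperiment::assay(ds, assay)
    labels <- sort(unique(cl))
    rows <- lapply(labels, function(k) {
        cells <- which(cl == k)
        sub <- v[need, cells, drop = FALSE]
        per_gene <- Matrix::rowSums(sub) / length(cells)
        data.frame(cluster = k, n_cells = length(cells),
                   metsig = sum(per_gene[signatureGenes(sig)]),
                   anchor_mean = per_gene[[anchorGene(sig)]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    top <- max(out$metsig)
    out$tie <- abs(out$metsig - top) <= 1e-9
    out$hi <- out$metsig == top
    if (sum(out$tie) > 1L)
        warning("signature-high flag is tied between clusters")
    attr(out, "anchor_agrees") <-
        out$cluster[which.max(out$metsig)] ==
        out$cluster[which.max(out$anchor_mean)]
    rownames(out) <- NULL
    out
}

#' Wilcoxon marker genes of one cluster against all other cells
#'
#' Candidate genes are pre-filtered on effect size and detection:
#' `|log2FC| > lfc_min` and `max(pct_in, pct_out) >= pct_min`, where the
#' fold change compares mean expression on the exponentiated
#' (`expm1`-of-logcounts) scale with a pseudo-value of 1e-9, and `pct` is
#' the fraction of cells with a nonzero count.  Genes passing the filter
#' are tested with a two-sided Wilcoxon rank-sum test on log-normalized
#' expression (cluster vs all remaining cells); a Bonferroni-adjusted
#' p-value over all genes in the dataset is reported alongside the nominal
#' one.
#'
#' @param ds a clustered [CellDataset-class] with `logcounts`.
#' @param cluster the cluster label to profile.
#' @param lfc_min log2 fold-change threshold (default 0.25).
#' @param pct_min detection-fraction threshold (default 0.25).
#' @return a data.frame with columns `gene_id`, `cluster`,
#'   `log2_fold_change`, `p_value`, `p_adj`, `pct_in`, `pct_out`, ordered
#'   by increasing p-value.
#' @export
findMarkers <- function(ds, cluster, lfc_min = 0.25, pct_min = 0.25) {
    stopifnot(is(ds, "CellDataset"))
    cl <- cellClusters(ds)
    if (is.null(cl)) stop("the dataset has no cluster labels")
    if (!cluster %in% cl)
        stop(sprintf("unknown cluster label '%s'", cluster))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(ds))
        stop("run logNormalizeCells() first")
    in_cells <- which(cl == cluster)
    out_cells <- which(cl != cluster)
    if (length(in_cells) < 3L) stop("the cluster has fewer than 3 cells")
    lg <- SummarizedExperiment::assay(ds, "logcounts")
    cnt <- SummarizedExperiment::assay(ds, "counts")
    eps <- 1e-9
    mean_in <- Matrix::rowMeans(expm1(lg[, in_cells, drop = FALSE]))
    mean_out <- Matrix::rowMeans(expm1(lg[, out_cells, drop = FALSE]))
    lfc <- log2((mean_in + eps) / (mean_out + eps))
    pct_in <- Matrix::rowMeans(cnt[, in_cells, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(cnt[, out_cells, drop = FALSE] > 0)
    pass <- abs(lfc) > lfc_min & pmax(pct_in, pct_out) >= pct_min
    genes <- rownames(ds)[pass]
    if (!length(genes))
        return(data.frame(gene_id = character(), cluster = character(),
                          log2_fold_change = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          pct_in = numeric(), pct_out = numeric(),
                          stringsAsFactors = FALSE))
    lgm <- as.matrix(lg[genes, , drop = FALSE])
    p <- vapply(genes, function(g)
        suppressWarnings(wilcox.test(lgm[g, in_cells], lgm[g, out_cells],
                                     alternative = "two.sided"))$p.value,
        0)
    out <- data.frame(gene_id = genes, cluster = as.character(cluster),
                      log2_fold_change = unname(lfc[pass]),
                      p_value = unname(p),
                      p_adj = pmin(unname(p) * nrow(ds), 1),
                      pct_in = unname(pct_in[pass]),
                      pct_out = unname(pct_out[pass]),
                      stringsAsFactors = FALSE)
    out[order(out$p_value, out$gene_id), , drop = FALSE]
}
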