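mk_cells <- function(cnt, mito = NULL) {
    if (is.null(rownames(cnt)))
        rownames(cnt) <- sprintf("gene%03d", seq_len(nrow(cnt)))
    if (is.null(colnames(cnt)))
        colnames(cnt) <- sprintf("c%03d", seq_len(ncol(cnt)))
    cellDataset(cnt, mito = mito)
}

test_that("QC filtering applies the canonical thresholds", {
    ## 3 cells: passing, low-feature, high-mito; 1000 genes incl. 10 mito
    set.seed(43)
    n_genes <- 1000
    mito <- c(rep(TRUE, 10), rep(FALSE, n_genes - 10))
    good <- c(rpois(10, 5), rbinom(n_genes - 10, 1, 0.6) * rpois(n_genes - 10, 3) + 1)
    good[sample(11:n_genes, 400)] <- 0   # 600 features, ~5% mito
    low <- good; low[401:n_genes] <- 0   # < 500 features
    him <- good; him[1:10] <- round(0.22 / 0.78 * sum(good[-(1:10)]) / 10)
    cnt <- cbind(pass = good, low = low, mito = him)
    rownames(cnt) <- sprintf("gene%04d", 1:n_genes)
    ds <- cellDataset(cnt, mito = mito)
    qc <- cellQC(ds)
    expect_true(qc$nFeatures[1] >= 500 && qc$mitoFraction[1] <= 0.20)
    expect_lt(qc$nFeatures[2], 500)
    expect_gt(qc$mitoFraction[3], 0.20)
    out <- qcFilter(ds)
    expect_identical(colnames(out), "pass")
    removed <- S4Vectors::metadata(out)$qc_removed
    expect_equal(removed[["low_features"]], 1)
    expect_equal(removed[["high_mito"]], 1)
    ## idempotence
    out2 <- qcFilter(out)
    expect_identical(colnames(out2), colnames(out))
    expect_error(qcFilter(ds, min_features = 1e6), "every cell")
})

test_that("log-normalization matches its closed form and is scale-free", {
    cnt <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"),
                                           c("c1", "c2")))
    cnt[, 1] <- c(1, 9999, 0)
    cnt[, 2] <- c(10, 20, 30)
    ds <- logNormalizeCells(mk_cells(cnt))
    lg <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
    expect_equal(lg["a", "c1"], log(2))  # 1/10000*1e4 -> log1p(1)
    ## doubling a cell's counts leaves its normalized profile unchanged
    cnt2 <- cnt; cnt2[, 2] <- cnt[, 2] * 2
    lg2 <- as.matrix(SummarizedExperiment::assay(
        logNormalizeCells(mk_cells(cnt2)), "logcounts"))
    expect_equal(lg2[, "c2"], lg[, "c2"])
    ## random fixture against direct recomputation
    set.seed(47)
    r <- matrix(rpois(200, 3), 20, 10)
    lgr <- as.matrix(SummarizedExperiment::assay(
        logNormalizeCells(mk_cells(r)), "logcounts"))
    ref <- log1p(sweep(r, 2, colSums(r), "/") * 1e4)
    expect_equal(unname(lgr), unname(ref))
    ## zero-total cells are an error
    cnt0 <- cnt; cnt0[, 2] <- 0
    expect_error(logNormalizeCells(mk_cells(cnt0)), "zero total")
})

test_that("PCA + K-means separates planted populations", {
    skip_if_not_installed("mclust")
    ds <- simulateSCDataset(scSimSpec(n_cells = 120, n_genes = 500,
                                      k_clusters = 2, signature_fold = 1,
                                      marker_genes_per_cluster = 40,
                                      seed = 53))
    ds <- logNormalizeCells(ds)
    ds <- clusterCells(ds, k = 2, n_pcs = 5, seed = 3)
    truth <- S4Vectors::metadata(ds)$truth$cluster
    ari <- mclust::adjustedRandIndex(cellClusters(ds), truth)
    expect_equal(ari, 1.0)
    expect_error(clusterCells(ds, k = 1), "at least 2")
    expect_error(clusterCells(ds, k = 500), "exceeds")
})

test_that("per-cluster aggregate scoring follows the quoted rule", {
    cnt <- rbind(sigA = c(1, 3, 0, 0), sigB = c(2, 4, 0, 0),
                 CDC42 = c(1, 1, 2, 2), other = c(5, 5, 5, 5))
    colnames(cnt) <- sprintf("c%d", 1:4)
    ds <- mk_cells(cnt)
    SummarizedExperiment::colData(ds)$cluster <- c(1, 1, 2, 2)
    sig <- signatureDefinition("CDC42", c("sigA", "sigB"))
    cs <- clusterMetsig(ds, sig, assay = "counts")
    ## cluster 1: (1+3)/2 + (2+4)/2 = 5
    expect_equal(cs$metsig[cs$cluster == 1], 5)
    expect_equal(cs$metsig[cs$cluster == 2], 0)
    expect_true(cs$hi[cs$cluster == 1])
    expect_equal(cs$anchor_mean, c(1, 2))
    expect_error(clusterMetsig(ds, signatureDefinition("CDC42", "nope"),
                               assay = "counts"), "nope")
    ## identical clusters tie and warn
    cnt2 <- cnt; cnt2[, 3:4] <- cnt[, 1:2]
    ds2 <- mk_cells(cnt2)
    SummarizedExperiment::colData(ds2)$cluster <- c(1, 1, 2, 2)
    expect_warning(cs2 <- clusterMetsig(ds2, sig, assay = "counts"),
                   "tied")
    expect_true(all(cs2$tie))
})

test_that("scoring is invariant to splitting an iid cluster in two", {
    ds <- simulateSCDataset(scSimSpec(n_cells = 200, n_genes = 300,
                                      k_clusters = 2, signature_fold = 2,
                                      seed = 59))
    ds <- logNormalizeCells(ds)
    truth <- S4Vectors::metadata(ds)$truth$cluster
    SummarizedExperiment::colData(ds)$cluster <- truth
    sig <- builtinMetSig()
    whole <- clusterMetsig(ds, sig)
    ## split cluster 1 into two random halves with identical distribution
    split_lab <- truth
    ones <- which(truth == 1)
    set.seed(60)
    split_lab[sample(ones, length(ones) %/% 2)] <- 3
    SummarizedExperiment::colData(ds)$cluster <- split_lab
    parts <- clusterMetsig(ds, sig)
    expect_equal(parts$metsig[parts$cluster == 3],
                 whole$metsig[whole$cluster == 1], tolerance = 0.15)
})

test_that("marker calling filters and tests as documented", {
    ds <- simulateSCDataset(scSimSpec(n_cells = 150, n_genes = 400,
                                      k_clusters = 3, signature_fold = 3,
                                      seed = 61))
    ds <- logNormalizeCells(ds)
    truth <- S4Vectors::metadata(ds)$truth
    SummarizedExperiment::colData(ds)$cluster <- truth$cluster
    mk <- findMarkers(ds, truth$hi_cluster)
    planted <- truth$marker_gene_ids[[truth$hi_cluster]]
    expect_true(all(planted %in% mk$gene_id))
    expect_true(all(abs(mk$log2_fold_change) > 0.25))
    expect_true(all(pmax(mk$pct_in, mk$pct_out) >= 0.25))
    expect_true(all(mk$p_adj >= mk$p_value))
    expect_error(findMarkers(ds, "not-a-cluster"), "unknown cluster")
})

test_that("flat and poorly detected genes are excluded before testing", {
    ## gene 'flat' identical everywhere; 'rare' detected in 20% vs 10%;
    ## a balance row keeps library sizes equal so per-cell normalization
    ## does not manufacture fold changes
    set.seed(67)
    n <- 40
    cnt <- rbind(flat = rep(4, n),
                 rare = c(rbinom(n / 2, 1, 0.2), rbinom(n / 2, 1, 0.1)) * 50,
                 real = c(rpois(n / 2, 20), rpois(n / 2, 2)))
    cnt <- rbind(cnt, balance = max(colSums(cnt)) + 50 - colSums(cnt))
    colnames(cnt) <- sprintf("c%02d", 1:n)
    ds <- logNormalizeCells(mk_cells(cnt))
    SummarizedExperiment::colData(ds)$cluster <- rep(1:2, each = n / 2)
    mk <- findMarkers(ds, 1)
    expect_false("flat" %in% mk$gene_id)
    expect_false("rare" %in% mk$gene_id)
    expect_true("real" %in% mk$gene_id)
})

test_that("Wilcoxon p-values match exact enumeration on tie-free data", {
    ## construct a tie-free two-group gene so both the implementation and
    ## the enumeration oracle are exact
    vals <- c(101, 205, 33, 154, 76, 58, 149, 12, 88, 97, 180, 140)
    cnt <- rbind(g = vals, filler = seq(1000, 1011))
    colnames(cnt) <- sprintf("c%02d", 1:12)
    ds <- logNormalizeCells(mk_cells(cnt))
    SummarizedExperiment::colData(ds)$cluster <- rep(1:2, each = 6)
    mk <- findMarkers(ds, 1, lfc_min = 0, pct_min = 0)
    lg <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
    for (gene in mk$gene_id) {
        p_oracle <- exact_ranksum_p(lg[gene, 1:6], lg[gene, 7:12])
        expect_equal(mk$p_value[mk$gene_id == gene], p_oracle,
                     tolerance = 1e-12)
    }
})
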