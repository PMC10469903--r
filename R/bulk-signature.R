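## Bulk signature derivation: anchor split -> normalization -> Welch DE ->
## cohort intersection -> TF-target filter -> correlation filter -> z-sum
## scoring.

#' Split samples by mean anchor expression
#'
#' Labels each sample `hi` when its anchor expression strictly exceeds the
#' cross-sample mean and `lo` otherwise (ties fall to `lo`).  Raw counts
#' are normalized to the log scale first, so the split is taken on the same
#' scale the differential test uses.
#'
#' @param m an [ExpressionMatrix-class] (raw counts or log-normalized).
#' @param anchor anchor gene identifier; must be present in `m`.
#' @return a factor of `"hi"`/`"lo"` labels named by sample id.
#' @export
splitByAnchor <- function(m, anchor) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (!anchor %in% geneIds(m))
        stop(sprintf("anchor gene '%s' not found in the matrix", anchor))
    if (identical(exprUnit(m), "raw_counts"))
        m <- normalizeCounts(m)
    a <- exprValues(m)[anchor, ]
    if (max(a) == min(a))
        warning(sprintf("anchor '%s' is constant: all samples labelled lo",
                        anchor))
    labels <- ifelse(a > mean(a), "hi", "lo")
    factor(setNames(labels, sampleIds(m)), levels = c("hi", "lo"))
}

#' Median-of-ratios normalization with log2 transform
#'
#' Computes median-of-ratios size factors (median of log ratios against the
#' geometric-mean reference over genes with all-positive counts, the
#' standard RNA-seq convention), divides each column by its size factor and
#' returns `log2(x + 1)` values.  When no gene has all-positive counts the
#' size factors fall back to geometric-mean-scaled library sizes, with a
#' warning.
#'
#' @param m an [ExpressionMatrix-class] with unit `"raw_counts"`.
#' @return an [ExpressionMatrix-class] with unit `"log_normalized"`.
#' @export
normalizeCounts <- function(m) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (!identical(exprUnit(m), "raw_counts"))
        stop("normalizeCounts expects raw counts")
    v <- exprValues(m)
    pos <- rowSums(v > 0) == ncol(v)
    if (any(pos)) {
        ## median of log ratios against the geometric-mean reference, the
        ## standard convention for RNA-seq size factors
        logref <- rowMeans(log(v[pos, , drop = FALSE]))
        sf <- apply(v[pos, , drop = FALSE], 2L,
                    function(col) exp(median(log(col) - logref)))
    } else {
        warning("no gene with all-positive counts: ",
                "using library-size factors")
        libs <- colSums(v)
        if (any(libs == 0)) stop("sample with zero total counts")
        sf <- libs / exp(mean(log(libs)))
    }
    norm <- log2(sweep(v, 2L, sf, `/`) + 1)
    out <- expressionMatrix(norm, unit = "log_normalized")
    S4Vectors::metadata(out)$size_factors <- setNames(sf, colnames(v))
    out
}

#' Per-gene Welch t-test between anchor-hi and anchor-lo samples
#'
#' Runs a two-sided Welch two-sample t-test per gene on log-normalized
#' values.  The log2 fold change is `mean(hi) - mean(lo)` (the values are
#' already on the log2 scale).  No multiplicity adjustment gates the
#' differential call; a Benjamini-Hochberg FDR column is reported for
#' information only.  Degenerate genes: equal group means with zero
#' within-group variance give p = 1; separated means with zero variance
#' give the smallest positive double.
#'
#' @param m an [ExpressionMatrix-class] with unit `"log_normalized"`.
#' @param labels factor of `"hi"`/`"lo"` per sample (see
#'   [splitByAnchor()]); both groups need at least 3 samples.
#' @return a data.frame with columns `gene_id`, `log2_fold_change`,
#'   `p_value`, `mean_hi`, `mean_lo`, `fdr`.
#' @export
deTest <- function(m, labels) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (!identical(exprUnit(m), "log_normalized"))
        stop("deTest expects log-normalized values")
    labels <- factor(labels, levels = c("hi", "lo"))
    v <- exprValues(m)
    stopifnot(length(labels) == ncol(v))
    n1 <- sum(labels == "hi", na.rm = TRUE)
    n2 <- sum(labels == "lo", na.rm = TRUE)
    if (n1 < 3L || n2 < 3L)
        stop("each anchor group needs at least 3 samples")
    x1 <- v[, which(labels == "hi"), drop = FALSE]
    x2 <- v[, which(labels == "lo"), drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * pt(-abs(tstat), df)
    zerovar <- se2 == 0
    p[zerovar & m1 == m2] <- 1
    p[zerovar & m1 != m2] <- .Machine$double.xmin
    p <- pmax(p, .Machine$double.xmin)
    data.frame(gene_id = rownames(v), log2_fold_change = m1 - m2,
               p_value = unname(p), mean_hi = unname(m1),
               mean_lo = unname(m2), fdr = p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect differential genes of two cohorts
#'
#' A gene is in the common set when it is nominally significant
#' (`p < alpha`) in both cohorts with the same fold-change sign.  The
#' per-cohort overlap fractions (common set over each cohort's own
#' differential set) are reported alongside.
#'
#' @param a,b data.frames from [deTest()].
#' @param alpha nominal significance level (default 0.05).
#' @return a list with `common` (gene ids), `fraction_of_a`,
#'   `fraction_of_b`.
#' @export
intersectDEGs <- function(a, b, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    deg_a <- a$gene_id[a$p_value < alpha]
    deg_b <- b$gene_id[b$p_value < alpha]
    both <- intersect(deg_a, deg_b)
    sign_a <- sign(a$log2_fold_change[match(both, a$gene_id)])
    sign_b <- sign(b$log2_fold_change[match(both, b$gene_id)])
    common <- both[sign_a == sign_b & sign_a != 0]
    list(common = common,
         fraction_of_a = if (length(deg_a)) length(common) / length(deg_a)
                         else NA_real_,
         fraction_of_b = if (length(deg_b)) length(common) / length(deg_b)
                         else NA_real_)
}

#' Co-expression K-means clustering of genes
#'
#' Clusters z-scored gene rows with Euclidean K-means (25 random restarts,
#' best within-cluster sum of squares kept), deterministic given the seed.
#' Cluster labels feed reporting; the signature derivation itself uses the
#' explicit filter chain.
#'
#' @param m a row-z-scored [ExpressionMatrix-class] or numeric matrix.
#' @param k number of clusters (>= 2, default 6).
#' @param seed integer random seed.
#' @param nstart random restarts (default 25).
#' @return integer cluster labels named by gene id.
#' @export
kmeansCoexpression <- function(m, k = 6L, seed = 1L, nstart = 25L) {
    v <- if (is(m, "ExpressionMatrix")) {
        if (!identical(exprUnit(m), "z_scored"))
            stop("kmeansCoexpression expects z-scored rows")
        exprValues(m)
    } else as.matrix(m)
    if (k < 2L) stop("k must be at least 2")
    if (k > nrow(v))
        stop(sprintf("k = %d exceeds the number of genes (%d)", k, nrow(v)))
    set.seed(seed)
    fit <- kmeans(v, centers = k, nstart = nstart, iter.max = 100L)
    setNames(fit$cluster, rownames(v))
}

#' Restrict genes to transcription-factor targets
#'
#' Keeps the genes that belong to the union of the target sets of the named
#' TFs.  A TF missing from the map is an error; an empty intersection is a
#' warning, not an error.
#'
#' @param genes character vector of candidate gene ids.
#' @param tfmap named list of TF target sets (see [readTFTargets()]).
#' @param tfs TF names whose targets are pooled.
#' @return the filtered gene vector (possibly empty).
#' @export
tfTargetFilter <- function(genes, tfmap, tfs) {
    if (!length(tfs)) stop("at least one TF name is required")
    missing <- setdiff(tfs, names(tfmap))
    if (length(missing))
        stop(sprintf("TF(s) absent from the target map: %s",
                     paste(missing, collapse = ", ")))
    pool <- unique(unlist(tfmap[tfs], use.names = FALSE))
    out <- genes[genes %in% pool]
    if (!length(out))
        warning("no candidate gene is a target of the named TFs")
    out
}

#' Prune candidates to an anchor-correlated, internally coherent set
#'
#' Iteratively drops the candidate with the lowest mean Spearman
#' correlation to the anchor plus the remaining candidates until every
#' remaining gene correlates with the anchor at `rho >= rho_min` and has a
#' mean pairwise correlation (to the anchor and the other retained genes)
#' of at least `rho_min`.  Ties are broken lexicographically by gene id, so
#' the pruning is deterministic.  Undefined correlations (constant rows)
#' rank below every real value and are pruned first.
#'
#' @param candidates character vector of candidate gene ids.
#' @param anchor anchor gene id.
#' @param m an [ExpressionMatrix-class] with log-normalized (or raw, then
#'   normalized internally) values covering anchor and candidates.
#' @param rho_min inclusion threshold in (0, 1); default 0.4.
#' @return the retained gene vector, with the pruning trace (gene dropped,
#'   its mean rho) in `attr(., "trace")`.
#' @export
correlationFilter <- function(candidates, anchor, m, rho_min = 0.4) {
    stopifnot(rho_min > 0, rho_min < 1)
    if (identical(exprUnit(m), "raw_counts")) m <- normalizeCounts(m)
    v <- exprValues(m)
    missing <- setdiff(c(anchor, candidates), rownames(v))
    if (length(missing))
        stop(sprintf("gene(s) absent from the matrix: %s",
                     paste(missing, collapse = ", ")))
    candidates <- unique(candidates)
    cm <- suppressWarnings(
        cor(t(v[c(anchor, candidates), , drop = FALSE]),
            method = "spearman"))
    trace <- data.frame(gene_id = character(), mean_rho = numeric(),
                        stringsAsFactors = FALSE)
    remaining <- candidates
    repeat {
        if (!length(remaining)) {
            e <- simpleError("all candidates pruned: empty signature")
            e$trace <- trace
            stop(e)
        }
        others <- lapply(remaining, function(g)
            setdiff(c(anchor, remaining), g))
        mean_rho <- vapply(seq_along(remaining), function(i)
            mean(cm[remaining[i], others[[i]]]), 0)
        mean_rho[is.na(mean_rho)] <- -Inf
        rho_anchor <- cm[remaining, anchor]
        rho_anchor[is.na(rho_anchor)] <- -Inf
        ok <- rho_anchor >= rho_min & mean_rho >= rho_min
        if (all(ok)) break
        worst <- remaining[order(mean_rho, remaining)][1L]
        trace <- rbind(trace, data.frame(
            gene_id = worst,
            mean_rho = mean_rho[match(worst, remaining)],
            stringsAsFactors = FALSE))
        remaining <- setdiff(remaining, worst)
    }
    structure(remaining, trace = trace)
}

#' Derive the anchor-related signature from two cohorts
#'
#' Runs the full derivation chain per cohort: median-of-ratios
#' normalization (when raw counts are given), mean split by the anchor
#' gene, per-gene Welch tests, intersection of genes upregulated in
#' anchor-hi samples in both cohorts (`p < alpha` and log2 fold change > 0
#' in each), restriction to targets of the named TFs, and the iterative
#' correlation filter.  By default a gene must pass the correlation filter
#' in both cohorts (`corMode = "both"`); `corMode = "pooled"` filters once
#' on the column-bound cohorts instead.  The final genes are ordered by
#' decreasing mean anchor correlation across cohorts.
#'
#' @param cohortA,cohortB [ExpressionMatrix-class] objects (raw counts or
#'   log-normalized), both containing the anchor gene.
#' @param anchor anchor gene id.
#' @param tfmap named list of TF target sets.
#' @param tfs TF names used for the target filter.
#' @param alpha nominal differential-expression level (default 0.05).
#' @param rho_min correlation-filter threshold (default 0.4).
#' @param corMode `"both"` (default) or `"pooled"`.
#' @return a [SignatureDefinition-class] with per-gene provenance.
#' @export
deriveSignature <- function(cohortA, cohortB, anchor, tfmap, tfs,
                            alpha = 0.05, rho_min = 0.4,
                            corMode = c("both", "pooled")) {
    corMode <- match.arg(corMode)
    prep <- function(m) {
        if (identical(exprUnit(m), "raw_counts")) normalizeCounts(m) else m
    }
    a <- prep(cohortA); b <- prep(cohortB)
    for (m in list(a, b))
        if (!anchor %in% geneIds(m))
            stop(sprintf("anchor gene '%s' missing from a cohort", anchor))
    de_a <- deTest(a, splitByAnchor(a, anchor))
    de_b <- deTest(b, splitByAnchor(b, anchor))
    up_a <- de_a$gene_id[de_a$p_value < alpha & de_a$log2_fold_change > 0]
    up_b <- de_b$gene_id[de_b$p_value < alpha & de_b$log2_fold_change > 0]
    up_both <- setdiff(intersect(up_a, up_b), anchor)
    tf_pass <- tfTargetFilter(up_both, tfmap, tfs)
    if (!length(tf_pass))
        stop("empty signature: no upregulated common gene is a TF target")
    shared <- intersect(geneIds(a), geneIds(b))
    tf_pass <- intersect(tf_pass, shared)
    if (corMode == "both") {
        keep_a <- tryCatch(correlationFilter(tf_pass, anchor, a, rho_min),
                           error = function(e) character())
        keep_b <- tryCatch(correlationFilter(tf_pass, anchor, b, rho_min),
                           error = function(e) character())
        final <- intersect(keep_a, keep_b)
    } else {
        pooled <- expressionMatrix(
            cbind(exprValues(a)[shared, , drop = FALSE],
                  exprValues(b)[shared, , drop = FALSE]),
            unit = "log_normalized")
        final <- as.character(
            correlationFilter(tf_pass, anchor, pooled, rho_min))
    }
    if (!length(final))
        stop("empty signature: every TF-target candidate was pruned ",
             "by the correlation filter")
    rho_of <- function(m) {
        v <- exprValues(m)
        suppressWarnings(as.vector(
            cor(t(v[final, , drop = FALSE]), v[anchor, ],
                method = "spearman")))
    }
    mean_rho <- (rho_of(a) + rho_of(b)) / 2
    final <- final[order(-mean_rho, final)]
    tf_of <- function(g) {
        hit <- tfs[vapply(tfs, function(tf) g %in% tfmap[[tf]], TRUE)]
        paste(hit, collapse = ";")
    }
    provenance <- data.frame(
        gene_id = up_both,
        de_both_cohorts = TRUE,
        tf_target = vapply(up_both, tf_of, ""),
        correlation_pass = up_both %in% final,
        stringsAsFactors = FALSE, row.names = NULL)
    signatureDefinition(anchor, final, provenance)
}

#' Score samples by summed z-transformed signature expression
#'
#' The per-sample score is the sum over signature genes of the row
#' z-transformed expression; the anchor's z-transformed expression is
#' returned alongside for stratification.  Standardization is performed
#' within each level of `groups` (e.g. per cohort) so that cohorts with
#' different scales can be co-displayed; with `groups = NULL` all samples
#' form one group.  Missing signature genes are an error, never silently
#' skipped.
#'
#' @param m an [ExpressionMatrix-class]; raw counts are normalized first,
#'   z-scored input is rejected (the z-transform is applied internally).
#' @param sig a [SignatureDefinition-class].
#' @param groups optional per-sample standardization group labels.
#' @return a [MetSigScores-class] object.
#' @export
metsigScore <- function(m, sig, groups = NULL) {
    stopifnot(is(m, "ExpressionMatrix"), is(sig, "SignatureDefinition"))
    if (identical(exprUnit(m), "z_scored"))
        stop("metsigScore z-scores internally: pass counts or ",
             "log-normalized values")
    if (ncol(m) < 2L) stop("scoring needs at least 2 samples")
    if (identical(exprUnit(m), "raw_counts")) m <- normalizeCounts(m)
    need <- c(signatureGenes(sig), anchorGene(sig))
    missing <- setdiff(need, geneIds(m))
    if (length(missing))
        stop(sprintf("signature gene(s) missing from the matrix: %s",
                     paste(missing, collapse = ", ")))
    v <- exprValues(m)[need, , drop = FALSE]
    if (is.null(groups)) groups <- rep("all", ncol(v))
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(v))
    z <- v * NA_real_
    for (g in unique(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2L)
            stop(sprintf("standardization group '%s' has fewer than 2 %s",
                         g, "samples"))
        z[, idx] <- .zscore_rows(v[, idx, drop = FALSE])
    }
    new("MetSigScores",
        sampleIds = colnames(v),
        metsig = unname(colSums(z[signatureGenes(sig), , drop = FALSE])),
        anchorZ = unname(z[anchorGene(sig), ]),
        group = groups)
}
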