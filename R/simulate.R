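## Synthetic-data generators: negative-binomial bulk cohorts with a latent
## factor driving an anchor gene plus a gene module, and clustered
## single-cell datasets with a planted signature-high cluster.

#' Bulk cohort simulation settings
#'
#' Defines the generative model for one bulk RNA-seq cohort: a standard-
#' normal latent factor per sample drives the anchor gene and a planted gene
#' module through log-linear loadings; counts are negative-binomial with a
#' shared size (dispersion) parameter.  A `tracked_fraction` of samples
#' follow the module-anchor relation; the remaining samples have their
#' anchor log-mean perturbed by `outlier_offset` (random sign, so the
#' anchor level stays comparable between groups while the coupling breaks).
#' A clinical disease-activity score (0-10 scale) is linear in the
#' standardized module score for tracked samples and independent noise
#' otherwise.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param module_genes number of planted module genes (anchor excluded).
#' @param anchor_beta,module_beta latent-factor loadings (log scale).
#' @param dispersion negative-binomial size parameter; `Inf` switches to
#'   Poisson sampling.
#' @param baseline_log_mean_range range (natural log) from which per-gene
#'   baseline log-means are drawn uniformly.
#' @param tracked_fraction fraction of samples following the module-anchor
#'   relation.
#' @param outlier_offset anchor log-mean perturbation applied to untracked
#'   samples.
#' @param clinical_slope,clinical_noise_sd clinical-score model for tracked
#'   samples: `mid + slope * standardized module score + N(0, sd)`.  The
#'   defaults (1, 0.75) plant a latent Pearson correlation of 0.8.
#' @param clinical_mid mid-scale clinical score (default 5 on the 0-10
#'   disease-activity scale).
#' @param anchor_id gene identifier given to the anchor.
#' @param cohort cohort label written to the annotation.
#' @param seed integer random seed for the cohort realization (samples,
#'   counts, clinical scores); all output is deterministic given the spec.
#' @param layout_seed integer seed for the gene panel (gene order, module
#'   placement, per-gene baselines).  Two cohorts simulated with the same
#'   dimensions and `layout_seed` share the gene universe and the planted
#'   module, as two sequencing cohorts of the same organism would.
#' @return a validated spec list for [simulateBulkCohort()].
#' @export
bulkSimSpec <- function(n_samples = 100L, n_genes = 500L,
                        module_genes = 20L, anchor_beta = 1,
                        module_beta = 1, dispersion = 10,
                        baseline_log_mean_range = c(2, 6),
                        tracked_fraction = 0.5, outlier_offset = 2,
                        clinical_slope = 1, clinical_noise_sd = 0.75,
                        clinical_mid = 5, anchor_id = "CDC42",
                        cohort = "cohortA", seed = 1L,
                        layout_seed = 1L) {
    spec <- list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 module_genes = as.integer(module_genes),
                 anchor_beta = anchor_beta, module_beta = module_beta,
                 dispersion = dispersion,
                 baseline_log_mean_range = baseline_log_mean_range,
                 tracked_fraction = tracked_fraction,
                 outlier_offset = outlier_offset,
                 clinical_slope = clinical_slope,
                 clinical_noise_sd = clinical_noise_sd,
                 clinical_mid = clinical_mid,
                 anchor_id = anchor_id, cohort = cohort,
                 seed = as.integer(seed),
                 layout_seed = as.integer(layout_seed))
    num <- c(spec$anchor_beta, spec$module_beta,
             spec$baseline_log_mean_range, spec$tracked_fraction,
             spec$outlier_offset, spec$clinical_slope,
             spec$clinical_noise_sd, spec$clinical_mid)
    if (anyNA(num) || any(!is.finite(num)))
        stop("all numeric parameters must be finite")
    if (!is.finite(spec$dispersion) && !is.infinite(spec$dispersion))
        stop("dispersion must be positive or Inf")
    if (spec$dispersion <= 0) stop("dispersion must be positive")
    if (spec$module_genes + 1L > spec$n_genes)
        stop("module_genes + 1 (anchor) must not exceed n_genes")
    if (spec$tracked_fraction < 0 || spec$tracked_fraction > 1)
        stop("tracked_fraction must lie in [0, 1]")
    if (spec$clinical_noise_sd < 0) stop("clinical_noise_sd must be >= 0")
    if (length(spec$baseline_log_mean_range) != 2L ||
        diff(spec$baseline_log_mean_range) < 0)
        stop("baseline_log_mean_range must be an increasing interval")
    class(spec) <- "BulkSimSpec"
    spec
}

.rcounts <- function(n, mu, size) {
    if (is.infinite(size)) rpois(n, lambda = mu)
    else rnbinom(n, mu = mu, size = size)
}

#' Simulate one bulk RNA-seq cohort with planted structure
#'
#' Generates counts, per-sample clinical annotation and the ground truth of
#' the planted structure (latent factor, module gene ids, tracked mask and
#' the planted clinical correlation target).
#'
#' Per sample i a latent factor `L_i ~ N(0,1)` sets gene means
#' `mu_g = exp(b_g + beta_g * L_i)` with `beta_g = module_beta` for module
#' genes, `anchor_beta` for the anchor and 0 otherwise; counts are
#' `NB(mu, size = dispersion)`.  Untracked samples add `+/- outlier_offset`
#' to the anchor log-mean.  The clinical score of tracked samples is
#' `clinical_mid + clinical_slope * s_i + N(0, clinical_noise_sd)` where
#' `s_i` is the standardized module z-sum computed from the generated
#' counts; untracked samples draw independent noise with the same marginal
#' spread.  Scores are clipped to \[0, 10\].
#'
#' The planted Spearman target reported in the truth converts the latent
#' Pearson correlation `slope / sqrt(slope^2 + noise^2)` to a Spearman
#' value via the bivariate-normal relation `(6 / pi) * asin(rho / 2)`.
#'
#' @param spec a [bulkSimSpec()] object.
#' @return a list with elements `expr` ([ExpressionMatrix-class], raw
#'   counts), `annotation` (data.frame: sample_id, cohort, das28,
#'   treatment, sex) and `truth` (list: latent, module_gene_ids, anchor_id,
#'   tracked_mask, true_clinical_link).
#' @examples
#' sim <- simulateBulkCohort(bulkSimSpec(n_samples = 20, n_genes = 50,
#'                                       module_genes = 5, seed = 7))
#' sim$expr
#' @export
simulateBulkCohort <- function(spec) {
    stopifnot(inherits(spec, "BulkSimSpec"))
    n <- spec$n_samples
    G <- spec$n_genes
    ## gene panel: placement and baselines are drawn under layout_seed so
    ## cohorts sharing a layout share the planted module
    set.seed(spec$layout_seed)
    gene_ids <- sprintf("g%04d", seq_len(G))
    anchor_pos <- sample.int(G, 1L)
    gene_ids[anchor_pos] <- spec$anchor_id
    module_pos <- sample(setdiff(seq_len(G), anchor_pos), spec$module_genes)
    beta <- numeric(G)
    beta[module_pos] <- spec$module_beta
    beta[anchor_pos] <- spec$anchor_beta
    b <- runif(G, spec$baseline_log_mean_range[1L],
               spec$baseline_log_mean_range[2L])

    set.seed(spec$seed)
    L <- rnorm(n)
    n_tracked <- round(spec$tracked_fraction * n)
    tracked <- rep(FALSE, n)
    tracked[sample.int(n, n_tracked)] <- TRUE
    offset_sign <- sample(c(-1, 1), n, replace = TRUE)

    logmu <- outer(b, rep(1, n)) + outer(beta, L)
    logmu[anchor_pos, !tracked] <- logmu[anchor_pos, !tracked] +
        spec$outlier_offset * offset_sign[!tracked]
    counts <- matrix(.rcounts(G * n, mu = exp(logmu),
                              size = spec$dispersion), G, n)
    sample_ids <- sprintf("%s_S%03d", spec$cohort, seq_len(n))
    dimnames(counts) <- list(gene_ids, sample_ids)

    ## standardized module z-sum from the realized counts, so the clinical
    ## link is planted against the observable score, not the latent factor
    zmod <- .zscore_rows(log2(counts[module_pos, , drop = FALSE] + 1))
    ms <- colSums(zmod)
    ms <- if (sd(ms) > 0) (ms - mean(ms)) / sd(ms) else ms * 0

    das28 <- numeric(n)
    das28[tracked] <- spec$clinical_mid +
        spec$clinical_slope * ms[tracked] +
        rnorm(sum(tracked), 0, spec$clinical_noise_sd)
    spread <- sqrt(spec$clinical_slope^2 + spec$clinical_noise_sd^2)
    das28[!tracked] <- spec$clinical_mid + rnorm(sum(!tracked), 0, spread)
    das28 <- pmin(pmax(das28, 0), 10)

    rho_p <- spec$clinical_slope / spread
    annotation <- data.frame(
        sample_id = sample_ids, cohort = spec$cohort, das28 = das28,
        treatment = sample(c("none", "MTX", "TNFi", "JAKi"), n,
                           replace = TRUE, prob = c(0.1, 0.4, 0.2, 0.3)),
        sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.75, 0.25)),
        stringsAsFactors = FALSE)
    list(expr = expressionMatrix(counts, unit = "raw_counts"),
         annotation = annotation,
         truth = list(latent = setNames(L, sample_ids),
                      module_gene_ids = gene_ids[module_pos],
                      anchor_id = spec$anchor_id,
                      tracked_mask = setNames(tracked, sample_ids),
                      module_score = setNames(ms, sample_ids),
                      true_clinical_link = (6 / pi) * asin(rho_p / 2)))
}

#' Simulate a transcription-factor target map covering a gene module
#'
#' Distributes the module genes over the named TFs (each module gene is a
#' target of at least one TF) and adds decoy targets drawn from the
#' remaining genes, emulating a curated TF-target annotation in which the
#' planted module is embedded among unrelated targets.
#'
#' @param module_genes character vector of planted module gene ids.
#' @param decoy_pool character vector of genes decoys are drawn from.
#' @param tfs TF names (default the three regulators used throughout).
#' @param n_decoys total number of decoy target genes.
#' @param seed integer random seed.
#' @return a named list of character vectors (TF -> targets).
#' @export
simulateTFTargets <- function(module_genes, decoy_pool,
                              tfs = c("NFE2L1", "HOXA2", "NFRKB"),
                              n_decoys = 200L, seed = 1L) {
    set.seed(seed)
    decoy_pool <- setdiff(decoy_pool, module_genes)
    n_decoys <- min(n_decoys, length(decoy_pool))
    decoys <- sample(decoy_pool, n_decoys)
    assign_tf <- function(genes)
        split(genes, sample(tfs, length(genes), replace = TRUE))
    mod_split <- assign_tf(module_genes)
    dec_split <- assign_tf(decoys)
    out <- lapply(tfs, function(tf)
        sort(unique(c(mod_split[[tf]], dec_split[[tf]]))))
    names(out) <- tfs
    out[vapply(out, length, 1L) > 0L]
}

#' Single-cell simulation settings
#'
#' Defines a clustered single-cell dataset: `k_clusters` cell populations
#' share per-gene baseline means (drawn once, so marker detection tests
#' fold-change logic rather than baseline drift); each cluster elevates its
#' own `marker_genes_per_cluster` marker genes 4-fold, and the designated
#' signature-high cluster additionally multiplies the six signature genes
#' and the anchor by `signature_fold`.  `qc_violators` cells are rebuilt to
#' fail the standard QC rules (too few detected features, or mitochondrial
#' fraction above 20%).
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param k_clusters number of planted populations.
#' @param hi_cluster_index which cluster carries the elevated signature.
#' @param signature_fold mean multiplier (> 1 plants a signature-high
#'   cluster; 1 plants none).
#' @param marker_genes_per_cluster planted 4-fold markers per cluster.
#' @param mito_genes number of mitochondrial genes (ids prefixed `MT-`).
#' @param qc_violators number of cells constructed to fail QC.
#' @param dispersion negative-binomial size parameter.
#' @param seed integer random seed.
#' @return a validated spec list for [simulateSCDataset()].
#' @export
scSimSpec <- function(n_cells = 300L, n_genes = 2000L, k_clusters = 5L,
                      hi_cluster_index = 1L, signature_fold = 3,
                      marker_genes_per_cluster = 20L, mito_genes = 13L,
                      qc_violators = 0L, dispersion = 2, seed = 1L) {
    spec <- list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 k_clusters = as.integer(k_clusters),
                 hi_cluster_index = as.integer(hi_cluster_index),
                 signature_fold = signature_fold,
                 marker_genes_per_cluster =
                     as.integer(marker_genes_per_cluster),
                 mito_genes = as.integer(mito_genes),
                 qc_violators = as.integer(qc_violators),
                 dispersion = dispersion, seed = as.integer(seed))
    if (spec$n_cells < spec$k_clusters)
        stop("n_cells must be at least k_clusters")
    if (spec$hi_cluster_index > spec$k_clusters ||
        spec$hi_cluster_index < 1L)
        stop("hi_cluster_index must lie in 1..k_clusters")
    if (spec$signature_fold < 1) stop("signature_fold must be >= 1")
    if (spec$dispersion <= 0) stop("dispersion must be positive")
    if (spec$qc_violators >= spec$n_cells)
        stop("qc_violators must be smaller than n_cells")
    class(spec) <- "SCSimSpec"
    spec
}

#' Simulate a clustered single-cell dataset with planted structure
#'
#' Cells are assigned evenly to clusters; counts follow a negative-binomial
#' model with shared per-gene baselines, 4-fold elevated cluster markers
#' and `signature_fold`-elevated signature genes (plus anchor) in the
#' signature-high cluster.  QC violators are constructed afterwards:
#' alternating cells are stripped to < 500 detected features or have their
#' mitochondrial counts inflated past a 20% fraction.  The truth labels
#' (cluster, violator flag and type, planted markers) are returned in
#' `metadata(ds)$truth`.
#'
#' @param spec an [scSimSpec()] object.
#' @param signature a [SignatureDefinition-class] whose genes (and anchor)
#'   are planted; defaults to [builtinMetSig()].
#' @return a [CellDataset-class] with truth labels in `metadata(.)$truth`
#'   and per-cell cluster truth in `colData(.)$true_cluster`.
#' @export
simulateSCDataset <- function(spec, signature = builtinMetSig()) {
    stopifnot(inherits(spec, "SCSimSpec"))
    set.seed(spec$seed)
    sig_genes <- c(signatureGenes(signature), anchorGene(signature))
    n_named <- length(sig_genes) + spec$mito_genes
    if (spec$n_genes < n_named + spec$k_clusters *
        spec$marker_genes_per_cluster)
        stop("n_genes too small for the requested named and marker genes")
    mito_ids <- sprintf("MT-%02d", seq_len(spec$mito_genes))
    n_bg <- spec$n_genes - n_named
    gene_ids <- c(sig_genes, mito_ids, sprintf("bg%05d", seq_len(n_bg)))

    ## shared baselines: background ~ lnN(log 1.5, 0.7), signature genes a
    ## little higher so fold elevation is detectable, mito genes high so the
    ## resting mitochondrial fraction sits near 4-5%
    base <- exp(rnorm(spec$n_genes, log(1.5), 0.7))
    base[seq_along(sig_genes)] <- exp(rnorm(length(sig_genes), log(3), 0.3))
    mito_idx <- length(sig_genes) + seq_len(spec$mito_genes)
    base[mito_idx] <- exp(rnorm(spec$mito_genes, log(12), 0.3))

    clusters <- sample(rep_len(seq_len(spec$k_clusters), spec$n_cells))
    marker_pool <- sample(which(!seq_len(spec$n_genes) %in%
                                c(seq_along(sig_genes), mito_idx)))
    markers <- split(marker_pool[seq_len(spec$k_clusters *
                                         spec$marker_genes_per_cluster)],
                     rep(seq_len(spec$k_clusters),
                         each = spec$marker_genes_per_cluster))

    mu <- matrix(base, spec$n_genes, spec$n_cells)
    for (k in seq_len(spec$k_clusters)) {
        cells_k <- clusters == k
        mu[markers[[k]], cells_k] <- mu[markers[[k]], cells_k] * 4
        if (k == spec$hi_cluster_index)
            mu[seq_along(sig_genes), cells_k] <-
                mu[seq_along(sig_genes), cells_k] * spec$signature_fold
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = spec$dispersion),
                     spec$n_genes, spec$n_cells)

    violator <- rep(FALSE, spec$n_cells)
    violator_type <- rep(NA_character_, spec$n_cells)
    if (spec$qc_violators > 0L) {
        vcells <- sample.int(spec$n_cells, spec$qc_violators)
        violator[vcells] <- TRUE
        types <- rep_len(c("low_features", "high_mito"), spec$qc_violators)
        violator_type[vcells] <- types
        for (i in seq_along(vcells)) {
            cc <- vcells[i]
            if (types[i] == "low_features") {
                keep <- sample.int(spec$n_genes, 300L)
                zeroed <- setdiff(seq_len(spec$n_genes), keep)
                counts[zeroed, cc] <- 0L
            } else {
                ## push the mitochondrial fraction to ~30%
                nonmito_total <- sum(counts[-mito_idx, cc])
                target <- ceiling(0.3 / 0.7 * nonmito_total)
                counts[mito_idx, cc] <- rpois(spec$mito_genes,
                                              target / spec$mito_genes) + 1L
            }
        }
    }
    cell_ids <- sprintf("cell%04d", seq_len(spec$n_cells))
    dimnames(counts) <- list(gene_ids, cell_ids)
    ds <- cellDataset(counts, mito = grepl("^MT-", gene_ids))
    SummarizedExperiment::colData(ds)$true_cluster <- clusters
    S4Vectors::metadata(ds)$truth <- list(
        cluster = setNames(clusters, cell_ids),
        violator = setNames(violator, cell_ids),
        violator_type = setNames(violator_type, cell_ids),
        hi_cluster = spec$hi_cluster_index,
        marker_gene_ids = lapply(markers, function(i) gene_ids[i]),
        signature_gene_ids = sig_genes)
    ds
}
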