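## End-to-end orchestration: simulate -> derive -> score -> stratify ->
## single-cell projection, with seed fan-out and a deterministic JSON
## report.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the reference
#' analysis values where one exists (alpha 0.05, residual threshold 1.0,
#' marker thresholds 0.25/0.25, QC 500/4500/20%) and validates ranges
#' before any computation runs.  The default configuration simulates both
#' bulk cohorts, the TF-target map and the single-cell dataset; paths to
#' on-disk inputs (`counts_a`, `counts_b`, `annotation`, `tf_gmt`,
#' `sc_dir`) may be given instead.
#'
#' @param seed global integer seed; per-stage child seeds are derived from
#'   it by a fixed rule so stages can be re-run in isolation.
#' @param anchor anchor gene id.
#' @param tfs TF names for the target filter.
#' @param alpha,rho_min,cor_mode signature-derivation parameters.
#' @param threshold residual cutoff of the line model.
#' @param sc_k,n_pcs single-cell clustering parameters (`sc_k` defaults to
#'   the planted cluster count of the demo simulation; for real synovial
#'   macrophage data the reference choice is 15).
#' @param qc_min_features,qc_max_features,qc_max_mito QC cut-offs.
#' @param lfc_min,pct_min marker thresholds.
#' @param bulk_a,bulk_b [bulkSimSpec()] objects for the simulated cohorts
#'   (seeds are overridden by the derived child seeds).
#' @param sc an [scSimSpec()] object for the simulated single-cell data.
#' @param counts_a,counts_b,annotation,tf_gmt,sc_dir optional input paths
#'   that replace the corresponding simulations.
#' @param out_dir output directory for per-stage artifacts, or `NULL` to
#'   skip writing.
#' @return a validated configuration list of class `MetsigConfig`.
#' @export
pipelineConfig <- function(seed = 1L, anchor = "CDC42",
                           tfs = c("NFE2L1", "HOXA2", "NFRKB"),
                           alpha = 0.05, rho_min = 0.4,
                           cor_mode = "both", threshold = 1.0,
                           sc_k = NULL, n_pcs = 10L,
                           qc_min_features = 500L,
                           qc_max_features = 4500L, qc_max_mito = 0.20,
                           lfc_min = 0.25, pct_min = 0.25,
                           bulk_a = bulkSimSpec(n_samples = 77L,
                                                n_genes = 2000L,
                                                tracked_fraction = 0.7,
                                                cohort = "cohortA"),
                           bulk_b = bulkSimSpec(n_samples = 59L,
                                                n_genes = 2000L,
                                                tracked_fraction = 0.7,
                                                cohort = "cohortB"),
                           sc = scSimSpec(),
                           counts_a = NULL, counts_b = NULL,
                           annotation = NULL, tf_gmt = NULL,
                           sc_dir = NULL, out_dir = NULL) {
    cfg <- as.list(environment())
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
        stop("seed must be a single integer")
    if (cfg$alpha <= 0 || cfg$alpha >= 1)
        stop("alpha must lie strictly in (0, 1)")
    if (cfg$rho_min <= 0 || cfg$rho_min >= 1)
        stop("rho_min must lie strictly in (0, 1)")
    if (cfg$threshold <= 0) stop("threshold must be positive")
    if (cfg$qc_max_mito <= 0 || cfg$qc_max_mito > 1)
        stop("qc_max_mito must lie in (0, 1]")
    if (cfg$qc_min_features < 0 ||
        cfg$qc_max_features < cfg$qc_min_features)
        stop("QC feature bounds must satisfy 0 <= min <= max")
    if (cfg$lfc_min < 0 || cfg$pct_min < 0 || cfg$pct_min > 1)
        stop("marker thresholds out of range")
    if (is.null(cfg$sc_k)) cfg$sc_k <- cfg$sc$k_clusters
    if (cfg$sc_k < 2L) stop("sc_k must be at least 2")
    class(cfg) <- "MetsigConfig"
    cfg
}

## fixed fan-out of the global seed into per-stage child seeds
.childSeed <- function(seed, stage) {
    offsets <- c(bulk_a = 101L, bulk_b = 202L, tfmap = 303L,
                 kmeans = 404L, sc = 505L, cluster = 606L)
    (as.integer(seed) * 31L + offsets[[stage]]) %% 2147483647L
}

#' Run the full signature pipeline
#'
#' Executes the stages in order -- input simulation (or loading), signature
#' derivation, per-cohort scoring, min/max-line stratification, clinical
#' association, and the single-cell projection (QC, normalization,
#' clustering, per-cluster scoring, marker calling) -- and returns a
#' structured report.  The report is identical for identical
#' (configuration, seed); when `out_dir` is set, per-stage artifacts
#' (signature JSON, score and stratification CSVs, cluster scores, markers
#' and the JSON report) are written there.  A failing stage aborts with the
#' stage name; artifacts of completed stages are retained.
#'
#' @param config a [pipelineConfig()] object.
#' @return the report, an S3 list of class `MetsigReport` (also serialized
#'   to `report.json` under `out_dir` when set).
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "MetsigConfig"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    out_dir <- config$out_dir
    emit <- function(writer) if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        writer(out_dir)
    }

    ## --- inputs -----------------------------------------------------------
    inputs <- stage("inputs", {
        if (is.null(config$counts_a)) {
            spec_a <- config$bulk_a
            spec_a$seed <- .childSeed(config$seed, "bulk_a")
            spec_b <- config$bulk_b
            spec_b$seed <- .childSeed(config$seed, "bulk_b")
            sim_a <- simulateBulkCohort(spec_a)
            sim_b <- simulateBulkCohort(spec_b)
            tfmap <- simulateTFTargets(
                union(sim_a$truth$module_gene_ids,
                      sim_b$truth$module_gene_ids),
                decoy_pool = setdiff(geneIds(sim_a$expr), config$anchor),
                tfs = config$tfs,
                seed = .childSeed(config$seed, "tfmap"))
            list(a = sim_a$expr, b = sim_b$expr,
                 ann = rbind(sim_a$annotation, sim_b$annotation),
                 tfmap = tfmap,
                 truth = list(a = sim_a$truth, b = sim_b$truth))
        } else {
            list(a = readCountsTSV(config$counts_a),
                 b = readCountsTSV(config$counts_b),
                 ann = readSampleAnnotation(config$annotation),
                 tfmap = readTFTargets(config$tf_gmt), truth = NULL)
        }
    })

    ## --- signature --------------------------------------------------------
    sig <- stage("derive_signature",
        deriveSignature(inputs$a, inputs$b, config$anchor, inputs$tfmap,
                        config$tfs, alpha = config$alpha,
                        rho_min = config$rho_min,
                        corMode = config$cor_mode))
    emit(function(d) jsonlite::write_json(
        list(anchor = anchorGene(sig), genes = signatureGenes(sig),
             provenance = signatureProvenance(sig)),
        file.path(d, "signature.json"), auto_unbox = TRUE, digits = NA))

    ## --- scoring & stratification (per cohort) ----------------------------
    strat_one <- function(m) {
        scores <- metsigScore(m, sig)
        model <- fitMinMaxLine(scores, threshold = config$threshold)
        strat <- classifyInside(scores, model)
        assoc <- associateClinical(strat, scores, inputs$ann)
        list(scores = scores, model = model, strat = strat, assoc = assoc)
    }
    res_a <- stage("stratify_cohort_a", strat_one(inputs$a))
    res_b <- stage("stratify_cohort_b", strat_one(inputs$b))
    pooled_inside <- (res_a$assoc$inside_n + res_b$assoc$inside_n) /
        (ncol(inputs$a) + ncol(inputs$b))
    emit(function(d) {
        for (nm in c("a", "b")) {
            r <- if (nm == "a") res_a else res_b
            df <- cbind(as.data.frame(r$scores),
                        as.data.frame(r$strat)[, c("residual", "inside")])
            write.csv(df, file.path(d, sprintf("stratified_%s.csv", nm)),
                      row.names = FALSE, quote = FALSE)
        }
    })

    ## --- single cell ------------------------------------------------------
    sc_res <- stage("single_cell", {
        if (is.null(config$sc_dir)) {
            ## the simulated single-cell dataset carries the derived
            ## signature genes, so the projection is coherent end to end
            sc_spec <- config$sc
            sc_spec$seed <- .childSeed(config$seed, "sc")
            ds <- simulateSCDataset(sc_spec, signature = sig)
            sc_sig <- sig
        } else {
            ds <- readCellDataset(config$sc_dir)
            sc_sig <- if (all(c(signatureGenes(sig), anchorGene(sig))
                              %in% rownames(ds))) sig else builtinMetSig()
        }
        ds <- qcFilter(ds, config$qc_min_features, config$qc_max_features,
                       config$qc_max_mito)
        ds <- logNormalizeCells(ds)
        ds <- clusterCells(ds, k = config$sc_k, n_pcs = config$n_pcs,
                           seed = .childSeed(config$seed, "cluster"))
        cs <- clusterMetsig(ds, sc_sig)
        hi <- cs$cluster[which.max(cs$metsig)]
        mk <- findMarkers(ds, hi, lfc_min = config$lfc_min,
                          pct_min = config$pct_min)
        list(ds = ds, cluster_scores = cs, hi_cluster = hi, markers = mk)
    })
    emit(function(d) {
        write.csv(sc_res$cluster_scores,
                  file.path(d, "cluster_scores.csv"),
                  row.names = FALSE, quote = FALSE)
        write.csv(sc_res$markers, file.path(d, "markers.csv"),
                  row.names = FALSE, quote = FALSE)
    })

    ## --- report -----------------------------------------------------------
    report <- list(
        schema_version = "1.0",
        seed = as.integer(config$seed),
        signature = list(anchor = anchorGene(sig),
                         genes = signatureGenes(sig),
                         n_genes = length(signatureGenes(sig))),
        stratification = list(
            cohort_a = list(inside_n = res_a$assoc$inside_n,
                            inside_fraction = res_a$assoc$inside_fraction,
                            clinical_rho = res_a$assoc$corr$rho,
                            clinical_p = res_a$assoc$corr$p_value,
                            wilcox_p = res_a$assoc$wilcox_p),
            cohort_b = list(inside_n = res_b$assoc$inside_n,
                            inside_fraction = res_b$assoc$inside_fraction,
                            clinical_rho = res_b$assoc$corr$rho,
                            clinical_p = res_b$assoc$corr$p_value,
                            wilcox_p = res_b$assoc$wilcox_p),
            pooled_inside_fraction = pooled_inside),
        single_cell = list(
            n_cells_retained = ncol(sc_res$ds),
            hi_cluster = sc_res$hi_cluster,
            anchor_agrees = attr(sc_res$cluster_scores, "anchor_agrees"),
            n_markers = nrow(sc_res$markers)))
    class(report) <- "MetsigReport"
    emit(function(d) jsonlite::write_json(
        unclass(report), file.path(d, "report.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE))
    invisible(list(report = report, signature = sig,
                   cohort_a = res_a, cohort_b = res_b, sc = sc_res,
                   inputs = inputs))
}
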