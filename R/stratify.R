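## Min/max-point line model, inside/outside classification and the
## clinical-score association of the inside subset.

#' Fit the min/max-point line
#'
#' The stratification reference is the line through the componentwise
#' extremes `(max x, max y)` and `(min x, min y)` of the score pair
#' (signature score as x, z-scored anchor as y).  The two coordinates of
#' each extreme point come from independent maxima/minima, not from any
#' single sample, so the line is always defined when the x-range is
#' positive.
#'
#' @param scores a [MetSigScores-class] object with at least 2 samples.
#' @param threshold residual cutoff stored in the model (default 1.0; on
#'   the z-scored anchor scale this is one standard deviation).
#' @return a [LineModel-class] object.
#' @examples
#' s <- new("MetSigScores", sampleIds = c("a", "b", "c"),
#'          metsig = c(0, 1, 2), anchorZ = c(0, 2, 4),
#'          group = rep("all", 3))
#' fitMinMaxLine(s)  # slope 2, intercept 0
#' @export
fitMinMaxLine <- function(scores, threshold = 1.0) {
    stopifnot(is(scores, "MetSigScores"))
    x <- scores@metsig; y <- scores@anchorZ
    if (length(x) < 2L) stop("at least 2 samples are required")
    if (max(x) == min(x)) stop("zero x-range: line undefined")
    slope <- (max(y) - min(y)) / (max(x) - min(x))
    new("LineModel", slope = slope,
        intercept = max(y) - slope * max(x),
        threshold = threshold, xName = "metsig", yName = "anchor_z")
}

#' Classify samples as inside or outside the line model
#'
#' The residual is `predicted - observed` anchor value; a sample is inside
#' iff `|residual| < threshold`, with a strict inequality, so a residual
#' exactly at the threshold falls outside.
#'
#' @param scores a [MetSigScores-class] object.
#' @param model a [LineModel-class] fitted on the same score pair.
#' @return a [StratifiedSamples-class] object.
#' @export
classifyInside <- function(scores, model) {
    stopifnot(is(scores, "MetSigScores"), is(model, "LineModel"))
    res <- (model@slope * scores@metsig + model@intercept) - scores@anchorZ
    new("StratifiedSamples", sampleIds = scores@sampleIds,
        residual = unname(res),
        inside = abs(unname(res)) < model@threshold,
        threshold = model@threshold)
}

#' Associate the inside subset with the clinical disease-activity score
#'
#' Computes the Spearman correlation between the signature score and the
#' clinical score (DAS28) on the inside subset, the inside fraction of the
#' cohort, inside-vs-outside group medians and a two-sided Wilcoxon
#' rank-sum comparison of the signature score between the groups.  With
#' fewer than 3 inside samples the correlation is undefined and flagged;
#' with an empty outside group the rank-sum comparison is flagged absent
#' while the correlation is still returned.
#'
#' @param strat a [StratifiedSamples-class] object.
#' @param scores the matching [MetSigScores-class] object.
#' @param ann annotation data.frame with `sample_id` and `das28`; DAS28
#'   must be available for every inside sample.
#' @return a list with elements `corr` (list rho/p_value/n), `inside_n`,
#'   `inside_fraction`, `group_stats` (data.frame of per-group medians),
#'   `wilcox_p` and `flags` (character vector of degeneracy notes).
#' @export
associateClinical <- function(strat, scores, ann) {
    stopifnot(is(strat, "StratifiedSamples"), is(scores, "MetSigScores"))
    stopifnot(identical(strat@sampleIds, scores@sampleIds))
    idx <- match(strat@sampleIds, ann$sample_id)
    if (anyNA(idx))
        stop("annotation is missing sample(s): ",
             paste(strat@sampleIds[is.na(idx)], collapse = ", "))
    das28 <- ann$das28[idx]
    inside <- strat@inside
    if (any(is.na(das28[inside])))
        stop("das28 unavailable for inside sample(s)")
    flags <- character()
    if (sum(inside) >= 3L) {
        corr <- spearmanTest(scores@metsig[inside], das28[inside])
    } else {
        corr <- list(rho = NA_real_, p_value = NA_real_, n = sum(inside))
        flags <- c(flags, "fewer than 3 inside samples: association undefined")
    }
    grp <- ifelse(inside, "inside", "outside")
    group_stats <- do.call(rbind, lapply(c("inside", "outside"), function(g) {
        sel <- grp == g
        data.frame(group = g, n = sum(sel),
                   median_metsig = if (any(sel))
                       median(scores@metsig[sel]) else NA_real_,
                   median_das28 = if (any(sel))
                       median(das28[sel], na.rm = TRUE) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    if (all(inside) || all(!inside)) {
        wilcox_p <- NA_real_
        flags <- c(flags, "one stratum empty: rank-sum comparison absent")
    } else {
        wilcox_p <- suppressWarnings(
            wilcox.test(scores@metsig[inside], scores@metsig[!inside],
                        alternative = "two.sided"))$p.value
    }
    list(corr = corr, inside_n = sum(inside),
         inside_fraction = mean(inside), group_stats = group_stats,
         wilcox_p = wilcox_p, flags = flags)
}

#' Screen genes for correlation with the clinical score
#'
#' Computes the per-gene Spearman correlation with DAS28 across samples and
#' returns the genes with `|rho| > rho_cut`, partitioned into directly
#' (rho > 0) and inversely (rho < 0) correlated sets.
#'
#' @param m an [ExpressionMatrix-class]; raw counts are normalized first.
#' @param ann annotation data.frame with `sample_id` and `das28` covering
#'   the samples of `m`.
#' @param rho_cut absolute-correlation threshold in (0, 1); default 0.5.
#' @return a data.frame with columns `gene_id`, `rho`, `direction`
#'   (`"direct"`/`"inverse"`), ordered by decreasing `|rho|`.
#' @export
clinicalGeneScreen <- function(m, ann, rho_cut = 0.5) {
    stopifnot(is(m, "ExpressionMatrix"), rho_cut > 0, rho_cut < 1)
    if (identical(exprUnit(m), "raw_counts")) m <- normalizeCounts(m)
    idx <- match(sampleIds(m), ann$sample_id)
    if (anyNA(idx))
        stop("annotation is missing sample(s): ",
             paste(sampleIds(m)[is.na(idx)], collapse = ", "))
    das28 <- ann$das28[idx]
    keep <- !is.na(das28)
    v <- exprValues(m)[, keep, drop = FALSE]
    rho <- suppressWarnings(
        as.vector(cor(t(v), das28[keep], method = "spearman")))
    hits <- which(!is.na(rho) & abs(rho) > rho_cut)
    out <- data.frame(gene_id = rownames(v)[hits], rho = rho[hits],
                      direction = ifelse(rho[hits] > 0, "direct",
                                         "inverse"),
                      stringsAsFactors = FALSE)
    out[order(-abs(out$rho), out$gene_id), , drop = FALSE]
}
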