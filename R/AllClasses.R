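#' @import methods
#' @importFrom stats cor median na.omit p.adjust pt rnbinom rnorm rpois runif
#'   sd setNames var kmeans prcomp wilcox.test quantile residuals
#' @importFrom utils read.csv read.delim write.csv write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

.EXPR_UNITS <- c("raw_counts", "log_normalized", "z_scored")

#' Gene-by-sample expression matrix
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one gene-by-sample assay (named `"exprs"`) plus the measurement unit.
#' Row names are gene identifiers, column names are sample identifiers; both
#' must be unique.  Raw-count matrices must be non-negative and free of
#' missing values.
#'
#' @slot unit one of `"raw_counts"`, `"log_normalized"`, `"z_scored"`.
#' @export
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         slots = c(unit = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
        msg <- c(msg, sprintf("'unit' must be one of %s",
                              paste(.EXPR_UNITS, collapse = ", ")))
    v <- SummarizedExperiment::assay(object, withDimnames = TRUE)
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene and sample identifiers (dimnames) are required")
    if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
        msg <- c(msg, sprintf("duplicate gene id(s): %s",
                 paste(unique(rownames(v)[duplicated(rownames(v))]),
                       collapse = ", ")))
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
        msg <- c(msg, sprintf("duplicate sample id(s): %s",
                 paste(unique(colnames(v)[duplicated(colnames(v))]),
                       collapse = ", ")))
    if (identical(object@unit, "raw_counts")) {
        if (anyNA(v))
            msg <- c(msg, "raw counts must not contain missing values")
        else if (any(v < 0))
            msg <- c(msg, "raw counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric gene-by-sample matrix with row names (gene ids) and
#'   column names (sample ids).
#' @param unit measurement unit of `values`; one of `"raw_counts"`,
#'   `"log_normalized"`, `"z_scored"`.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("S1", "S2")))
#' expressionMatrix(m)
#' @export
expressionMatrix <- function(values, unit = "raw_counts") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("ExpressionMatrix", se, unit = unit)
}

#' @describeIn expressionMatrix the assay matrix.
#' @param x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn expressionMatrix the measurement unit.
#' @export
exprUnit <- function(x) x@unit

#' @describeIn expressionMatrix gene identifiers (row names).
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn expressionMatrix sample identifiers (column names).
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), object@unit))
})

#' Gene signature definition
#'
#' An ordered gene list anchored to a reference gene, with per-gene
#' provenance describing which derivation filters each gene passed.
#' The anchor gene is never part of the signature itself.
#'
#' @slot anchorGene the anchor gene identifier.
#' @slot genes ordered character vector of signature gene identifiers.
#' @slot provenance data.frame with one row per candidate gene recording the
#'   derivation filters passed (may be empty for curated signatures).
#' @export
setClass("SignatureDefinition",
         slots = c(anchorGene = "character",
                   genes = "character",
                   provenance = "data.frame"))

setValidity("SignatureDefinition", function(object) {
    msg <- character()
    if (length(object@anchorGene) != 1L || !nzchar(object@anchorGene))
        msg <- c(msg, "'anchorGene' must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "'genes' must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "'genes' must be duplicate-free")
    if (object@anchorGene %in% object@genes)
        msg <- c(msg, "the anchor gene cannot be a signature gene")
    if (length(msg)) msg else TRUE
})

#' Construct a SignatureDefinition
#'
#' @param anchorGene anchor gene identifier.
#' @param genes character vector of signature genes (anchor excluded).
#' @param provenance optional data.frame of per-gene filter provenance.
#' @return a [SignatureDefinition-class] object.
#' @examples
#' signatureDefinition("CDC42", c("PSMB6", "COX7A2"))
#' @export
signatureDefinition <- function(anchorGene, genes,
                                provenance = data.frame()) {
    new("SignatureDefinition", anchorGene = anchorGene,
        genes = as.character(genes), provenance = provenance)
}

#' @describeIn signatureDefinition the anchor gene.
#' @param sig a `SignatureDefinition`.
#' @export
anchorGene <- function(sig) sig@anchorGene

#' @describeIn signatureDefinition the signature genes.
#' @export
signatureGenes <- function(sig) sig@genes

#' @describeIn signatureDefinition the per-gene derivation provenance.
#' @export
signatureProvenance <- function(sig) sig@provenance

setMethod("show", "SignatureDefinition", function(object) {
    cat(sprintf("SignatureDefinition: anchor %s, %d genes\n",
                object@anchorGene, length(object@genes)))
    cat(" ", paste(head(object@genes, 10), collapse = ", "),
        if (length(object@genes) > 10) "..." else "", "\n")
})

#' The published six-gene metabolic signature
#'
#' The curated six-gene metabolic signature (ATP5BP, COX7A2, PSMB6, PSME3,
#' GTF3C6, GTF2E2) anchored to CDC42, covering oxidative phosphorylation,
#' proteasome and general-transcription-factor genes co-expressed with the
#' anchor in CD14+ monocytes of rheumatoid-arthritis patients.
#'
#' @return a [SignatureDefinition-class] with anchor `CDC42`.
#' @examples
#' builtinMetSig()
#' @export
builtinMetSig <- function() {
    signatureDefinition(
        anchorGene = "CDC42",
        genes = c("ATP5BP", "COX7A2", "PSMB6", "PSME3", "GTF3C6", "GTF2E2"),
        provenance = data.frame(
            gene_id = c("ATP5BP", "COX7A2", "PSMB6", "PSME3",
                        "GTF3C6", "GTF2E2"),
            de_both_cohorts = TRUE,
            tf_target = TRUE,
            correlation_pass = TRUE,
            curated = TRUE))
}

#' Per-sample signature scores
#'
#' Holds, for one scoring run, the per-sample signature score (sum of
#' z-transformed signature-gene expression) and the z-transformed anchor
#' expression used for stratification, plus the standardization group each
#' sample belonged to.
#'
#' @slot sampleIds sample identifiers.
#' @slot metsig per-sample signature score.
#' @slot anchorZ per-sample z-scored anchor expression.
#' @slot group standardization group of each sample (e.g. cohort).
#' @export
setClass("MetSigScores",
         slots = c(sampleIds = "character",
                   metsig = "numeric",
                   anchorZ = "numeric",
                   group = "character"))

setValidity("MetSigScores", function(object) {
    n <- length(object@sampleIds)
    msg <- character()
    if (length(object@metsig) != n || length(object@anchorZ) != n ||
        length(object@group) != n)
        msg <- c(msg, "score vectors must match the number of samples")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn metsigScore per-sample signature scores as numeric vector.
#' @export
scoreValues <- function(scores) setNames(scores@metsig, scores@sampleIds)

#' @describeIn metsigScore per-sample z-scored anchor expression.
#' @export
anchorZ <- function(scores) setNames(scores@anchorZ, scores@sampleIds)

setMethod("show", "MetSigScores", function(object) {
    cat(sprintf("MetSigScores: %d samples, %d group(s)\n",
                length(object@sampleIds), length(unique(object@group))))
})

#' @export
#' @describeIn metsigScore coerce scores to a data.frame with columns
#'   `sample_id`, `metsig`, `anchor_z`, `group`.
#' @param row.names,optional,... passed on conventionally (unused).
as.data.frame.MetSigScores <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    data.frame(sample_id = x@sampleIds, metsig = x@metsig,
               anchor_z = x@anchorZ, group = x@group,
               stringsAsFactors = FALSE)
}

#' Min/max-point line model
#'
#' The stratification reference line through the componentwise extremes
#' `(max x, max y)` and `(min x, min y)` of a score pair, with the residual
#' threshold that defines the inside/outside classification.
#'
#' @slot slope,intercept line coefficients (y = slope * x + intercept).
#' @slot threshold residual cutoff (same units as y); must be positive.
#' @slot xName,yName names of the predictor and response scores.
#' @export
setClass("LineModel",
         slots = c(slope = "numeric", intercept = "numeric",
                   threshold = "numeric", xName = "character",
                   yName = "character"))

setValidity("LineModel", function(object) {
    msg <- character()
    if (!is.finite(object@slope)) msg <- c(msg, "slope must be finite")
    if (!is.finite(object@intercept)) msg <- c(msg, "intercept must be finite")
    if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
        object@threshold <= 0)
        msg <- c(msg, "threshold must be a positive number")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LineModel", function(object) {
    cat(sprintf("LineModel: %s = %.4g * %s + %.4g (residual threshold %g)\n",
                object@yName, object@slope, object@xName, object@intercept,
                object@threshold))
})

#' Inside/outside sample stratification
#'
#' Per-sample residuals from a [LineModel-class] and the resulting
#' inside/outside labels (`inside` iff `|residual| < threshold`, strict).
#'
#' @slot sampleIds sample identifiers.
#' @slot residual predicted minus observed response per sample.
#' @slot inside logical inside-the-model flag per sample.
#' @slot threshold the residual cutoff used.
#' @export
setClass("StratifiedSamples",
         slots = c(sampleIds = "character", residual = "numeric",
                   inside = "logical", threshold = "numeric"))

setValidity("StratifiedSamples", function(object) {
    n <- length(object@sampleIds)
    msg <- character()
    if (length(object@residual) != n || length(object@inside) != n)
        msg <- c(msg, "residual and inside must match the number of samples")
    if (!identical(object@inside,
                   abs(object@residual) < object@threshold))
        msg <- c(msg, "inside labels must equal |residual| < threshold")
    if (length(msg)) msg else TRUE
})

#' @describeIn classifyInside logical inside-the-model flags.
#' @export
insideModel <- function(strat) setNames(strat@inside, strat@sampleIds)

#' @describeIn classifyInside signed residuals (predicted - observed).
#' @export
residuals.StratifiedSamples <- function(object, ...)
    setNames(object@residual, object@sampleIds)

setMethod("show", "StratifiedSamples", function(object) {
    cat(sprintf("StratifiedSamples: %d samples, %d inside (threshold %g)\n",
                length(object@sampleIds), sum(object@inside),
                object@threshold))
})

#' @export
#' @describeIn classifyInside coerce to data.frame with columns `sample_id`,
#'   `residual`, `inside`.
#' @param row.names,optional,... conventional arguments (unused).
as.data.frame.StratifiedSamples <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    data.frame(sample_id = x@sampleIds, residual = x@residual,
               inside = x@inside, stringsAsFactors = FALSE)
}

#' Single-cell expression dataset
#'
#' A [SingleCellExperiment::SingleCellExperiment] carrying gene-by-cell
#' counts, a per-gene mitochondrial mask (`rowData(x)$mito`) and per-cell QC
#' metrics: `colData(x)$nFeatures` (genes detected with count > 0) and
#' `colData(x)$mitoFraction` (mitochondrial counts / total counts).
#' Cluster labels, when assigned, live in `colData(x)$cluster`.
#'
#' @export
setClass("CellDataset", contains = "SingleCellExperiment")

setValidity("CellDataset", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    rd <- SummarizedExperiment::rowData(object)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    if (!"mito" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a logical 'mito' column")
    if (!all(c("nFeatures", "mitoFraction") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'nFeatures' and 'mitoFraction'")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and cell identifiers are required")
    if (!length(msg)) {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        nf <- Matrix::colSums(cnt > 0)
        if (!isTRUE(all.equal(unname(as.numeric(nf)),
                              as.numeric(cd$nFeatures))))
            msg <- c(msg, "nFeatures inconsistent with the counts matrix")
        tot <- Matrix::colSums(cnt)
        mt <- Matrix::colSums(cnt[rd$mito, , drop = FALSE])
        mf <- ifelse(tot > 0, mt / tot, 0)
        if (!isTRUE(all.equal(unname(as.numeric(mf)),
                              as.numeric(cd$mitoFraction), tolerance = 1e-8)))
            msg <- c(msg, "mitoFraction inconsistent with the counts matrix")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CellDataset
#'
#' QC metrics (detected features, mitochondrial fraction) are computed from
#' the counts at construction time.
#'
#' @param counts gene-by-cell count matrix (dense or `Matrix` sparse) with
#'   gene row names and cell column names.
#' @param mito logical per-gene mitochondrial mask, or `NULL` to flag genes
#'   whose identifier starts with `"MT-"`.
#' @param clusters optional per-cell cluster labels.
#' @return a [CellDataset-class] object.
#' @export
cellDataset <- function(counts, mito = NULL, clusters = NULL) {
    counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
    if (is.null(mito)) mito <- grepl("^MT-", rownames(counts))
    stopifnot(length(mito) == nrow(counts))
    tot <- Matrix::colSums(counts)
    mtc <- Matrix::colSums(counts[mito, , drop = FALSE])
    cd <- S4Vectors::DataFrame(
        nFeatures = as.integer(Matrix::colSums(counts > 0)),
        mitoFraction = as.numeric(ifelse(tot > 0, mtc / tot, 0)),
        row.names = colnames(counts))
    if (!is.null(clusters)) cd$cluster <- clusters
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(mito = as.logical(mito),
                                       row.names = rownames(counts)),
        colData = cd)
    new("CellDataset", sce)
}

#' @describeIn cellDataset per-cell cluster labels (or NULL).
#' @param x a `CellDataset`.
#' @export
cellClusters <- function(x) SummarizedExperiment::colData(x)$cluster

#' @describeIn cellDataset per-cell QC metrics as a data.frame.
#' @export
cellQC <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(cell_id = colnames(x), nFeatures = cd$nFeatures,
               mitoFraction = cd$mitoFraction, stringsAsFactors = FALSE)
}

setMethod("show", "CellDataset", function(object) {
    cl <- cellClusters(object)
    cat(sprintf("CellDataset: %d genes x %d cells (%d mito genes)%s\n",
                nrow(object), ncol(object),
                sum(SummarizedExperiment::rowData(object)$mito),
                if (is.null(cl)) ""
                else sprintf(", %d clusters", length(unique(cl)))))
})
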