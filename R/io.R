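#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is tab-delimited UTF-8 text with a header row of
#' sample identifiers and the gene identifier in the first column.  Row and
#' column order are preserved from the file.
#'
#' @param path path to the TSV file.
#' @return an [ExpressionMatrix-class] with unit `"raw_counts"`.
#' @seealso [writeCountsTSV()]
#' @export
readCountsTSV <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count TSV needs a gene-id column plus at least one sample")
    gene_ids <- df[[1L]]
    sample_ids <- colnames(df)[-1L]
    if (anyDuplicated(sample_ids))
        stop(sprintf("duplicate sample id(s) in header: %s",
             paste(unique(sample_ids[duplicated(sample_ids)]),
                   collapse = ", ")))
    if (anyDuplicated(gene_ids))
        stop(sprintf("duplicate gene id(s): %s",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
    body <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
    if (anyNA(num)) {
        bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                     body[bad[1L], bad[2L]], gene_ids[bad[1L]],
                     sample_ids[bad[2L]]))
    }
    dimnames(num) <- list(gene_ids, sample_ids)
    expressionMatrix(num, unit = "raw_counts")
}

#' Write a count matrix to canonical TSV
#'
#' Writes the tab-delimited layout read by [readCountsTSV()]: header
#' `gene_id` plus sample ids, one gene per row.  Values are written with
#' full precision via [format()] on R's default 15 significant digits;
#' integers print without a decimal point, so integer count matrices
#' round-trip byte-identically.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountsTSV <- function(m, path) {
    stopifnot(is(m, "ExpressionMatrix"))
    v <- exprValues(m)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
    body <- apply(format(v, trim = TRUE, scientific = FALSE), 1L,
                  paste, collapse = "\t")
    writeLines(paste(rownames(v), body, sep = "\t"), con)
    invisible(path)
}

#' Read per-sample clinical annotation from CSV
#'
#' Expects columns `sample_id`, `cohort`, `das28`, `treatment` and
#' optionally `sex`.  DAS28 values must lie in \[0, 10\].
#'
#' @param path path to the CSV file.
#' @return a data.frame with one row per sample.
#' @export
readSampleAnnotation <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    required <- c("sample_id", "cohort", "das28", "treatment")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop(sprintf("annotation is missing column(s): %s",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in annotation")
    df$das28 <- as.numeric(df$das28)
    ok <- is.na(df$das28) | (df$das28 >= 0 & df$das28 <= 10)
    if (!all(ok))
        stop(sprintf("das28 out of [0, 10] for sample(s): %s",
                     paste(df$sample_id[!ok], collapse = ", ")))
    df
}

#' @rdname readSampleAnnotation
#' @param ann annotation data.frame.
#' @param path output file path.
#' @export
writeSampleAnnotation <- function(ann, path) {
    write.csv(ann, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a transcription-factor target map from a GMT file
#'
#' Each GMT line holds a set name, a description and a tab-separated gene
#' list.  The result maps each TF name to its non-empty target gene set.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors (TF name -> target gene ids).
#' @export
readTFTargets <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 1L) < 3L
    if (any(short))
        stop(sprintf("GMT line %d has no target genes", which(short)[1L]))
    tfs <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(tfs))
        stop(sprintf("duplicate TF entr(ies): %s",
                     paste(unique(tfs[duplicated(tfs)]), collapse = ", ")))
    targets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(targets) <- tfs
    targets
}

#' @rdname readTFTargets
#' @param tfmap named list of character vectors (TF -> target genes).
#' @param descriptions optional per-TF description column; defaults to the
#'   TF name.
#' @export
writeTFTargets <- function(tfmap, path, descriptions = names(tfmap)) {
    stopifnot(length(descriptions) == length(tfmap))
    lines <- vapply(seq_along(tfmap), function(i)
        paste(c(names(tfmap)[i], descriptions[i], tfmap[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a single-cell dataset from a matrix-market triplet directory
#'
#' Expects `matrix.mtx` (genes x cells), `features.tsv` (gene ids in the
#' first column) and `barcodes.tsv` (one cell id per line).  Mitochondrial
#' genes are identified by the `"MT-"` prefix unless an explicit mask is
#' given.
#'
#' @param dir directory holding the triplet files.
#' @param mito optional logical per-gene mitochondrial mask.
#' @return a [CellDataset-class].
#' @export
readCellDataset <- function(dir, mito = NULL) {
    mtx <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    if (nrow(feats) != nrow(mtx) || length(cells) != ncol(mtx))
        stop("features/barcodes do not match the matrix dimensions")
    rownames(mtx) <- feats[[1L]]
    colnames(mtx) <- cells
    cellDataset(mtx, mito = mito)
}

#' @rdname readCellDataset
#' @param ds a [CellDataset-class] to write.
#' @export
writeCellDataset <- function(ds, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cnt <- SummarizedExperiment::assay(ds, "counts")
    Matrix::writeMM(cnt, file.path(dir, "matrix.mtx"))
    write.table(data.frame(rownames(ds)),
                file.path(dir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    writeLines(colnames(ds), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}
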