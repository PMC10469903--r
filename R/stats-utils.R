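## Shared statistical utilities: row z-transformation and Spearman
## correlation with a small-sample exact permutation p-value.

.zscore_rows <- function(v) {
    if (ncol(v) < 2L)
        stop("z-transformation needs at least 2 samples per row")
    mu <- rowMeans(v)
    sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
    z <- (v - mu) / sdv
    z[sdv == 0, ] <- 0  # constant rows carry no information
    z
}

#' Row-wise z-transformation
#'
#' Standardizes every gene row to mean 0 and unit sample standard deviation
#' (denominator n - 1).  Constant rows map to all-zero rows rather than
#' erroring, so flat housekeeping genes cannot poison downstream signature
#' scores.
#'
#' @param m an [ExpressionMatrix-class] (unit must not already be
#'   `"z_scored"`) or a plain numeric matrix.
#' @return an object of the same kind with z-scored rows; for
#'   `ExpressionMatrix` input the unit becomes `"z_scored"`.
#' @examples
#' zscoreRows(matrix(1:6, 2, 3, byrow = TRUE,
#'                   dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
#' @export
zscoreRows <- function(m) {
    if (is(m, "ExpressionMatrix")) {
        if (identical(exprUnit(m), "z_scored"))
            stop("matrix is already z-scored")
        expressionMatrix(.zscore_rows(exprValues(m)), unit = "z_scored")
    } else {
        .zscore_rows(as.matrix(m))
    }
}

## all permutations of seq_len(n) as an n! x n integer matrix (n <= 9)
.all_perms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .all_perms(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    row <- 0L
    for (pos in seq_len(n)) {
        idx <- row + seq_len(nrow(sub))
        out[idx, pos] <- n
        out[idx, -pos] <- sub
        row <- row + nrow(sub)
    }
    out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes the Spearman correlation on average ranks (ties averaged) with a
#' two-sided p-value: the t-approximation for n >= 10 and the exact
#' permutation distribution (all n! rank permutations) for n < 10.  A
#' constant input vector leaves the correlation undefined; the result then
#' carries `rho = NA` and a warning is emitted.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return a list with elements `rho`, `p_value` and `n`.
#' @examples
#' spearmanTest(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanTest <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 3L) stop("Spearman correlation needs n >= 3")
    if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant input: Spearman correlation undefined")
        return(list(rho = NA_real_, p_value = NA_real_, n = n))
    }
    rx <- rank(x)
    ry <- rank(y)
    rho <- cor(rx, ry)
    if (n >= 10L) {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tstat), df = n - 2)
        p <- max(min(p, 1), .Machine$double.xmin)
    } else {
        ## exact two-sided permutation p-value over all n! orderings of y
        perms <- .all_perms(n)
        ry_perm <- matrix(ry[perms], nrow(perms), n)
        num <- as.vector(ry_perm %*% rx) - n * mean(rx) * mean(ry)
        den <- (n - 1) * sd(rx) * sd(ry)
        rho_perm <- num / den
        p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    }
    list(rho = rho, p_value = p, n = n)
}
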