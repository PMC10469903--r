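## shared fixture builders; everything is generated in code at test time

random_counts <- function(genes = 10, samples = 6, seed = 1,
                          lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(genes * samples, lambda), genes, samples,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  expressionMatrix(m, unit = "raw_counts")
}

lognorm_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expressionMatrix(values, unit = "log_normalized")
}

## independent brute-force z-sum oracle: explicit loops, sample sd
brute_force_metsig <- function(values, sig_genes, anchor) {
  z <- values * NA_real_
  for (g in rownames(values)) {
    row <- values[g, ]
    s <- sd(row)
    z[g, ] <- if (s == 0) 0 else (row - mean(row)) / s
  }
  list(metsig = vapply(colnames(values),
                       function(s) sum(z[sig_genes, s]), 0),
       anchor_z = z[anchor, ])
}

## exact two-sided rank-sum p-value by enumeration of group assignments
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ew <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - ew)
  ws <- abs(colSums(matrix(r[idx], nrow = n1)) - ew)
  mean(ws >= obs - 1e-12)
}
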