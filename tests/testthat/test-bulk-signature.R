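test_that("anchor mean-split follows the strict-mean rule", {
    m <- lognorm_matrix(matrix(c(10, 20, 30, 40), 1, 4,
                               dimnames = list("CDC42", NULL)),
                        genes = "CDC42")
    expect_identical(as.character(splitByAnchor(m, "CDC42")),
                     c("lo", "lo", "hi", "hi"))
    flat <- lognorm_matrix(matrix(3, 1, 4), genes = "CDC42")
    expect_warning(lab <- splitByAnchor(flat, "CDC42"), "constant")
    expect_true(all(lab == "lo"))
    expect_error(splitByAnchor(m, "NOPE"), "NOPE")
    ## random vector against brute-force mean comparison
    set.seed(31)
    vals <- matrix(rnorm(40, 8), 1, 40, dimnames = list("CDC42", NULL))
    lab <- splitByAnchor(lognorm_matrix(vals, genes = "CDC42"), "CDC42")
    expect_identical(sum(lab == "hi"), sum(vals[1, ] > mean(vals[1, ])))
})

test_that("median-of-ratios size factors behave like the field standard", {
    c1 <- c(10, 100, 40, 7)
    m <- expressionMatrix(cbind(S1 = c1, S2 = 2 * c1) |>
                          (\(x) {rownames(x) <- paste0("g", 1:4); x})())
    out <- normalizeCounts(m)
    sf <- S4Vectors::metadata(out)$size_factors
    expect_equal(unname(sf[2] / sf[1]), 2)
    expect_equal(exprValues(out)[, 1], exprValues(out)[, 2])
    ## identical columns give unit factors
    m2 <- expressionMatrix(cbind(S1 = c1, S2 = c1) |>
                           (\(x) {rownames(x) <- paste0("g", 1:4); x})())
    expect_equal(unname(S4Vectors::metadata(normalizeCounts(m2))$size_factors),
                 c(1, 1))
    ## independent oracle on a random matrix
    skip_if_not_installed("DESeq2")
    em <- random_counts(genes = 50, samples = 8, seed = 7)
    sf_ours <- S4Vectors::metadata(normalizeCounts(em))$size_factors
    sf_ref <- DESeq2::estimateSizeFactorsForMatrix(exprValues(em))
    expect_equal(unname(sf_ours), unname(sf_ref), tolerance = 1e-12)
})

test_that("normalization falls back to library sizes without a reference", {
    m <- expressionMatrix(matrix(c(0, 5, 3, 0), 2, 2,
                                 dimnames = list(c("a", "b"),
                                                 c("S1", "S2"))))
    expect_warning(out <- normalizeCounts(m), "library-size")
    expect_identical(exprUnit(out), "log_normalized")
})

test_that("Welch DE test handles signal, null and degenerate genes", {
    labels <- factor(rep(c("hi", "lo"), each = 4), levels = c("hi", "lo"))
    vals <- rbind(
        flat   = rep(2, 8),
        sep    = c(rep(3, 4), rep(2, 4)),       # lfc 1, zero variance
        noise  = c(1.2, 1.9, 1.4, 1.7, 1.5, 1.3, 1.8, 1.6))
    de <- deTest(lognorm_matrix(vals, genes = rownames(vals)), labels)
    expect_equal(de$log2_fold_change[1], 0)
    expect_equal(de$p_value[1], 1)
    expect_equal(de$log2_fold_change[2], 1)
    expect_equal(de$p_value[2], .Machine$double.xmin)
    ## ordinary gene agrees with the reference Welch implementation
    ref <- t.test(vals[3, 1:4], vals[3, 5:8])
    expect_equal(de$p_value[3], ref$p.value)
    expect_equal(de$log2_fold_change[3],
                 unname(ref$estimate[1] - ref$estimate[2]))
    expect_error(deTest(lognorm_matrix(vals, genes = rownames(vals)),
                        factor(c("hi", "hi", rep("lo", 6)),
                               levels = c("hi", "lo"))),
                 "at least 3")
})

test_that("cohort DEG intersection uses significance and sign", {
    a <- data.frame(gene_id = c("A", "B", "C", "D"),
                    log2_fold_change = c(1, 1, -1, 1),
                    p_value = c(0.01, 0.02, 0.03, 0.5))
    b <- data.frame(gene_id = c("B", "C", "D", "E"),
                    log2_fold_change = c(2, -2, 1, 1),
                    p_value = c(0.01, 0.01, 0.01, 0.01))
    out <- intersectDEGs(a, b)
    expect_setequal(out$common, c("B", "C"))
    expect_equal(out$fraction_of_a, 2 / 3)
    expect_equal(out$fraction_of_b, 2 / 4)
    ## discordant sign is excluded
    b$log2_fold_change[2] <- 2
    a$log2_fold_change[3] <- -1
    b$log2_fold_change[1] <- -2
    out2 <- intersectDEGs(a, b)
    expect_false("B" %in% out2$common)
})

test_that("co-expression K-means recovers separable structure", {
    up <- rep(c(-1, 1), 5)
    z <- rbind(matrix(rep(up, 4), 4, 10, byrow = TRUE),
               matrix(rep(-up, 4), 4, 10, byrow = TRUE))
    rownames(z) <- paste0("g", 1:8)
    cl <- kmeansCoexpression(z, k = 2, seed = 1)
    expect_equal(length(unique(cl[1:4])), 1L)
    expect_equal(length(unique(cl[5:8])), 1L)
    expect_false(cl[1] == cl[5])
    ## duplicate rows always co-cluster
    expect_equal(cl[["g1"]], cl[["g2"]])
    expect_error(kmeansCoexpression(z, k = 9), "exceeds")
    expect_error(kmeansCoexpression(z, k = 1), "at least 2")
})

test_that("TF-target filtering is a union-membership restriction", {
    tfmap <- list(NFE2L1 = c("g1"), HOXA2 = c("g3"), NFRKB = c("g9"))
    genes <- c("g1", "g2", "g3")
    expect_setequal(tfTargetFilter(genes, tfmap, c("NFE2L1", "HOXA2")),
                    c("g1", "g3"))
    expect_error(tfTargetFilter(genes, tfmap, c("NFE2L1", "MISSING")),
                 "MISSING")
    expect_warning(out <- tfTargetFilter("g2", tfmap, "NFE2L1"), "no cand")
    expect_length(out, 0)
    ## brute-force union membership on a random map
    set.seed(12)
    pool <- sprintf("g%02d", 1:40)
    tfmap2 <- lapply(setNames(1:3, c("A", "B", "C")),
                     function(i) sample(pool, 10))
    genes2 <- sample(pool, 15)
    expect_setequal(tfTargetFilter(genes2, tfmap2, c("A", "C")),
                    genes2[genes2 %in% union(tfmap2$A, tfmap2$C)])
})

test_that("correlation filter keeps coherent genes and prunes strays", {
    ## candidates duplicating the anchor are all retained
    set.seed(41)
    base <- rnorm(30)
    vals <- rbind(CDC42 = base, c1 = base, c2 = base, c3 = base)
    m <- lognorm_matrix(vals, genes = rownames(vals))
    expect_setequal(as.character(
        correlationFilter(c("c1", "c2", "c3"), "CDC42", m)),
        c("c1", "c2", "c3"))
    ## an anti-correlated candidate is pruned
    vals2 <- rbind(CDC42 = base, good = base + rnorm(30, 0, 0.1),
                   bad = -base)
    kept <- correlationFilter(c("good", "bad"), "CDC42",
                              lognorm_matrix(vals2, genes = rownames(vals2)))
    expect_identical(as.character(kept), "good")
    expect_identical(attr(kept, "trace")$gene_id, "bad")
    ## a planted independent candidate is pruned in nearly all seeds
    hits <- 0L
    for (s in 1:20) {
        set.seed(s)
        sig <- rnorm(200)
        vals3 <- rbind(CDC42 = sig + rnorm(200, 0, 0.3),
                       m1 = sig + rnorm(200, 0, 0.3),
                       m2 = sig + rnorm(200, 0, 0.3),
                       indep = rnorm(200))
        kept <- correlationFilter(c("m1", "m2", "indep"), "CDC42",
                                  lognorm_matrix(vals3,
                                                 genes = rownames(vals3)))
        if (!"indep" %in% kept && all(c("m1", "m2") %in% kept))
            hits <- hits + 1L
    }
    expect_gte(hits, 19)
    ## full pruning raises an informative error carrying the trace
    vals4 <- rbind(CDC42 = base, u1 = rev(base), u2 = -base)
    err <- tryCatch(correlationFilter(c("u1", "u2"), "CDC42",
                    lognorm_matrix(vals4, genes = rownames(vals4))),
                    error = identity)
    expect_match(conditionMessage(err), "empty signature")
})

test_that("the shipped six-gene signature is a valid definition", {
    sig <- builtinMetSig()
    expect_s4_class(sig, "SignatureDefinition")
    expect_identical(anchorGene(sig), "CDC42")
    expect_identical(signatureGenes(sig),
                     c("ATP5BP", "COX7A2", "PSMB6", "PSME3",
                       "GTF3C6", "GTF2E2"))
    expect_false(anchorGene(sig) %in% signatureGenes(sig))
    expect_error(signatureDefinition("CDC42", c("CDC42", "X")), "anchor")
    expect_error(signatureDefinition("CDC42", character()), "non-empty")
})

test_that("signature derivation recovers a planted module end to end", {
    sa <- simulateBulkCohort(bulkSimSpec(
        n_samples = 60, n_genes = 400, module_genes = 10,
        tracked_fraction = 1, cohort = "A", seed = 51, layout_seed = 5))
    sb <- simulateBulkCohort(bulkSimSpec(
        n_samples = 60, n_genes = 400, module_genes = 10,
        tracked_fraction = 1, cohort = "B", seed = 52, layout_seed = 5))
    mod <- sa$truth$module_gene_ids
    tfmap <- simulateTFTargets(mod, decoy_pool = geneIds(sa$expr),
                               n_decoys = 50, seed = 5)
    sig <- deriveSignature(sa$expr, sb$expr, "CDC42", tfmap,
                           c("NFE2L1", "HOXA2", "NFRKB"))
    expect_gte(mean(mod %in% signatureGenes(sig)), 0.8)
    expect_lte(sum(!signatureGenes(sig) %in% mod), 5)
    prov <- signatureProvenance(sig)
    expect_true(all(signatureGenes(sig) %in% prov$gene_id))
    expect_true(all(prov$correlation_pass[
        match(signatureGenes(sig), prov$gene_id)]))
    ## a TF map covering no differential gene annihilates the signature
    tfmap_off <- list(NFE2L1 = "zzz1", HOXA2 = "zzz2", NFRKB = "zzz3")
    expect_error(suppressWarnings(
        deriveSignature(sa$expr, sb$expr, "CDC42", tfmap_off,
                        c("NFE2L1", "HOXA2", "NFRKB"))),
        "empty signature")
})

test_that("null cohorts do not yield a signature", {
    ## with no planted coupling the filter chain collapses to (near-)empty
    empties <- 0L
    for (s in 1:5) {
        sa <- simulateBulkCohort(bulkSimSpec(
            n_samples = 40, n_genes = 300, module_genes = 10,
            module_beta = 0, anchor_beta = 1, tracked_fraction = 1,
            cohort = "A", seed = 60 + s, layout_seed = s))
        sb <- simulateBulkCohort(bulkSimSpec(
            n_samples = 40, n_genes = 300, module_genes = 10,
            module_beta = 0, anchor_beta = 1, tracked_fraction = 1,
            cohort = "B", seed = 80 + s, layout_seed = s))
        tfmap <- simulateTFTargets(sa$truth$module_gene_ids,
                                   decoy_pool = geneIds(sa$expr),
                                   n_decoys = 100, seed = s)
        sig <- tryCatch(suppressWarnings(
            deriveSignature(sa$expr, sb$expr, "CDC42", tfmap,
                            c("NFE2L1", "HOXA2", "NFRKB"))),
            error = function(e) NULL)
        if (is.null(sig) || length(signatureGenes(sig)) <= 2L)
            empties <- empties + 1L
    }
    expect_gte(empties, 4)
})

test_that("signature scoring is a z-sum with the stated invariances", {
    m <- lognorm_matrix(matrix(c(1, 3, 2, 6), 2, 2, byrow = TRUE),
                        genes = c("a", "b"), samples = c("s1", "s2"))
    sig <- signatureDefinition("b", "a")
    sc <- metsigScore(m, sig)
    expect_equal(unname(scoreValues(sc)), c(-sqrt(2) / 2, sqrt(2) / 2))
    ## two signature genes: the example 2x2 matrix gives -+sqrt(2)
    m3 <- lognorm_matrix(rbind(c(1, 3), c(2, 6), c(5, 4)),
                         genes = c("a", "b", "anchor"),
                         samples = c("s1", "s2"))
    sc3 <- metsigScore(m3, signatureDefinition("anchor", c("a", "b")))
    expect_equal(unname(scoreValues(sc3)), c(-sqrt(2), sqrt(2)),
                 tolerance = 1e-10)
    ## constant matrix scores zero everywhere
    mc <- lognorm_matrix(matrix(4, 3, 3), genes = c("a", "b", "anchor"))
    scc <- metsigScore(mc, signatureDefinition("anchor", c("a", "b")))
    expect_true(all(scoreValues(scc) == 0))
    ## gene-order permutation and per-gene affine rescaling change nothing
    set.seed(71)
    vals <- matrix(rnorm(50, 5), 5, 10,
                   dimnames = list(c("a", "b", "c", "d", "anchor"), NULL))
    m4 <- lognorm_matrix(vals, genes = rownames(vals))
    s_fwd <- metsigScore(m4, signatureDefinition("anchor",
                                                 c("a", "b", "c", "d")))
    s_rev <- metsigScore(m4, signatureDefinition("anchor",
                                                 c("d", "c", "b", "a")))
    expect_equal(scoreValues(s_fwd), scoreValues(s_rev))
    vals2 <- vals * c(2, 3, 0.5, 10, 7) + c(1, -2, 0, 5, 3)
    s_aff <- metsigScore(lognorm_matrix(vals2, genes = rownames(vals)),
                         signatureDefinition("anchor",
                                             c("a", "b", "c", "d")))
    expect_equal(scoreValues(s_aff), scoreValues(s_fwd),
                 tolerance = 1e-10)
    ## missing genes are a hard error
    expect_error(metsigScore(m4, signatureDefinition("anchor",
                                                     c("a", "nope"))),
                 "nope")
    ## per-group standardization: scores sum to zero within each group
    grp <- rep(c("x", "y"), each = 5)
    s_g <- metsigScore(m4, signatureDefinition("anchor", c("a", "b")),
                       groups = grp)
    expect_equal(sum(scoreValues(s_g)[grp == "x"]), 0, tolerance = 1e-10)
    expect_equal(sum(scoreValues(s_g)[grp == "y"]), 0, tolerance = 1e-10)
})
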