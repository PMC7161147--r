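test_that("every QC cutoff is honored at its boundary", {
    m <- makeQcMatrix()
    # neutralize the gene-prevalence filter for the cell-level boundary check
    out <- qcFilter(m, minCellFrac = 0)
    kept <- colnames(out)
    expect_false("det499" %in% kept)
    expect_true("det500" %in% kept)
    expect_false("lo1999" %in% kept)
    expect_true("lo2000" %in% kept)
    expect_true("hi9000" %in% kept)
    expect_false("hi9001" %in% kept)
    expect_true("mito5" %in% kept)
    expect_false("mito5p" %in% kept)
})

test_that("genes must be detected in at least the stated fraction of cells", {
    set.seed(2)
    m <- matrix(rpois(60 * 30, 200), 60, 30,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("c%02d", 1:30)))
    m["g01", ] <- 0L; m["g01", 1:3] <- 100L    # exactly 10% of 30 cells
    m["g02", ] <- 0L; m["g02", 1:2] <- 100L    # 6.7%: removed
    out <- qcFilter(m, minGenes = 10, countRange = c(1, 1e9))
    expect_true("g01" %in% rownames(out))
    expect_false("g02" %in% rownames(out))
    # brute-force recount of survivors
    keepGene <- rowSums(m > 0) >= 0.10 * ncol(m)
    expect_setequal(rownames(out), rownames(m)[keepGene])
})

test_that("QC is invariant to input order and can empty out with an error", {
    sc <- simulateCounts(nCells = 60, nGenes = 300, nModules = 2,
                         moduleSize = 100, seed = 9)
    out1 <- qcFilter(sc$counts, minGenes = 100, countRange = c(500, 1e6))
    perm <- sample(ncol(sc$counts)); gperm <- sample(nrow(sc$counts))
    out2 <- qcFilter(sc$counts[gperm, perm], minGenes = 100,
                     countRange = c(500, 1e6))
    expect_setequal(colnames(out1), colnames(out2))
    expect_setequal(rownames(out1), rownames(out2))
    expect_error(qcFilter(sc$counts, countRange = c(1e8, 1e9)),
                 "every cell")
})

test_that("the detected-gene reading of the count window is available", {
    m <- makeQcMatrix()
    out <- qcFilter(m, minCellFrac = 0, countRange = c(501, 650),
                    byDetected = TRUE)
    expect_false("det500" %in% colnames(out))  # 500 detected < window low 501
    expect_true("det500" %in% colnames(
        qcFilter(m, minCellFrac = 0, countRange = c(500, 650),
                 byDetected = TRUE)))
})

test_that("log normalization follows ln(1 + cpm-scaled counts)", {
    m <- matrix(c(0L, 1L, 4L, 5L), 2, 2,
                dimnames = list(c("a", "b"), c("c1", "c2")))
    ln <- logNormalize(m)
    expect_equal(ln["a", "c1"], 0)
    expect_equal(ln["b", "c1"], log(1 + 1e6), tolerance = 1e-9)
    expect_equal(ln["b", "c1"], 13.8155, tolerance = 1e-4)
    # per-cell scale invariance
    expect_equal(logNormalize(m * 2L), ln)
    expect_error(logNormalize(matrix(0L, 2, 1)), "zero-total")
})

test_that("log normalization matches the Seurat implementation", {
    sc <- simulateCounts(nCells = 25, nGenes = 80, nModules = 1,
                         moduleSize = 20, nMitoGenes = 5, nCcGenes = 5,
                         seed = 4)
    ours <- logNormalize(sc$counts)
    theirs <- as.matrix(suppressWarnings(
        Seurat::LogNormalize(sc$counts, scale.factor = 1e6,
                             verbose = FALSE)))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("gene-set scores are centred under the null and track planted phases", {
    sc <- simulateCounts(nCells = 100, nGenes = 600, nModules = 0,
                         moduleSize = 0, nMitoGenes = 0, nCcGenes = 40,
                         nClusters = 1, seed = 15)
    ln <- logNormalize(sc$counts)
    # null set: random non-phase genes score near zero on average
    nullSet <- setdiff(rownames(ln), c(sc$manifest$g1s_genes,
                                       sc$manifest$g2m_genes))[1:40]
    s0 <- geneSetScore(ln, nullSet, seed = 2)
    expect_lt(abs(mean(s0)), 0.2)
    # planted G1/S effect
    s1 <- geneSetScore(ln, sc$manifest$g1s_genes, seed = 2)
    phase <- sc$cellMeta$phase
    expect_gt(mean(s1[phase == "G1S"]), mean(s1[phase != "G1S"]))
    # determinism
    expect_identical(s1, geneSetScore(ln, sc$manifest$g1s_genes, seed = 2))
    expect_error(geneSetScore(ln, c("nope1", "nope2")), "empty")
})

test_that("covariate regression produces exactly orthogonal residuals", {
    set.seed(8)
    n <- 50
    covar <- data.frame(mito = rnorm(n), cc = rnorm(n))
    y <- matrix(rnorm(n * 20), 20, n,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    res <- regressOut(y, covar)
    expect_lt(max(abs(res %*% covar$mito)), 1e-8)
    expect_lt(max(abs(res %*% covar$cc)), 1e-8)
    expect_lt(max(abs(rowSums(res))), 1e-8)   # intercept removed

    # a gene exactly linear in a covariate vanishes
    y2 <- rbind(lin = 3 + 2 * covar$mito, y)
    res2 <- regressOut(y2, covar)
    expect_lt(max(abs(res2["lin", ])), 1e-10)

    # a covariate orthogonal to a gene leaves the centred values
    x <- rep(c(-1, 1), length.out = n)
    g <- rep(c(1, 1, 5, 5), length.out = n)   # orthogonal to x by design
    stopifnot(abs(sum(x * (g - mean(g)))) < 1e-12)
    res3 <- regressOut(matrix(g, 1, n, dimnames = list("g", NULL)),
                       data.frame(x = x))
    expect_equal(as.numeric(res3), g - mean(g), tolerance = 1e-12)

    expect_error(regressOut(y, data.frame(a = covar$mito,
                                          b = 2 * covar$mito)),
                 "collinear.*b")
})

test_that("variable-gene bounds are inclusive and match a recount", {
    # three-cell genes whose mean and variance are exact in floating point:
    # gene (m-d, m, m+d) has mean m and variance d^2, so VMR = d^2 / m
    m <- rbind(
        meanLo   = c(-0.4, 0.4, 1.2),   # mean 0.4 < 0.5 -> excluded
        bothEdge = c(0, 0.5, 1),        # mean 0.5, VMR 0.5: both inclusive
        mid      = c(1, 3, 5),          # mean 3, VMR 4/3
        vmrEdge  = c(0, 5, 10),         # mean 5, VMR exactly 5: kept
        vmrOver  = c(-0.5, 5, 10.5),    # VMR 6.05 > 5 -> excluded
        meanEdge = c(4, 8, 12),         # mean exactly 8, VMR 2: kept
        meanOver = c(4.1, 8.1, 12.1),   # mean 8.1 -> excluded
        konst    = c(2, 2, 2))          # VMR 0 -> excluded
    colnames(m) <- c("c1", "c2", "c3")
    expect_setequal(variableGenes(m),
                    c("bothEdge", "mid", "vmrEdge", "meanEdge"))

    # recount oracle on a simulated 200-gene matrix
    sc <- simulateCounts(nCells = 80, nGenes = 200, nModules = 1,
                         moduleSize = 50, seed = 12)
    ln <- logNormalize(sc$counts)
    vg2 <- variableGenes(ln)
    mu <- rowMeans(ln); v <- apply(ln, 1, var)
    expect_setequal(vg2, rownames(ln)[mu >= 0.5 & mu <= 8 &
                                      v / mu >= 0.5 & v / mu <= 5])
})
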