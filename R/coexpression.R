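#' @include enrichment.R
NULL

#' Quality-control filtering of a single-cell count matrix
#'
#' Applies the cortical-dataset thresholds in their stated order:
#' (1) remove cells with fewer than `minGenes` detected genes;
#' (2) remove genes detected in fewer than `minCellFrac` of the remaining
#' cells; (3) remove cells whose total counts fall outside `countRange`
#' (inclusive) or whose mitochondrial fraction exceeds `maxMitoFrac`.
#' Totals and fractions are recomputed after the gene filter.
#'
#' @param counts genes x cells integer matrix (raw counts) with dimnames.
#' @param minGenes minimum detected genes per cell (default 500).
#' @param minCellFrac minimum fraction of cells a gene must be detected in
#'   (default 0.10).
#' @param countRange inclusive total-count window per cell (default
#'   2000-9000, read as total transcript counts; see `byDetected`).
#' @param maxMitoFrac maximum mitochondrial count fraction (default 0.05).
#' @param mitoGenes character vector of mitochondrial gene ids; defaults to
#'   rownames starting `MT-`.
#' @param byDetected interpret `countRange` as detected-gene numbers rather
#'   than total transcript counts (the alternative reading of the
#'   thresholds).
#' @return the filtered count matrix, with attribute `"qc"` summarizing the
#'   cells/genes removed at each step.
#' @export
qcFilter <- function(counts, minGenes = 500, minCellFrac = 0.10,
                     countRange = c(2000, 9000), maxMitoFrac = 0.05,
                     mitoGenes = NULL, byDetected = FALSE) {
    stopifnot(is.matrix(counts), !is.null(rownames(counts)))
    if (is.null(mitoGenes))
        mitoGenes <- grep("^MT-", rownames(counts), value = TRUE)
    detected <- colSums(counts > 0)
    keepCell1 <- detected >= minGenes
    m <- counts[, keepCell1, drop = FALSE]
    keepGene <- rowSums(m > 0) >= minCellFrac * ncol(m)
    m <- m[keepGene, , drop = FALSE]
    totals <- colSums(m)
    mito <- intersect(mitoGenes, rownames(m))
    mitoFrac <- if (length(mito)) colSums(m[mito, , drop = FALSE]) / totals
                else rep(0, ncol(m))
    rangeStat <- if (byDetected) colSums(m > 0) else totals
    keepCell2 <- rangeStat >= countRange[1L] & rangeStat <= countRange[2L] &
        mitoFrac <= maxMitoFrac
    out <- m[, keepCell2, drop = FALSE]
    if (ncol(out) == 0L)
        stop("QC filtering removed every cell")
    attr(out, "qc") <- list(
        cells_low_detection = sum(!keepCell1),
        genes_low_prevalence = sum(!keepGene),
        cells_out_of_range = sum(!keepCell2),
        n_cells = ncol(out), n_genes = nrow(out))
    out
}

#' LogNormalize a count matrix
#'
#' `value = ln(1 + count / cell_total * scale)` with the scale factor of
#' 1,000,000 used for the cortical dataset (counts per million, log1p).
#' Values are invariant to rescaling all counts within a cell.
#'
#' @param counts genes x cells matrix; every column total must be > 0.
#' @param scale scale factor (default 1e6).
#' @return numeric matrix of the same shape.
#' @export
logNormalize <- function(counts, scale = 1e6) {
    totals <- colSums(counts)
    if (any(totals <= 0)) stop("zero-total cell(s): cannot normalize")
    log1p(sweep(counts, 2L, totals, "/") * scale)
}

#' Per-cell gene-set score with expression-matched controls
#'
#' The cell-cycle scoring construction: the score of a cell is the mean
#' normalized expression of the set genes minus the mean of a control pool,
#' where controls are drawn (per set gene, `nCtrl` draws) from the same
#' average-expression bin, so the score is centred near 0 for sets with no
#' coordinated signal.
#'
#' @param normalized genes x cells normalized matrix.
#' @param geneSet character vector of set genes (must intersect rownames).
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl control genes drawn per set gene (default 100, with
#'   replacement).
#' @param seed RNG seed for the control draws.
#' @return numeric per-cell score vector.
#' @export
geneSetScore <- function(normalized, geneSet, nBins = 25, nCtrl = 100,
                         seed = 1) {
    geneSet <- intersect(geneSet, rownames(normalized))
    if (length(geneSet) == 0L)
        stop("gene set is empty after intersecting with the matrix")
    avg <- rowMeans(normalized)
    nBins <- min(nBins, length(avg))
    bin <- cut(rank(avg, ties.method = "first"), breaks = nBins,
               labels = FALSE)
    names(bin) <- rownames(normalized)
    ctrl <- with_seed(seed, {
        unlist(lapply(geneSet, function(g) {
            pool <- names(bin)[bin == bin[[g]]]
            sample(pool, nCtrl, replace = TRUE)
        }))
    })
    setMean <- colMeans(normalized[geneSet, , drop = FALSE])
    ctrlMean <- colMeans(normalized[ctrl, , drop = FALSE])
    setMean - ctrlMean
}

#' Regress covariates out of a normalized matrix
#'
#' Per gene, ordinary least squares of expression on the covariates (with
#' intercept); the returned matrix holds the residuals, which are exactly
#' orthogonal to every covariate. Used to remove cell-to-cell variation
#' driven by mitochondrial content and cell-cycle scores before network
#' construction.
#'
#' @param normalized genes x cells matrix.
#' @param covariates data.frame or matrix of per-cell covariates (rows =
#'   cells, aligned with columns of `normalized`).
#' @return residual matrix, same shape as `normalized`.
#' @export
regressOut <- function(normalized, covariates) {
    X <- as.matrix(covariates)
    if (nrow(X) != ncol(normalized))
        stop("covariate rows must align with matrix columns (cells)")
    design <- cbind(`(Intercept)` = 1, X)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
        dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
        stop("rank-deficient design; collinear covariate(s): ",
             paste(dropped, collapse = ", "))
    }
    res <- t(qr.resid(qrd, t(normalized)))
    dimnames(res) <- dimnames(normalized)
    res
}

#' Select highly variable genes by mean and variance-to-mean ratio
#'
#' Genes whose average normalized expression lies in `meanRange` and whose
#' variance-to-mean ratio lies in `vmrRange`, both inclusive (the cortical
#' thresholds: mean in [0.5, 8], VMR in [0.5, 5]).
#'
#' @param normalized genes x cells matrix.
#' @param meanRange,vmrRange inclusive bounds.
#' @return character vector of gene ids.
#' @export
variableGenes <- function(normalized, meanRange = c(0.5, 8),
                          vmrRange = c(0.5, 5)) {
    if (nrow(normalized) == 0L || ncol(normalized) == 0L)
        stop("empty matrix")
    mu <- rowMeans(normalized)
    v <- apply(normalized, 1L, var)
    vmr <- ifelse(mu > 0, v / mu, 0)
    keep <- mu >= meanRange[1L] & mu <= meanRange[2L] &
        vmr >= vmrRange[1L] & vmr <= vmrRange[2L]
    rownames(normalized)[keep]
}
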