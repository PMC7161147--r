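#' @include AllClasses.R
NULL

#' Accessors for sncRegulome classes
#'
#' `regions()` and `linkage()` extract the region `GRanges` and the
#' region-gene linkage table from a [RegulatorySet-class]; `regionIds()` and
#' `regionClass()` extract per-region identifiers and classes;
#' `sncLineage()` and `sncFrequency()` extract SNC metadata from an
#' [SNCCatalog-class]; `observedStat()`, `permPvalue()` and `permZscore()`
#' read a [PermutationResult-class]; `motifId()` and `maxScore()` read a
#' [MotifMatrix-class].
#'
#' @param x an object of the respective class.
#' @return the slot or metadata vector named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setMethod("regions", "RegulatorySet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("linkage", function(x) standardGeneric("linkage"))
#' @rdname accessors
#' @export
setMethod("linkage", "RegulatorySet", function(x) x@linkage)

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setMethod("regionIds", "RegulatorySet",
    function(x) mcols(x@regions)$region_id)
#' @rdname accessors
#' @export
setMethod("regionIds", "GRanges", function(x) mcols(x)$region_id)

#' @rdname accessors
#' @export
setGeneric("regionClass", function(x) standardGeneric("regionClass"))
#' @rdname accessors
#' @export
setMethod("regionClass", "RegulatorySet",
    function(x) mcols(x@regions)$region_class)

#' @rdname accessors
#' @export
setGeneric("sncLineage", function(x) standardGeneric("sncLineage"))
#' @rdname accessors
#' @export
setMethod("sncLineage", "SNCCatalog", function(x) mcols(x)$lineage)

#' @rdname accessors
#' @export
setGeneric("sncFrequency", function(x) standardGeneric("sncFrequency"))
#' @rdname accessors
#' @export
setMethod("sncFrequency", "SNCCatalog", function(x) mcols(x)$frequency)

#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname accessors
#' @export
setMethod("observedStat", "PermutationResult", function(x) x@observed)

#' @rdname accessors
#' @export
setGeneric("permPvalue", function(x) standardGeneric("permPvalue"))
#' @rdname accessors
#' @export
setMethod("permPvalue", "PermutationResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("permZscore", function(x) standardGeneric("permZscore"))
#' @rdname accessors
#' @export
setMethod("permZscore", "PermutationResult", function(x) x@zScore)

#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setMethod("motifId", "MotifMatrix", function(x) x@motifId)

#' @rdname accessors
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))
#' @rdname accessors
#' @export
setMethod("maxScore", "MotifMatrix", function(x) {
    sum(apply(logOddsMatrix(x)[.DNA_BASES, , drop = FALSE], 2L, max))
})

#' Log2-odds scoring matrix of a motif
#'
#' Returns the 5 x m log2-odds matrix used by [scanPWM()]: rows A, C, G, T
#' scored as `log2((p + pseudocount') / bg)` after pseudocount smoothing and
#' renormalization, plus a fifth row `N` of zeros (positions with unknown
#' base contribute background-level evidence, i.e. 0).
#'
#' @param x a [MotifMatrix-class].
#' @return numeric matrix with rows A, C, G, T, N.
#' @export
logOddsMatrix <- function(x) {
    stopifnot(is(x, "MotifMatrix"))
    p <- x@profile + x@pseudocount
    p <- sweep(p, 2L, colSums(p), "/")
    lo <- log2(p / x@background)
    rbind(lo, N = 0)
}

#' Subset a RegulatorySet by region
#'
#' Subsets the regions; the linkage table is restricted to the retained
#' region ids.
#'
#' @param x a [RegulatorySet-class].
#' @param i index into the regions (logical, integer, or region_id character).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "RegulatorySet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, regionIds(x))
    gr <- x@regions[i]
    keep <- x@linkage$region_id %in% mcols(gr)$region_id
    initialize(x, regions = gr, linkage = x@linkage[keep, , drop = FALSE])
})

setMethod("show", "SNCCatalog", function(object) {
    n <- length(object)
    nm <- sum(mcols(object)$lineage == "modern")
    cat("SNCCatalog with", n, "changes (", nm, "modern,", n - nm, "archaic )\n")
    if (n) callNextMethod()
})

setMethod("show", "RegulatorySet", function(object) {
    gr <- object@regions
    tab <- table(factor(mcols(gr)$region_class, levels = .VALID_CLASSES))
    cat("RegulatorySet:", length(gr), "regions (",
        tab[["enhancer"]], "enhancers,", tab[["promoter"]], "promoters );",
        nrow(object@linkage), "region-gene links;",
        length(unique(object@linkage$gene_id)), "genes\n")
    if (!is.null(mcols(gr)$n_modern))
        cat("  annotated: ", sum(mcols(gr)$n_modern > 0), "regions with >=1 mSNC,",
            sum(mcols(gr)$n_archaic > 0), "with >=1 archaic SNC\n")
})

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult: observed =", object@observed,
        "| null", sprintf("%.2f +/- %.2f", object@permMean, object@permSd),
        "| z =", sprintf("%.2f", object@zScore),
        "| p =", format(object@pValue, digits = 4),
        paste0("(", object@alternative, ", ", object@nPerm, " permutations)\n"))
})

setMethod("show", "MotifMatrix", function(object) {
    cons <- paste(.DNA_BASES[apply(object@profile, 2L, which.max)],
                  collapse = "")
    cat("MotifMatrix", object@motifId, ":", ncol(object@profile),
        "bp, consensus", cons, "\n")
})
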