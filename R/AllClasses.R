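#' @include sncRegulome-package.R
NULL

.VALID_LINEAGES <- c("modern", "archaic")
.VALID_CLASSES  <- c("enhancer", "promoter")
.DNA_BASES      <- c("A", "C", "G", "T")

# ---- SNCCatalog -------------------------------------------------------------

#' Catalog of lineage-specific single-nucleotide changes
#'
#' An `SNCCatalog` is a [GenomicRanges::GRanges] of width-1 positions, one per
#' single-nucleotide change (SNC), with metadata columns `ancestral`,
#' `derived`, `lineage` (`"modern"` or `"archaic"`) and `frequency` (the
#' derived-allele frequency, in (0, 1]). Modern SNCs are changes on the
#' modern-human lineage where Neanderthals/Denisovans carry the ancestral
#' allele; archaic SNCs are the converse. An optional logical column `fixed`
#' overrides the frequency-based fixed/nearly-fixed classification for
#' catalogs that report classes rather than numeric frequencies.
#'
#' @slot ... see [GenomicRanges::GRanges]; the class adds validity checks only.
#' @seealso [SNCCatalog()], [readSncCatalog()], [annotateRegions()]
#' @export
setClass("SNCCatalog", contains = "GRanges")

.validSNCCatalog <- function(object) {
    msg <- character()
    md <- mcols(object)
    need <- c("ancestral", "derived", "lineage", "frequency")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all SNC ranges must have width 1")
        if (!all(md$ancestral %in% .DNA_BASES) || !all(md$derived %in% .DNA_BASES))
            msg <- c(msg, "ancestral/derived alleles must be one of A, C, G, T")
        if (any(md$ancestral == md$derived))
            msg <- c(msg, "ancestral and derived alleles must differ")
        if (!all(md$lineage %in% .VALID_LINEAGES))
            msg <- c(msg, "lineage must be 'modern' or 'archaic'")
        if (any(!is.finite(md$frequency)) ||
            any(md$frequency <= 0) || any(md$frequency > 1))
            msg <- c(msg, "frequency must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SNCCatalog", .validSNCCatalog)

#' Construct an SNC catalog
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based positions (catalog/VCF convention).
#' @param ancestral,derived single-base alleles.
#' @param lineage `"modern"` or `"archaic"` per change.
#' @param frequency derived-allele frequency in (0, 1].
#' @param fixed optional logical; overrides frequency-based fixed calls.
#' @param genome optional genome (named lengths or [GenomeInfoDb::Seqinfo]).
#' @return an [SNCCatalog-class] object.
#' @examples
#' SNCCatalog("chr7", 113727420, "G", "A", "modern", 0.997)
#' @export
SNCCatalog <- function(chrom, pos, ancestral, derived, lineage, frequency,
                       fixed = NULL, genome = NULL) {
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    if (!is.null(genome))
        seqinfo(gr) <- .asSeqinfo(genome)[seqlevels(gr)]
    mcols(gr) <- DataFrame(
        ancestral = as.character(ancestral),
        derived = as.character(derived),
        lineage = as.character(lineage),
        frequency = as.numeric(frequency))
    if (!is.null(fixed))
        mcols(gr)$fixed <- as.logical(fixed)
    new("SNCCatalog", gr)
}

# ---- RegulatorySet ----------------------------------------------------------

#' A set of regulatory regions with gene linkage
#'
#' Bundles the regulatory regions (enhancers/promoters active in the
#' developing cortex) with the region-to-gene linkage table derived from
#' chromatin-conformation (Hi-C) data. Regions are a [GenomicRanges::GRanges]
#' with metadata columns `region_id`, `region_class` (`"enhancer"` or
#' `"promoter"`) and `source`; after [annotateRegions()] they additionally
#' carry `n_modern`, `n_modern_fixed` and `n_archaic` SNC counts.
#'
#' @slot regions a `GRanges` of regulatory regions.
#' @slot linkage a `data.frame` with columns `region_id`, `gene_id` (one row
#'   per region-gene pair).
#' @seealso [RegulatorySet()], [annotateRegions()], [selectCandidates()],
#'   [resolveGeneList()]
#' @export
setClass("RegulatorySet",
    slots = c(regions = "GRanges", linkage = "data.frame"))

.validRegulatorySet <- function(object) {
    msg <- character()
    gr <- object@regions
    md <- mcols(gr)
    need <- c("region_id", "region_class", "source")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        return(paste("regions missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (length(gr)) {
        if (anyDuplicated(md$region_id))
            msg <- c(msg, "region_id values must be unique")
        if (!all(md$region_class %in% .VALID_CLASSES))
            msg <- c(msg, "region_class must be 'enhancer' or 'promoter'")
        if (any(width(gr) < 1L))
            msg <- c(msg, "regions must have width >= 1")
        cnt <- intersect(c("n_modern", "n_modern_fixed", "n_archaic"),
                         colnames(md))
        for (cc in cnt)
            if (any(md[[cc]] < 0)) msg <- c(msg, paste(cc, "must be >= 0"))
        if (all(c("n_modern", "n_modern_fixed") %in% colnames(md)) &&
            any(md$n_modern_fixed > md$n_modern))
            msg <- c(msg, "n_modern_fixed cannot exceed n_modern")
    }
    lk <- object@linkage
    if (!all(c("region_id", "gene_id") %in% colnames(lk)))
        msg <- c(msg, "linkage needs columns region_id, gene_id")
    if (length(msg)) msg else TRUE
}
setValidity("RegulatorySet", .validRegulatorySet)

#' Construct a RegulatorySet
#'
#' @param regions a `GRanges` with metadata columns `region_id`,
#'   `region_class`, `source` (the latter defaults to `"unspecified"` if
#'   absent).
#' @param linkage a `data.frame` with columns `region_id`, `gene_id`.
#' @return a [RegulatorySet-class].
#' @export
RegulatorySet <- function(regions,
                          linkage = data.frame(region_id = character(),
                                               gene_id = character())) {
    if (is.null(mcols(regions)$source))
        mcols(regions)$source <- "unspecified"
    new("RegulatorySet", regions = regions,
        linkage = as.data.frame(linkage, stringsAsFactors = FALSE))
}

# ---- PermutationResult ------------------------------------------------------

#' Result of a permutation-based region-overlap enrichment test
#'
#' @slot observed observed statistic (number of query regions overlapping at
#'   least one feature).
#' @slot nPerm number of permutations.
#' @slot permMean,permSd mean and sd of the permutation null.
#' @slot pValue empirical p-value, `(b + 1) / (nPerm + 1)`.
#' @slot zScore `(observed - permMean) / permSd`.
#' @slot alternative `"greater"` or `"less"`.
#' @slot permStats the permutation statistics (kept for diagnostics).
#' @seealso [permutationOverlapTest()]
#' @export
setClass("PermutationResult",
    slots = c(observed = "numeric", nPerm = "integer",
              permMean = "numeric", permSd = "numeric",
              pValue = "numeric", zScore = "numeric",
              alternative = "character", permStats = "numeric"))

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
    lo <- 1 / (object@nPerm + 1)
    if (object@pValue < lo - 1e-12 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [1/(nPerm+1), 1]")
    if (!object@alternative %in% c("greater", "less"))
        msg <- c(msg, "alternative must be 'greater' or 'less'")
    if (length(msg)) msg else TRUE
})

# ---- MotifMatrix ------------------------------------------------------------

#' A position weight matrix for known-motif scanning
#'
#' Column-stochastic base probabilities (rows A, C, G, T), a background base
#' composition, and a log-odds score threshold used by [scanPWM()]. Columns
#' are pseudocount-smoothed before log-odds scoring to avoid infinite scores
#' on zero entries.
#'
#' @slot motifId motif identifier.
#' @slot profile 4 x m numeric matrix of per-position base probabilities,
#'   rownames A, C, G, T; each column sums to 1 (within 1e-6).
#' @slot background length-4 base composition (sums to 1).
#' @slot pseudocount smoothing constant added to probabilities before
#'   log-odds (default 1e-4).
#' @slot scoreThreshold minimum log2-odds score reported as a hit; `NA` means
#'   "use 80% of the maximum achievable score".
#' @seealso [MotifMatrix()], [readJasparMotifs()], [scanPWM()]
#' @export
setClass("MotifMatrix",
    slots = c(motifId = "character", profile = "matrix",
              background = "numeric", pseudocount = "numeric",
              scoreThreshold = "numeric"))

setValidity("MotifMatrix", function(object) {
    msg <- character()
    pr <- object@profile
    if (nrow(pr) != 4L || !identical(rownames(pr), .DNA_BASES))
        msg <- c(msg, "profile must have rows named A, C, G, T")
    else if (any(abs(colSums(pr) - 1) > 1e-6))
        msg <- c(msg, "profile columns must sum to 1 (within 1e-6)")
    if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must be 4 probabilities summing to 1")
    if (!is.na(object@scoreThreshold) && nrow(pr) == 4L &&
        identical(rownames(pr), .DNA_BASES)) {
        if (object@scoreThreshold > maxScore(object) + 1e-9)
            msg <- c(msg, "scoreThreshold exceeds the maximum achievable score")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MotifMatrix
#'
#' @param motifId motif identifier string.
#' @param profile 4 x m matrix of counts or probabilities (rows A, C, G, T in
#'   that order; rownames optional).
#' @param background base composition (default uniform).
#' @param pseudocount probability smoothing before log-odds (default 1e-4).
#' @param scoreThreshold log2-odds hit threshold; `NA` = 80% of maximum.
#' @return a [MotifMatrix-class].
#' @export
MotifMatrix <- function(motifId, profile, background = rep(0.25, 4),
                        pseudocount = 1e-4, scoreThreshold = NA_real_) {
    profile <- as.matrix(profile)
    stopifnot(nrow(profile) == 4L)
    rownames(profile) <- .DNA_BASES
    cs <- colSums(profile)
    if (any(cs <= 0)) stop("each profile column needs positive mass")
    profile <- sweep(profile, 2L, cs, "/")
    background <- background / sum(background)
    new("MotifMatrix", motifId = as.character(motifId), profile = profile,
        background = background, pseudocount = pseudocount,
        scoreThreshold = as.numeric(scoreThreshold))
}
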