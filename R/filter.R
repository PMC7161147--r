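#' @include genomic-core.R
NULL

#' Annotate regulatory regions with lineage-specific SNC counts
#'
#' Fills the per-region counts `n_modern` (modern-human SNCs inside the
#' region), `n_modern_fixed` (those at fixed frequency, i.e. frequency
#' `>= 1 - epsilonFixed`, or flagged fixed in the catalog) and `n_archaic`
#' (Neanderthal/Denisovan SNCs). The frequency classes follow the source
#' catalog: fixed, or nearly fixed (frequency in [0.90, 1)).
#'
#' @param rset a [RegulatorySet-class].
#' @param sncs an [SNCCatalog-class].
#' @param epsilonFixed frequencies `>= 1 - epsilonFixed` count as fixed
#'   (default 1e-6); an explicit `fixed` column in the catalog overrides
#'   this.
#' @return the [RegulatorySet-class] with count columns filled.
#' @seealso [selectCandidates()], [classifyFixedGenes()]
#' @export
annotateRegions <- function(rset, sncs, epsilonFixed = 1e-6) {
    stopifnot(is(rset, "RegulatorySet"), is(sncs, "SNCCatalog"))
    bad <- setdiff(unique(sncLineage(sncs)), .VALID_LINEAGES)
    if (length(bad))
        stop("SNC catalog has unknown lineage value(s): ",
             paste(bad, collapse = ", "))
    gr <- regions(rset)
    isFixed <- if (!is.null(mcols(sncs)$fixed)) mcols(sncs)$fixed
               else sncFrequency(sncs) >= 1 - epsilonFixed
    modern <- sncs[sncLineage(sncs) == "modern"]
    modernFixed <- modern[isFixed[sncLineage(sncs) == "modern"]]
    archaic <- sncs[sncLineage(sncs) == "archaic"]
    mcols(gr)$n_modern <- countHits(gr, modern)
    mcols(gr)$n_modern_fixed <- countHits(gr, modernFixed)
    mcols(gr)$n_archaic <- countHits(gr, archaic)
    initialize(rset, regions = gr)
}

#' Select candidate regions: harbor mSNCs, depleted of archaic changes
#'
#' The core depletion filter: a region is a candidate iff it contains at
#' least one modern-human SNC and zero Neanderthal/Denisovan SNCs (of any
#' frequency).
#'
#' @param rset an annotated [RegulatorySet-class] (see [annotateRegions()]).
#' @return the subset [RegulatorySet-class] of candidate regions.
#' @export
selectCandidates <- function(rset) {
    md <- mcols(regions(rset))
    if (is.null(md$n_modern) || is.null(md$n_archaic))
        stop("regions are not annotated; run annotateRegions() first")
    rset[md$n_modern >= 1L & md$n_archaic == 0L]
}

#' Containment filter for adult enhancers against histone-mark peaks
#'
#' An enhancer passes iff its coordinates are completely contained in at
#' least one H3K27ac peak (active-enhancer signal) that itself has zero
#' overlap with any H3K4me3 peak (promoter signal). `mode = "enhancer"`
#' applies the H3K4me3 disqualification to the enhancer itself instead of
#' the containing peak (the alternative reading of the filter).
#'
#' @param enhancers `GRanges` (or [RegulatorySet-class]) of enhancers.
#' @param h3k27acPeaks,h3k4me3Peaks `GRanges` of peaks.
#' @param mode where the H3K4me3 disqualification applies.
#' @return logical vector parallel to `enhancers` (`TRUE` = passes).
#' @export
adultEnhancerFilter <- function(enhancers, h3k27acPeaks, h3k4me3Peaks,
                                mode = c("peak", "enhancer")) {
    mode <- match.arg(mode)
    gr <- if (is(enhancers, "RegulatorySet")) regions(enhancers) else enhancers
    if (mode == "peak") {
        activePeaks <- h3k27acPeaks[
            countOverlaps(h3k27acPeaks, h3k4me3Peaks,
                          ignore.strand = TRUE) == 0L]
        countOverlaps(gr, activePeaks, type = "within",
                      ignore.strand = TRUE) >= 1L
    } else {
        contained <- countOverlaps(gr, h3k27acPeaks, type = "within",
                                   ignore.strand = TRUE) >= 1L
        clean <- countOverlaps(gr, h3k4me3Peaks, ignore.strand = TRUE) == 0L
        contained & clean
    }
}

#' Resolve the candidate gene list with per-gene evidence
#'
#' Union semantics: a gene enters the list if at least one linked region is
#' a candidate. Candidate regions missing from the linkage table are dropped
#' with a warning.
#'
#' @param candidates a candidate [RegulatorySet-class] (annotated and
#'   filtered); its own linkage slot is used unless `linkageTable` is given.
#' @param linkageTable optional data.frame with `region_id`, `gene_id`.
#' @return list: `genes` (sorted character vector) and `evidence`
#'   (data.frame with one row per gene-region support pair: `gene_id`,
#'   `region_id`, `region_class`, `n_modern`, `n_modern_fixed`,
#'   `n_archaic`).
#' @export
resolveGeneList <- function(candidates, linkageTable = NULL) {
    gr <- regions(candidates)
    md <- mcols(gr)
    lk <- if (is.null(linkageTable)) linkage(candidates) else linkageTable
    unlinked <- setdiff(md$region_id, lk$region_id)
    if (length(unlinked))
        warning(length(unlinked), " candidate region(s) missing from the ",
                "linkage table were excluded: ",
                paste(head(unlinked, 5L), collapse = ", "))
    lk <- lk[lk$region_id %in% md$region_id, , drop = FALSE]
    idx <- match(lk$region_id, md$region_id)
    evidence <- data.frame(
        gene_id = lk$gene_id,
        region_id = lk$region_id,
        region_class = md$region_class[idx],
        n_modern = md$n_modern[idx],
        n_modern_fixed = md$n_modern_fixed[idx],
        n_archaic = md$n_archaic[idx],
        stringsAsFactors = FALSE)
    evidence <- unique(evidence)
    list(genes = sort(unique(evidence$gene_id)), evidence = evidence)
}

#' Classify genes by fixed changes in enhancers and/or promoters
#'
#' A gene carries fixed enhancer (promoter) changes iff at least one linked
#' candidate region of that class contains >= 1 fixed mSNC; `both` is the
#' intersection (the pattern the single gene LRRC23 shows in the cortical
#' dataset: fixed changes in both its enhancer and its promoter).
#'
#' @param evidence the `evidence` data.frame from [resolveGeneList()].
#' @return list of sorted character vectors: `enhancer_fixed`,
#'   `promoter_fixed`, `both`.
#' @export
classifyFixedGenes <- function(evidence) {
    fx <- evidence[evidence$n_modern_fixed >= 1L, , drop = FALSE]
    enh <- sort(unique(fx$gene_id[fx$region_class == "enhancer"]))
    prom <- sort(unique(fx$gene_id[fx$region_class == "promoter"]))
    list(enhancer_fixed = enh, promoter_fixed = prom,
         both = intersect(enh, prom))
}
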