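#' @include genomic-core.R
NULL

# Draw `nPerm` randomized placements for each query width. Returns a list
# with chrom (character matrix n x nPerm) and start1 (1-based start matrix).
.drawPlacements <- function(widths, si, nPerm, origChrom = NULL,
                            keepChrom = FALSE) {
    lens <- seqlengths(si)
    n <- length(widths)
    chrom <- matrix(NA_character_, n, nPerm)
    start1 <- matrix(NA_integer_, n, nPerm)
    for (i in seq_len(n)) {
        w <- widths[i]
        if (keepChrom) {
            eligible <- origChrom[i]
            if (lens[[eligible]] < w)
                stop("placement error: region wider than its chromosome")
            ch <- rep(eligible, nPerm)
        } else {
            eligible <- names(lens)[lens >= w]
            if (!length(eligible))
                stop("placement error: region wider than every chromosome")
            ch <- if (length(eligible) == 1L) rep(eligible, nPerm)
                  else sample(eligible, nPerm, replace = TRUE,
                              prob = lens[eligible])
        }
        chrom[i, ] <- ch
        start1[i, ] <- floor(runif(nPerm, 0, lens[ch] - w + 1)) + 1L
    }
    list(chrom = chrom, start1 = start1)
}

#' Length-preserving uniform randomization of a region set
#'
#' Produces one random interval per input region with the same length:
#' chromosome reassigned with probability proportional to chromosome length
#' (among chromosomes the region fits on), start uniform over the
#' `chromosome length - region length + 1` valid positions. This is the
#' null model behind [permutationOverlapTest()]. No masking or gap handling
#' (the toy genomes carry none).
#'
#' @param query `GRanges` (or [RegulatorySet-class]) to randomize.
#' @param genome genome to place on.
#' @param keepChrom keep each region on its original chromosome.
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used.
#' @return a `GRanges` with the same multiset of lengths as the input.
#' @export
randomizeRegions <- function(query, genome = toyGenome(), keepChrom = FALSE,
                             seed = NULL) {
    gr <- if (is(query, "RegulatorySet")) regions(query) else query
    si <- .asSeqinfo(genome)
    draw <- function() {
        pl <- .drawPlacements(width(gr), si, 1L,
                              origChrom = as.character(seqnames(gr)),
                              keepChrom = keepChrom)
        GRanges(pl$chrom[, 1L], IRanges(pl$start1[, 1L], width = width(gr)),
                seqinfo = si)
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Permutation test for region-set overlap enrichment
#'
#' Observed statistic: the number of query regions overlapping at least one
#' feature. The null distribution is built by randomizing the query set
#' `nPerm` times (length-preserving uniform placement, see
#' [randomizeRegions()]) and recomputing the statistic. The empirical
#' p-value is `(b + 1) / (nPerm + 1)` where `b` counts permutations with a
#' statistic at least as extreme as observed, so p can never be 0 and its
#' minimum is `1 / (nPerm + 1)`.
#'
#' @param query `GRanges` (or [RegulatorySet-class]); must be non-empty.
#' @param features `GRanges` of the feature set (sweep regions, disease
#'   loci, ...).
#' @param genome genome for randomization.
#' @param nPerm number of permutations (default 10000, as in the cortical
#'   analysis).
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion).
#' @param keepChrom keep regions on their original chromosomes when
#'   randomizing.
#' @param seed optional RNG seed.
#' @param chunkSize permutations per internal block (memory control).
#' @return a [PermutationResult-class].
#' @examples
#' g <- toyGenome()
#' q <- simulateFeatures(g, nFeatures = 40, seed = 5)
#' f <- simulateFeatures(g, nFeatures = 30, seed = 6)
#' permutationOverlapTest(q, f, g, nPerm = 200, seed = 1)
#' @export
permutationOverlapTest <- function(query, features, genome = toyGenome(),
                                   nPerm = 10000,
                                   alternative = c("greater", "less"),
                                   keepChrom = FALSE, seed = NULL,
                                   chunkSize = 2000L) {
    alternative <- match.arg(alternative)
    gr <- if (is(query, "RegulatorySet")) regions(query) else query
    if (length(gr) == 0L)
        stop("empty query set: the overlap statistic is undefined")
    si <- .asSeqinfo(genome)
    nPerm <- as.integer(nPerm)
    stopifnot(nPerm >= 1L)
    observed <- sum(countOverlaps(gr, features, ignore.strand = TRUE) > 0L)
    n <- length(gr)
    run <- function() {
        stats <- integer(nPerm)
        done <- 0L
        while (done < nPerm) {
            b <- min(chunkSize, nPerm - done)
            pl <- .drawPlacements(width(gr), si, b,
                                  origChrom = as.character(seqnames(gr)),
                                  keepChrom = keepChrom)
            big <- GRanges(as.vector(pl$chrom),
                           IRanges(as.vector(pl$start1),
                                   width = rep(width(gr), b)))
            ov <- findOverlaps(big, features, ignore.strand = TRUE)
            hit <- unique(queryHits(ov))
            permId <- (hit - 1L) %/% n + 1L
            stats[done + seq_len(b)] <- tabulate(permId, nbins = b)
            done <- done + b
        }
        stats
    }
    permStats <- if (is.null(seed)) run() else with_seed(seed, run())
    b <- if (alternative == "greater") sum(permStats >= observed)
         else sum(permStats <= observed)
    pm <- mean(permStats); psd <- sd(permStats)
    new("PermutationResult",
        observed = as.numeric(observed), nPerm = nPerm,
        permMean = pm, permSd = psd,
        pValue = (b + 1) / (nPerm + 1),
        zScore = if (isTRUE(psd > 0)) (observed - pm) / psd else NA_real_,
        alternative = alternative,
        permStats = as.numeric(permStats))
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric test of a query gene list against each term
#' set, within a stated gene universe, with Benjamini-Hochberg adjustment
#' across terms (the graph-aware 'gSCS' correction of the original g:Profiler
#' analysis is deliberately not reproduced; BH is the transparent standard
#' substitute and the output column is named accordingly).
#'
#' @param queryGenes character vector; must lie within `universe`.
#' @param termSets named list of character vectors (e.g. from [readGmt()]);
#'   genes outside the universe are dropped per term.
#' @param universe character vector of background genes (non-empty).
#' @return data.frame: `term_id`, `universe_size`, `term_size`,
#'   `query_size`, `overlap`, `p_value`, `adj_p` (BH).
#' @examples
#' hypergeomGeneTest(letters[1:5], list(t1 = letters[1:5]), letters[1:20])
#' @export
hypergeomGeneTest <- function(queryGenes, termSets, universe) {
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty gene universe")
    queryGenes <- unique(queryGenes)
    out <- setdiff(queryGenes, universe)
    if (length(out))
        stop("query gene(s) outside the universe: ",
             paste(head(out, 5L), collapse = ", "))
    N <- length(universe)
    n <- length(queryGenes)
    res <- lapply(names(termSets), function(tid) {
        term <- intersect(unique(termSets[[tid]]), universe)
        K <- length(term)
        k <- length(intersect(term, queryGenes))
        p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = tid, universe_size = N, term_size = K,
                   query_size = n, overlap = k, p_value = p,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$adj_p <- p.adjust(res$p_value, method = "BH")
    res
}
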