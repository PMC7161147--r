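# Independent brute-force oracles. These deliberately avoid the package's
# fast paths (interval indexes, cross-products, vectorized scans) so that
# agreement is a genuine dual-route check.

# number of points (width-1 ranges) inside each region, by explicit scan
bruteCountHits <- function(regions, points) {
    rc <- as.character(GenomicRanges::seqnames(regions))
    rs <- GenomicRanges::start(regions)
    re <- GenomicRanges::end(regions)
    pc <- as.character(GenomicRanges::seqnames(points))
    pp <- GenomicRanges::start(points)
    vapply(seq_along(regions), function(i)
        sum(pc == rc[i] & pp >= rs[i] & pp <= re[i]), 0L)
}

# does each query region overlap >= 1 feature (explicit pair scan)
bruteOverlapsAny <- function(query, features) {
    qc <- as.character(GenomicRanges::seqnames(query))
    qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
    fc <- as.character(GenomicRanges::seqnames(features))
    fs <- GenomicRanges::start(features); fe <- GenomicRanges::end(features)
    vapply(seq_along(query), function(i)
        any(fc == qc[i] & fs <= qe[i] & fe >= qs[i]), NA)
}

# exhaustive-enumeration hypergeometric tail: universe 1..N, term 1..K,
# draw all C(N, n) subsets, P(overlap >= k)
enumHyperTail <- local({
    cache <- new.env()
    function(N, K, n, k) {
        key <- paste(N, n, sep = "_")
        M <- get0(key, envir = cache)
        if (is.null(M)) {
            M <- utils::combn(N, n)
            assign(key, M, envir = cache)
        }
        ov <- colSums(M <= K)
        mean(ov >= k)
    }
})

# O(n^3) topological overlap
bruteTom <- function(a) {
    n <- nrow(a)
    diag(a) <- 1
    k <- rowSums(a) - 1
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    dimnames(tom) <- dimnames(a)
    tom
}

# naive per-position PWM scan on both strands (double loop)
naiveScanPWM <- function(seqChar, pwm, threshold) {
    lo <- logOddsMatrix(pwm)
    m <- ncol(lo)
    codeOf <- function(s) {
        x <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T", "N"))
        x[is.na(x)] <- 5L
        x
    }
    scoreAt <- function(code, i) {
        s <- 0
        for (j in seq_len(m)) s <- s + lo[code[i + j - 1L], j]
        s
    }
    n <- nchar(seqChar)
    out <- data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    if (n < m) return(out)
    fwd <- codeOf(seqChar)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqChar)))
    rev <- codeOf(rc)
    for (i in seq_len(n - m + 1L)) {
        s <- scoreAt(fwd, i)
        if (s >= threshold)
            out <- rbind(out, data.frame(start = i, strand = "+", score = s))
        s <- scoreAt(rev, i)
        if (s >= threshold)
            out <- rbind(out, data.frame(start = n - m - i + 2L,
                                         strand = "-", score = s))
    }
    out[order(out$start, out$strand), , drop = FALSE]
}

# sort-and-slice density ranking oracle (per class, ceil fraction, ties by
# longer length then lexicographic id)
bruteTopDensity <- function(records, fraction) {
    flagged <- character()
    for (cl in unique(records$region_class)) {
        sub <- records[records$region_class == cl, , drop = FALSE]
        ord <- order(-sub$density, -sub$length, sub$region_id, method = "radix")
        nTop <- ceiling(fraction * nrow(sub))
        flagged <- c(flagged, sub$region_id[ord][seq_len(nTop)])
    }
    flagged
}

# a small convenience used by several tests
toyRegulatorySet <- function(tbl, linkage = NULL) {
    gr <- bedInterval(tbl$chrom, tbl$start, tbl$end)
    S4Vectors::mcols(gr)$region_id <- tbl$region_id
    S4Vectors::mcols(gr)$region_class <- tbl$region_class
    S4Vectors::mcols(gr)$source <- "test"
    if (is.null(linkage))
        linkage <- data.frame(region_id = character(),
                              gene_id = character())
    RegulatorySet(gr, linkage)
}

# Engineered count matrix exercising every QC cutoff at its boundary.
# 1000 genes x 12 cells; cells sit exactly on, just under, or just over
# each threshold (detection 499/500; totals 1999/2000/9000/9001; mito
# fraction 5% / just over 5%).
makeQcMatrix <- function() {
    nGenes <- 1000L
    genes <- c(sprintf("MT-%02d", 1:10), sprintf("g%04d", 1:990))
    fill <- function(nDetected, total, mitoCounts = 0L) {
        x <- integer(nGenes)
        nonMito <- 11:nGenes
        idx <- nonMito[seq_len(nDetected - (mitoCounts > 0))]
        base <- total - mitoCounts
        x[idx] <- c(rep(base %/% length(idx) + 1L, base %% length(idx)),
                    rep(base %/% length(idx),
                        length(idx) - base %% length(idx)))
        if (mitoCounts > 0) x[1L] <- mitoCounts
        x
    }
    m <- cbind(
        det499 = fill(499L, 3000L),
        det500 = fill(500L, 3000L),
        lo1999 = fill(600L, 1999L),
        lo2000 = fill(600L, 2000L),
        hi9000 = fill(600L, 9000L),
        hi9001 = fill(600L, 9001L),
        mito5 = fill(600L, 4000L, mitoCounts = 200L),
        mito5p = fill(600L, 4000L, mitoCounts = 201L),
        okA = fill(700L, 5000L, mitoCounts = 100L),
        okB = fill(700L, 5200L, mitoCounts = 100L),
        okC = fill(650L, 4500L),
        okD = fill(620L, 4100L))
    rownames(m) <- genes
    m
}
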