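#' @include AllGenerics.R
NULL

#' Read PWMs in JASPAR-style plain text
#'
#' Parses records of the form
#' \preformatted{
#' >MA0139.1 CTCF
#' A [ 87 167 281 ... ]
#' C [291 145  49 ... ]
#' G [ 76 414 449 ... ]
#' T [459 187 134 ... ]
#' }
#' Counts or probabilities are accepted; columns are normalized to sum to 1.
#'
#' @param path file path.
#' @param background,pseudocount,scoreThreshold passed to [MotifMatrix()].
#' @return named list of [MotifMatrix-class] objects.
#' @export
readJasparMotifs <- function(path, background = rep(0.25, 4),
                             pseudocount = 1e-4, scoreThreshold = NA_real_) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no motif records (no '>' headers) in ", path)
    motifs <- lapply(starts, function(s) {
        header <- sub("^>\\s*", "", lines[s])
        id <- strsplit(header, "\\s+")[[1L]][1L]
        rows <- lines[s + 1:4]
        vals <- lapply(rows, function(r) {
            base <- sub("^([ACGT]).*", "\\1", r)
            nums <- regmatches(r, gregexpr("[0-9.eE+-]+", r))[[1L]]
            # drop a leading stray from e.g. "A [ ... ]" bracket content only
            list(base = base, x = as.numeric(nums))
        })
        bases <- vapply(vals, `[[`, "", "base")
        if (!setequal(bases, .DNA_BASES))
            stop("motif ", id, ": expected rows A, C, G, T")
        m <- do.call(rbind, lapply(vals, `[[`, "x"))
        rownames(m) <- bases
        m <- m[.DNA_BASES, , drop = FALSE]
        MotifMatrix(id, m, background = background,
                    pseudocount = pseudocount,
                    scoreThreshold = scoreThreshold)
    })
    names(motifs) <- vapply(motifs, motifId, "")
    motifs
}

.encodeSeq <- function(x) {
    chars <- strsplit(toupper(as.character(x)), "")[[1L]]
    code <- match(chars, c(.DNA_BASES, "N"))
    code[is.na(code)] <- 5L   # anything unknown scores as background
    code
}

.scoreAllPositions <- function(code, lo) {
    m <- ncol(lo)
    np <- length(code) - m + 1L
    if (np < 1L) return(numeric())
    sc <- numeric(np)
    for (j in seq_len(m))
        sc <- sc + lo[code[j:(j + np - 1L)], j]
    sc
}

#' Scan a sequence with a PWM
#'
#' Reports every position (both strands) whose log2-odds score
#' `sum(log2(p_base / bg_base))` meets the threshold. Positions containing
#' `N` contribute 0 (background-level evidence). Minus-strand hits are
#' reported by the forward-strand start of the matching window.
#'
#' @param sequence character string, [Biostrings::DNAString] or length-1
#'   `DNAStringSet`.
#' @param pwm a [MotifMatrix-class].
#' @param threshold log2-odds threshold; default: the motif's
#'   `scoreThreshold`, or 80% of the maximum achievable score if that is
#'   `NA`.
#' @return data.frame: `start` (1-based), `strand`, `score`; zero rows if
#'   the sequence is shorter than the motif.
#' @examples
#' pwm <- pwmFromConsensus("ex", "TGACGTCA")
#' scanPWM("AATGACGTCATT", pwm)
#' @export
scanPWM <- function(sequence, pwm, threshold = NULL) {
    stopifnot(is(pwm, "MotifMatrix"))
    if (is(sequence, "DNAStringSet")) sequence <- sequence[[1L]]
    seqChar <- as.character(sequence)
    if (is.null(threshold))
        threshold <- if (is.na(pwm@scoreThreshold)) 0.8 * maxScore(pwm)
                     else pwm@scoreThreshold
    lo <- logOddsMatrix(pwm)
    m <- ncol(lo)
    n <- nchar(seqChar)
    if (n < m)
        return(data.frame(start = integer(), strand = character(),
                          score = numeric(), stringsAsFactors = FALSE))
    fwd <- .scoreAllPositions(.encodeSeq(seqChar), lo)
    rcChar <- as.character(reverseComplement(DNAString(seqChar)))
    rev <- .scoreAllPositions(.encodeSeq(rcChar), lo)
    hitF <- which(fwd >= threshold)
    hitR <- which(rev >= threshold)
    out <- data.frame(
        start = c(hitF, n - m - hitR + 2L),
        strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
        score = c(fwd[hitF], rev[hitR]),
        stringsAsFactors = FALSE)
    out[order(out$start, out$strand), , drop = FALSE]
}

# Batch hit detection: all sequences are concatenated with m 'N' spacers and
# scored in one vectorized pass per strand; windows straddling a spacer are
# masked out by position, so results equal per-sequence scanning exactly.
.batchHasHit <- function(seqChars, pwm, threshold) {
    lo <- logOddsMatrix(pwm)
    m <- ncol(lo)
    spacer <- strrep("N", m)
    scoreStrand <- function(chars) {
        concat <- paste(chars, collapse = spacer)
        code <- .encodeSeq(concat)
        sc <- .scoreAllPositions(code, lo)
        offs <- cumsum(c(0L, head(nchar(chars), -1L) + m))
        hit <- logical(length(chars))
        ok <- which(sc >= threshold)
        if (length(ok)) {
            seqIdx <- findInterval(ok, offs + 1L)
            valid <- ok + m - 1L <= offs[seqIdx] + nchar(chars)[seqIdx]
            hit[unique(seqIdx[valid])] <- TRUE
        }
        hit
    }
    fwd <- scoreStrand(seqChars)
    rcAll <- as.character(reverseComplement(DNAStringSet(seqChars)))
    fwd | scoreStrand(rcAll)
}

#' Known-motif enrichment of target vs background sequences
#'
#' Per motif, each region is reduced to a binary hit indicator (at least one
#' scan hit on either strand); enrichment of hits in the target set against
#' the pooled target + background total is tested with a one-sided
#' hypergeometric test, and Benjamini-Hochberg q-values are computed across
#' motifs. Significant known motifs are conventionally reported at
#' q < 0.05.
#'
#' @param targets named [Biostrings::DNAStringSet] of target-region
#'   sequences (non-empty).
#' @param background [Biostrings::DNAStringSet] of background-region
#'   sequences (non-empty; user-supplied, no GC-matched autogeneration).
#' @param pwms list of [MotifMatrix-class] objects.
#' @param threshold optional log2-odds threshold applied to every motif
#'   (default: per-motif, see [scanPWM()]).
#' @return data.frame: `motif_id`, `targets_with_hit`, `n_targets`,
#'   `background_with_hit`, `n_background`, `p_value`, `q_value`.
#' @export
motifEnrichment <- function(targets, background, pwms, threshold = NULL) {
    if (length(targets) == 0L || length(background) == 0L)
        stop("targets and background must both be non-empty")
    if (is(pwms, "MotifMatrix")) pwms <- list(pwms)
    tChar <- as.character(targets)
    bChar <- as.character(background)
    res <- lapply(pwms, function(pwm) {
        m <- ncol(pwm@profile)
        thr <- if (!is.null(threshold)) threshold
               else if (is.na(pwm@scoreThreshold)) 0.8 * maxScore(pwm)
               else pwm@scoreThreshold
        if (all(nchar(c(tChar, bChar)) < m)) {
            warning("motif ", motifId(pwm),
                    " is longer than every region; p set to 1")
            return(data.frame(motif_id = motifId(pwm), targets_with_hit = 0L,
                              n_targets = length(tChar),
                              background_with_hit = 0L,
                              n_background = length(bChar),
                              p_value = 1, stringsAsFactors = FALSE))
        }
        hitT <- sum(.batchHasHit(tChar, pwm, thr))
        hitB <- sum(.batchHasHit(bChar, pwm, thr))
        tot <- hitT + hitB
        nT <- length(tChar); nB <- length(bChar)
        p <- phyper(hitT - 1L, tot, nT + nB - tot, nT, lower.tail = FALSE)
        data.frame(motif_id = motifId(pwm), targets_with_hit = hitT,
                   n_targets = nT, background_with_hit = hitB,
                   n_background = nB, p_value = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    res$q_value <- p.adjust(res$p_value, method = "BH")
    res
}
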