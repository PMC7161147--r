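#' @include AllClasses.R
NULL

# Genome descriptions are accepted either as a named vector of chromosome
# lengths or as a Seqinfo; everything downstream uses Seqinfo.
.asSeqinfo <- function(genome) {
    if (is(genome, "Seqinfo")) return(genome)
    if (is.numeric(genome) && !is.null(names(genome))) {
        if (anyDuplicated(names(genome)))
            stop("duplicated chromosome names in genome")
        if (any(genome <= 0)) stop("chromosome lengths must be > 0")
        return(Seqinfo(seqnames = names(genome),
                       seqlengths = as.integer(genome)))
    }
    stop("genome must be a named length vector or a Seqinfo object")
}

#' Default toy genome
#'
#' Two chromosomes of 5 Mb and 3 Mb: large enough to place several hundred
#' disjoint regulatory regions, small enough that exhaustive brute-force
#' oracles stay cheap.
#'
#' @return a [GenomeInfoDb::Seqinfo] with chr1 (5 Mb) and chr2 (3 Mb).
#' @examples
#' toyGenome()
#' @export
toyGenome <- function() {
    Seqinfo(seqnames = c("chr1", "chr2"),
            seqlengths = c(5000000L, 3000000L))
}

#' Build an interval from BED-style 0-based half-open coordinates
#'
#' Regulatory-region files use the BED convention (0-based, half-open
#' `[start, end)`); internally coordinates live in `GRanges` (1-based,
#' closed). This constructor performs the conversion, so tests and examples
#' can be phrased in BED coordinates.
#'
#' @param chrom chromosome name(s).
#' @param start0 0-based inclusive start(s).
#' @param end0 0-based exclusive end(s); must exceed `start0`.
#' @param genome optional genome for seqinfo.
#' @return a `GRanges`.
#' @examples
#' bedInterval("chr1", 0, 10)   # first ten bases
#' @export
bedInterval <- function(chrom, start0, end0, genome = NULL) {
    if (any(start0 < 0)) stop("start must be >= 0")
    if (any(end0 <= start0)) stop("end must be > start (zero-length intervals are invalid)")
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    if (!is.null(genome)) seqinfo(gr) <- .asSeqinfo(genome)[seqlevels(gr)]
    gr
}

#' Convert a 1-based point position to an interval
#'
#' SNC catalogs report 1-based positions (e.g. the FOXP2-promoter change at
#' 7:113727420); in BED space the corresponding single-base interval is
#' `[pos - 1, pos)`.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s), >= 1.
#' @return a width-1 `GRanges` whose BED projection is `[pos - 1, pos)`.
#' @examples
#' pointToInterval("chr7", 113727420)
#' @export
pointToInterval <- function(chrom, pos) {
    if (any(pos < 1)) stop("invalid coordinate: positions are 1-based (pos >= 1)")
    GRanges(chrom, IRanges(as.integer(pos), width = 1L))
}

#' Pairwise interval overlap and containment
#'
#' `intervalOverlaps(a, b)` is `TRUE` where `a` and `b` share at least one
#' base on the same chromosome (half-open adjacency does not overlap);
#' `intervalContains(outer, inner)` is `TRUE` where `inner` lies entirely
#' within `outer` (identity counts as containment). Both recycle length-1
#' arguments.
#'
#' @param a,b,outer,inner `GRanges` of equal length (or length 1).
#' @return logical vector.
#' @examples
#' intervalOverlaps(bedInterval("chr1", 0, 10), bedInterval("chr1", 9, 20))
#' intervalContains(bedInterval("chr1", 50, 300), bedInterval("chr1", 100, 200))
#' @export
intervalOverlaps <- function(a, b) {
    as.logical(poverlaps(a, b, type = "any"))
}

#' @rdname intervalOverlaps
#' @export
intervalContains <- function(outer, inner) {
    as.logical(poverlaps(inner, outer, type = "within"))
}

#' Count SNCs falling inside each region
#'
#' The numerator of the mutation-density statistic: the number of catalog
#' positions inside each region. Results are identical to a brute-force scan
#' over all (region, SNC) pairs; the fast path is the `GenomicRanges`
#' interval index.
#'
#' @param regions a `GRanges`.
#' @param sncs an [SNCCatalog-class] (or any width-1 `GRanges`).
#' @return integer vector parallel to `regions`.
#' @export
countHits <- function(regions, sncs) {
    countOverlaps(regions, sncs, ignore.strand = TRUE)
}

#' Normalize chromosome-name style
#'
#' Source datasets mix "chr1" and "1" conventions; comparisons are exact
#' string matches after optional normalization.
#'
#' @param x a `GRanges` (or character vector of chromosome names).
#' @param style `"asis"` (keep), `"chr"` (ensure prefix) or `"plain"`
#'   (strip prefix).
#' @return object of the same type with renamed chromosomes.
#' @export
normalizeChromNames <- function(x, style = c("asis", "chr", "plain")) {
    style <- match.arg(style)
    rename <- function(nm) switch(style,
        asis  = nm,
        chr   = ifelse(grepl("^chr", nm), nm, paste0("chr", nm)),
        plain = sub("^chr", "", nm))
    if (is.character(x)) return(rename(x))
    seqlevels(x) <- rename(seqlevels(x))
    x
}

# ---- file formats -----------------------------------------------------------

#' Read/write BED interval files
#'
#' `readBed()` parses a BED3+ file into a `GRanges` (column 4, if present,
#' becomes `region_id`; columns 5-6 are kept as `score`/strand). Zero-length
#' records are rejected. `writeBed()` writes a `GRanges` back out with
#' `region_id` in column 4; a write-then-read round trip reproduces the
#' interval set exactly.
#'
#' @param path file path.
#' @param style chromosome-name normalization applied on read
#'   (see [normalizeChromNames()]).
#' @param genome optional genome for seqinfo.
#' @return `readBed()` a `GRanges`; `writeBed()` the path, invisibly.
#' @export
readBed <- function(path, style = "asis", genome = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1L))
        stop("zero-length interval in ", path,
             " (start == end is invalid)")
    if (!is.null(mcols(gr)$name)) {
        mcols(gr)$region_id <- mcols(gr)$name
        mcols(gr)$name <- NULL
    }
    if (!is.null(genome)) {
        gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                      strand = strand(gr),
                      seqinfo = .asSeqinfo(genome), mcols(gr))
    }
    normalizeChromNames(gr, style)
}

#' @rdname readBed
#' @param gr a `GRanges` to write.
#' @export
writeBed <- function(gr, path) {
    out <- granges(gr)
    if (!is.null(mcols(gr)$region_id)) mcols(out)$name <- mcols(gr)$region_id
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read/write SNC catalogs as TSV
#'
#' Tab-separated with a required header `chrom, pos, ancestral, derived,
#' lineage, frequency` (an optional `fixed` column, 0/1, overrides the
#' frequency-based fixed classification); `#` comment lines allowed;
#' positions 1-based.
#'
#' @param path file path.
#' @param style chromosome-name normalization on read.
#' @param genome optional genome for seqinfo.
#' @return `readSncCatalog()` an [SNCCatalog-class]; `writeSncCatalog()` the
#'   path, invisibly.
#' @export
readSncCatalog <- function(path, style = "asis", genome = NULL) {
    df <- read.delim(path, header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ancestral", "derived", "lineage", "frequency")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("SNC table missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$lineage), .VALID_LINEAGES)
    if (length(bad))
        stop("unknown lineage value(s): ", paste(bad, collapse = ", "))
    cat <- SNCCatalog(normalizeChromNames(df$chrom, style), df$pos,
                      df$ancestral, df$derived, df$lineage, df$frequency,
                      fixed = if ("fixed" %in% colnames(df)) df$fixed == 1L,
                      genome = genome)
    cat
}

#' @rdname readSncCatalog
#' @param x an [SNCCatalog-class] to write.
#' @export
writeSncCatalog <- function(x, path) {
    df <- data.frame(chrom = as.character(seqnames(x)),
                     pos = start(x),
                     ancestral = mcols(x)$ancestral,
                     derived = mcols(x)$derived,
                     lineage = mcols(x)$lineage,
                     frequency = mcols(x)$frequency,
                     stringsAsFactors = FALSE)
    if (!is.null(mcols(x)$fixed)) df$fixed <- as.integer(mcols(x)$fixed)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read/write region-gene linkage tables
#'
#' One row per region-gene pair: `region_id, chrom, start, end,
#' region_class, gene_id` with BED-style 0-based half-open coordinates.
#' `readRegulatorySet()` assembles the full [RegulatorySet-class] from such
#' a table (regions deduplicated by `region_id`).
#'
#' @param path file path.
#' @return `readLinkage()` a `data.frame`; `readRegulatorySet()` a
#'   [RegulatorySet-class]; writers return the path, invisibly.
#' @export
readLinkage <- function(path) {
    df <- read.delim(path, header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    need <- c("region_id", "chrom", "start", "end", "region_class", "gene_id")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("linkage table missing column(s): ", paste(miss, collapse = ", "))
    df
}

#' @rdname readLinkage
#' @param x a [RegulatorySet-class] to write.
#' @export
writeLinkage <- function(x, path) {
    gr <- regions(x)
    idx <- match(x@linkage$region_id, mcols(gr)$region_id)
    df <- data.frame(region_id = x@linkage$region_id,
                     chrom = as.character(seqnames(gr))[idx],
                     start = start(gr)[idx] - 1L,
                     end = end(gr)[idx],
                     region_class = mcols(gr)$region_class[idx],
                     gene_id = x@linkage$gene_id,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readLinkage
#' @param style,genome see [readBed()].
#' @param source source tag stored on the regions.
#' @export
readRegulatorySet <- function(path, style = "asis", genome = NULL,
                              source = "unspecified") {
    df <- readLinkage(path)
    first <- !duplicated(df$region_id)
    gr <- bedInterval(normalizeChromNames(df$chrom[first], style),
                      df$start[first], df$end[first], genome = genome)
    mcols(gr)$region_id <- df$region_id[first]
    mcols(gr)$region_class <- df$region_class[first]
    mcols(gr)$source <- source
    RegulatorySet(gr, df[, c("region_id", "gene_id")])
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, "", 1L)
    sets
}
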