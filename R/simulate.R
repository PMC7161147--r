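#' @include genomic-core.R
NULL

# Exact uniform placement of k disjoint lengths on [0, chromLen) with a
# minimum gap: draw the total slack, split it by sorted uniforms, lay the
# regions down in sequence. Returns 0-based starts parallel to `lengths`.
.placeDisjoint <- function(lengths, chromLen, minGap) {
    k <- length(lengths)
    if (k == 0L) return(integer())
    free <- chromLen - sum(lengths) - (k - 1L) * minGap
    if (free < 0) return(NULL)
    slack <- diff(c(0, sort(runif(k, 0, free))))
    starts <- integer(k)
    cursor <- 0
    for (i in seq_len(k)) {
        starts[i] <- floor(cursor + slack[i])
        cursor <- starts[i] + lengths[i] + minGap
    }
    starts
}

#' Simulate regulatory regions with gene linkage
#'
#' Places non-overlapping enhancer and promoter intervals on a toy genome
#' and links each region to 1-`maxGenesPerRegion` genes drawn from a shared
#' synthetic gene catalog (so some genes are regulated by several regions,
#' as with real Hi-C linkage tables). Region lengths are log-normal, clipped
#' to `lengthRange`; a 1000 bp density-eligibility cutoff downstream means
#' the default range straddles that boundary on purpose.
#'
#' @param genome genome (named lengths or `Seqinfo`); default [toyGenome()].
#' @param nEnhancers,nPromoters region counts per class.
#' @param lengthMeanLog,lengthSdLog log-normal length parameters (bp).
#' @param lengthRange inclusive length clip (bp).
#' @param minGap minimum gap between placed regions (bp).
#' @param nGenes size of the synthetic gene catalog.
#' @param maxGenesPerRegion upper bound on genes linked per region.
#' @param seed RNG seed; the generator is a pure function of seed and
#'   parameters.
#' @param maxTries placement retries before a capacity error.
#' @return a [RegulatorySet-class].
#' @examples
#' rs <- simulateRegions(nEnhancers = 20, nPromoters = 10, seed = 1)
#' rs
#' @export
simulateRegions <- function(genome = toyGenome(),
                            nEnhancers = 300, nPromoters = 200,
                            lengthMeanLog = log(1500), lengthSdLog = 0.5,
                            lengthRange = c(200, 5000), minGap = 100,
                            nGenes = 400, maxGenesPerRegion = 3,
                            seed = 1, maxTries = 20) {
    si <- .asSeqinfo(genome)
    n <- nEnhancers + nPromoters
    with_seed(seed, {
        ids <- c(sprintf("E%04d", seq_len(nEnhancers)),
                 sprintf("P%04d", seq_len(nPromoters)))
        cls <- rep(c("enhancer", "promoter"), c(nEnhancers, nPromoters))
        if (n == 0L) {
            gr <- GRanges(seqinfo = si)
            mcols(gr) <- DataFrame(region_id = character(),
                                   region_class = character(),
                                   source = character())
            return(RegulatorySet(gr))
        }
        lens <- pmin(pmax(round(rlnorm(n, lengthMeanLog, lengthSdLog)),
                          lengthRange[1L]), lengthRange[2L])
        chromLens <- seqlengths(si)
        ord <- sample.int(n)      # shuffle before chromosome assignment
        placed <- NULL
        for (try in seq_len(maxTries)) {
            chrom <- sample(seqlevels(si), n, replace = TRUE,
                            prob = chromLens / sum(chromLens))
            starts <- rep(NA_integer_, n)
            ok <- TRUE
            for (ch in seqlevels(si)) {
                idx <- ord[chrom[ord] == ch]
                st <- .placeDisjoint(lens[idx], chromLens[[ch]], minGap)
                if (is.null(st)) { ok <- FALSE; break }
                starts[idx] <- st
            }
            if (ok) { placed <- list(chrom = chrom, starts = starts); break }
        }
        if (is.null(placed))
            stop("capacity error: could not place ", n,
                 " disjoint regions on the genome after ", maxTries, " tries")
        gr <- GRanges(placed$chrom,
                      IRanges(placed$starts + 1L, width = lens),
                      seqinfo = si)
        mcols(gr) <- DataFrame(region_id = ids, region_class = cls,
                               source = "synthetic")
        catalog <- sprintf("G%04d", seq_len(nGenes))
        nlink <- sample.int(maxGenesPerRegion, n, replace = TRUE)
        linkage <- data.frame(
            region_id = rep(ids, nlink),
            gene_id = unlist(lapply(nlink, function(k) sample(catalog, k))),
            stringsAsFactors = FALSE)
        RegulatorySet(gr, linkage)
    })
}

#' Simulate SNC catalogs with planted candidate regions
#'
#' Each region is independently assigned a status: *modern-only* (>= 1 mSNC,
#' no archaic change; these are the planted candidates), *archaic*
#' (>= 1 Neanderthal/Denisovan change, possibly plus mSNCs, so the depletion
#' filter has work to do) or *empty*. Modern derived-allele frequencies are
#' 1.0 with probability `pFixedGivenModern`, otherwise uniform on
#' [0.90, 1 - epsilonFixed). Background SNCs are scattered strictly outside
#' all regions. The returned manifest records the exact planted truth,
#' derived from the planting decisions, not by re-running the filter.
#'
#' @param rset a [RegulatorySet-class].
#' @param genome genome the regions live on.
#' @param pModernOnly,pArchaic status probabilities (sum must be <= 1).
#' @param pFixedGivenModern probability a modern SNC is fixed (frequency 1).
#' @param backgroundRate background SNCs per bp outside regions.
#' @param epsilonFixed frequencies >= 1 - epsilonFixed count as fixed.
#' @param seed RNG seed.
#' @return list with elements `sncs` ([SNCCatalog-class]) and `manifest`
#'   (list: `candidate_region_ids`, `candidate_genes`,
#'   `fixed_enhancer_genes`, `fixed_promoter_genes`, `both_genes`,
#'   `region_status`, `rng_seed`).
#' @export
simulateSncs <- function(rset, genome = toyGenome(),
                         pModernOnly = 0.3, pArchaic = 0.2,
                         pFixedGivenModern = 0.5,
                         backgroundRate = 1e-4, epsilonFixed = 1e-6,
                         seed = 1) {
    stopifnot(pModernOnly >= 0, pArchaic >= 0, pModernOnly + pArchaic <= 1)
    si <- .asSeqinfo(genome)
    gr <- regions(rset)
    n <- length(gr)
    with_seed(seed, {
        status <- if (n) sample(c("modern_only", "archaic", "empty"), n,
                                replace = TRUE,
                                prob = c(pModernOnly, pArchaic,
                                         max(0, 1 - pModernOnly - pArchaic)))
                  else character()
        chrom <- character(); pos <- integer()
        lineage <- character(); freq <- numeric()
        regionFixed <- logical(n)   # region has >= 1 fixed mSNC
        drawModernFreqs <- function(k) {
            isFix <- runif(k) < pFixedGivenModern
            ifelse(isFix, 1, runif(k, 0.90, 1 - epsilonFixed))
        }
        for (i in seq_len(n)) {
            if (status[i] == "empty") next
            w <- width(gr)[i]
            nMod <- if (status[i] == "modern_only") 1L + rpois(1L, 0.8)
                    else rpois(1L, 0.8)
            nArch <- if (status[i] == "archaic") 1L + rpois(1L, 0.5) else 0L
            tot <- nMod + nArch
            if (tot == 0L) next
            offs <- sample.int(w, min(tot, w))
            nMod <- min(nMod, length(offs))
            nArch <- length(offs) - nMod
            p <- start(gr)[i] + offs - 1L
            chrom <- c(chrom, rep(as.character(seqnames(gr)[i]), length(offs)))
            pos <- c(pos, p)
            lineage <- c(lineage, rep(c("modern", "archaic"), c(nMod, nArch)))
            fm <- drawModernFreqs(nMod)
            freq <- c(freq, fm, rep(1, nArch))
            if (status[i] == "modern_only" && any(fm >= 1 - epsilonFixed))
                regionFixed[i] <- TRUE
        }
        # background changes, strictly outside every region
        chromLens <- seqlengths(si)
        nBg <- rpois(1L, backgroundRate * sum(chromLens))
        if (nBg > 0L) {
            got <- 0L
            while (got < nBg) {
                m <- (nBg - got) * 2L
                bgChrom <- sample(seqlevels(si), m, replace = TRUE,
                                  prob = chromLens / sum(chromLens))
                bgPos <- floor(runif(m, 0, chromLens[bgChrom])) + 1L
                cand <- GRanges(bgChrom, IRanges(bgPos, width = 1L))
                keep <- countOverlaps(cand, gr) == 0L
                keep <- which(keep)[seq_len(min(sum(keep), nBg - got))]
                if (length(keep)) {
                    chrom <- c(chrom, bgChrom[keep])
                    pos <- c(pos, bgPos[keep])
                    bgLin <- sample(c("modern", "archaic"), length(keep),
                                    replace = TRUE)
                    lineage <- c(lineage, bgLin)
                    bgFreq <- rep(1, length(keep))
                    bgFreq[bgLin == "modern"] <-
                        drawModernFreqs(sum(bgLin == "modern"))
                    freq <- c(freq, bgFreq)
                    got <- got + length(keep)
                }
            }
        }
        anc <- sample(.DNA_BASES, length(pos), replace = TRUE)
        der <- vapply(anc, function(a)
            sample(setdiff(.DNA_BASES, a), 1L), "")
        sncs <- SNCCatalog(chrom, pos, anc, der, lineage, freq, genome = si)

        md <- mcols(gr)
        candIds <- md$region_id[status == "modern_only"]
        lk <- linkage(rset)
        candLink <- lk[lk$region_id %in% candIds, , drop = FALSE]
        classOf <- setNames(md$region_class, md$region_id)
        fixedIds <- md$region_id[regionFixed]
        fixedLink <- lk[lk$region_id %in% fixedIds, , drop = FALSE]
        fixEnh <- sort(unique(
            fixedLink$gene_id[classOf[fixedLink$region_id] == "enhancer"]))
        fixProm <- sort(unique(
            fixedLink$gene_id[classOf[fixedLink$region_id] == "promoter"]))
        manifest <- list(
            candidate_region_ids = sort(candIds),
            candidate_genes = sort(unique(candLink$gene_id)),
            fixed_enhancer_genes = fixEnh,
            fixed_promoter_genes = fixProm,
            both_genes = intersect(fixEnh, fixProm),
            region_status = setNames(status, md$region_id),
            rng_seed = seed)
        list(sncs = sncs, manifest = manifest)
    })
}

#' Simulate feature region sets with a planted overlap fraction
#'
#' Emulates feature BEDs (selective-sweep regions, disease loci) whose
#' enrichment against candidate regions is under test: `round(rho *
#' nFeatures)` features are forced to overlap a randomly chosen candidate
#' region; the remainder are placed uniformly on the genome. `rho = 0` is
#' the null case.
#'
#' @param genome genome to place on.
#' @param candidates `GRanges` of candidate regions (may be empty when
#'   `rho = 0`).
#' @param rho forced-overlap fraction in [0, 1].
#' @param nFeatures number of features.
#' @param lengthRange feature lengths, uniform over this range (bp).
#' @param seed RNG seed.
#' @return a `GRanges` of features.
#' @export
simulateFeatures <- function(genome = toyGenome(), candidates = GRanges(),
                             rho = 0, nFeatures = 50,
                             lengthRange = c(2000, 8000), seed = 1) {
    stopifnot(rho >= 0, rho <= 1)
    si <- .asSeqinfo(genome)
    chromLens <- seqlengths(si)
    with_seed(seed, {
        lens <- floor(runif(nFeatures, lengthRange[1L], lengthRange[2L] + 1))
        nForced <- round(rho * nFeatures)
        if (nForced > 0L && length(candidates) == 0L)
            stop("rho > 0 requires a non-empty candidate set")
        chrom <- character(nFeatures); start0 <- numeric(nFeatures)
        for (i in seq_len(nFeatures)) {
            L <- lens[i]
            if (i <= nForced) {
                tgt <- candidates[sample.int(length(candidates), 1L)]
                ch <- as.character(seqnames(tgt))
                lo <- max(0L, start(tgt) - L)        # bed start of window
                hi <- min(chromLens[[ch]] - L, end(tgt) - 1L)
                s <- floor(runif(1L, lo, hi + 1))
            } else {
                fits <- names(chromLens)[chromLens >= L]
                if (!length(fits)) stop("feature longer than every chromosome")
                ch <- sample(fits, 1L, prob = chromLens[fits])
                s <- floor(runif(1L, 0, chromLens[[ch]] - L + 1))
            }
            chrom[i] <- ch; start0[i] <- s
        }
        gr <- GRanges(chrom, IRanges(start0 + 1L, width = lens), seqinfo = si)
        mcols(gr)$region_id <- sprintf("F%04d", seq_len(nFeatures))
        mcols(gr)$forced <- seq_len(nFeatures) <= nForced
        gr
    })
}

#' Build a motif from a consensus string
#'
#' Each column puts `dominant` probability on the consensus base and splits
#' the remainder evenly; handy for defining planted and decoy motifs.
#'
#' @param motifId identifier.
#' @param consensus DNA string over A/C/G/T.
#' @param dominant probability of the consensus base per column.
#' @param ... passed to [MotifMatrix()].
#' @return a [MotifMatrix-class].
#' @export
pwmFromConsensus <- function(motifId, consensus, dominant = 0.9, ...) {
    bases <- strsplit(toupper(consensus), "")[[1L]]
    stopifnot(all(bases %in% .DNA_BASES))
    prof <- matrix((1 - dominant) / 3, nrow = 4L, ncol = length(bases),
                   dimnames = list(.DNA_BASES, NULL))
    prof[cbind(match(bases, .DNA_BASES), seq_along(bases))] <- dominant
    MotifMatrix(motifId, prof, ...)
}

#' Default motif set for simulations
#'
#' One plantable 10-bp motif (`M_PLANT`) plus three decoys of comparable
#' information content, so Benjamini-Hochberg correction across motifs is
#' exercised.
#'
#' @return named list of [MotifMatrix-class] objects.
#' @export
defaultMotifSet <- function() {
    list(M_PLANT = pwmFromConsensus("M_PLANT", "TGACGTCATG"),
         M_DEC1 = pwmFromConsensus("M_DEC1", "CCGGAAGTGA"),
         M_DEC2 = pwmFromConsensus("M_DEC2", "ATTGCATAAC"),
         M_DEC3 = pwmFromConsensus("M_DEC3", "GGGCGGGAAT"))
}

#' Simulate region sequences with a planted motif
#'
#' Generates i.i.d. background sequence for `n` regions and inserts one
#' motif instance (sampled column-wise from the PWM, uniform position and
#' strand) into `round(fractionPlanted * n)` of them.
#'
#' @param n number of regions.
#' @param pwm a [MotifMatrix-class] to plant.
#' @param fractionPlanted fraction of regions receiving an instance.
#' @param length region length (bp); must be >= motif length.
#' @param baseComp background base composition (A, C, G, T).
#' @param seed RNG seed.
#' @param prefix sequence-name prefix.
#' @return list: `sequences` (named [Biostrings::DNAStringSet]),
#'   `planted_ids` (character).
#' @export
simulateMotifSequences <- function(n = 100, pwm = defaultMotifSet()$M_PLANT,
                                   fractionPlanted = 0.5, length = 200,
                                   baseComp = rep(0.25, 4), seed = 1,
                                   prefix = "region") {
    m <- ncol(pwm@profile)
    if (length < m) stop("region length must be >= motif length")
    with_seed(seed, {
        seqs <- vapply(seq_len(n), function(i)
            paste(sample(.DNA_BASES, length, replace = TRUE,
                         prob = baseComp), collapse = ""), "")
        k <- round(fractionPlanted * n)
        planted <- sort(sample.int(n, k))
        for (i in planted) {
            inst <- vapply(seq_len(m), function(j)
                sample(.DNA_BASES, 1L, prob = pwm@profile[, j]), "")
            inst <- paste(inst, collapse = "")
            if (runif(1L) < 0.5)
                inst <- as.character(reverseComplement(DNAString(inst)))
            at <- sample.int(length - m + 1L, 1L)
            substr(seqs[i], at, at + m - 1L) <- inst
        }
        names(seqs) <- sprintf("%s_%04d", prefix, seq_len(n))
        list(sequences = DNAStringSet(seqs),
             planted_ids = names(seqs)[planted])
    })
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Counts are negative binomial around a per-cell library size, with
#' log-rate structure `baseline + cluster marker shift + module loading x
#' per-cell latent factor + cell-cycle phase shift`; single-cell
#' overdispersion is required for the QC and variable-gene thresholds to be
#' meaningful. Co-expression modules arise from one latent factor per module
#' with gene-specific loadings (uniform on `loadingRange`, giving hub-like
#' heterogeneous connectivity). Designated mitochondrial genes (named
#' `MT-*`) carry an elevated share of counts in a subset of cells, and
#' designated G1/S / G2/M gene sets have phase-dependent means.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param nClusters number of cell clusters (markers: `markerFraction` of
#'   genes shifted by `markerShift` log-units per cluster).
#' @param nModules,moduleSize planted co-expression modules (first
#'   `nModules * moduleSize` genes; requires
#'   `nModules * moduleSize + nMitoGenes + 2 * nCcGenes <= nGenes`).
#' @param loadingRange module loading range (log-rate units per latent-factor
#'   standard deviation).
#' @param baselineMean,baselineSd normal parameters of the per-gene baseline
#'   log-rate; the default keeps module genes expressed enough for their
#'   co-variation to be observable at the simulated sequencing depth.
#' @param libsizeMeanLog,libsizeSdLog log-normal library-size parameters.
#' @param nbDispersion negative-binomial size parameter.
#' @param nMitoGenes,nCcGenes designated mitochondrial genes and cell-cycle
#'   genes per phase (taken from the non-module genes).
#' @param mitoHighFraction fraction of cells with strongly elevated
#'   mitochondrial content (these should fail the 5% mito QC filter).
#' @param markerFraction,markerShift cluster-marker parameters.
#' @param phaseShift log-rate increase of phase genes in cells of that phase.
#' @param seed RNG seed.
#' @return list: `counts` (genes x cells integer matrix), `geneMeta`,
#'   `cellMeta` (data.frames), `manifest` (module/cluster truth, gene sets,
#'   seed).
#' @export
simulateCounts <- function(nCells = 120, nGenes = 1200, nClusters = 2,
                           nModules = 4, moduleSize = 250,
                           loadingRange = c(0.8, 1.8),
                           baselineMean = 0.8, baselineSd = 0.6,
                           libsizeMeanLog = log(5000), libsizeSdLog = 0.3,
                           nbDispersion = 2,
                           nMitoGenes = 20, nCcGenes = 40,
                           mitoHighFraction = 0.1,
                           markerFraction = 0.05, markerShift = 0.8,
                           phaseShift = 1.0, seed = 1) {
    nModGenes <- nModules * moduleSize
    if (nModGenes + nMitoGenes + 2L * nCcGenes > nGenes)
        stop("nModules * moduleSize + special genes exceeds nGenes")
    with_seed(seed, {
        geneId <- sprintf("G%05d", seq_len(nGenes))
        free <- setdiff(seq_len(nGenes), seq_len(nModGenes))
        mitoIdx <- head(free, nMitoGenes)
        g1sIdx <- head(setdiff(free, mitoIdx), nCcGenes)
        g2mIdx <- head(setdiff(free, c(mitoIdx, g1sIdx)), nCcGenes)
        geneId[mitoIdx] <- sprintf("MT-G%04d", seq_along(mitoIdx))
        module <- rep("unassigned", nGenes)
        if (nModules > 0L)
            module[seq_len(nModGenes)] <-
                rep(sprintf("M%d", seq_len(nModules)), each = moduleSize)

        alpha <- rnorm(nGenes, baselineMean, baselineSd)
        # mito genes sized for ~3% of counts in ordinary cells
        alpha[mitoIdx] <- alpha[mitoIdx] + 0.6
        cluster <- sample(seq_len(nClusters), nCells, replace = TRUE)
        phase <- sample(c("G1S", "G2M", "none"), nCells, replace = TRUE,
                        prob = c(0.25, 0.25, 0.5))
        libsize <- rlnorm(nCells, libsizeMeanLog, libsizeSdLog)

        logRate <- matrix(alpha, nGenes, nCells)
        # cluster markers
        markers <- vector("list", nClusters)
        for (k in seq_len(nClusters)) {
            mk <- sample.int(nGenes, round(markerFraction * nGenes))
            markers[[k]] <- geneId[mk]
            logRate[mk, cluster == k] <- logRate[mk, cluster == k] + markerShift
        }
        # module latent factors
        loading <- runif(nGenes, loadingRange[1L], loadingRange[2L])
        if (nModules > 0L) {
            fac <- matrix(rnorm(nModules * nCells), nModules, nCells)
            for (m in seq_len(nModules)) {
                gi <- which(module == sprintf("M%d", m))
                logRate[gi, ] <- logRate[gi, ] +
                    outer(loading[gi], fac[m, ])
            }
        }
        # cell-cycle phase effects
        if (nCcGenes > 0L) {
            logRate[g1sIdx, phase == "G1S"] <-
                logRate[g1sIdx, phase == "G1S"] + phaseShift
            logRate[g2mIdx, phase == "G2M"] <-
                logRate[g2mIdx, phase == "G2M"] + phaseShift
        }
        # mito-high cells
        mitoHigh <- runif(nCells) < mitoHighFraction
        if (length(mitoIdx))
            logRate[mitoIdx, mitoHigh] <- logRate[mitoIdx, mitoHigh] + 1.5

        rate <- exp(logRate)
        p <- sweep(rate, 2L, colSums(rate), "/")
        mu <- sweep(p, 2L, libsize, "*")
        counts <- matrix(rnbinom(nGenes * nCells, size = nbDispersion,
                                 mu = mu), nGenes, nCells)
        storage.mode(counts) <- "integer"
        cellId <- sprintf("cell_%04d", seq_len(nCells))
        dimnames(counts) <- list(geneId, cellId)

        geneMeta <- data.frame(
            gene_id = geneId,
            mito = seq_len(nGenes) %in% mitoIdx,
            cc_phase = ifelse(seq_len(nGenes) %in% g1sIdx, "G1S",
                       ifelse(seq_len(nGenes) %in% g2mIdx, "G2M", "none")),
            module = module, stringsAsFactors = FALSE)
        cellMeta <- data.frame(
            cell_id = cellId, cluster = sprintf("C%d", cluster),
            phase = phase, mito_high = mitoHigh, stringsAsFactors = FALSE)
        manifest <- list(
            module_assignment = setNames(module, geneId),
            cluster_assignment = setNames(cellMeta$cluster, cellId),
            mito_genes = geneId[mitoIdx],
            g1s_genes = geneId[g1sIdx],
            g2m_genes = geneId[g2mIdx],
            cluster_markers = markers,
            rng_seed = seed)
        list(counts = counts, geneMeta = geneMeta, cellMeta = cellMeta,
             manifest = manifest)
    })
}

# ---- emission / ingestion of synthetic datasets ----------------------------

#' Write/read count matrices
#'
#' TSV layout: first column `gene_id`, remaining columns one per cell.
#' MatrixMarket layout: `<stem>.mtx` plus `<stem>.genes.tsv` and
#' `<stem>.cells.tsv` (via the Matrix package).
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path TSV path, or `.mtx` path for the MTX pair.
#' @return readers return the matrix; writers the path, invisibly.
#' @export
writeCountsTsv <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
}

#' @rdname writeCountsTsv
#' @export
writeCountsMtx <- function(counts, path) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    paste0(stem, ".mtx"))
    writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
    writeLines(colnames(counts), paste0(stem, ".cells.tsv"))
    invisible(paste0(stem, ".mtx"))
}

#' @rdname writeCountsTsv
#' @export
readCountsMtx <- function(path) {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
    dimnames(m) <- list(readLines(paste0(stem, ".genes.tsv")),
                        readLines(paste0(stem, ".cells.tsv")))
    storage.mode(m) <- "integer"
    m
}

#' Write/read a ground-truth manifest as JSON
#'
#' @param manifest a manifest list (from [simulateSncs()] or
#'   [simulateCounts()]).
#' @param path JSON path.
#' @return `readManifest()` the list; `writeManifest()` the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
    write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    read_json(path, simplifyVector = TRUE)
}
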