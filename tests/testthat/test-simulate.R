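test_that("simulated regions are pairwise disjoint with the requested gap", {
    rs <- simulateRegions(nEnhancers = 100, nPromoters = 0, minGap = 100,
                          seed = 2)
    gr <- sort(regions(rs))
    expect_length(gr, 100L)
    byChrom <- split(gr, seqnames(gr))
    for (g in byChrom) {
        if (length(g) < 2L) next
        gaps <- start(g)[-1L] - end(g)[-length(g)] - 1L
        expect_true(all(gaps >= 100L))
    }
})

test_that("region generation is a pure function of seed and parameters", {
    f1 <- tempfile(); f2 <- tempfile()
    writeLinkage(simulateRegions(seed = 77), f1)
    writeLinkage(simulateRegions(seed = 77), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_false(identical(readLines(f1),
        { writeLinkage(simulateRegions(seed = 78), f2); readLines(f2) }))
})

test_that("empty region request yields a valid empty set; tiny genomes error", {
    rs <- simulateRegions(nEnhancers = 0, nPromoters = 0, seed = 1)
    expect_length(regions(rs), 0L)
    expect_true(validObject(rs))
    expect_error(
        simulateRegions(genome = c(chr1 = 5000), nEnhancers = 100,
                        nPromoters = 0, seed = 1),
        "capacity")
})

test_that("SNC manifest agrees with an independent recount of emitted files", {
    g <- toyGenome()
    rs <- simulateRegions(g, nEnhancers = 300, nPromoters = 200, seed = 10)
    sim <- simulateSncs(rs, g, pModernOnly = 0.3, pArchaic = 0.2, seed = 10)
    fS <- tempfile(); fL <- tempfile()
    writeSncCatalog(sim$sncs, fS)
    writeLinkage(rs, fL)
    sncs <- readSncCatalog(fS)
    back <- readRegulatorySet(fL)
    gr <- regions(back)
    nMod <- bruteCountHits(gr, sncs[sncLineage(sncs) == "modern"])
    nArc <- bruteCountHits(gr, sncs[sncLineage(sncs) == "archaic"])
    recounted <- sort(regionIds(back)[nMod >= 1L & nArc == 0L])
    expect_identical(recounted, sim$manifest$candidate_region_ids)

    lk <- linkage(back)
    genes <- sort(unique(lk$gene_id[lk$region_id %in% recounted]))
    expect_identical(genes, sim$manifest$candidate_genes)
})

test_that("SNC planting respects the degenerate status probabilities", {
    rs <- simulateRegions(nEnhancers = 40, nPromoters = 20, seed = 4)
    all <- simulateSncs(rs, pModernOnly = 1, pArchaic = 0, seed = 4)
    expect_setequal(all$manifest$candidate_region_ids, regionIds(rs))
    none <- simulateSncs(rs, pModernOnly = 0, pArchaic = 0.3, seed = 4)
    expect_length(none$manifest$candidate_region_ids, 0L)
})

test_that("modern frequencies are fixed or in the nearly-fixed band", {
    rs <- simulateRegions(nEnhancers = 100, nPromoters = 50, seed = 6)
    sim <- simulateSncs(rs, pModernOnly = 0.8, seed = 6)
    fr <- sncFrequency(sim$sncs)[sncLineage(sim$sncs) == "modern"]
    expect_true(all(fr == 1 | (fr >= 0.90 & fr < 1)))
    expect_true(any(fr == 1) && any(fr < 1))
})

test_that("feature planting forces the requested overlap fraction", {
    g <- toyGenome()
    cand <- regions(simulateRegions(g, 50, 0, seed = 8))
    all50 <- simulateFeatures(g, cand, rho = 1, nFeatures = 50, seed = 8)
    expect_true(all(bruteOverlapsAny(all50, cand)))
    half <- simulateFeatures(g, cand, rho = 0.5, nFeatures = 100, seed = 8)
    expect_gte(sum(bruteOverlapsAny(half, cand)), 50L)
    expect_error(simulateFeatures(g, GRanges(), rho = 0.5, seed = 1),
                 "non-empty")
})

test_that("expected observed overlap grows with the planted fraction", {
    g <- toyGenome()
    cand <- regions(simulateRegions(g, 60, 40, seed = 12))
    meanObs <- vapply(c(0, 0.5, 1), function(rho) {
        mean(vapply(1:5, function(s) {
            f <- simulateFeatures(g, cand, rho = rho, nFeatures = 50,
                                  seed = 100 + s)
            sum(bruteOverlapsAny(cand, f))
        }, 0))
    }, 0)
    expect_true(meanObs[1L] < meanObs[2L] && meanObs[2L] < meanObs[3L])
})

test_that("motif planting count and determinism hold", {
    sim0 <- simulateMotifSequences(n = 40, fractionPlanted = 0, seed = 5)
    expect_length(sim0$planted_ids, 0L)
    sim1 <- simulateMotifSequences(n = 40, fractionPlanted = 1, length = 10,
                                   seed = 5)
    expect_length(sim1$planted_ids, 40L)
    expect_true(all(Biostrings::width(sim1$sequences) == 10L))
    a <- simulateMotifSequences(n = 20, seed = 9)
    b <- simulateMotifSequences(n = 20, seed = 9)
    expect_identical(as.character(a$sequences), as.character(b$sequences))
})

test_that("counts are reproducible and structured as declared", {
    a <- simulateCounts(seed = 21)
    b <- simulateCounts(seed = 21)
    expect_identical(a$counts, b$counts)
    expect_equal(dim(a$counts), c(1200L, 120L))
    expect_setequal(unique(a$geneMeta$module),
                    c(sprintf("M%d", 1:4), "unassigned"))
    expect_equal(sum(a$geneMeta$module == "M1"), 250L)
    expect_true(all(startsWith(a$manifest$mito_genes, "MT-")))
    expect_identical(a$manifest$module_assignment,
                     setNames(a$geneMeta$module, a$geneMeta$gene_id))
})

test_that("without planted modules, gene-gene bicor is consistent with independence", {
    sc <- simulateCounts(nCells = 200, nGenes = 150, nModules = 0,
                         moduleSize = 0, nMitoGenes = 0, nCcGenes = 0,
                         nClusters = 1, seed = 31)
    bc <- bicorMatrix(logNormalize(sc$counts))
    off <- abs(bc[upper.tri(bc)])
    expect_lt(max(off), 0.45)
    expect_lt(mean(off), 0.10)
})

test_that("count matrices round-trip through TSV and MatrixMarket", {
    sc <- simulateCounts(nCells = 15, nGenes = 60, nModules = 1,
                         moduleSize = 10, nMitoGenes = 5, nCcGenes = 5,
                         seed = 3)
    f <- tempfile(fileext = ".tsv")
    writeCountsTsv(sc$counts, f)
    expect_identical(readCountsTsv(f), sc$counts)
    m <- tempfile(fileext = ".mtx")
    writeCountsMtx(sc$counts, m)
    expect_identical(readCountsMtx(m), sc$counts)
})

test_that("manifests round-trip through JSON", {
    rs <- simulateRegions(nEnhancers = 20, nPromoters = 10, seed = 14)
    sim <- simulateSncs(rs, seed = 14)
    f <- tempfile(fileext = ".json")
    writeManifest(sim$manifest, f)
    back <- readManifest(f)
    expect_equal(back$candidate_region_ids, sim$manifest$candidate_region_ids)
    expect_equal(back$rng_seed, sim$manifest$rng_seed)
})
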