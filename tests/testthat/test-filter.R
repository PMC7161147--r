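makeAnnotated <- function() {
    tbl <- data.frame(
        chrom = "chr1",
        start = c(1000, 3000, 5000, 7000),
        end = c(2000, 4000, 6000, 8000),
        region_id = c("E1", "E2", "P1", "P2"),
        region_class = c("enhancer", "enhancer", "promoter", "promoter"))
    lk <- data.frame(region_id = c("E1", "E2", "P1", "P2", "E1"),
                     gene_id = c("GA", "GA", "GA", "GB", "GC"))
    toyRegulatorySet(tbl, lk)
}

test_that("region annotation classifies fixed vs nearly fixed mSNCs", {
    rs <- makeAnnotated()
    sncs <- SNCCatalog(
        chrom = rep("chr1", 4),
        pos = c(1500, 3500, 3600, 5500),
        ancestral = c("A", "A", "C", "G"),
        derived = c("T", "G", "T", "A"),
        lineage = c("modern", "modern", "archaic", "modern"),
        frequency = c(1.0, 0.95, 1.0, 1.0))
    ann <- annotateRegions(rs, sncs)
    md <- mcols(regions(ann))
    # E1: one fixed mSNC; E2: one nearly fixed mSNC plus an archaic change
    expect_equal(md$n_modern, c(1L, 1L, 1L, 0L))
    expect_equal(md$n_modern_fixed, c(1L, 0L, 1L, 0L))
    expect_equal(md$n_archaic, c(0L, 1L, 0L, 0L))
})

test_that("an explicit fixed flag overrides the frequency-based call", {
    rs <- makeAnnotated()
    sncs <- SNCCatalog("chr1", 1500, "A", "T", "modern", 0.93, fixed = TRUE)
    ann <- annotateRegions(rs, sncs)
    expect_equal(mcols(regions(ann))$n_modern_fixed[1L], 1L)
})

test_that("candidate selection requires >= 1 mSNC and archaic depletion", {
    rs <- makeAnnotated()
    sncs <- SNCCatalog(
        chrom = rep("chr1", 4),
        pos = c(1500, 3500, 3600, 5500),
        ancestral = rep("A", 4), derived = rep("T", 4),
        lineage = c("modern", "modern", "archaic", "modern"),
        frequency = c(1, 0.95, 1, 1))
    cand <- selectCandidates(annotateRegions(rs, sncs))
    # E2 has 2 modern-lineage-context changes but 1 archaic -> excluded;
    # P2 has none -> excluded
    expect_setequal(regionIds(cand), c("E1", "P1"))
    expect_error(selectCandidates(rs), "not annotated")
})

test_that("candidate selection is idempotent and order-independent", {
    g <- toyGenome()
    rs <- simulateRegions(g, 60, 40, seed = 17)
    sim <- simulateSncs(rs, g, seed = 17)
    ann <- annotateRegions(rs, sim$sncs)
    cand <- selectCandidates(ann)
    expect_identical(regionIds(selectCandidates(cand)), regionIds(cand))

    perm <- sample(length(regions(rs)))
    rsShuf <- RegulatorySet(regions(rs)[perm], linkage(rs))
    sncShuf <- sim$sncs[sample(length(sim$sncs))]
    candShuf <- selectCandidates(annotateRegions(rsShuf, sncShuf))
    expect_setequal(regionIds(candShuf), regionIds(cand))
})

test_that("annotation counts equal a brute-force recount on synthetic data", {
    g <- toyGenome()
    rs <- simulateRegions(g, 300, 200, seed = 23)
    sim <- simulateSncs(rs, g, seed = 23)
    ann <- annotateRegions(rs, sim$sncs)
    md <- mcols(regions(ann))
    sncs <- sim$sncs
    isFix <- sncFrequency(sncs) >= 1 - 1e-6
    expect_identical(md$n_modern,
        bruteCountHits(regions(ann), sncs[sncLineage(sncs) == "modern"]))
    expect_identical(md$n_modern_fixed,
        bruteCountHits(regions(ann),
                       sncs[sncLineage(sncs) == "modern" & isFix]))
    expect_identical(md$n_archaic,
        bruteCountHits(regions(ann), sncs[sncLineage(sncs) == "archaic"]))
})

test_that("adding SNCs moves regions across the candidate boundary monotonically", {
    rs <- makeAnnotated()
    base <- SNCCatalog("chr1", 1500, "A", "T", "modern", 1)
    cand1 <- regionIds(selectCandidates(annotateRegions(rs, base)))
    expect_true("E1" %in% cand1)
    # adding an archaic change inside E1 can only remove it
    plusArch <- SNCCatalog(c("chr1", "chr1"), c(1500, 1600),
                           c("A", "C"), c("T", "G"),
                           c("modern", "archaic"), c(1, 1))
    cand2 <- regionIds(selectCandidates(annotateRegions(rs, plusArch)))
    expect_false("E1" %in% cand2)
    expect_true(all(cand2 %in% cand1))
    # adding a modern change to P2 can only add it
    plusMod <- SNCCatalog(c("chr1", "chr1"), c(1500, 7500),
                          c("A", "C"), c("T", "G"),
                          c("modern", "modern"), c(1, 0.92))
    cand3 <- regionIds(selectCandidates(annotateRegions(rs, plusMod)))
    expect_setequal(cand3, union(cand1, "P2"))
})

test_that("the containment filter applies H3K4me3 at the peak level", {
    enh <- bedInterval("chr1", c(100, 100, 100), c(200, 200, 200))
    # case 1: contained in a clean H3K27ac peak -> pass
    expect_true(adultEnhancerFilter(enh[1], bedInterval("chr1", 50, 300),
                                    GRanges()))
    # case 2: only partial overlap with the peak -> fail
    expect_false(adultEnhancerFilter(enh[1], bedInterval("chr1", 150, 300),
                                     GRanges()))
    # case 3: containing peak touched by H3K4me3 -> fail
    expect_false(adultEnhancerFilter(enh[1], bedInterval("chr1", 50, 300),
                                     bedInterval("chr1", 290, 310)))
    # enhancer-level reading: the same H3K4me3 peak does not touch the
    # enhancer itself, so the alternative mode passes it
    expect_true(adultEnhancerFilter(enh[1], bedInterval("chr1", 50, 300),
                                    bedInterval("chr1", 290, 310),
                                    mode = "enhancer"))
})

test_that("gene resolution deduplicates and keeps per-region evidence", {
    rs <- makeAnnotated()
    sncs <- SNCCatalog(c("chr1", "chr1"), c(1500, 3500), c("A", "C"),
                       c("T", "G"), c("modern", "modern"), c(1, 1))
    cand <- selectCandidates(annotateRegions(rs, sncs))
    res <- resolveGeneList(cand)
    expect_setequal(res$genes, c("GA", "GC"))
    expect_equal(sum(res$evidence$gene_id == "GA"), 2L)  # E1 and E2 support GA

    none <- selectCandidates(annotateRegions(rs,
        SNCCatalog("chr1", 1500, "A", "T", "archaic", 1)))
    expect_length(resolveGeneList(none)$genes, 0L)
})

test_that("candidate regions missing from the linkage table warn and drop", {
    rs <- makeAnnotated()
    sncs <- SNCCatalog("chr1", 1500, "A", "T", "modern", 1)
    cand <- selectCandidates(annotateRegions(rs, sncs))
    lk <- data.frame(region_id = "E2", gene_id = "GX")
    expect_warning(res <- resolveGeneList(cand, lk), "missing from the")
    expect_length(res$genes, 0L)
})

test_that("fixed-change gene classes follow the enhancer/promoter evidence", {
    # the LRRC23 pattern: fixed changes in both an enhancer and a promoter
    ev <- data.frame(
        gene_id = c("LRRC23", "LRRC23", "NEUROD6", "SETD1A", "FOXP2"),
        region_id = c("e1", "p1", "e2", "p2", "p3"),
        region_class = c("enhancer", "promoter", "enhancer", "promoter",
                         "promoter"),
        n_modern = c(3L, 1L, 1L, 1L, 1L),
        n_modern_fixed = c(3L, 1L, 1L, 1L, 0L),   # FOXP2: nearly fixed only
        n_archaic = 0L)
    cls <- classifyFixedGenes(ev)
    expect_setequal(cls$enhancer_fixed, c("LRRC23", "NEUROD6"))
    expect_setequal(cls$promoter_fixed, c("LRRC23", "SETD1A"))
    expect_equal(cls$both, "LRRC23")
    expect_false("FOXP2" %in% unlist(cls))
})

test_that("filter results on synthetic data equal the planted manifest", {
    g <- toyGenome()
    rs <- simulateRegions(g, 120, 80, seed = 29)
    sim <- simulateSncs(rs, g, seed = 29)
    cand <- selectCandidates(annotateRegions(rs, sim$sncs))
    expect_setequal(regionIds(cand), sim$manifest$candidate_region_ids)
    res <- resolveGeneList(cand)
    expect_setequal(res$genes, sim$manifest$candidate_genes)
    cls <- classifyFixedGenes(res$evidence)
    expect_setequal(cls$enhancer_fixed, sim$manifest$fixed_enhancer_genes)
    expect_setequal(cls$promoter_fixed, sim$manifest$fixed_promoter_genes)
    expect_setequal(cls$both, sim$manifest$both_genes)
})
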