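## Default synthetic scenario with truth tracts replayed as 10 identical
## painting replicates: consensus equals the true target tracts, so library
## construction and assembly can be tested without painter noise.
truthLibrary <- function(nAdmixed = 30L, nSites = 500L, chromLength = 5e5,
                         quota = 10L, seed = 13L, missingRate = 0) {
    cfg <- simConfig(nSamples = c(HM = 10L, Han = 10L), driftF = 0.2,
                     nAdmixed = nAdmixed, otherPop = "Han",
                     nSites = nSites, chromLength = chromLength,
                     g = 60L, missingRate = missingRate, seed = seed)
    sim <- simulatePanel(cfg)
    cons <- consensusSegments(truthReplicates(sim$truth), "HM")
    adm <- samplesOfPop(sim$panel, "Yao")
    subpop <- setNames(rep(c("sub1", "sub2", "sub3"),
                           length.out = length(adm))[order(order(adm))],
                       adm)
    lib <- buildLibrary(cons, sim$panel, subpop, quotaPerSubpop = quota)
    list(sim = sim, cons = cons, lib = lib)
}

test_that("a balanced 10+10+10 donor selection yields a 60-haplotype library", {
    tl <- truthLibrary()
    expect_length(tl$lib@haplotypeIds, 60)
    expect_equal(as.vector(table(tl$lib@subpopOf)), c(10L, 10L, 10L))
})

test_that("insufficient donors abort naming the subpopulation", {
    tl <- truthLibrary(nAdmixed = 6L, quota = 2L)
    adm <- samplesOfPop(tl$sim$panel, "Yao")
    subpop <- setNames(c(rep("big", 5), "small"), adm)
    expect_error(buildLibrary(tl$cons, tl$sim$panel, subpop,
                              quotaPerSubpop = 2L),
                 "insufficient samples in subpopulation small")
})

test_that("coverage counts candidate haplotypes per position", {
    L <- 10000L
    seg <- do.call(rbind, lapply(1:13, function(i)
        data.frame(haplotype = sprintf("S%02d.hap%d", ceiling(i / 2),
                                       (i - 1) %% 2),
                   start = 2000L, end = 7000L, support = 10L)))
    cons <- makeConsensus(seg, L)
    panel <- makePanel(matrix(0L, 3, 14), c(1000L, 4000L, 8000L),
                       pops = rep("P", 7), chromLength = L)
    subpop <- setNames(rep("sub1", 7), sampleIds(panel))
    lib <- buildLibrary(cons, panel, subpop, quotaPerSubpop = 7L)
    cov <- coverageTrack(lib)
    expect_equal(cov$count[cov$start == 2000], 13L)
    expect_equal(cov$count[cov$start == 0], 0L)
    ## a donor haplotype with no consensus segments contributes nothing
    expect_false("S07.hap1" %in% segments2(lib)$haplotype)
})

test_that("coverage mask applies the at-least-12 rule exactly", {
    L <- 9000L
    mkSeg <- function(n, start, end) do.call(rbind, lapply(seq_len(n),
        function(i) data.frame(haplotype = sprintf("S%02d.hap%d",
                                                   ceiling(i / 2),
                                                   (i - 1) %% 2),
                               start = start, end = end, support = 10L)))
    ## [0,3000): 12 haplotypes; [3000,6000): 11; rest 0
    seg <- rbind(mkSeg(12, 0L, 3000L), mkSeg(11, 3000L, 6000L))
    cons <- makeConsensus(seg, L)
    panel <- makePanel(matrix(0L, 2, 24), c(100L, 5000L),
                       pops = rep("P", 12), chromLength = L)
    lib <- buildLibrary(cons, panel,
                        setNames(rep("sub1", 12), sampleIds(panel)),
                        quotaPerSubpop = 12L)
    mask <- coverageMask(lib, minCoverage = 12L)
    expect_equal(mask$start, 0L)
    expect_equal(mask$end, 3000L)                 # c = 11 stays masked
    maskAll <- coverageMask(lib, minCoverage = 0L)
    expect_equal(maskAll$end, L)                  # nothing masked
    ## default threshold is 20% of the library size
    expect_equal(attr(coverageMask(lib), "minCoverage"),
                 ceiling(0.2 * 24))
})

test_that("a single-donor library reproduces the donor on its segments", {
    cfg <- simConfig(nSamples = c(HM = 5L, Han = 5L), driftF = 0.2,
                     nAdmixed = 1L, otherPop = "Han", nSites = 300L,
                     chromLength = 3e5, g = 60L, missingRate = 0,
                     seed = 4)
    sim <- simulatePanel(cfg)
    cons <- consensusSegments(truthReplicates(sim$truth), "HM")
    seg <- segments2(cons)
    seg <- seg[seg$haplotype == "Yao01.hap0", , drop = FALSE]
    cons1 <- makeConsensus(seg, cfg$chromLength)
    lib <- buildLibrary(cons1, sim$panel,
                        setNames("Yao01", "Yao01"), quotaPerSubpop = 1L)
    lib@segments <- lib@segments[lib@segments$haplotype == "Yao01.hap0", ]
    rec <- assemblePanel(lib, nGenomes = 1L, minCoverage = 1L, seed = 6)
    got <- haplotypes(reconstructedPanel(rec))[, 1]
    donor <- haplotypes(sim$panel)[, "Yao01.hap0"]
    pos <- positions(sim$panel)
    inSeg <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(seg)))
        inSeg <- inSeg | (pos >= seg$start[i] & pos < seg$end[i])
    expect_identical(got[inSeg], donor[inSeg])
    expect_true(all(is.na(got[!inSeg])))
})

test_that("provenance chunks respect the 6 kb cap and allele fidelity holds", {
    tl <- truthLibrary(nSites = 800L, chromLength = 2e5, seed = 23)
    rec <- assemblePanel(tl$lib, nGenomes = 10L, seed = 31)
    pr <- provenance(rec)
    expect_true(all(pr$end - pr$start <= 6000))
    expect_true(all(pr$end > pr$start))
    ## every non-missing allele equals its provenance source allele
    hm <- haplotypes(reconstructedPanel(rec))
    src <- haplotypes(tl$lib@panel)
    pos <- positions(tl$lib@panel)
    for (k in sample(nrow(pr), 200)) {
        idx <- which(pos >= pr$start[k] & pos < pr$end[k])
        if (!length(idx)) next
        expect_identical(hm[idx, pr$haplotype[k]],
                         src[idx, pr$source[k]])
    }
})

test_that("an unbounded chunk cap stops only at segment or region ends", {
    tl <- truthLibrary(nAdmixed = 6L, quota = 2L, nSites = 300L,
                       chromLength = 3e5, seed = 9)
    rec <- assemblePanel(tl$lib, nGenomes = 2L, minCoverage = 1L,
                         maxChunk = .Machine$integer.max, seed = 2)
    pr <- provenance(rec)
    seg <- segments2(tl$lib)
    mask <- coverageMaskIntervals(rec)
    boundaries <- sort(unique(c(seg$end, mask$end)))
    expect_true(all(pr$end %in% boundaries))
})

test_that("assembly is reproducible from the master seed", {
    tl <- truthLibrary(nAdmixed = 9L, quota = 3L, nSites = 200L,
                       chromLength = 1e5, seed = 3)
    r1 <- assemblePanel(tl$lib, nGenomes = 4L, seed = 77)
    r2 <- assemblePanel(tl$lib, nGenomes = 4L, seed = 77)
    expect_identical(haplotypes(reconstructedPanel(r1)),
                     haplotypes(reconstructedPanel(r2)))
    expect_identical(provenance(r1), provenance(r2))
    r3 <- assemblePanel(tl$lib, nGenomes = 4L, seed = 78)
    expect_false(identical(provenance(r1), provenance(r3)))
})

test_that("30 genomes give 60 haplotypes with the mask emitted as missing", {
    tl <- truthLibrary(nSites = 400L, chromLength = 3e5, seed = 41)
    rec <- assemblePanel(tl$lib, nGenomes = 30L, seed = 5)
    expect_equal(nHaplotypes(rec), 60)
    hm <- haplotypes(reconstructedPanel(rec))
    pos <- positions(tl$sim$panel)
    mask <- coverageMaskIntervals(rec)
    inMask <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(mask)))
        inMask <- inMask | (pos >= mask$start[i] & pos < mask$end[i])
    ## donors are fully observed, so missing <=> below-coverage region
    expect_true(all(is.na(hm[!inMask, ])))
    expect_true(all(!is.na(hm[inMask, ])))
})

test_that("reconstructed genomes are unrelated by KING kinship", {
    ## At this simulated scale the per-pair KING estimator carries sampling
    ## noise of the same order as the third-degree cutoff (0.0442), which
    ## genome-scale site counts would average away; the check is that the
    ## panel-wide kinship sits below the third-degree cutoff and no pair
    ## reaches even second degree (0.0884).
    tl <- truthLibrary(nSites = 1500L, chromLength = 1e6, seed = 55)
    rec <- assemblePanel(tl$lib, nGenomes = 15L, seed = 19)
    hm <- haplotypes(reconstructedPanel(rec))
    geno <- hm[, seq(1, ncol(hm), 2)] + hm[, seq(2, ncol(hm), 2)]
    ok <- rowSums(is.na(geno)) == 0
    phi <- kinshipKing(geno[ok, , drop = FALSE])
    expect_lt(mean(phi, na.rm = TRUE), 0.0442)
    expect_lt(max(phi, na.rm = TRUE), 0.0884)
})

test_that("reconstruction enriches target ancestry over the donor baseline", {
    tl <- truthLibrary(nSites = 400L, chromLength = 4e5, seed = 67)
    rec <- assemblePanel(tl$lib, nGenomes = 10L, seed = 8)
    enr <- provenanceTargetFraction(rec, tl$sim$truth, "HM")
    base <- targetAncestryFraction(tl$sim$truth, "HM")
    expect_equal(enr, 1)       # consensus from truth: chunks are pure target
    expect_lt(base, 1)
})
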