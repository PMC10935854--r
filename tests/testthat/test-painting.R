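## Toy panel: donor pops A (samples 1-2) and B (3-4) with fixed opposite
## alleles, plus one query sample (5) identical to A.
fixedPanel <- function() {
    nS <- 40L
    hap <- cbind(matrix(1L, nS, 4), matrix(0L, nS, 4), matrix(1L, nS, 2))
    makePanel(hap, positions = seq(0, by = 1000, length.out = nS),
              pops = c("A", "A", "B", "B", "Q"), chromLength = 50000)
}

test_that("unambiguous emissions give a single tract of the matching donor", {
    panel <- fixedPanel()
    reps <- paintPanel(panel, "Q", c("A", "B"), lambda = 1e-6,
                       nReplicates = 3, seed = 1)
    for (r in reps) {
        tr <- tracts(r)
        expect_equal(nrow(tr), 2)            # one per query haplotype
        expect_true(all(tr$pop == "A"))
        expect_true(all(tr$start == 0 & tr$end == 50000))
    }
})

test_that("lambda = 0 forbids switches: exactly one tract per haplotype", {
    cfg <- simConfig(nSamples = c(HM = 8L, Han = 8L), driftF = 0.1,
                     nAdmixed = 4L, otherPop = "Han", nSites = 120L,
                     chromLength = 1e6, g = 200L, missingRate = 0,
                     seed = 5)
    sim <- simulatePanel(cfg)
    reps <- paintPanel(sim$panel, "Yao", c("HM", "Han"), lambda = 0,
                       nReplicates = 2, seed = 2)
    for (r in reps) {
        tr <- tracts(r)
        expect_equal(nrow(tr), length(unique(tr$haplotype)))
    }
})

test_that("posterior decoding matches an independent forward-backward oracle", {
    cfg <- simConfig(nSamples = c(HM = 10L, Han = 10L, Dai = 6L),
                     driftF = 0.2, nAdmixed = 2L, otherPop = "Han",
                     nSites = 200L, chromLength = 2e6, g = 300L,
                     missingRate = 0.05, seed = 21)
    sim <- simulatePanel(cfg)
    panel <- sim$panel
    qHap <- haplotypes(panel)[, "Yao01.hap0"]
    lambda <- 2e-6
    post <- paintPosterior(panel, qHap, c("HM", "Han", "Dai"),
                           lambda = lambda)
    donorFreq <- lapply(c("HM", "Han", "Dai"), function(p) {
        af <- popAlleleFreqs(panel, p)
        (af$freq * af$n + 1) / (af$n + 2)
    })
    oracle <- oracleHmmPosterior(qHap, donorFreq, positions(panel), lambda)
    expect_lt(max(abs(post - oracle)), 1e-10)
})

test_that("sampled replicates marginally agree with the posterior", {
    panel <- {
        set.seed(42)
        nS <- 60L
        fA <- runif(nS, 0.1, 0.9); fB <- runif(nS, 0.1, 0.9)
        hap <- cbind(matrix(rbinom(nS * 6, 1, fA), nS),
                     matrix(rbinom(nS * 6, 1, fB), nS),
                     matrix(rbinom(nS * 2, 1, (fA + fB) / 2), nS))
        makePanel(hap, seq(0, by = 5000, length.out = nS),
                  pops = c(rep("A", 3), rep("B", 3), "Q"),
                  chromLength = 3e5)
    }
    lambda <- 1e-6
    post <- paintPosterior(panel, haplotypes(panel)[, "S07.hap0"],
                           c("A", "B"), lambda = lambda)
    reps <- paintPanel(panel, "Q", c("A", "B"), lambda = lambda,
                       nReplicates = 200, seed = 9,
                       querySamples = "S07")
    ## per-site frequency of label A among sampled paths for hap0
    freqA <- rowMeans(vapply(reps, function(r) {
        tr <- tracts(r)
        tr <- tr[tr$haplotype == "S07.hap0" & tr$pop == "A", ,
                 drop = FALSE]
        pos <- positions(panel)
        inA <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(tr)))
            inA <- inA | (pos >= tr$start[i] & pos < tr$end[i])
        inA
    }, logical(nSites(panel))))
    expect_lt(mean(abs(freqA - post[, "A"])), 0.035)
})

test_that("painting accuracy increases with population differentiation", {
    acc <- vapply(c(0.01, 0.1, 0.3), function(F) {
        cfg <- simConfig(nSamples = c(HM = 12L, Han = 12L), driftF = F,
                         nAdmixed = 3L, otherPop = "Han", nSites = 250L,
                         chromLength = 4e6, g = 150L, missingRate = 0,
                         seed = 31)
        sim <- simulatePanel(cfg)
        pos <- positions(sim$panel)
        trueLab <- function(h) {
            tr <- tracts(sim$truth)
            tr <- tr[tr$haplotype == h, ]
            tr$pop[findInterval(pos, tr$start)]
        }
        haps <- paste0("Yao0", 1:3, ".hap0")
        mean(vapply(haps, function(h) {
            post <- paintPosterior(sim$panel, haplotypes(sim$panel)[, h],
                                   c("HM", "Han"), lambda = 5e-7)
            call <- colnames(post)[max.col(post)]
            mean(call == trueLab(h))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(acc) > 0))
})

test_that("consensus applies the at-least-half support rule per position", {
    L <- 10000L
    mkRep <- function(r, hmEnd) {
        tr <- data.frame(haplotype = "q.hap0",
                         start = c(0L, hmEnd), end = c(hmEnd, L),
                         pop = c("HM", "Han"))
        asPaintingReplicate(TractSet(tr, L), r)
    }
    ## positions < 4000 supported by 10/10; [4000, 6000) by 5/10;
    ## [6000, 8000) by 4/10
    reps <- c(lapply(1:4, mkRep, hmEnd = 4000L),
              lapply(5:5, mkRep, hmEnd = 4000L),
              lapply(6:9, mkRep, hmEnd = 8000L),
              lapply(10:10, mkRep, hmEnd = 6000L))
    cons <- consensusSegments(reps, "HM", minSupport = 5L)
    seg <- segments2(cons)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$start, 0)
    expect_equal(seg$end, 6000)      # 5/10 in, 4/10 out
    expect_equal(seg$support, 5)

    ## unanimity: consensus equals any single replicate's target tracts
    uni <- consensusSegments(lapply(1:10, mkRep, hmEnd = 4000L), "HM")
    expect_equal(segments2(uni)$end, 4000)
    expect_equal(segments2(uni)$support, 10)
})

test_that("consensus is monotone in an all-target replicate", {
    L <- 50000L
    set.seed(8)
    mkRandRep <- function(r) {
        cuts <- sort(sample(1000:49000, 3))
        tr <- data.frame(haplotype = "q.hap0",
                         start = c(0L, cuts), end = c(cuts, L),
                         pop = sample(c("HM", "Han"), 4, replace = TRUE))
        tr <- tr[tr$start < tr$end, ]
        asPaintingReplicate(TractSet(tr, L), r)
    }
    reps <- lapply(1:9, mkRandRep)
    allTarget <- asPaintingReplicate(TractSet(
        data.frame(haplotype = "q.hap0", start = 0L, end = L, pop = "HM"),
        L), 10L)
    base <- segments2(consensusSegments(reps, "HM", minSupport = 5L))
    grown <- segments2(consensusSegments(c(reps, list(allTarget)), "HM",
                                         minSupport = 5L))
    ## every base interval is contained in some grown interval
    for (i in seq_len(nrow(base))) {
        covered <- any(grown$start <= base$start[i] &
                       grown$end >= base$end[i])
        expect_true(covered)
    }
})

test_that("replicates over different haplotype sets are rejected", {
    L <- 1000L
    r1 <- asPaintingReplicate(TractSet(
        data.frame(haplotype = "a.hap0", start = 0L, end = L, pop = "HM"),
        L), 1L)
    r2 <- asPaintingReplicate(TractSet(
        data.frame(haplotype = "b.hap0", start = 0L, end = L, pop = "HM"),
        L), 2L)
    expect_error(consensusSegments(list(r1, r2), "HM"),
                 "different haplotype sets")
})
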