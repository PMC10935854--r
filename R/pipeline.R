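#' Pipeline configuration
#'
#' Bundles every stage parameter of the synthetic end-to-end run with the
#' method's canonical defaults: 10 painting replicates reduced at 5-of-10
#' support, a 6000 bp chunk cap, the 20\%-of-library coverage rule, 9-sample
#' x 100-replicate balanced FST, top 0.1\% / 1\% screen quantiles, a 0.3
#' gradient frequency difference, a 20\% polarizing MAF cap, and a 3 SD Ne
#' divergence threshold.
#'
#' @param sim a \code{\link{simConfig}} describing the synthetic panel.
#' @param nReplicates painting replicates.
#' @param minSupport consensus support threshold.
#' @param lambda painting switch rate per bp.
#' @param nSubpops admixed samples are split into this many library
#'   subpopulations (emulating several present-day descendant populations).
#' @param nGenomes reconstructed diploid genomes.
#' @param maxChunk assembly chunk cap (bp).
#' @param minCoverage coverage threshold; NULL = 20\% rule.
#' @param subset,reps balanced-FST subsample size and replicate count.
#' @param q1,q2 top-FST quantiles (primary, relaxed).
#' @param minDiff gradient-screen frequency difference.
#' @param mafMax polarizing MAF cap.
#' @param kSd Ne-divergence threshold (SD units).
#' @param seed master seed for the painting/assembly/statistics stages.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), nReplicates = 10L,
                           minSupport = 5L, lambda = 1e-6, nSubpops = 3L,
                           nGenomes = 30L, maxChunk = 6000L,
                           minCoverage = NULL, subset = 9L, reps = 100L,
                           q1 = 0.001, q2 = 0.01, minDiff = 0.3,
                           mafMax = 0.20, kSd = 3, seed = 1L) {
    structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order on a simulated panel with known
#' ancestry tracts: simulate, paint (R replicates), consensus, candidate
#' library, mosaic reconstruction, balanced FST, outgroup f3 ranking of the
#' reconstructed panel, and the differentiation screens. Per-stage counts
#' are collected in a log; the same config and seed give identical results.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, the panel VCFs, truth and
#'   provenance BEDs and the screen report TSV are written there.
#' @return list with elements sim, replicates, consensus, library,
#'   reconstructed, fst, f3rank, screen, enrichment, log.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "pipelineConfig"))
    log <- list()
    sim <- simulatePanel(config$sim)
    cfg <- config$sim
    log$sites <- nSites(sim$panel)
    admSamples <- samplesOfPop(sim$panel, cfg$admixedPop)

    donors <- setdiff(names(cfg$nSamples), "Mbuti")
    replicates <- paintPanel(sim$panel, queryPop = cfg$admixedPop,
                             donors = donors, lambda = config$lambda,
                             nReplicates = config$nReplicates,
                             seed = config$seed)
    cons <- consensusSegments(replicates, targetLabel = cfg$targetPop,
                              minSupport = config$minSupport)
    log$consensusSegments <- nrow(segments2(cons))

    subpop <- setNames(paste0(cfg$admixedPop,
                              rep(seq_len(config$nSubpops),
                                  length.out = length(admSamples))),
                       admSamples)
    quota <- min(table(subpop))
    lib <- buildLibrary(cons, sim$panel, subpop, quotaPerSubpop = quota)
    log$libraryHaplotypes <- length(lib@haplotypeIds)

    recon <- assemblePanel(lib, nGenomes = config$nGenomes,
                           maxChunk = config$maxChunk,
                           minCoverage = config$minCoverage,
                           seed = config$seed + 1L)
    log$reconstructableBp <- sum(recon@mask$end - recon@mask$start)

    fst <- pairwiseFstBalanced(sim$panel, cfg$admixedPop, cfg$otherPop,
                               subset = config$subset, reps = config$reps,
                               seed = config$seed + 2L)

    ## drift sharing of the reconstructed panel with the source populations
    pO <- popAlleleFreqs(sim$panel, "Mbuti")$freq
    aF <- alleleFreqs(reconstructedPanel(recon),
                      reconstructedPanel(recon)@samples)
    refs <- sapply(donors, function(p) popAlleleFreqs(sim$panel, p)$freq)
    f3rank <- rankByDrift(pO, aF$freq, refs, positions(sim$panel),
                          minSites = 50L, blockSize = 1e6)

    groups <- c(list(Han = samplesOfPop(sim$panel, cfg$otherPop)),
                split(names(subpop), subpop))
    screen <- screenReport(sim$panel, recon, groups,
                           refPop = cfg$otherPop,
                           targetPops = cfg$admixedPop,
                           q1 = config$q1, q2 = config$q2,
                           minDiff = config$minDiff)
    log$sitesRetained <- sum(screen$retained)
    log$extraSnvs <- sum(screen$extraSnv, na.rm = TRUE)

    enrichment <- list(
        reconstructed = provenanceTargetFraction(recon, sim$truth,
                                                 cfg$targetPop),
        baseline = targetAncestryFraction(sim$truth, cfg$targetPop))

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writePanelVcf(sim$panel, file.path(outDir, "panel.vcf"))
        writePanelVcf(reconstructedPanel(recon),
                      file.path(outDir, "reconstructed.vcf"))
        writeTractsBed(sim$truth, file.path(outDir, "truth_tracts.bed"))
        prov <- provenance(recon)
        write.table(prov, file.path(outDir, "provenance.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(screen, file.path(outDir, "screen_report.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(sim = sim, replicates = replicates, consensus = cons,
         library = lib, reconstructed = recon, fst = fst,
         f3rank = f3rank, screen = screen, enrichment = enrichment,
         log = log)
}
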