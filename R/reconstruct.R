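#' Build the balanced candidate haplotype library
#'
#' Restricts the consensus target-ancestry segments to a balanced donor set
#' (a fixed quota of samples per subpopulation; with the defaults of three
#' subpopulations of 10 samples this yields a 60-haplotype library) and
#' computes the per-base coverage track c(x): how many candidate haplotypes
#' carry a consensus segment over each position.
#'
#' @param consensus a \linkS4class{ConsensusSegments} over candidate donor
#'   haplotypes.
#' @param panel the \linkS4class{HaplotypePanel} holding the donor alleles.
#' @param subpopOf named character vector mapping donor sample ID to
#'   subpopulation.
#' @param quotaPerSubpop samples retained per subpopulation.
#' @param selection optional explicit sample selection (must respect the
#'   quota); default is deterministic lexicographic order per subpopulation.
#' @return A \linkS4class{CandidateLibrary}.
#' @export
buildLibrary <- function(consensus, panel, subpopOf, quotaPerSubpop = 10L,
                         selection = NULL) {
    stopifnot(is(consensus, "ConsensusSegments"))
    if (is.null(names(subpopOf)))
        stop("subpopOf must be a named sample -> subpopulation vector")
    if (is.null(selection)) {
        selection <- unlist(lapply(split(names(subpopOf), subpopOf),
            function(smp) {
                smp <- sort(smp)
                if (length(smp) < quotaPerSubpop)
                    stop("insufficient samples in subpopulation ",
                         subpopOf[[smp[1]]], ": have ", length(smp),
                         ", need ", quotaPerSubpop)
                smp[seq_len(quotaPerSubpop)]
            }), use.names = FALSE)
    } else {
        tab <- table(subpopOf[selection])
        if (any(tab != quotaPerSubpop))
            stop("selection does not meet the per-subpopulation quota")
    }
    hapIds <- haplotypeNames(selection)
    seg <- segments2(consensus)
    seg <- seg[seg$haplotype %in% hapIds, , drop = FALSE]
    L <- consensus@chromLength
    cov <- IRanges::coverage(toIRanges(seg$start, seg$end), width = L)
    covDf <- data.frame(
        end = cumsum(S4Vectors::runLength(cov)),
        count = as.integer(S4Vectors::runValue(cov)))
    covDf$start <- c(0L, covDf$end[-nrow(covDf)])
    covDf <- covDf[, c("start", "end", "count")]
    new("CandidateLibrary",
        segments = seg[, c("haplotype", "start", "end")],
        haplotypeIds = hapIds,
        subpopOf = subpopOf[selection],
        panel = subsetSamples(panel, selection),
        coverage = covDf)
}

## Panel restricted to a set of samples (keeps all sites).
subsetSamples <- function(panel, samples) {
    idx <- match(samples, panel@samples)
    HaplotypePanel(panel@haplotypes[, hapColumns(panel, samples),
                                    drop = FALSE],
                   panel@positions, samples, panel@populations[idx],
                   chrom = panel@chrom, chromLength = panel@chromLength)
}

#' Reconstructable regions under the minimum-coverage rule
#'
#' Positions covered by at least \code{minCoverage} candidate haplotypes are
#' reconstructable; the rest are masked and emitted as missing. The default
#' threshold is 20\% of the library size (12 for a 60-haplotype library).
#'
#' @param library a \linkS4class{CandidateLibrary}.
#' @param minCoverage coverage threshold; default
#'   \code{ceiling(0.2 * nHaplotypes)}.
#' @return data.frame of reconstructable intervals (start, end; 0-based
#'   half-open), merged and sorted.
#' @export
coverageMask <- function(library, minCoverage = NULL) {
    if (is.null(minCoverage))
        minCoverage <- as.integer(ceiling(0.2 *
            length(library@haplotypeIds)))
    cov <- library@coverage
    keep <- cov[cov$count >= minCoverage, , drop = FALSE]
    if (!nrow(keep))
        return(structure(data.frame(start = integer(), end = integer()),
                         minCoverage = as.integer(minCoverage)))
    merged <- fromIRanges(IRanges::reduce(toIRanges(keep$start, keep$end)))
    structure(merged, minCoverage = as.integer(minCoverage))
}

## Assemble one mosaic haplotype. At each junction a candidate whose
## consensus segment covers the junction is drawn uniformly at random,
## excluding the immediately preceding source when an alternative exists;
## copying extends to min(junction + maxChunk, segment end, region end).
## Returns the provenance chunk list; alleles are filled in by the caller.
assembleChunks <- function(seg, mask, maxChunk) {
    maxChunk <- as.numeric(maxChunk)    # avoid integer overflow at x + cap
    chunks <- vector("list", 64L); nc <- 0L
    for (i in seq_len(nrow(mask))) {
        x <- as.numeric(mask$start[i]); re <- mask$end[i]
        prev <- NA_character_
        while (x < re) {
            rows <- which(seg$start <= x & seg$end > x)
            if (!length(rows))
                stop("no candidate haplotype covers position ", x,
                     "; lower minCoverage or rebuild the mask")
            if (length(rows) > 1L && !is.na(prev)) {
                alt <- rows[seg$haplotype[rows] != prev]
                if (length(alt)) rows <- alt
            }
            pick <- rows[sample.int(length(rows), 1L)]
            endx <- min(x + maxChunk, seg$end[pick], re)
            nc <- nc + 1L
            if (nc > length(chunks))
                chunks <- c(chunks, vector("list", length(chunks)))
            chunks[[nc]] <- c(x, endx, pick)
            prev <- seg$haplotype[pick]
            x <- endx
        }
    }
    m <- do.call(rbind, chunks[seq_len(nc)])
    data.frame(source = seg$haplotype[m[, 3]], start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
}

#' Assemble a panel of mosaic ancestral-proxy genomes
#'
#' Each haplotype is assembled left to right across every reconstructable
#' region: starting at the region edge (and subsequently at each chunk end),
#' a candidate haplotype covering the junction is chosen uniformly at
#' random — never the immediately preceding source when an alternative
#' covers the junction — and its alleles are copied for at most
#' \code{maxChunk} bp, stopping early at the end of that candidate's
#' consensus segment or of the region. Haplotypes are assembled under
#' independent child seeds of \code{seed} (the library is reused freely
#' across haplotypes) and paired sequentially into diploid genomes. Masked
#' regions are emitted as missing.
#'
#' @param library a \linkS4class{CandidateLibrary}.
#' @param nGenomes number of diploid genomes to assemble (2 haplotypes
#'   each).
#' @param maxChunk chunk-length cap in bp.
#' @param minCoverage coverage threshold for the mask; default the 20\% rule
#'   of \code{\link{coverageMask}}.
#' @param seed master seed.
#' @param prefix sample-name prefix for the reconstructed genomes.
#' @return A \linkS4class{ReconstructedPanel}.
#' @export
assemblePanel <- function(library, nGenomes = 30L, maxChunk = 6000L,
                          minCoverage = NULL, seed = 1L, prefix = "aHM") {
    stopifnot(is(library, "CandidateLibrary"))
    if (!length(library@haplotypeIds) || !nrow(library@segments))
        stop("empty candidate library")
    mask <- coverageMask(library, minCoverage)
    minCoverage <- attr(mask, "minCoverage")
    if (!nrow(mask))
        stop("no reconstructable region at coverage >= ", minCoverage)
    pos <- library@panel@positions
    hapMat <- library@panel@haplotypes
    nHap <- 2L * nGenomes
    seeds <- childSeeds(seed, nHap)
    samples <- sprintf("%s%02d", prefix, seq_len(nGenomes))
    hapNames <- haplotypeNames(samples)
    out <- matrix(NA_integer_, nrow = length(pos), ncol = nHap)
    prov <- vector("list", nHap)
    for (j in seq_len(nHap)) {
        chunks <- withSeed(seeds[j],
            assembleChunks(library@segments, mask, maxChunk))
        srcCol <- match(chunks$source, colnames(hapMat))
        lo <- findInterval(chunks$start - 1L, pos) + 1L
        hi <- findInterval(chunks$end - 1L, pos)
        for (k in seq_len(nrow(chunks))) {
            if (lo[k] > hi[k]) next      # chunk spans no site
            idx <- lo[k]:hi[k]
            out[idx, j] <- hapMat[idx, srcCol[k]]
        }
        chunks$haplotype <- hapNames[j]
        prov[[j]] <- chunks[, c("haplotype", "source", "start", "end")]
    }
    panel <- HaplotypePanel(out, pos, samples,
                            rep(prefix, nGenomes),
                            chrom = library@panel@chrom,
                            chromLength = library@panel@chromLength)
    new("ReconstructedPanel", panel = panel,
        provenance = do.call(rbind, prov),
        mask = as.data.frame(mask), minCoverage = minCoverage,
        maxChunk = as.integer(maxChunk))
}

#' Fraction of reconstructed bases drawn from true target-ancestry tracts
#'
#' End-to-end quality measure on synthetic data: for every provenance chunk,
#' the bases whose source haplotype position lies inside a true
#' target-ancestry tract are counted, and the total is divided by the
#' reconstructed base count.
#'
#' @param reconstructed a \linkS4class{ReconstructedPanel}.
#' @param truth the \linkS4class{TractSet} of true ancestry tracts for the
#'   donor haplotypes.
#' @param targetPop target-ancestry label in \code{truth}.
#' @return proportion in [0, 1].
#' @export
provenanceTargetFraction <- function(reconstructed, truth, targetPop) {
    pr <- provenance(reconstructed)
    tr <- tracts(truth)
    tr <- tr[tr$pop == targetPop, , drop = FALSE]
    total <- sum(pr$end - pr$start)
    hit <- 0
    for (h in unique(pr$source)) {
        p <- pr[pr$source == h, , drop = FALSE]
        t <- tr[tr$haplotype == h, , drop = FALSE]
        if (!nrow(t)) next
        ## per-chunk overlap (chunks may repeat a source, so do not merge)
        ov <- IRanges::findOverlaps(toIRanges(p$start, p$end),
                                    toIRanges(t$start, t$end))
        qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        hit <- hit + sum(pmin(p$end[qi], t$end[si]) -
                         pmax(p$start[qi], t$start[si]))
    }
    hit / total
}
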