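#' Filter sites by per-group missing rate
#'
#' A site survives only if its genotype missing rate is at most
#' \code{maxRate} in every group — the screens' joint missingness filter
#' (default 10\%).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param groups named list mapping group name to diploid sample IDs.
#' @param maxRate maximum tolerated per-group missing rate.
#' @return logical vector over sites (TRUE = retained).
#' @export
filterByMissingness <- function(panel, groups, maxRate = 0.10) {
    stopifnot(is.list(groups), length(groups) >= 1L)
    keep <- rep(TRUE, nSites(panel))
    for (g in names(groups)) {
        smp <- groups[[g]]
        if (!length(smp)) stop("empty group: ", g)
        h <- panel@haplotypes[, hapColumns(panel, smp), drop = FALSE]
        ## both alleles of a genotype are missing together; count genotypes
        missRate <- rowSums(is.na(h[, seq(1, ncol(h), 2), drop = FALSE])) /
            length(smp)
        keep <- keep & missRate <= maxRate
    }
    keep
}

#' Top-quantile FST selection screen
#'
#' Flags the sites in the top \code{quantile} tail of the per-site FST
#' distribution: the threshold is the k-th largest value with
#' \code{k = floor(quantile * n)}, and all ties at the threshold are
#' included. With fewer than \code{1/quantile} sites the screen warns and
#' returns nothing.
#'
#' @param fst per-site FST values (NA allowed; never flagged).
#' @param quantile upper tail mass, e.g. 0.001 for the top 0.1\%.
#' @return logical vector over sites.
#' @export
topFstScreen <- function(fst, quantile = 0.001) {
    n <- sum(!is.na(fst))
    k <- floor(quantile * n)
    if (k < 1L) {
        warning("fewer than 1/quantile usable sites; nothing flagged")
        return(rep(FALSE, length(fst)))
    }
    thr <- sort(fst, decreasing = TRUE)[k]
    !is.na(fst) & fst >= thr
}

#' Extra SNVs unmasked by the reconstructed ancestral panel
#'
#' Sites in the top \code{q1} (default 0.1\%) of the ancestral-vs-reference
#' FST track but outside the top \code{q2} (default 1\%) of the present-day
#' vs-reference track: differentiation signals diluted in the present-day
#' population by recent gene flow and only visible against the
#' reconstructed gene pool.
#'
#' @param fstAncestral,fstPresent per-site FST tracks over the same sites.
#' @param q1 upper tail for the ancestral track.
#' @param q2 upper tail for the present-day track.
#' @return logical vector over sites.
#' @export
extraSnvs <- function(fstAncestral, fstPresent, q1 = 0.001, q2 = 0.01) {
    if (length(fstAncestral) != length(fstPresent))
        stop("FST tracks must cover the same site universe")
    topFstScreen(fstAncestral, q1) & !topFstScreen(fstPresent, q2)
}

#' Three-criterion gradient screen for population-specific adaptive alleles
#'
#' A site is flagged iff (i) the reference (Han) allele frequency is fixed
#' (0 or 1, within \code{fixedTol}); (ii) the ancestral-vs-reference
#' frequency difference is at least \code{minDiff}; and (iii) the
#' frequencies are ordered monotonically ancestral -> present-day ->
#' reference (non-strict), so the candidate allele exists only in the
#' target populations and decays toward the reference. Sites missing a
#' frequency in any panel are excluded; their count is attached as
#' attribute \code{nExcluded}.
#'
#' @param pHan,pHM,pAHM alternate-allele frequencies in the reference,
#'   present-day target, and reconstructed ancestral panels.
#' @param minDiff minimum ancestral-vs-reference frequency difference.
#' @param fixedTol tolerance for "fixed" in the reference (default exact).
#' @return logical vector over sites with attribute \code{nExcluded}.
#' @export
gradientScreen <- function(pHan, pHM, pAHM, minDiff = 0.3, fixedTol = 0) {
    excluded <- is.na(pHan) | is.na(pHM) | is.na(pAHM)
    fixed <- pHan <= fixedTol | pHan >= 1 - fixedTol
    diffOk <- abs(pAHM - pHan) >= minDiff
    mono <- (pAHM >= pHM & pHM >= pHan) | (pAHM <= pHM & pHM <= pHan)
    flag <- !excluded & fixed & diffOk & mono
    flag[is.na(flag)] <- FALSE
    structure(flag, nExcluded = sum(excluded))
}

#' Per-variant screen report
#'
#' Runs the missingness filter and the three differentiation screens over a
#' shared site universe and assembles the per-variant report: group
#' frequencies, FST tracks, and the screen flags
#' (top-FST present-day, top-FST ancestral, extra SNV, gradient hit).
#'
#' @param panel present-day \linkS4class{HaplotypePanel} (reference +
#'   target populations).
#' @param ancestral a \linkS4class{ReconstructedPanel} or
#'   \linkS4class{HaplotypePanel} of reconstructed genomes.
#' @param groups named list of missingness groups (sample IDs).
#' @param refPop reference population label (e.g. Han).
#' @param targetPops present-day target population label(s), pooled.
#' @param maxMissing per-group missing-rate cap.
#' @param q1,q2 top-FST quantiles (primary / relaxed).
#' @param minDiff gradient-screen frequency-difference threshold.
#' @return data.frame: position, frequencies, FST tracks, flags; filtered
#'   sites carry NA statistics and FALSE flags.
#' @export
screenReport <- function(panel, ancestral, groups, refPop = "Han",
                         targetPops, maxMissing = 0.10, q1 = 0.001,
                         q2 = 0.01, minDiff = 0.3) {
    aPanel <- if (is(ancestral, "ReconstructedPanel"))
        reconstructedPanel(ancestral) else ancestral
    if (!identical(aPanel@positions, panel@positions))
        stop("ancestral and present-day panels must share the site set")
    keep <- filterByMissingness(panel, groups, maxMissing)
    fRef <- alleleFreqs(panel, samplesOfPop(panel, refPop))
    fHM <- alleleFreqs(panel,
        unlist(lapply(targetPops, samplesOfPop, panel = panel)))
    fA <- alleleFreqs(aPanel, aPanel@samples)
    fstHM <- siteFst(fHM$freq, fRef$freq, fHM$n, fRef$n)$fst
    fstA <- siteFst(fA$freq, fRef$freq, fA$n, fRef$n)$fst
    fstHM[!keep] <- NA; fstA[!keep] <- NA
    ## sites masked in the reconstruction are ineligible for its screens
    fstA[fA$n == 0] <- NA
    topHM <- topFstScreen(fstHM, q1)
    topA <- topFstScreen(fstA, q1)
    extra <- topA & !topFstScreen(fstHM, q2)
    pH <- fRef$freq; pM <- fHM$freq; pA <- fA$freq
    pH[!keep] <- NA; pM[!keep] <- NA; pA[!keep] <- NA
    grad <- gradientScreen(pH, pM, pA, minDiff = minDiff)
    data.frame(position = panel@positions, retained = keep,
               freqRef = pH, freqTarget = pM, freqAncestral = pA,
               fstTargetRef = fstHM, fstAncestralRef = fstA,
               topFstTarget = topHM, topFstAncestral = topA,
               extraSnv = extra, gradientHit = as.vector(grad))
}
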