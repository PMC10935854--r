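#' Hudson per-site FST
#'
#' The Hudson estimator from allele frequencies and allele counts:
#' numerator \eqn{(p_A - p_B)^2 - p_A(1-p_A)/(n_A-1) - p_B(1-p_B)/(n_B-1)},
#' denominator \eqn{p_A(1-p_B) + p_B(1-p_A)}. Sites with fewer than two
#' observed alleles in either population are excluded (NA). Negative
#' per-site values are retained: they belong in ratio-of-sums genome-wide
#' estimates.
#'
#' @param pA,pB alternate-allele frequencies per site.
#' @param nA,nB observed allele counts per site.
#' @return list: \code{fst} per-site value (numerator/denominator, NA where
#'   excluded or the denominator is 0), \code{num}, \code{den}.
#' @export
siteFst <- function(pA, pB, nA, nB) {
    ok <- !is.na(pA) & !is.na(pB) & nA >= 2 & nB >= 2
    num <- den <- rep(NA_real_, length(pA))
    num[ok] <- (pA[ok] - pB[ok])^2 -
        pA[ok] * (1 - pA[ok]) / (nA[ok] - 1) -
        pB[ok] * (1 - pB[ok]) / (nB[ok] - 1)
    den[ok] <- pA[ok] * (1 - pB[ok]) + pB[ok] * (1 - pA[ok])
    list(fst = ifelse(!is.na(den) & den > 0, num / den, NA_real_),
         num = num, den = den)
}

#' Genome-wide Hudson FST (ratio of sums)
#'
#' @inheritParams siteFst
#' @param clamp clamp the reported value at 0 (negative estimates arise by
#'   sampling noise when the true differentiation is ~0).
#' @return single FST value.
#' @export
genomeFst <- function(pA, pB, nA, nB, clamp = TRUE) {
    s <- siteFst(pA, pB, nA, nB)
    v <- sum(s$num, na.rm = TRUE) / sum(s$den, na.rm = TRUE)
    if (clamp) max(0, v) else v
}

#' Balanced pairwise FST by repeated equal-size subsampling
#'
#' To remove sample-size bias, each of \code{reps} replicates draws
#' \code{subset} samples per population without replacement and computes the
#' genome-wide Hudson FST from the subsets; the defaults (9 samples, 100
#' replicates) match a design balanced to the smallest population.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param popA,popB population labels.
#' @param subset samples drawn per population per replicate.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return list: \code{replicates} (raw, unclamped per-replicate values),
#'   \code{mean}, \code{sd}, and \code{fst} (mean clamped at 0).
#' @export
pairwiseFstBalanced <- function(panel, popA, popB, subset = 9L,
                                reps = 100L, seed = 1L) {
    sA <- sort(samplesOfPop(panel, popA))
    sB <- sort(samplesOfPop(panel, popB))
    if (length(sA) < subset || length(sB) < subset)
        stop("need at least ", subset, " samples per population")
    vals <- withSeed(seed, vapply(seq_len(reps), function(r) {
        fa <- alleleFreqs(panel, sample(sA, subset))
        fb <- alleleFreqs(panel, sample(sB, subset))
        genomeFst(fa$freq, fb$freq, fa$n, fb$n, clamp = FALSE)
    }, numeric(1)))
    list(popA = popA, popB = popB, replicates = vals,
         mean = mean(vals), sd = sd(vals), fst = max(0, mean(vals)))
}

#' Relative difference of genomic affinity
#'
#' \deqn{RD(A,B;X) = \frac{F_{ST}(A,X) - F_{ST}(B,X)}
#'                        {F_{ST}(A,X) + F_{ST}(B,X)}}
#' A positive value means X is genetically closer to B (more recent
#' communication with B); a negative value means closer to A. Undefined
#' (returned as NA) when the denominator is not positive.
#'
#' @param fstAX,fstBX FST of the test population X with targets A and B.
#' @return the relative difference in [-1, 1] for nonnegative inputs.
#' @export
relativeDifference <- function(fstAX, fstBX) {
    den <- fstAX + fstBX
    ifelse(is.na(den) | den <= 0, NA_real_, (fstAX - fstBX) / den)
}

#' Outgroup f3 statistic with block jackknife
#'
#' Shared genetic drift between A and B relative to outgroup O:
#' the mean over sites of \eqn{(p_O - p_A)(p_O - p_B)}. The standard error
#' comes from a leave-one-block-out jackknife over physical blocks
#' (default 5 Mb).
#'
#' @param pO,pA,pB allele frequencies per site (NA = missing; such sites are
#'   dropped).
#' @param pos physical positions (bp) for block assignment.
#' @param blockSize jackknife block size in bp.
#' @return list: \code{f3}, \code{se} (NA when fewer than 2 non-empty
#'   blocks), \code{nSites}, \code{nBlocks}.
#' @export
f3Outgroup <- function(pO, pA, pB, pos, blockSize = 5e6) {
    ok <- !is.na(pO) & !is.na(pA) & !is.na(pB)
    if (!any(ok)) stop("no usable sites for f3")
    x <- (pO[ok] - pA[ok]) * (pO[ok] - pB[ok])
    blk <- floor(pos[ok] / blockSize)
    f3 <- mean(x)
    blocks <- split(x, blk)
    B <- length(blocks)
    se <- NA_real_
    if (B >= 2) {
        tot <- sum(x); n <- length(x)
        loo <- vapply(blocks, function(b)
            (tot - sum(b)) / (n - length(b)), numeric(1))
        se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
    }
    list(f3 = f3, se = se, nSites = sum(ok), nBlocks = B)
}

#' Rank reference populations by shared drift with a query
#'
#' Computes outgroup f3(O; query, ref) against every reference frequency
#' track and ranks references by decreasing f3 — the drift-sharing ranking
#' used to attach sparse (e.g. ancient) samples to their closest reference.
#' References with fewer than \code{minSites} jointly observed sites are
#' flagged and excluded from the ranking. Ties break lexicographically.
#'
#' @param pO outgroup frequencies per site.
#' @param pQuery query frequencies per site (NA = unobserved).
#' @param refFreqs matrix of reference frequencies, sites x references
#'   (column names = reference labels).
#' @param pos physical positions for the jackknife.
#' @param minSites minimum jointly observed site count per reference.
#' @param blockSize jackknife block size in bp.
#' @return data.frame ranked by f3: reference, f3, se, nSites, flagged;
#'   flagged references (insufficient sites) sort last with NA f3.
#' @export
rankByDrift <- function(pO, pQuery, refFreqs, pos, minSites = 100L,
                        blockSize = 5e6) {
    refs <- colnames(refFreqs)
    res <- lapply(refs, function(r) {
        ok <- !is.na(pO) & !is.na(pQuery) & !is.na(refFreqs[, r])
        if (sum(ok) < minSites)
            return(data.frame(reference = r, f3 = NA_real_,
                              se = NA_real_, nSites = sum(ok),
                              flagged = TRUE))
        f <- f3Outgroup(pO, pQuery, refFreqs[, r], pos, blockSize)
        data.frame(reference = r, f3 = f$f3, se = f$se,
                   nSites = f$nSites, flagged = FALSE)
    })
    res <- do.call(rbind, res)
    res[order(res$flagged, -ifelse(is.na(res$f3), -Inf, res$f3),
              res$reference), , drop = FALSE]
}
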