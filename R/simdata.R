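#' Simulation configuration
#'
#' Parameters of the synthetic study design: several drifted source
#' populations (Balding-Nichols model around shared ancestral frequencies),
#' one of which is the target ancestry, plus an admixed population whose
#' haplotypes are single-pulse mosaics of target and non-target ancestry with
#' exponential tract lengths. The defaults emulate a minority-population
#' resequencing design: a drifted target gene pool (\code{HM}), a large
#' reference population (\code{Han}) exchanging recent migrants with it, a
#' smaller outlying reference (\code{Dai}), and an admixed present-day
#' population (\code{Yao}) carrying target-ancestry tracts.
#'
#' @param nSamples named integer vector of diploid sample counts per source
#'   population; the first name is the target ancestry.
#' @param nAdmixed number of admixed diploid samples.
#' @param admixedPop label for the admixed population.
#' @param otherPop the non-target source of the admixed pulse (must be a
#'   source population).
#' @param driftF per-population Balding-Nichols drift parameter in [0,1);
#'   recycled across source populations.
#' @param nSites number of biallelic sites (>= 1).
#' @param chromLength chromosome length in bp (> nSites).
#' @param m admixture proportion of target ancestry in [0,1].
#' @param g generations since the admixture pulse (positive).
#' @param recombRate recombination rate per bp per generation.
#' @param missingRate i.i.d. per-genotype missingness probability in [0,1).
#' @param ancestralFreqRange range of the uniform ancestral frequency draw.
#' @param seed integer seed; identical configs give identical output.
#' @return A validated list of class \code{simConfig}.
#' @export
simConfig <- function(nSamples = c(HM = 30L, Han = 40L, Dai = 10L,
                                   Mbuti = 10L),
                      nAdmixed = 30L, admixedPop = "Yao", otherPop = "Han",
                      driftF = c(0.2, 0.2, 0.2, 0.6), nSites = 2000L,
                      chromLength = 1e7,
                      m = 0.5, g = 100L, recombRate = 1e-8,
                      missingRate = 0.02, ancestralFreqRange = c(0.05, 0.95),
                      seed = 1L) {
    if (is.null(names(nSamples)) || any(!nzchar(names(nSamples))))
        stop("nSamples must be a named vector of source populations")
    driftF <- rep_len(driftF, length(nSamples))
    if (any(driftF < 0) || any(driftF >= 1))
        stop("driftF must lie in [0, 1)")
    if (m < 0 || m > 1) stop("admixture proportion m must lie in [0, 1]")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    if (nSites < 1) stop("nSites must be >= 1")
    if (chromLength <= nSites) stop("chromLength must exceed nSites")
    if (g < 1) stop("admixture age g must be a positive integer")
    if (!otherPop %in% names(nSamples))
        stop("otherPop must be one of the source populations")
    if (admixedPop %in% names(nSamples))
        stop("admixedPop label collides with a source population")
    structure(list(nSamples = as.integer(nSamples) |>
                       setNames(names(nSamples)),
                   nAdmixed = as.integer(nAdmixed),
                   admixedPop = admixedPop, otherPop = otherPop,
                   targetPop = names(nSamples)[1L],
                   driftF = setNames(driftF, names(nSamples)),
                   nSites = as.integer(nSites),
                   chromLength = as.integer(chromLength),
                   m = m, g = as.integer(g), recombRate = recombRate,
                   missingRate = missingRate,
                   ancestralFreqRange = ancestralFreqRange,
                   seed = as.integer(seed)),
              class = "simConfig")
}

## Exponential-tract ancestry process for one haplotype: alternating
## sojourns in target (rate r*g*(1-m) to leave) and non-target (rate r*g*m).
simulateTractProcess <- function(L, m, g, recombRate, targetPop, otherPop) {
    rateLeaveTarget <- recombRate * g * (1 - m)
    rateLeaveOther <- recombRate * g * m
    state <- rbinom(1L, 1L, m) == 1L    # TRUE = target ancestry
    x <- 0
    starts <- numeric(); pops <- character()
    while (x < L) {
        starts <- c(starts, x)
        pops <- c(pops, if (state) targetPop else otherPop)
        rate <- if (state) rateLeaveTarget else rateLeaveOther
        x <- if (rate > 0) x + rexp(1L, rate) else Inf
        state <- !state
    }
    data.frame(start = floor(starts),
               end = c(floor(starts[-1]), L), pop = pops,
               stringsAsFactors = FALSE)
}

#' Simulate a phased panel with known ancestry tracts
#'
#' Draws ancestral allele frequencies Uniform(range), per-population
#' frequencies from the Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
#' distribution, i.i.d. source haplotypes, and admixed haplotypes as
#' single-pulse ancestry mosaics whose tract lengths are exponential with
#' leave rates \code{recombRate * g * (1-m)} (target) and
#' \code{recombRate * g * m} (non-target), so the stationary target-ancestry
#' fraction is \code{m}. Genotype missingness is i.i.d. per genotype (both
#' alleles of a diploid genotype are dropped together, as in a failed call).
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{panel} (\linkS4class{HaplotypePanel}) and
#'   \code{truth} (\linkS4class{TractSet} for the admixed haplotypes).
#' @export
simulatePanel <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(config$seed, {
        ns <- config$nSites
        pAnc <- runif(ns, config$ancestralFreqRange[1],
                      config$ancestralFreqRange[2])
        popFreq <- sapply(names(config$nSamples), function(k) {
            f <- config$driftF[[k]]
            if (f == 0) pAnc
            else rbeta(ns, pAnc * (1 - f) / f, (1 - pAnc) * (1 - f) / f)
        })
        pos <- sort(sample.int(config$chromLength, ns)) - 1L

        srcHaps <- lapply(names(config$nSamples), function(k) {
            nh <- 2L * config$nSamples[[k]]
            matrix(rbinom(ns * nh, 1L, popFreq[, k]), nrow = ns)
        })
        samples <- unlist(lapply(names(config$nSamples), function(k)
            sprintf("%s%02d", k, seq_len(config$nSamples[[k]]))))
        populations <- rep(names(config$nSamples), config$nSamples)

        admSamples <- sprintf("%s%02d", config$admixedPop,
                              seq_len(config$nAdmixed))
        admHapNames <- haplotypeNames(admSamples)
        admHaps <- matrix(NA_integer_, nrow = ns,
                          ncol = 2L * config$nAdmixed)
        truth <- vector("list", 2L * config$nAdmixed)
        for (j in seq_len(2L * config$nAdmixed)) {
            tr <- simulateTractProcess(config$chromLength, config$m,
                config$g, config$recombRate, config$targetPop,
                config$otherPop)
            srcAtSite <- tr$pop[findInterval(pos, tr$start)]
            p <- popFreq[cbind(seq_len(ns), match(srcAtSite,
                colnames(popFreq)))]
            admHaps[, j] <- rbinom(ns, 1L, p)
            tr$haplotype <- admHapNames[j]
            truth[[j]] <- tr
        }

        hap <- cbind(do.call(cbind, srcHaps), admHaps)
        samples <- c(samples, admSamples)
        populations <- c(populations, rep(config$admixedPop,
                                          config$nAdmixed))
        if (config$missingRate > 0) {
            missing <- matrix(rbinom(ns * length(samples), 1L,
                config$missingRate) == 1L, nrow = ns)
            full <- missing[, rep(seq_along(samples), each = 2L)]
            hap[full] <- NA_integer_
        }
        panel <- HaplotypePanel(hap, pos, samples, populations,
                                chromLength = config$chromLength)
        truthDf <- do.call(rbind, truth)[, c("haplotype", "start",
                                             "end", "pop")]
        truthDf$start <- as.integer(truthDf$start)
        truthDf$end <- as.integer(truthDf$end)
        list(panel = panel,
             truth = TractSet(truthDf, config$chromLength))
    })
}

#' True target-ancestry fraction of the admixed haplotypes
#'
#' @param truth a \linkS4class{TractSet} of true ancestry tracts.
#' @param targetPop target-ancestry label.
#' @return genome-wide base fraction of target ancestry across haplotypes.
#' @export
targetAncestryFraction <- function(truth, targetPop) {
    tr <- tracts(truth)
    sum((tr$end - tr$start)[tr$pop == targetPop]) /
        sum(tr$end - tr$start)
}

#' Simulate Ne trajectories with a planted divergence time
#'
#' Reference populations share a common Ne trajectory plus i.i.d. Gaussian
#' noise; the query population follows the same trajectory in bins older
#' than \code{trueSplitTime} and is offset by \code{effect} noise-SD units in
#' younger bins (an absolute offset of \code{effect} when \code{noiseSd} is
#' 0). Fixture for \code{\link{neDivergence}}.
#'
#' @param pops reference population labels (>= 2 recommended).
#' @param timeBins ascending vector of bin boundaries in years before
#'   present (length B+1 for B bins).
#' @param trueSplitTime boundary age: bins strictly younger than this carry
#'   the divergence signal.
#' @param queryPop label of the diverging population.
#' @param baseNe baseline effective size.
#' @param noiseSd SD of the per-bin Ne noise (Ne units).
#' @param effect divergence effect size in SD units.
#' @param seed integer seed.
#' @return data.frame (class \code{NeTable} layout): pop, left, right, Ne.
#' @export
simulateNeTrajectories <- function(pops = c("HM1", "HM2", "HM3"),
                                   timeBins, trueSplitTime,
                                   queryPop = "Han", baseNe = 10000,
                                   noiseSd = 0, effect = 10, seed = 1L) {
    if (any(diff(timeBins) <= 0))
        stop("timeBins must be strictly ascending")
    withSeed(seed, {
        left <- timeBins[-length(timeBins)]
        right <- timeBins[-1]
        B <- length(left)
        mu <- baseNe * (1 + 0.1 * seq_len(B))  # mild growth with age
        ref <- do.call(rbind, lapply(pops, function(p)
            data.frame(pop = p, left = left, right = right,
                       Ne = mu + rnorm(B, 0, noiseSd))))
        offset <- if (noiseSd > 0) effect * noiseSd else effect
        young <- right <= trueSplitTime
        qNe <- mu + rnorm(B, 0, noiseSd) + ifelse(young, offset, 0)
        rbind(ref, data.frame(pop = queryPop, left = left, right = right,
                              Ne = qNe))
    })
}

#' Simulate shared-variant indicators for related and unrelated pairs
#'
#' Bernoulli sharing indicators per sample pair, the fixture for the
#' familial-aggregation Fisher test. Counts can be forced exactly to
#' reproduce a printed contingency table.
#'
#' @param nRelated,nUnrelated pair counts.
#' @param sharingProbRelated,sharingProbUnrelated sharing probabilities.
#' @param forceRelatedSharers,forceUnrelatedSharers optional exact sharer
#'   counts overriding the Bernoulli draw.
#' @param seed integer seed.
#' @return data.frame: pair, related (0/1), shares (0/1).
#' @export
simulateRelatedPairs <- function(nRelated, nUnrelated,
                                 sharingProbRelated = 0.1,
                                 sharingProbUnrelated = 0.01,
                                 forceRelatedSharers = NULL,
                                 forceUnrelatedSharers = NULL, seed = 1L) {
    stopifnot(sharingProbRelated >= 0, sharingProbRelated <= 1,
              sharingProbUnrelated >= 0, sharingProbUnrelated <= 1)
    withSeed(seed, {
        shr <- if (is.null(forceRelatedSharers))
            rbinom(nRelated, 1L, sharingProbRelated)
        else rep(c(1L, 0L), c(forceRelatedSharers,
                              nRelated - forceRelatedSharers))
        shu <- if (is.null(forceUnrelatedSharers))
            rbinom(nUnrelated, 1L, sharingProbUnrelated)
        else rep(c(1L, 0L), c(forceUnrelatedSharers,
                              nUnrelated - forceUnrelatedSharers))
        data.frame(pair = seq_len(nRelated + nUnrelated),
                   related = rep(c(1L, 0L), c(nRelated, nUnrelated)),
                   shares = c(shr, shu))
    })
}

#' Contingency table of pair sharing
#'
#' @param pairs output of \code{\link{simulateRelatedPairs}}.
#' @return 2x2 matrix: rows related/unrelated, columns sharing/non-sharing.
#' @export
pairSharingTable <- function(pairs) {
    m <- matrix(c(sum(pairs$related == 1 & pairs$shares == 1),
                  sum(pairs$related == 1 & pairs$shares == 0),
                  sum(pairs$related == 0 & pairs$shares == 1),
                  sum(pairs$related == 0 & pairs$shares == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("related", "unrelated"),
                                c("sharing", "nonsharing")))
    m
}
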