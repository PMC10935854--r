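#' Local-ancestry painting by a population-frequency HMM
#'
#' Assigns each site of each query haplotype a donor-population label with a
#' first-order hidden Markov model. Emission probabilities are add-one
#' smoothed donor allele frequencies; the probability of switching between
#' different populations across a gap of d bp is \code{min(lambda * d,
#' 0.49)}, split evenly over the other populations. Each replicate draws one
#' hidden path by forward-filtering backward-sampling, so replicates differ
#' only through their seeds; reducing them with \code{\link{consensusSegments}}
#' recovers high-confidence target-ancestry segments.
#'
#' Sites where any donor population has no observed allele are skipped
#' (emission 1 for every state), so the label there is inherited from the
#' flanking sites. Missing query alleles are treated the same way.
#'
#' @param panel a \linkS4class{HaplotypePanel} containing donors and queries.
#' @param queryPop population whose samples are painted (ignored when
#'   \code{querySamples} is given).
#' @param donors donor design: either a character vector of donor population
#'   labels (all their samples are used) or a named list mapping population
#'   label to an explicit set of donor sample IDs.
#' @param lambda switch rate per bp; the per-gap switch probability is
#'   \code{min(lambda * d, 0.49)}.
#' @param nReplicates number of painting replicates.
#' @param seed master seed; each replicate gets a derived child seed.
#' @param donorExclude sample IDs removed from the donor sets (in addition to
#'   the query samples themselves, which are always excluded).
#' @param querySamples explicit query samples (overrides \code{queryPop}).
#' @return list of \linkS4class{PaintingReplicate}.
#' @export
paintPanel <- function(panel, queryPop, donors, lambda = 1e-6,
                       nReplicates = 10L, seed = 1L, donorExclude = NULL,
                       querySamples = NULL) {
    if (is.null(querySamples))
        querySamples <- samplesOfPop(panel, queryPop)
    if (!length(querySamples)) stop("no query samples")
    prep <- paintingSetup(panel, donors,
                          exclude = c(donorExclude, querySamples),
                          lambda = lambda)
    qCols <- hapColumns(panel, querySamples)
    qNames <- haplotypeNames(querySamples)
    seeds <- childSeeds(seed, nReplicates)
    lapply(seq_len(nReplicates), function(r) withSeed(seeds[r], {
        states <- vapply(seq_along(qCols), function(j)
            ffbsSample(panel@haplotypes[, qCols[j]], prep),
            integer(nSites(panel)))
        tr <- do.call(rbind, lapply(seq_along(qCols), function(j)
            statesToTracts(prep$pops[states[, j]], panel@positions,
                           panel@chromLength, qNames[j])))
        new("PaintingReplicate", TractSet(tr, panel@chromLength),
            replicateId = as.integer(r))
    }))
}

## Precompute donor emission frequencies and transition switch probabilities.
paintingSetup <- function(panel, donors, exclude, lambda) {
    if (!is.list(donors))
        donors <- setNames(lapply(donors, samplesOfPop, panel = panel),
                           donors)
    donors <- lapply(donors, setdiff, y = exclude)
    nDonorHaps <- vapply(donors, length, integer(1)) * 2L
    if (any(nDonorHaps == 0L))
        stop("no donor haplotypes for population(s): ",
             paste(names(donors)[nDonorHaps == 0L], collapse = ", "))
    freq <- sapply(names(donors), function(k) {
        af <- alleleFreqs(panel, donors[[k]])
        (af$freq * af$n + 1) / (af$n + 2)   # add-one smoothing
    })
    freq[is.na(freq)] <- 0.5                # all-missing donor pop at a site
    skip <- rowSums(sapply(names(donors), function(k)
        alleleFreqs(panel, donors[[k]])$n) == 0) > 0
    q <- pmin(lambda * diff(panel@positions), 0.49)
    list(pops = names(donors), freq = freq, skip = skip, q = q,
         K = length(donors))
}

## Emission matrix for one query haplotype: sites x states.
emissionMatrix <- function(hap, prep) {
    E <- ifelse(matrix(rep(hap, prep$K), ncol = prep$K) == 1L,
                prep$freq, 1 - prep$freq)
    E[is.na(hap), ] <- 1
    E[prep$skip, ] <- 1
    E
}

## Forward pass with scaling; returns alpha (sites x states).
forwardPass <- function(E, prep) {
    S <- nrow(E); K <- prep$K
    alpha <- matrix(0, S, K)
    a <- E[1L, ] / K
    alpha[1L, ] <- a / sum(a)
    for (s in seq_len(S - 1L)) {
        q <- prep$q[s]
        pred <- alpha[s, ] * (1 - q - q / (K - 1)) +
            sum(alpha[s, ]) * q / (K - 1)
        a <- pred * E[s + 1L, ]
        alpha[s + 1L, ] <- a / sum(a)
    }
    alpha
}

## One posterior path draw by backward sampling from the filtered densities.
ffbsSample <- function(hap, prep) {
    E <- emissionMatrix(hap, prep)
    alpha <- forwardPass(E, prep)
    S <- nrow(E); K <- prep$K
    z <- integer(S)
    z[S] <- sample.int(K, 1L, prob = alpha[S, ])
    for (s in seq(S - 1L, 1L)) {
        q <- prep$q[s]
        w <- alpha[s, ] * q / (K - 1)
        w[z[s + 1L]] <- alpha[s, z[s + 1L]] * (1 - q)
        z[s] <- sample.int(K, 1L, prob = w)
    }
    z
}

#' Per-site posterior ancestry probabilities for one query haplotype
#'
#' Exact forward-backward smoothing under the painting HMM; the marginal
#' distribution that \code{\link{paintPanel}} samples paths from.
#'
#' @inheritParams paintPanel
#' @param hap 0/1/NA allele vector over the panel's sites.
#' @return matrix sites x donor populations of posterior probabilities.
#' @export
paintPosterior <- function(panel, hap, donors, lambda = 1e-6,
                           donorExclude = NULL) {
    prep <- paintingSetup(panel, donors, exclude = donorExclude,
                          lambda = lambda)
    E <- emissionMatrix(hap, prep)
    S <- nrow(E); K <- prep$K
    alpha <- forwardPass(E, prep)
    beta <- matrix(0, S, K)
    beta[S, ] <- 1
    for (s in seq(S - 1L, 1L)) {
        q <- prep$q[s]
        v <- beta[s + 1L, ] * E[s + 1L, ]
        b <- v * (1 - q - q / (K - 1)) + sum(v) * q / (K - 1)
        beta[s, ] <- b / sum(b)
    }
    post <- alpha * beta
    post <- post / rowSums(post)
    colnames(post) <- prep$pops
    post
}

#' Reduce painting replicates to consensus target-ancestry segments
#'
#' A position enters a consensus segment iff at least \code{minSupport} of
#' the replicates label it \code{targetLabel}; maximal runs of qualifying
#' positions become intervals. With the defaults this is the
#' at-least-half-of-10-paintings rule.
#'
#' @param replicates list of \linkS4class{PaintingReplicate} covering the
#'   same haplotypes.
#' @param targetLabel ancestry label the consensus is taken over.
#' @param minSupport minimum number of supporting replicates.
#' @return A \linkS4class{ConsensusSegments}.
#' @export
consensusSegments <- function(replicates, targetLabel, minSupport = 5L) {
    stopifnot(length(replicates) >= 1L)
    hapSets <- lapply(replicates, function(r)
        sort(unique(tracts(r)$haplotype)))
    if (!all(vapply(hapSets, identical, logical(1), y = hapSets[[1]])))
        stop("replicates cover different haplotype sets")
    L <- replicates[[1]]@chromLength
    haps <- hapSets[[1]]
    segs <- lapply(haps, function(h) {
        irl <- lapply(replicates, function(r) {
            tr <- tracts(r)
            tr <- tr[tr$haplotype == h & tr$pop == targetLabel, ,
                     drop = FALSE]
            toIRanges(tr$start, tr$end)
        })
        cov <- IRanges::coverage(do.call(c, irl), width = L)
        sl <- IRanges::slice(cov, lower = minSupport)
        if (!length(sl)) return(NULL)
        out <- fromIRanges(methods::as(sl, "IRanges"))
        out$support <- as.integer(IRanges::viewMins(sl))
        out$haplotype <- h
        out[, c("haplotype", "start", "end", "support")]
    })
    segs <- do.call(rbind, segs)
    if (is.null(segs))
        segs <- data.frame(haplotype = character(), start = integer(),
                           end = integer(), support = integer())
    new("ConsensusSegments", segments = segs,
        targetLabel = targetLabel, minSupport = as.integer(minSupport),
        nReplicates = as.integer(length(replicates)), chromLength = L)
}

#' Wrap externally produced (or true) tracts as a painting replicate
#'
#' Lets real painter output, or simulated truth tracts, enter the consensus
#' and reconstruction stages through the same contract as
#' \code{\link{paintPanel}}.
#'
#' @param tractSet a \linkS4class{TractSet}.
#' @param replicateId replicate index to attach.
#' @return A \linkS4class{PaintingReplicate}.
#' @export
asPaintingReplicate <- function(tractSet, replicateId = 1L)
    new("PaintingReplicate", tractSet,
        replicateId = as.integer(replicateId))
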