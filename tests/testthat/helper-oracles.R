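## Independent oracles and small fixture builders. Everything here is
## deliberately written as a separate code path from the package internals.

## Literal transcription of the Hudson per-site estimator and its
## ratio-of-sums genome-wide form.
oracleHudsonSite <- function(p1, p2, n1, n2) {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    num / den
}
oracleHudsonGenome <- function(p1, p2, n1, n2) {
    num <- den <- 0
    for (i in seq_along(p1)) {
        if (n1[i] < 2 || n2[i] < 2) next
        num <- num + (p1[i] - p2[i])^2 -
            p1[i] * (1 - p1[i]) / (n1[i] - 1) -
            p2[i] * (1 - p2[i]) / (n2[i] - 1)
        den <- den + p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
    }
    num / den
}

## Direct Monte-Carlo of the Balding-Nichols + balanced Hudson pipeline:
## draws population frequencies and finite samples from scratch and returns
## the per-replicate genome-wide Hudson FST values.
oracleBalancedFstMC <- function(F1, F2, nSites, nPerPop, reps,
                                seed, freqRange = c(0.05, 0.95)) {
    set.seed(seed)
    vapply(seq_len(reps), function(r) {
        p <- runif(nSites, freqRange[1], freqRange[2])
        drawPop <- function(FF) {
            pf <- if (FF == 0) p else
                rbeta(nSites, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF)
            cnt <- rbinom(nSites, 2L * nPerPop, pf)
            list(p = cnt / (2 * nPerPop), n = rep(2L * nPerPop, nSites))
        }
        a <- drawPop(F1); b <- drawPop(F2)
        oracleHudsonGenome(a$p, b$p, a$n, b$n)
    }, numeric(1))
}

## Independent forward-backward posterior decoding for the painting HMM:
## same model contract (add-one smoothed donor frequencies, distance-scaled
## switch probability capped at 0.49), implemented with explicit transition
## matrices and log-free scaling, separately from the package.
oracleHmmPosterior <- function(queryHap, donorFreqList, pos, lambda) {
    K <- length(donorFreqList)
    S <- length(queryHap)
    E <- matrix(1, S, K)
    for (k in seq_len(K)) {
        f <- donorFreqList[[k]]
        e <- ifelse(queryHap == 1L, f, 1 - f)
        e[is.na(queryHap)] <- 1
        E[, k] <- e
    }
    Tm <- function(d) {
        q <- min(lambda * d, 0.49)
        m <- matrix(q / (K - 1), K, K)
        diag(m) <- 1 - q
        m
    }
    al <- matrix(0, S, K)
    al[1, ] <- E[1, ] / K; al[1, ] <- al[1, ] / sum(al[1, ])
    for (s in 2:S) {
        a <- (al[s - 1, ] %*% Tm(pos[s] - pos[s - 1])) * E[s, ]
        al[s, ] <- a / sum(a)
    }
    be <- matrix(0, S, K)
    be[S, ] <- 1
    for (s in (S - 1):1) {
        b <- Tm(pos[s + 1] - pos[s]) %*% (be[s + 1, ] * E[s + 1, ])
        be[s, ] <- b / sum(b)
    }
    post <- al * be
    post / rowSums(post)
}

## Two-sided Fisher exact p by exhaustive enumeration of the hypergeometric
## support, summing probabilities no larger than the observed one (with the
## conventional 1 + 1e-7 tie tolerance).
oracleFisherP <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- vapply(support, function(x)
        exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
        numeric(1))
    pObs <- pr[match(a, support)]
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

## Textbook neighbor-joining (Saitou-Nei Q-matrix), returning the set of
## non-trivial splits (as sorted label subsets) of the unrooted topology.
oracleNJSplits <- function(D) {
    labs <- rownames(D)
    nodes <- as.list(labs)           # leaf sets carried per working node
    created <- list()                # cluster born at each merge = one edge
    repeat {
        n <- nrow(D)
        if (n <= 3) break
        rs <- rowSums(D)
        Q <- (n - 2) * D - outer(rs, rs, "+")
        diag(Q) <- Inf
        ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
        i <- min(ij); j <- max(ij)
        merged <- c(nodes[[i]], nodes[[j]])
        created <- c(created, list(merged))
        dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(n), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                    c(dNew[keep], 0))
        nodes <- c(nodes[keep], list(merged))
        rownames(D2) <- colnames(D2) <- NULL
        D <- D2
    }
    splits <- Filter(function(s) length(s) >= 2 &&
                         length(s) <= length(labs) - 2, created)
    unique(lapply(splits, function(s) {
        s <- sort(s)
        o <- sort(setdiff(labs, s))
        if (paste(s, collapse = ",") < paste(o, collapse = ","))
            s else o
    }))
}

## Non-trivial splits of an unrooted ape tree, same canonical form.
treeSplits <- function(tree) {
    labs <- sort(tree$tip.label)
    bp <- ape::prop.part(tree)
    splits <- lapply(bp, function(ix) sort(attr(bp, "labels")[ix]))
    splits <- Filter(function(s) length(s) >= 2 &&
                         length(s) <= length(labs) - 2, splits)
    unique(lapply(splits, function(s) {
        o <- sort(setdiff(labs, s))
        if (paste(s, collapse = ",") < paste(o, collapse = ","))
            s else o
    }))
}

## KING-robust between-family kinship from diploid genotype dosages
## (columns = individuals). phi > 0.0442 flags third-degree or closer.
kinshipKing <- function(geno) {
    nInd <- ncol(geno)
    phi <- matrix(NA_real_, nInd, nInd)
    for (i in seq_len(nInd - 1)) for (j in (i + 1):nInd) {
        gi <- geno[, i]; gj <- geno[, j]
        ok <- !is.na(gi) & !is.na(gj)
        gi <- gi[ok]; gj <- gj[ok]
        nhh <- sum(gi == 1 & gj == 1)
        nopp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
        nhi <- sum(gi == 1); nhj <- sum(gj == 1)
        phi[i, j] <- (nhh - 2 * nopp) / (nhi + nhj)
    }
    phi
}

## Small hand-built phased panel: hapMatrix is sites x haplotypes.
makePanel <- function(hapMatrix, positions, pops, chromLength = NULL) {
    nSamp <- ncol(hapMatrix) / 2
    samples <- sprintf("S%02d", seq_len(nSamp))
    HaplotypePanel(hapMatrix, positions, samples, pops,
                   chromLength = chromLength)
}

## Consensus object built directly from a segment table (bypasses painting).
makeConsensus <- function(segments, chromLength, target = "HM",
                          minSupport = 5L, nReplicates = 10L) {
    segments$support <- if (is.null(segments$support))
        rep(nReplicates, nrow(segments)) else segments$support
    methods::new("ConsensusSegments", segments = segments,
                 targetLabel = target, minSupport = as.integer(minSupport),
                 nReplicates = as.integer(nReplicates),
                 chromLength = as.integer(chromLength))
}

## Truth tracts replayed as R identical painting replicates.
truthReplicates <- function(truth, R = 10L)
    lapply(seq_len(R), function(r) asPaintingReplicate(truth, r))
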