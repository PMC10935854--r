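#' Divergence dating from Ne trajectories
#'
#' Compares a query population's effective-size trajectory against a group
#' of reference trajectories over shared time bins. Per bin, the reference
#' mean and SD (pooled over reference populations) are computed; the query
#' is divergent in a bin when its Ne falls outside mean +/- \code{kSd} SD
#' (with SD = 0, any difference counts). The estimate is taken from the
#' most recent maximal run of consecutive divergent bins: the midpoint of
#' that run's oldest bin (\code{boundary = "oldest"}, the default — the
#' earliest time range of the latest divergence, i.e. when the populations
#' started to diverge), or of its youngest bin
#' (\code{boundary = "youngest"}).
#'
#' The rule is invariant to rescaling all Ne values by a common constant.
#'
#' @param neTable data.frame with columns pop, left, right (years before
#'   present, bins ascending in age), Ne — e.g. from
#'   \code{\link{simulateNeTrajectories}} or \code{\link{readNeTable}}.
#' @param refPops reference population labels (>= 1).
#' @param queryPop query population label.
#' @param kSd divergence threshold in SD units (default 3).
#' @param boundary which bin of the divergent run dates the split.
#' @return list: \code{divergent} (logical), \code{time} (years, NA when no
#'   divergence detected), \code{bin} (c(left, right) of the dating bin),
#'   \code{perBin} data.frame of per-bin statistics and flags.
#' @export
neDivergence <- function(neTable, refPops, queryPop, kSd = 3,
                         boundary = c("oldest", "youngest")) {
    boundary <- match.arg(boundary)
    pops <- c(refPops, queryPop)
    tabs <- lapply(pops, function(p) {
        d <- neTable[neTable$pop == p, , drop = FALSE]
        if (!nrow(d)) stop("population absent from NeTable: ", p)
        d[order(d$left), , drop = FALSE]
    })
    bins <- tabs[[1]][, c("left", "right")]
    for (d in tabs)
        if (!isTRUE(all.equal(d$left, bins$left)) ||
            !isTRUE(all.equal(d$right, bins$right)))
            stop("populations have mismatched time bins")
    refNe <- sapply(tabs[seq_along(refPops)], function(d) d$Ne)
    if (is.null(dim(refNe))) refNe <- matrix(refNe, nrow = 1)
    mu <- rowMeans(refNe)
    sdv <- apply(refNe, 1, sd)
    sdv[is.na(sdv)] <- 0              # single reference population
    qNe <- tabs[[length(tabs)]]$Ne
    divergent <- ifelse(sdv > 0, abs(qNe - mu) > kSd * sdv, qNe != mu)
    perBin <- data.frame(left = bins$left, right = bins$right,
                         refMean = mu, refSd = sdv, queryNe = qNe,
                         divergent = divergent)
    if (!any(divergent))
        return(list(divergent = FALSE, time = NA_real_, bin = NULL,
                    perBin = perBin))
    ## bins are ordered young -> old; take the run containing the youngest
    ## divergent bin
    r <- rle(divergent)
    runEnd <- cumsum(r$lengths)
    runStart <- c(1L, runEnd[-length(runEnd)] + 1L)
    i <- which(r$values)[1]
    binIdx <- if (boundary == "youngest") runStart[i] else runEnd[i]
    list(divergent = TRUE,
         time = (bins$left[binIdx] + bins$right[binIdx]) / 2,
         bin = c(left = bins$left[binIdx], right = bins$right[binIdx]),
         perBin = perBin)
}

#' Linguistic distance from lexical similarity
#'
#' Transforms a pairwise lexical-similarity matrix s (sharing proportions of
#' lexical cognates, in (0, 1]) into a distance matrix
#' \deqn{D = (-\log_{10} s) \times 100.}
#' The diagonal maps to 0; a similarity of exactly 0 yields an infinite
#' distance (returned as \code{Inf}).
#'
#' @param sim square symmetric similarity matrix with unit diagonal.
#' @return distance matrix of the same dimension and labels.
#' @export
linguisticDistance <- function(sim) {
    sim <- as.matrix(sim)
    if (nrow(sim) != ncol(sim) || !isSymmetric(unname(sim)))
        stop("similarity matrix must be square and symmetric")
    if (any(diag(sim) != 1))
        stop("similarity of a language with itself must be 1")
    if (any(sim < 0 | sim > 1))
        stop("similarities must lie in [0, 1]")
    D <- -log10(sim) * 100
    diag(D) <- 0
    D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree (via \code{\link[ape]{nj}}) from
#' a symmetric zero-diagonal distance matrix, e.g. a linguistic distance
#' matrix.
#'
#' @param dist square symmetric distance matrix with zero diagonal and
#'   finite entries; row/column names label the leaves.
#' @return an \code{ape} \code{phylo} tree.
#' @export
buildTree <- function(dist) {
    dist <- as.matrix(dist)
    if (nrow(dist) != ncol(dist) || !isSymmetric(unname(dist)))
        stop("distance matrix must be square and symmetric")
    if (any(diag(dist) != 0))
        stop("distance matrix must have zero diagonal")
    if (any(!is.finite(dist)))
        stop("distance matrix must be finite (infinite linguistic",
             " distances cannot be placed on a tree)")
    ape::nj(stats::as.dist(dist))
}

#' Newick serialization of a tree
#' @param tree an \code{ape} \code{phylo} object.
#' @return single Newick string.
#' @export
treeNewick <- function(tree) ape::write.tree(tree)
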