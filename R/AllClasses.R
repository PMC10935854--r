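#' @import methods
#' @importFrom stats quantile rbinom rbeta runif rexp rnorm setNames sd
#'   fisher.test dhyper median
#' @importFrom utils read.table write.table
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' Phased haplotype panel
#'
#' A phased, biallelic genotype panel: a sites-by-haplotypes 0/1 allele
#' matrix (NA = missing) with physical positions and per-sample population
#' labels. Each diploid sample contributes two haplotype columns named
#' \code{<sample>.hap0} and \code{<sample>.hap1}. Positions are 0-based bp
#' on a single chromosome; the VCF writer converts to 1-based.
#'
#' @slot haplotypes integer matrix, sites x haplotypes, values 0/1/NA.
#' @slot positions integer vector of strictly increasing 0-based positions.
#' @slot chrom single chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot samples diploid sample identifiers.
#' @slot populations population label per sample (parallel to samples).
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
    representation(
        haplotypes = "matrix",
        positions = "integer",
        chrom = "character",
        chromLength = "integer",
        samples = "character",
        populations = "character"
    )
)

setValidity("HaplotypePanel", function(object) {
    msg <- character()
    h <- object@haplotypes
    if (nrow(h) != length(object@positions))
        msg <- c(msg, "nrow(haplotypes) must equal length(positions)")
    if (ncol(h) != 2L * length(object@samples))
        msg <- c(msg, "each sample must contribute exactly two haplotypes")
    if (length(object@populations) != length(object@samples))
        msg <- c(msg, "one population label per sample required")
    if (length(object@positions) &&
        any(diff(object@positions) <= 0L))
        msg <- c(msg, "positions must be strictly increasing")
    if (length(object@positions) &&
        (min(object@positions) < 0L ||
         max(object@positions) >= object@chromLength))
        msg <- c(msg, "positions must lie in [0, chromLength)")
    vals <- h[!is.na(h)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
        msg <- c(msg, "alleles must be 0, 1 or NA")
    if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes sites x haplotypes 0/1 matrix (NA = missing).
#' @param positions 0-based physical positions, strictly increasing.
#' @param samples diploid sample identifiers; haplotype columns are taken in
#'   sample order as hap0, hap1 pairs.
#' @param populations population label per sample.
#' @param chrom chromosome name.
#' @param chromLength chromosome length in bp; defaults to max position + 1.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(haplotypes, positions, samples, populations,
                           chrom = "1", chromLength = NULL) {
    storage.mode(haplotypes) <- "integer"
    if (is.null(chromLength))
        chromLength <- max(positions) + 1
    colnames(haplotypes) <- haplotypeNames(samples)
    new("HaplotypePanel",
        haplotypes = haplotypes,
        positions = as.integer(positions),
        chrom = as.character(chrom),
        chromLength = as.integer(chromLength),
        samples = as.character(samples),
        populations = as.character(populations))
}

haplotypeNames <- function(samples)
    as.vector(rbind(paste0(samples, ".hap0"), paste0(samples, ".hap1")))

#' Per-haplotype ancestry tracts
#'
#' Ancestry intervals for a set of haplotypes, in 0-based half-open bp
#' coordinates on a single chromosome. Used both for simulated truth tracts
#' and for painted local-ancestry calls.
#'
#' @slot tracts data.frame with columns haplotype, start, end, pop.
#' @slot chromLength chromosome length in bp.
#'
#' @exportClass TractSet
setClass("TractSet",
    representation(tracts = "data.frame", chromLength = "integer"))

setValidity("TractSet", function(object) {
    tr <- object@tracts
    need <- c("haplotype", "start", "end", "pop")
    if (!all(need %in% names(tr)))
        return("tracts needs columns haplotype, start, end, pop")
    if (nrow(tr)) {
        if (any(tr$start >= tr$end))
            return("tract start must be < end (half-open)")
        if (any(tr$start < 0) || any(tr$end > object@chromLength))
            return("tracts must lie within [0, chromLength)")
        bad <- vapply(split(tr, tr$haplotype), function(d) {
            d <- d[order(d$start), ]
            any(d$start[-1] < d$end[-nrow(d)])
        }, logical(1))
        if (any(bad))
            return("tracts overlap within a haplotype")
    }
    TRUE
})

#' Construct a TractSet
#' @param tracts data.frame with columns haplotype, start, end, pop
#'   (0-based half-open bp).
#' @param chromLength chromosome length in bp.
#' @return A \linkS4class{TractSet}.
#' @export
TractSet <- function(tracts, chromLength) {
    tracts <- tracts[order(tracts$haplotype, tracts$start), , drop = FALSE]
    rownames(tracts) <- NULL
    new("TractSet", tracts = tracts, chromLength = as.integer(chromLength))
}

#' One replicate local-ancestry painting
#'
#' A \linkS4class{TractSet} carrying the replicate index of the painting run
#' that produced it.
#'
#' @slot replicateId replicate number (1..R).
#' @exportClass PaintingReplicate
setClass("PaintingReplicate", contains = "TractSet",
    representation(replicateId = "integer"))

#' Consensus target-ancestry segments
#'
#' Intervals called target-ancestry in at least \code{minSupport} of
#' \code{nReplicates} painting replicates, per haplotype.
#'
#' @slot segments data.frame: haplotype, start, end, support (minimum
#'   replicate support inside the interval).
#' @slot targetLabel the ancestry label the consensus was taken over.
#' @slot minSupport support threshold used.
#' @slot nReplicates number of replicates reduced.
#' @slot chromLength chromosome length in bp.
#' @exportClass ConsensusSegments
setClass("ConsensusSegments",
    representation(segments = "data.frame", targetLabel = "character",
                   minSupport = "integer", nReplicates = "integer",
                   chromLength = "integer"))

setValidity("ConsensusSegments", function(object) {
    seg <- object@segments
    if (nrow(seg) && any(seg$support < object@minSupport))
        return("all consensus segments must meet the support threshold")
    TRUE
})

#' Candidate haplotype library
#'
#' The balanced donor set for mosaic assembly: consensus target-ancestry
#' segments for each library haplotype, the donor panel holding their
#' alleles, and the per-base coverage track c(x) counting candidate
#' haplotypes covering each position.
#'
#' @slot segments data.frame: haplotype, start, end (0-based half-open).
#' @slot haplotypeIds library haplotype identifiers.
#' @slot subpopOf named character, donor sample -> subpopulation.
#' @slot panel \linkS4class{HaplotypePanel} holding the donor haplotypes.
#' @slot coverage data.frame step function: start, end, count tiling
#'   [0, chromLength).
#' @exportClass CandidateLibrary
setClass("CandidateLibrary",
    representation(segments = "data.frame", haplotypeIds = "character",
                   subpopOf = "character", panel = "HaplotypePanel",
                   coverage = "data.frame"))

#' Reconstructed mosaic panel
#'
#' Assembled ancestral-proxy haplotypes paired into diploid genomes, the
#' provenance log of copied chunks, and the coverage mask.
#'
#' @slot panel \linkS4class{HaplotypePanel} of reconstructed genomes
#'   (NA outside reconstructable regions).
#' @slot provenance data.frame: haplotype, source, start, end — each copied
#'   chunk (0-based half-open), length <= the chunk cap.
#' @slot mask data.frame of reconstructable intervals: start, end.
#' @slot minCoverage coverage threshold used for the mask.
#' @slot maxChunk chunk-length cap in bp.
#' @exportClass ReconstructedPanel
setClass("ReconstructedPanel",
    representation(panel = "HaplotypePanel", provenance = "data.frame",
                   mask = "data.frame", minCoverage = "integer",
                   maxChunk = "integer"))

## ---- generics -------------------------------------------------------------

#' @rdname HaplotypePanel-class
#' @param x,object a panel-like object
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname TractSet-class
#' @param x a TractSet
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))
#' @rdname ConsensusSegments-class
#' @param x a ConsensusSegments or CandidateLibrary
#' @export
setGeneric("segments2", function(x) standardGeneric("segments2"))
#' @rdname CandidateLibrary-class
#' @param x a CandidateLibrary
#' @export
setGeneric("coverageTrack", function(x) standardGeneric("coverageTrack"))
#' @rdname ReconstructedPanel-class
#' @param x a ReconstructedPanel
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ReconstructedPanel-class
#' @export
setGeneric("coverageMaskIntervals", function(x)
    standardGeneric("coverageMaskIntervals"))

setMethod("nSites", "HaplotypePanel", function(x) nrow(x@haplotypes))
setMethod("nHaplotypes", "HaplotypePanel", function(x) ncol(x@haplotypes))
setMethod("positions", "HaplotypePanel", function(x) x@positions)
setMethod("sampleIds", "HaplotypePanel", function(x) x@samples)
setMethod("popLabels", "HaplotypePanel",
    function(x) setNames(x@populations, x@samples))
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)
setMethod("tracts", "TractSet", function(x) x@tracts)
setMethod("segments2", "ConsensusSegments", function(x) x@segments)
setMethod("segments2", "CandidateLibrary", function(x) x@segments)
setMethod("coverageTrack", "CandidateLibrary", function(x) x@coverage)
setMethod("provenance", "ReconstructedPanel", function(x) x@provenance)
setMethod("coverageMaskIntervals", "ReconstructedPanel", function(x) x@mask)

setMethod("nSites", "ReconstructedPanel", function(x) nSites(x@panel))
setMethod("nHaplotypes", "ReconstructedPanel",
    function(x) nHaplotypes(x@panel))

#' Extract the HaplotypePanel from a ReconstructedPanel
#' @param x a \linkS4class{ReconstructedPanel}
#' @return the inner \linkS4class{HaplotypePanel}
#' @export
reconstructedPanel <- function(x) {
    stopifnot(is(x, "ReconstructedPanel"))
    x@panel
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "HaplotypePanel", function(object) {
    cat("HaplotypePanel:", nSites(object), "sites x",
        nHaplotypes(object), "haplotypes (",
        length(object@samples), "diploid samples )\n")
    cat("  chrom", object@chrom, "length", object@chromLength, "bp\n")
    tab <- table(object@populations)
    cat("  populations:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    miss <- mean(is.na(object@haplotypes))
    cat(sprintf("  missing: %.2f%%\n", 100 * miss))
})

setMethod("show", "TractSet", function(object) {
    cat(class(object), ":", nrow(object@tracts), "tracts on",
        length(unique(object@tracts$haplotype)), "haplotypes;",
        "chromLength", object@chromLength, "bp\n")
})

setMethod("show", "ConsensusSegments", function(object) {
    cat("ConsensusSegments:", nrow(object@segments), "segments,",
        "target", object@targetLabel, sprintf("(support >= %d of %d)\n",
        object@minSupport, object@nReplicates))
})

setMethod("show", "CandidateLibrary", function(object) {
    cat("CandidateLibrary:", length(object@haplotypeIds), "haplotypes from",
        length(unique(names(object@subpopOf))), "samples in",
        length(unique(object@subpopOf)), "subpopulations\n")
    cov <- object@coverage
    cat(sprintf("  coverage: max %d, mean %.1f\n", max(cov$count),
        sum(cov$count * (cov$end - cov$start)) / sum(cov$end - cov$start)))
})

setMethod("show", "ReconstructedPanel", function(object) {
    cat("ReconstructedPanel:", nHaplotypes(object), "haplotypes /",
        length(object@panel@samples), "genomes\n")
    cat("  chunk cap", object@maxChunk, "bp; min coverage",
        object@minCoverage, "\n")
    covbp <- sum(object@mask$end - object@mask$start)
    cat(sprintf("  reconstructable: %d bp (%.1f%% of chromosome)\n",
        covbp, 100 * covbp / object@panel@chromLength))
})
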