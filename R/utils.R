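## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not disturb the session stream.
#' @noRd
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

## Derive child seeds from a master seed (kept below 2^31).
childSeeds <- function(seed, n)
    withSeed(seed, sample.int(.Machine$integer.max, n))

## 0-based half-open intervals <-> IRanges (1-based closed).
toIRanges <- function(start, end)
    IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))

fromIRanges <- function(ir)
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))

## Haplotype column indices of a set of samples in a panel.
hapColumns <- function(panel, samples) {
    idx <- match(samples, panel@samples)
    if (anyNA(idx))
        stop("unknown samples: ",
             paste(samples[is.na(idx)], collapse = ", "))
    as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Samples belonging to one or more populations
#' @param panel a \linkS4class{HaplotypePanel}
#' @param pop population label(s)
#' @return character vector of diploid sample IDs
#' @export
samplesOfPop <- function(panel, pop) panel@samples[panel@populations %in% pop]

#' Alternate-allele frequencies for a set of haplotype columns
#'
#' @return list(freq, n): per-site alternate-allele frequency among
#'   non-missing alleles and the non-missing allele count. Sites with no
#'   observed allele get freq NA, n 0.
#' @noRd
alleleFreqs <- function(panel, samples = NULL, cols = NULL) {
    if (is.null(cols)) cols <- hapColumns(panel, samples)
    h <- panel@haplotypes[, cols, drop = FALSE]
    n <- rowSums(!is.na(h))
    alt <- rowSums(h, na.rm = TRUE)
    list(freq = ifelse(n > 0, alt / n, NA_real_), n = n)
}

#' Population allele frequencies
#'
#' Alternate-allele frequency and non-missing allele count per site for one
#' population of a panel.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param pop population label
#' @return data.frame with columns \code{freq} and \code{n} (one row per site)
#' @export
popAlleleFreqs <- function(panel, pop) {
    smp <- samplesOfPop(panel, pop)
    if (!length(smp)) stop("no samples in population ", pop)
    af <- alleleFreqs(panel, smp)
    data.frame(freq = af$freq, n = af$n)
}

## Merge per-site state labels into bp tracts tiling [0, chromLength).
## Boundaries between runs are placed at the midpoint between flanking sites.
statesToTracts <- function(states, pos, chromLength, haplotype) {
    r <- rle(states)
    k <- length(r$lengths)
    last <- cumsum(r$lengths)
    first <- c(1L, last[-k] + 1L)
    start <- c(0L, as.integer(floor((pos[last[-k]] + pos[first[-1]]) / 2)))
    end <- c(start[-1], as.integer(chromLength))
    data.frame(haplotype = haplotype, start = start, end = end,
               pop = r$values, stringsAsFactors = FALSE)
}
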