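#' Read a phased VCF into a HaplotypePanel
#'
#' Accepts VCF 4.x with biallelic SNVs and a GT field. 1-based VCF
#' positions are converted to the internal 0-based coordinates. Genotypes
#' \code{./.} (or \code{.|.}) become missing; unphased genotypes are an
#' error when \code{requirePhased} (the first offending record is named).
#'
#' @param path VCF file (plain or bgzipped).
#' @param popMap named character vector sample -> population; samples
#'   absent from the map get population \code{"unknown"}.
#' @param chromLength chromosome length in bp; default max position + 1.
#' @param requirePhased error on unphased genotypes.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
readPanelVcf <- function(path, popMap = NULL, chromLength = NULL,
                         requirePhased = TRUE) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    if (any(nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L |
            grepl(",", fix[, "ALT"], fixed = TRUE)))
        stop("only biallelic SNVs are supported")
    if (length(unique(fix[, "CHROM"])) != 1L)
        stop("panel must cover a single chromosome")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt[is.na(gt)] <- "./."
    bad <- matrix(!grepl("^(\\.[|/]\\.|[01][|/][01])$", gt),
                  nrow = nrow(gt))
    if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop("malformed GT at record ", w[1], " (POS ",
             fix[w[1], "POS"], "), sample ", colnames(gt)[w[2]])
    }
    unphased <- matrix(grepl("/", gt, fixed = TRUE) &
                       !grepl("^\\./\\.$", gt), nrow = nrow(gt))
    if (requirePhased && any(unphased)) {
        w <- which(unphased, arr.ind = TRUE)[1, ]
        stop("unphased genotype at record ", w[1], " (POS ",
             fix[w[1], "POS"], "), sample ", colnames(gt)[w[2]])
    }
    a0 <- substr(gt, 1, 1); a1 <- substr(gt, 3, 3)
    toInt <- function(a) {
        x <- suppressWarnings(as.integer(a))
        matrix(x, nrow = nrow(gt))
    }
    h0 <- toInt(a0); h1 <- toInt(a1)
    samples <- colnames(gt)
    hap <- matrix(NA_integer_, nrow = nrow(gt), ncol = 2L * ncol(gt))
    hap[, seq(1, ncol(hap), 2)] <- h0
    hap[, seq(2, ncol(hap), 2)] <- h1
    pops <- if (is.null(popMap)) rep("unknown", length(samples))
        else ifelse(samples %in% names(popMap), popMap[samples], "unknown")
    HaplotypePanel(hap, as.integer(fix[, "POS"]) - 1L, samples, pops,
                   chrom = fix[1, "CHROM"], chromLength = chromLength)
}

#' Write a HaplotypePanel as phased VCF 4.2
#'
#' Alleles are written REF = A, ALT = G (site identity is positional in
#' this panel representation); internal 0-based positions convert to
#' 1-based. Missing genotypes are written \code{./.}.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePanelVcf <- function(panel, path) {
    h <- panel@haplotypes
    g0 <- h[, seq(1, ncol(h), 2), drop = FALSE]
    g1 <- h[, seq(2, ncol(h), 2), drop = FALSE]
    gt <- matrix(paste0(g0, "|", g1), nrow = nrow(h))
    gt[is.na(g0) | is.na(g1)] <- "./."
    body <- cbind(panel@chrom, panel@positions + 1L, ".", "A", "G", ".",
                  "PASS", ".", "GT", gt)
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", panel@chrom, ",length=",
                    panel@chromLength, ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", panel@samples),
                   collapse = "\t"))
    writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
    invisible(path)
}

#' Write ancestry tracts as BED
#'
#' Columns: chrom, start, end, pop, haplotype (0-based half-open, as BED).
#' @param tractSet a \linkS4class{TractSet} (or
#'   \linkS4class{PaintingReplicate}).
#' @param path output file.
#' @param chrom chromosome name.
#' @return \code{path}, invisibly.
#' @export
writeTractsBed <- function(tractSet, path, chrom = "1") {
    tr <- tracts(tractSet)
    write.table(data.frame(chrom, tr$start, tr$end, tr$pop, tr$haplotype),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read ancestry tracts from BED
#' @param path BED file written by \code{\link{writeTractsBed}} (chrom,
#'   start, end, pop, haplotype).
#' @param chromLength chromosome length in bp.
#' @return A \linkS4class{TractSet}.
#' @export
readTractsBed <- function(path, chromLength) {
    d <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "pop",
                                  "haplotype"))
    TractSet(d[, c("haplotype", "start", "end", "pop")], chromLength)
}

#' Read / write Ne trajectory tables
#'
#' TSV with columns pop, left, right (years before present), Ne.
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readNeTable <- function(path) {
    d <- read.table(path, sep = "\t", header = TRUE)
    need <- c("pop", "left", "right", "Ne")
    if (!all(need %in% names(d)))
        stop("NeTable needs columns ", paste(need, collapse = ", "))
    d
}

#' @rdname readNeTable
#' @param neTable data.frame: pop, left, right, Ne.
#' @export
writeNeTable <- function(neTable, path) {
    write.table(neTable, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a language similarity matrix from CSV
#'
#' Square numeric CSV with language labels as header and first column.
#' @param path CSV file.
#' @return labeled numeric matrix.
#' @export
readSimilarityMatrix <- function(path) {
    d <- read.table(path, sep = ",", header = TRUE, row.names = 1,
                    check.names = FALSE)
    as.matrix(d)
}
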