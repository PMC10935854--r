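#' Polarize derived alleles in a reference panel
#'
#' In a recently related population group, the lower-frequency allele at a
#' low-MAF site is treated as the recently derived allele. Sites are
#' retained when the polarizing-panel MAF is at most \code{mafMax} and the
#' annotated biological effect is moderate or high; sites with MAF exactly
#' 0.5 cannot be polarized and are dropped with a warning.
#'
#' @param freq alternate-allele frequency per site in the polarizing panel
#'   (e.g. the Han reference genomes).
#' @param effects effect class per site
#'   (\code{high}/\code{moderate}/\code{low}/\code{modifier}), from an
#'   external annotation table.
#' @param mafMax MAF cap (default 0.20).
#' @return data.frame per site: \code{site} index, \code{derivedIsAlt},
#'   \code{derivedFreq} (polarizing panel), \code{effect},
#'   \code{qualifying}.
#' @export
polarizeDerived <- function(freq, effects, mafMax = 0.20) {
    stopifnot(length(freq) == length(effects))
    maf <- pmin(freq, 1 - freq)
    tie <- !is.na(freq) & freq == 0.5
    if (any(tie))
        warning(sum(tie), " site(s) with MAF exactly 0.5 cannot be",
                " polarized and were excluded")
    qualifying <- !is.na(freq) & !tie & maf <= mafMax &
        effects %in% c("moderate", "high")
    data.frame(site = seq_along(freq),
               derivedIsAlt = !is.na(freq) & freq < 0.5,
               derivedFreq = maf, effect = effects,
               qualifying = qualifying)
}

## Derived-allele dosage (0/1/2, NA-aware) per individual at given sites.
derivedDosage <- function(panel, samples, siteIdx, derivedIsAlt) {
    cols <- hapColumns(panel, samples)
    h <- panel@haplotypes[siteIdx, cols, drop = FALSE]
    der <- matrix(ifelse(derivedIsAlt, 1L, 0L), nrow = length(siteIdx),
                  ncol = length(cols))
    hit <- (h == der)
    hit0 <- hit[, seq(1, ncol(hit), 2), drop = FALSE]
    hit1 <- hit[, seq(2, ncol(hit), 2), drop = FALSE]
    (!is.na(hit0) & hit0) + (!is.na(hit1) & hit1)
}

#' Carrying rate of derived alleles over a site set
#'
#' Proportion of diploid individuals carrying at least one derived allele
#' at any of the given sites.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param pop population label.
#' @param siteIdx site indices (rows of the panel).
#' @param derivedIsAlt logical per site: is the derived allele the ALT
#'   allele?
#' @return fraction in [0, 1].
#' @export
carryingRate <- function(panel, pop, siteIdx, derivedIsAlt) {
    smp <- samplesOfPop(panel, pop)
    if (!length(smp)) stop("no samples in population ", pop)
    dos <- derivedDosage(panel, smp, siteIdx, derivedIsAlt)
    mean(colSums(dos) >= 1L)
}

#' Gene screen for dispersed rare derived alleles of strong effect
#'
#' Evaluates, per gene, the four criteria for genes enriched with dispersed
#' strong-effect rare derived alleles: (1) no derived allele observed in
#' the reference population; (2) more than \code{carrierMin} of target
#' individuals carry at least one derived allele; (3) the highest
#' per-site derived-allele frequency in the target population is below
#' \code{freqMax}; (4) the gene carries at least \code{minSnvs} qualifying
#' SNVs. Genes with no mapped qualifying site are omitted.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param calls output of \code{\link{polarizeDerived}}.
#' @param geneMap data.frame: gene, start, end (0-based half-open bp).
#' @param targetPop target population label.
#' @param refPop reference population label.
#' @param carrierMin carrier-fraction threshold (strict >).
#' @param freqMax derived-frequency cap in the target population (strict <).
#' @param minSnvs minimum qualifying SNVs per gene.
#' @return data.frame per gene: nSnvs, carrierRate, maxDerivedFreq,
#'   noRefDerived, carrierOk, freqOk, multiSnv, pass.
#' @export
geneScreen <- function(panel, calls, geneMap, targetPop, refPop = "Han",
                       carrierMin = 0.10, freqMax = 0.05, minSnvs = 2L) {
    q <- calls[calls$qualifying, , drop = FALSE]
    pos <- panel@positions
    refSmp <- samplesOfPop(panel, refPop)
    tgtSmp <- samplesOfPop(panel, targetPop)
    out <- lapply(seq_len(nrow(geneMap)), function(i) {
        inGene <- q$site[pos[q$site] >= geneMap$start[i] &
                         pos[q$site] < geneMap$end[i]]
        if (!length(inGene)) return(NULL)
        der <- calls$derivedIsAlt[inGene]
        refDos <- derivedDosage(panel, refSmp, inGene, der)
        tgtDos <- derivedDosage(panel, tgtSmp, inGene, der)
        tgtAF <- alleleFreqs(panel, tgtSmp)
        fDer <- ifelse(der, tgtAF$freq[inGene], 1 - tgtAF$freq[inGene])
        carrier <- mean(colSums(tgtDos) >= 1L)
        maxF <- max(fDer, na.rm = TRUE)
        crit <- c(noRefDerived = sum(refDos) == 0L,
                  carrierOk = carrier > carrierMin,
                  freqOk = maxF < freqMax,
                  multiSnv = length(inGene) >= minSnvs)
        data.frame(gene = geneMap$gene[i], nSnvs = length(inGene),
                   carrierRate = carrier, maxDerivedFreq = maxF,
                   t(crit), pass = all(crit))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(gene = character(), nSnvs = integer(),
                          carrierRate = numeric(),
                          maxDerivedFreq = numeric(),
                          noRefDerived = logical(), carrierOk = logical(),
                          freqOk = logical(), multiSnv = logical(),
                          pass = logical())
    rownames(out) <- NULL
    out
}

#' Familial-aggregation Fisher exact test
#'
#' Two-sided Fisher exact test on a 2x2 sharing table (related vs unrelated
#' pairs x sharing vs not), with the two-sided p-value obtained by summing
#' hypergeometric probabilities no larger than that of the observed table.
#' Degenerate margins give p = 1.
#'
#' @param table 2x2 matrix of nonnegative counts (rows: related/unrelated;
#'   columns: sharing/non-sharing), e.g. from
#'   \code{\link{pairSharingTable}}.
#' @return list: \code{p} (two-sided), \code{oddsRatio} (conditional MLE;
#'   may be Inf), \code{table}.
#' @export
familialAggregation <- function(table) {
    table <- as.matrix(table)
    stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
              any(table > 0))
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(list(p = 1, oddsRatio = NA_real_, table = table))
    ft <- fisher.test(table)
    list(p = ft$p.value, oddsRatio = unname(ft$estimate), table = table)
}
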