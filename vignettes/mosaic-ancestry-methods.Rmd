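---
title: "Reconstructing an ancestral gene pool from admixed genomes: models and methods"
author: "MosaicAncestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing an ancestral gene pool from admixed genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MosaicAncestry)
```

## The problem

A minority population that has long exchanged migrants with larger
neighbours carries its distinctive ancestry as genomic tracts interleaved
with recently introduced material. Population-level statistics computed on
such genomes conflate the ancestral gene pool with recent gene flow.
`MosaicAncestry` addresses this by reconstructing proxy genomes for the
ancestral population: it collects the tracts confidently assigned to the
target ancestry across many carriers and reassembles them into mosaic
haplotypes, which then anchor differentiation and drift statistics that
recent admixture would otherwise dilute.

## Local-ancestry painting

Queries are painted with a first-order HMM whose hidden states are donor
*populations* (a collapsed model, not per-donor-haplotype copying as in
Li–Stephens painters). Emissions are add-one smoothed donor allele
frequencies: with `a` alternate alleles among `n` observed donor alleles,
the probability of observing the alternate allele is `(a + 1)/(n + 2)`.
Across a physical gap of `d` bp the probability of switching population is
`min(lambda * d, 0.49)`, shared evenly among the other populations;
`lambda` (per bp, default `1e-6`) plays the role of a recombination-scaled
switch rate and caps below 1/2 so transitions never become
anti-persistent. Sites where a donor population has no observed allele, and
sites where the query allele is missing, emit 1 in every state: the label
there is inherited from the flanks.

Replicate paintings — 10 by default — are independent posterior path draws
by forward-filtering backward-sampling under derived child seeds. Nothing
else differs between replicates, so replicate-to-replicate agreement
directly measures posterior confidence; `paintPosterior()` exposes the
exact smoothed marginals the sampler draws from, and the test suite checks
the sampler against them. The collapsed model trades the haplotype-copying
accuracy of full painters for transparency and testability; the module
also accepts externally produced tract files (`readTractsBed()`,
`asPaintingReplicate()`), so output of a production painter can be
substituted at the same contract.

## Consensus and the candidate library

A position is *candidate target ancestry* iff at least `minSupport` of the
replicates (5 of 10: at least half) label it target. The rule is evaluated
per position, and maximal qualifying runs become consensus segments; the
alternative — evaluating support per painter-emitted segment — is
ill-defined when replicate breakpoints disagree, which is why the
position-level reduction was chosen. Consensus is monotone: a replicate
that labels everything target can only grow segments.

The candidate library balances donors — a fixed quota of samples per
subpopulation (default 10 from each of 3 descendant subpopulations, i.e.
60 haplotypes), selected by an explicit list or deterministic lexicographic
order. The per-base coverage `c(x)` counts library haplotypes whose
consensus segments cover `x`. Regions with `c(x)` below 20% of the library
size (12 of 60) are masked: too few candidates would make the mosaic
locally near-clonal.

## Mosaic assembly

Within each reconstructable region, assembly starts at the left edge; at
each junction one candidate haplotype covering the junction is drawn
uniformly at random and copied until the first of: 6000 bp (the chunk
cap), the end of that candidate's consensus segment, or the region end.
Two sampling conventions are reconciled as follows: *within* one haplotype
the immediately preceding source is excluded at the next junction whenever
an alternative covers it (no immediate self-continuation, which would
defeat the chunk cap); *across* haplotypes and genomes the library is
reused freely. Junctions are the only breakpoint source besides the cap:
interior disagreement between replicate boundaries is already absorbed by
the position-level consensus. Each haplotype is assembled under a child
seed derived from the master seed, so panels are reproducible and
haplotypes independent. Assembled haplotypes are paired sequentially into
diploid genomes — the genomes are population-level proxies, not
individuals, so the pairing carries no meaning.

Invariants maintained (and asserted in the tests): every emitted allele
equals its provenance source's allele; no provenance chunk exceeds the
cap; missingness in the output equals the coverage mask when donors are
fully observed (with donor missingness, copied gaps add to it).

At desk scale the relatedness of the output panel is checked with the KING
robust kinship estimator. With 10^3–10^4 simulated sites the per-pair
estimator noise is of the same order as the third-degree threshold
(0.0442), so the suite asserts that mean kinship is below the third-degree
threshold and no pair reaches second degree; the per-pair third-degree
claim only becomes testable at genome-scale site counts.

## Statistics

**Hudson FST.** Per site,
`num = (pA − pB)^2 − pA(1 − pA)/(nA − 1) − pB(1 − pB)/(nB − 1)` and
`den = pA(1 − pB) + pB(1 − pA)`; sites with fewer than two observed
alleles in either population are excluded. Genome-wide values are ratios
of sums; negative per-site values stay in the sums, and only the reported
genome-wide value is clamped at zero. To remove sample-size bias,
`pairwiseFstBalanced()` draws 9 samples per population (the smallest
population's size in the motivating design), 100 times, and summarizes the
replicate distribution. The balanced-estimator reference cited by the
motivating study does not print its formula; Hudson's estimator with
equal-size subsamples is used and labeled as such.

**Relative difference.** `RD(A,B;X) = (FST(A,X) − FST(B,X)) /
(FST(A,X) + FST(B,X))`, antisymmetric in (A, B) and bounded by 1 in
magnitude for nonnegative inputs; positive values mean X is closer to B.
Undefined when the denominator is not positive (returned as `NA`).

**Outgroup f3.** `mean((pO − pA)(pO − pB))` over jointly observed sites
with per-site available-sample frequencies (no imputation); the standard
error comes from a delete-one block jackknife over 5 Mb physical blocks
(block size is a free parameter; 5 Mb comfortably exceeds admixture LD
ranges). `rankByDrift()` ranks references by f3 for sparse queries,
flagging references below a joint-site minimum and breaking ties
lexicographically.

**Selection screens.** Sites failing a 10% missing-rate cap in any
analysis group are removed first. The top-tail screen flags the `k =
floor(q * n)` largest FST values, including ties at the threshold —
quantiles are computed on the post-filter site universe. *Extra SNVs* are
sites in the top 0.1% of the ancestral-vs-reference track but outside the
top 1% of the present-day track: differentiation that recent gene flow has
erased from the present-day population. The *gradient screen* requires the
reference frequency to be exactly fixed (a tolerance knob exists, default
0), an ancestral-vs-reference difference of at least 0.3, and a non-strict
monotone ordering ancestral → present-day → reference (strictness is not
specified by the motivating description; non-strict keeps boundary cases).
Sites masked in the reconstruction are ineligible for ancestral-panel
screens.

**Rare strong-effect variants.** In a closely related population group the
lower-frequency allele at a low-MAF site is taken as recently derived;
polarization uses the reference (Han) panel with a 20% MAF cap and
moderate/high effect classes from an external annotation table (no
annotation engine is bundled). A gene passes when (1) the reference panel
carries no derived allele, (2) more than 10% of target individuals carry
at least one, (3) the highest per-site derived frequency in the target
stays below 5%, and (4) at least two qualifying SNVs map to the gene.
"Samples" in criterion 2 are diploid individuals. The familial-aggregation
test is a two-sided Fisher exact test (minimum-likelihood summation
convention, which reproduces printed values) on the related/unrelated ×
sharing/non-sharing pair table; relatedness labels are an input.

**Divergence dating from Ne trajectories.** Per shared time bin the
reference populations' Ne mean and SD are pooled; the query is divergent
where it falls outside mean ± 3 SD (any difference counts when SD = 0,
e.g. with identical references). The estimate is the midpoint of the
*oldest* bin of the most recent run of consecutive divergent bins — the
earliest time range of the latest divergence, i.e. when the populations
began to diverge; the youngest-bin reading is selectable. The rule is
invariant to rescaling all Ne by a constant, so it applies equally to
coalescence-rate-scaled outputs.

**Linguistic distance.** `D = (−log10 s) × 100` elementwise on a lexical
similarity matrix (diagonal 1 → distance 0; similarity 0 → `Inf`
sentinel, which cannot be placed on a tree and is rejected by
`buildTree()`). Trees are neighbor-joining (`ape::nj`) — the method is a
package choice, as the motivating description names none — and NJ's
consistency on additive matrices makes topology recovery exactly testable.

## The synthetic-data generator

`simulatePanel()` draws ancestral frequencies Uniform(0.05, 0.95),
per-population frequencies from the Balding–Nichols distribution
Beta(p(1−F)/F, (1−p)(1−F)/F), i.i.d. source haplotypes, and admixed
haplotypes as single-pulse ancestry mosaics: sojourns in target ancestry
end at rate `r·g·(1−m)` per bp and sojourns in the other ancestry at
`r·g·m`, giving exponential tract lengths, stationary target fraction `m`,
and mean tract length `1/(r·g·m(1−m))`-scaled — with the defaults
(`r = 1e-8`, `g = 100`, `m = 0.5`) a mean tract of ~2 Mb, three orders of
magnitude above the 6 kb chunk cap, the regime in which re-chunking is
meaningful. Missingness is i.i.d. per genotype (both alleles drop
together). Coordinates are 0-based half-open internally; VCF output is
1-based.

Defaults emulate the motivating design qualitatively: a drifted target
pool (`HM`), a large reference exchanging recent migrants (`Han`), a
smaller outlying reference (`Dai`), a deeply drifted outgroup (`Mbuti`,
F = 0.6), and an admixed present-day population (`Yao`). Drift is set to
`F = 0.2` between sources — larger than realistic continental
differentiation — because the test instances carry 10^2–10^4 sparse
independent sites rather than millions of LD-linked ones; the per-window
information available to the painter is kept comparable by raising
per-site differentiation. What the generator does **not** model: linkage
disequilibrium within populations, recombination-map and mutation-rate
variation, sex chromosomes, archaic introgression, and correlated
missingness. Passing tests therefore demonstrate the correctness of the
algorithms under frequency differentiation and tract structure — the two
properties the pipeline consumes — not painter performance on real
LD-structured data.

`simulateNeTrajectories()` plants a divergence of a chosen effect size (in
noise-SD units; absolute when noise is 0) in all bins younger than a split
time, and `simulateRelatedPairs()` draws Bernoulli sharing indicators (or
forces exact counts) for the familial test.

## Numerical choices and degenerate inputs

- One documented PRNG stream per seeded operation; child seeds are drawn
  from the master seed by a single `sample.int`, and the caller's RNG
  state is always restored.
- Painting: emission 1 (skip) at donor-empty or query-missing sites; the
  switch probability cap 0.49 keeps transitions proper.
- Assembly: junction candidates are looked up on half-open intervals; the
  previous-source exclusion is waived when it is the only cover, so a
  one-haplotype library reproduces its donor exactly.
- FST: sites with `n < 2` excluded; genome-wide clamp at 0 only on
  report.
- Screens: `k < 1` for a quantile yields a warning and an empty flag set;
  ties at the threshold are all included.
- Fisher: degenerate margins return p = 1; infinite odds ratios pass
  through.
- NJ and drift ranking: ties break lexicographically.

## Problem sizes

The test and acceptance runs use 10^2–2×10^4 sites on 0.05–40 Mb
chromosomes, 10–80 diploid samples per population, 6–30 reconstructed
genomes, and 5–50 replicate Monte-Carlo comparisons; the balanced-FST
recovery run (20,000 sites, 30+30 samples, 100 replicate subsamples)
matches its independent 50-replicate simulation oracle. These sizes were
chosen so each verification isolates one property at the smallest scale
where its expected signal dominates Monte-Carlo noise.

## Known limitations

- The painter is a population-frequency HMM: on real, LD-rich data a
  haplotype-copying painter will outperform it; use external tract files
  for production painting.
- Reconstructed "genomes" are population-level resamples of the candidate
  library: they carry the ancestral gene pool's frequencies but not
  individual-level genealogies, and residual relatedness scales inversely
  with local library coverage.
- The gradient screen's literal fixation requirement is sensitive to
  reference sample size; the tolerance knob should be raised for small
  reference panels.
- Annotation (effect classes, gene intervals) and relatedness labels are
  external inputs by design.
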