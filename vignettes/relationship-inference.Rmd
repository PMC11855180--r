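---
title: "Inferring pairwise relationships from SNP genotypes: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pairwise relationships from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairkin)
```

## The problem

Given dense SNP genotypes for two individuals, how confidently can we say
whether they are full siblings, first, second or third cousins, or
unrelated? The question drives forensic investigative genetic genealogy,
where an unknown sample is matched against relatives in genealogy
databases, and it shapes the design of forensic kinship SNP panels. The
answer depends jointly on the statistical method and on the marker panel:
likelihood ratios extract the most from sparse panels, whereas
segment-based approaches need density but scale gracefully.

`pairkin` provides the complete loop for studying this: a pedigree
simulator with exact identity-by-descent (IBD) ground truth, five
inference methods, genotype-error injection, and a classification layer
that turns method outputs into one of five classes — S1 (full siblings,
1st degree), S2 (first cousins, 3rd), S3 (second cousins, 5th), S4 (third
cousins, 7th), Un (unrelated).

An outbred pair's relationship is summarised by the Cotterman coefficients
$(\kappa_0, \kappa_1, \kappa_2)$: the probabilities of sharing 0, 1 or 2
alleles identical by descent at a locus. The package's class table is

| class | degree | $\kappa_0,\kappa_1,\kappa_2$ | kinship $\phi=\kappa_1/4+\kappa_2/2$ |
|---|---|---|---|
| S1 | 1st | 1/4, 1/2, 1/4 | 0.25 |
| S2 | 3rd | 3/4, 1/4, 0 | 0.0625 |
| S3 | 5th | 15/16, 1/16, 0 | 0.015625 |
| S4 | 7th | 63/64, 1/64, 0 | 0.0039 |
| Un | — | 1, 0, 0 | 0 |

`kappaExact()` derives these values by enumerating every inheritance
vector through the explicit pedigrees rather than quoting them.

## The simulator

`simulateIBDTracks()` drops gametes through the pedigree connecting a pair
via a common-ancestor couple. Haplotypes are piecewise-constant
founder-label functions of genetic position; a meiosis samples crossover
positions and splices the parent's two haplotypes. Because founder labels
are globally unique, IBD at a position is simply label identity between
the pair's haplotypes, so the true IBD track (with level 1 = half
identical, level 2 = fully identical, the latter only for siblings) is a
by-product of the drop, not an approximation.

`simulatePair()` superimposes genotypes: founder haplotype alleles are
drawn independently per marker from the panel's allele frequencies
(linkage equilibrium) and propagated along the dropped haplotypes.
Genotypes are therefore consistent with the true track by construction.
Simulating founders from frequencies rather than re-using a real cohort's
haplotypes removes both background linkage disequilibrium (LD) and the
founder-reuse bias of resampling a finite reference panel; it also makes
the likelihood models' no-LD assumption exactly true. The flip side is
that passing tests here say nothing about robustness to real LD or to
population substructure — methods that ignore LD will look slightly
better on these data than on real genomes.

**Genetic map.** The default map (`buildDefaultMap()`) has 22 autosomes
with cM lengths proportional to a deCODE-like profile, total sex-averaged
length 3280 cM, and physical positions at a constant 1 Mb/cM. The total
is the genome length implied by expected full-sibling half-identical
sharing of 2460 cM ($0.75 \times 3280$). A single sex-averaged map is
used; sex-specific recombination is out of scope.

**Crossovers.** The default crossover process is a stationary
gamma-renewal (chi-square) model with shape $\nu = 2.63$, the refined
Housworth–Stahl interference strength for human meiosis; the first event
on each chromosome is drawn from the exact equilibrium delay
distribution. Interference matters less for mean sharing (which is pinned
by the kappas) than for dispersion: under the no-interference Haldane
model the probability that a third-cousin pair shares *no* IBD segment at
all is about 2.3% (we verified this against an exact killed-Markov-chain
computation over inheritance vectors), while under the interference model
it is about 1.0–1.1%, in line with the 1–2% typically reported for third
cousins. `interference = "poisson"` switches to Haldane; `nu` is
configurable. Even with interference, this fraction stays somewhat below
values reported from sex-specific-map simulations, because averaging the
sexes removes the lineage-composition variance in crossover counts —
a known, accepted limitation of the single-map design.

**Panels.** `makeFixturePanels()` builds schematic panels at the filtered
sizes of six published forensic/genealogy panels (92, 4073, 9618, 17231,
53593, 142350 markers), with positions uniform over the map and allele
frequencies from Beta(0.8, 0.8) truncated to [0.05, 0.95] — an
SNP-array-like ascertainment with common alleles only. Under this model
the probability that two unrelated individuals are opposite homozygotes
at a marker averages $q \approx 0.07$, a quantity several defaults below
are derived from.

**Errors.** `injectErrors()` mutates one individual's genotypes with
three per-marker rates: homozygote→heterozygote, homozygote→opposite
homozygote, heterozygote→homozygote. A collapsing heterozygote becomes
either homozygote with probability 1/2 — the natural symmetric choice for
an unspecified direction. `errorRateTable()` holds the six study rows
(0.5%/2% for the het-generating and het-collapsing types, 0.1%/1% for
opposite homozygotes).

## The five inference methods

**Likelihood ratio, linked.** `linkedLogLik()` evaluates the genotype
pair under a hypothesis with a hidden Markov model over IBD states along
each chromosome: stationary distribution equal to the hypothesis kappas,
transition kernel $P(d) = \Pi + e^{-ad}(I - \Pi)$ with reversion rate
$a = m/100$ per cM for $m$ meioses. Full siblings are modelled exactly as
two independent per-parent two-state chains with two meioses each; for
the unilineal classes the two-state chain is the standard close
approximation to the full Lander–Green computation. Chromosomes restart
at stationarity; the forward pass scales per marker, so likelihoods of
100k-marker pairs stay in range. At 100 cM spacing the model reduces to
the unlinked likelihood — the classical "fictive map" trick for treating
markers as independent.

**Likelihood ratio, unlinked.** `unlinkedLogLik()` is the composite
likelihood $\sum_m \log \sum_k \kappa_k P(g_a, g_b \mid k, p_m)$.
`lrClassify()` maximises either likelihood over the five hypotheses; ties
break toward the more distant class, a deliberately conservative rule
that suppresses false relatedness. An optional likelihood-ratio buffer
(`lrThreshold`) can declare near-ties inconclusive; it is off by default.

**ML kappa.** `mlKappa()` maximises the composite likelihood over the
kappa simplex by EM (E-step: per-marker posterior over the IBD state;
M-step: average), tolerance $10^{-8}$ relative, 500 iterations. The
composite log-likelihood is monotone across iterations. The EM is
warm-started from the KING-robust kinship estimate: when a true kappa
component is zero the optimum sits on the simplex boundary, which EM
approaches only geometrically, and a moment-based start roughly halves
the iterations spent on that crawl.
`kappaDistanceClassify()` picks the class whose reference kappa vector is
nearest in Euclidean distance. The reference table is kept as published —
including a third-cousin row (0.97, 0.0312, 0) that disagrees with the
closed-form pedigree value (63/64, 1/64, 0); we flag rather than silently
correct it, and all expectation checks use the closed form.

**KING-robust kinship.** `kingRobustPhi()` implements the
method-of-moments estimator from IBS counts; it needs no allele
frequencies. The published description makes the higher-heterozygosity
individual the reference (denominator) individual; the original source
uses the opposite convention. On frequency-matched simulated data both
conventions centre full-sibling estimates at 0.25 (we verified this), so
the package defaults to the higher-heterozygosity reading and exposes
`reference = "lower"`. `phiThresholdClassify()` bins estimates at
geometric midpoints of the class expectations ($2^{-3}, 2^{-5}, 2^{-7},
2^{-9}$); the lowest boundary continues the geometric ladder one step
below S4, boundary values go to the more distant class, and the bins
partition the whole line.

**Segment approach.** `callSegments()` finds maximal runs of markers with
no opposite homozygote (IBS0) — within true IBD at least one allele is
always shared, so IBS0 is impossible there absent errors — and keeps runs
spanning at least `minCM` (default 5 cM) with at least `minSnps` markers.
Zero IBS0 sites are tolerated inside a run. The span convention is first
to last marker of the run (the inner span), which slightly shrinks
segments at low density but never invents length.

The `minSnps` default matters more than it looks. With $q \approx 0.07$,
chance IBS0-free runs between true segments are long: at the ~10k-marker
density, requiring only 16 markers per segment would let chance runs
cover roughly 40% of the genome and push first cousins into the sibling
bin. Published implementations choose per-panel values by small optimization
studies whose numbers are generally not public, so `defaultMinSnps()` reconstructs
that calibration analytically: using the panel's IBS0 probability and
density, it picks the marker count at which the expected chance-run
length gained equals the expected true-segment length lost for a
first-cousin reference pair (segment lengths $\sim$ Exp(mean
$100/m$ cM)). This yields 62 markers for the 9618-marker panel and ~103
for the densest panel, and at 92 markers the requirement exceeds any
chromosome's marker count — segment calling is effectively disabled,
which is the right answer for a panel that sparse.

**Windowed kinship.** `windowedSegments()` tiles each chromosome with
windows of `windowSize` markers (default 60 at the 9618-marker panel
size, scaled proportionally, clamped to [30, 300]); a window seeds a
segment when its fraction of IBS ≥ 1 markers reaches `fMin` = 0.95, and
adjacent seeds merge into superwindows. The published description leaves
the superwindow decision rule open. The minimal reading — call a
superwindow IBD when the KING-robust kinship pooled over its markers
reaches `aMin` = 0.23 — under-detects badly here: chance seed windows
chain onto true IBD windows and dilute the pooled kinship (on the
9618-marker panel it recovers only ~47% of first-cousin sharing). The
package therefore calls a superwindow IBD when the pooled kinship *or any
member window's* kinship reaches `aMin`, which keeps seed-chain dilution
from masking a genuine IBD core. This rule is mean-calibrated (mean
called first-cousin total ~829 cM against an expected 818) and
reproduces the documented behaviour of the windowed approach, including
its inflated false-positive sharing on unrelated pairs. A two-phase
sliding variant was evaluated and rejected: it classifies slightly
better at S2 but over-extends calls by ~25%, which would systematically
push second cousins across the S2/S3 boundary.

## Classification and evaluation

`cmClassify()` bins total shared cM at geometric midpoints of the class
means (2460, 818, 298, 49, and 10 cM of chance sharing for unrelated):
boundaries ≈ 1419, 494, 121, 22 cM, boundary values to the more distant
class. The class-mean table is an argument, so a user can substitute a
different calibration. Note the published second-cousin mean (298 cM) is
internally inconsistent with the kappa-implied value (~205 cM on this
map); the bins keep the published table, and no expectation check uses
the S3 row.

`segmentFeatureClassify()` classifies on (segment count, mean segment
length) by nearest class centroid after z-scoring both features with
pooled standard deviations (`buildSegmentFeatureReference()` builds the
centroids from true-IBD simulations; the features live on incommensurate
scales, hence the scaling). `consensusClassify()` requires `k` methods to
agree, else returns inconclusive. `classificationMatrix()` tallies
row-stochastic classification-rate matrices, and
`errorImpactExperiment()` re-runs the error-sensitive methods (linked LR,
windowed kinship, plain segments) over the error-rate grid in a paired
design: the same simulated pairs and the same injection seeds are used in
every row, so the zero-error row reproduces the baseline bit for bit.

All tie-breaks package-wide use the fixed order S1 < S2 < S3 < S4 < Un
and resolve toward the more distant class.

## Numerical and degenerate-input choices

* Coordinates are 1-based bp and linear-interpolated cM; segments are
  closed cM intervals. Level-1 and level-2 true-IBD regions are counted
  once (half-identical union) before the length cutoff is applied.
* Likelihoods accumulate in log space with per-marker scaling; an
  observation that is impossible under a hypothesis yields $-\infty$
  flagged with the count of impossible markers.
* An empty marker set gives equal likelihoods for all hypotheses, and the
  tie rule then returns Un.
* Markers with a missing genotype in either individual (possible only for
  file-derived data) are excluded pairwise; missing sites never break a
  segment run.
* Every stochastic operation takes an explicit seed; batch experiments
  derive per-pair seeds from one master seed, and `runManifest()` records
  seeds and file digests for a run.

## Problem sizes used in the checks

The shipped checks simulate 2,000 pairs per class for expected-sharing
summaries (5,000 for third cousins, whose sharing is most variable),
10,000 third-cousin pairs for the zero-IBD fraction, and 500 (script) or
1,500 (test suite) first-cousin pairs on the 9618-marker panel for the
classification-rate comparison, with 100,000 replicate loci for
single-locus kappa recovery. These sizes put Monte-Carlo standard errors
well inside the tolerances asserted (e.g. binomial SE ≈ 0.12 percentage
points for the zero-IBD fraction, and ≈ 0.5 points on a 96% rate at
n = 1,500).

## Known limitations

* Founders are in linkage equilibrium: no LD, no haplotype structure, no
  allele-frequency misspecification. Real-data performance of the
  likelihood methods will be worse than these simulations suggest,
  particularly for dense panels where residual LD inflates relatedness.
* Unrelated pairs are frequency draws, so the background relatedness of a
  finite population sample is absent by construction.
* One sex-averaged map; no sex-specific recombination, no X/Y, no
  inbreeding, no half-relationships or once-removed classes.
* The segment-feature reference is built from true IBD tracks while the
  classifier consumes called segments; at low marker density the two
  diverge, and the feature classifier is accordingly weak there — a
  documented property of the approach, not a defect of the reference.
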