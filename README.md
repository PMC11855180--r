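# pairkin

Pairwise relationship inference from SNP genotypes, with a pedigree
simulator that carries exact identity-by-descent (IBD) ground truth.

## What problem this solves

Forensic investigative genetic genealogy and forensic kinship testing both
reduce to one question: given two genotyped individuals, are they full
siblings (S1), first cousins (S2), second cousins (S3), third cousins
(S4), or unrelated (Un)? Different communities answer it with different
statistics — likelihood ratios in forensics, shared-segment totals in
direct-to-consumer genealogy, method-of-moments kinship estimators in
cohort screening — and their relative merits depend strongly on how many
SNPs the panel provides. `pairkin` is for researchers who want to compare
these methods under controlled conditions: it simulates relative pairs
with known true IBD segments on a configurable genetic map, runs five
inference methods on the resulting genotypes, injects genotyping errors,
and tabulates classification rates.

An outbred pair's relationship is captured by the Cotterman coefficients
(κ0, κ1, κ2) — the probabilities of sharing 0, 1 or 2 alleles IBD at a
locus — with kinship φ = κ1/4 + κ2/2. The five methods are:

* **Linked likelihood ratio** — a hidden Markov model over IBD states
  along each chromosome (stationary distribution = the hypothesis kappas,
  reversion rate m/100 per cM for m meioses; siblings as two independent
  per-parent chains), maximised over the five hypotheses.
* **Unlinked likelihood ratio** — the composite likelihood
  Σ log Σₖ κₖ P(gₐ, g_b | k, p) treating markers as independent.
* **ML kappa** — EM maximisation of the composite likelihood over the
  kappa simplex, classified by Euclidean distance to class kappas.
* **KING-robust kinship** — the frequency-free method-of-moments
  estimator from IBS counts, classified by geometric-midpoint bins.
* **Segment / windowed-kinship approaches** — half-identical segment
  detection (plain maximal runs, or f/a-thresholded windows merged into
  superwindows), classified by total shared cM.

## Worked example

```r
library(pairkin)

map <- buildDefaultMap()                       # 22 autosomes, 3280 cM
panel <- makeFixturePanels(map, sizes = 9618, seed = 1)[[1]]

obs <- simulatePair("S2", panel, map, seed = 42)   # first cousins
trueIBDStats(obs, minCM = 5)$total_cm
#> [1] 929.3193

kingRobustPhi(obs)
#> [1] 0.06818843
phiThresholdClassify(kingRobustPhi(obs))
#> [1] "S2"

suppressWarnings(mlKappa(obs))$kappa
#>      kappa0      kappa1      kappa2
#> 0.724935705 0.269923352 0.005140943

lrClassify(obs)$loglik
#>        S1        S2        S3        S4        Un
#> -15651.25 -15615.17 -15638.36 -15674.41 -15861.88

totalSharedCM(callSegments(obs, map = map))
#> [1] 1218.893
cmClassify(totalSharedCM(callSegments(obs, map = map)))
#> [1] "S2"
```

The simulated pair truly shares 929 cM of half-identical genome (first
cousins average ~818 cM on this map; this pair drew a little more). The
KING kinship estimate 0.068 sits at the first-cousin expectation
(0.0625), the ML kappa estimate is close to the first-cousin vector
(0.75, 0.25, 0), the linked likelihood is maximised by the S2 hypothesis
(by a log-likelihood margin of ~23 over the next best), and the segment
caller's 1219 cM falls in the first-cousin bin (494–1419 cM): all five
routes classify this pair correctly.

Error sensitivity, consensus calling and classification-rate matrices:

```r
res <- errorImpactExperiment(panel, map, classes = c("S1", "S2", "Un"),
                             nPairs = 50, seed = 7)
res$baseline$segment          # row-stochastic classification-rate matrix
```

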