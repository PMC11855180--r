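#' @import methods
NULL

.CLASS_LEVELS <- c("S1", "S2", "S3", "S4", "Un")
.INCONCLUSIVE <- "INCONCLUSIVE"

#' GeneticMap: a piecewise-linear bp/cM coordinate system
#'
#' A sex-averaged genetic map over one or more chromosomes. Each chromosome
#' carries an ordered set of anchor points `(bp, cM)`; positions between
#' anchors are interpolated linearly, so the map defines a monotone bijection
#' between physical (base-pair) and genetic (centiMorgan) coordinates.
#'
#' @slot anchors data.frame with columns `chrom` (character), `bp` (numeric,
#'   1-based), `cM` (numeric). Within each chromosome, anchors are strictly
#'   increasing in both `bp` and `cM`, and the first anchor is at cM 0.
#'
#' @seealso [buildDefaultMap()], [bpToCm()], [cmToBp()], [totalCM()]
#' @export
setClass("GeneticMap", representation(anchors = "data.frame"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(a)))
    return("anchors must have columns chrom, bp, cM")
  if (nrow(a) < 2L) return("need at least two anchor points")
  for (ch in unique(a$chrom)) {
    x <- a[a$chrom == ch, , drop = FALSE]
    if (nrow(x) < 2L) return(sprintf("chromosome %s needs >= 2 anchors", ch))
    if (any(diff(x$bp) <= 0)) return(sprintf("bp not strictly increasing on %s", ch))
    if (any(diff(x$cM) <= 0)) return(sprintf("cM not strictly increasing on %s", ch))
    if (x$cM[1L] != 0) return(sprintf("first anchor on %s must be at cM 0", ch))
  }
  TRUE
})

#' SNPPanel: marker positions and allele frequencies defining a SNP panel
#'
#' @slot name single character label.
#' @slot markers data.frame with columns `chrom`, `bp`, `cM`, `freq`
#'   (alternative-allele frequency, strictly inside (0, 1)), sorted by
#'   `(chrom, bp)`.
#'
#' @seealso [makeFixturePanels()], [readPanel()], [nMarkers()]
#' @export
setClass("SNPPanel", representation(name = "character", markers = "data.frame"))

setValidity("SNPPanel", function(object) {
  m <- object@markers
  need <- c("chrom", "bp", "cM", "freq")
  if (!all(need %in% names(m)))
    return("markers must have columns chrom, bp, cM, freq")
  if (length(object@name) != 1L) return("name must be a single string")
  if (any(m$freq <= 0 | m$freq >= 1))
    return("allele frequencies must lie strictly in (0, 1)")
  for (ch in unique(m$chrom)) {
    x <- m[m$chrom == ch, , drop = FALSE]
    if (is.unsorted(x$bp, strictly = TRUE))
      return(sprintf("markers not sorted / not unique in bp on %s", ch))
    if (is.unsorted(x$cM))
      return(sprintf("marker cM positions not sorted on %s", ch))
  }
  TRUE
})

#' RelationshipSpec: a pairwise relationship class
#'
#' Describes one of the five study classes: full siblings (S1), first cousins
#' (S2), second cousins (S3), third cousins (S4) or unrelated (Un). The kappa
#' slot holds the Cotterman coefficients (probabilities of sharing 0, 1 or 2
#' alleles identical by descent at a locus) implied by the pedigree.
#'
#' @slot label one of "S1", "S2", "S3", "S4", "Un".
#' @slot degree integer degree of relationship (1, 3, 5, 7; NA for unrelated).
#' @slot kappa numeric(3), closed-form pedigree Cotterman coefficients.
#' @slot meioses for the unilineal classes S2--S4 the total number of meioses
#'   on the path connecting the pair through the common-ancestor couple (4, 6,
#'   8); for S1 the number of meioses per parental lineage (2); NA for Un.
#' @slot nCommonAncestors 2 for S1--S4, 0 for Un.
#'
#' @seealso [relationshipSpec()], [kappaExact()]
#' @export
setClass("RelationshipSpec",
         representation(label = "character", degree = "integer",
                        kappa = "numeric", meioses = "numeric",
                        nCommonAncestors = "integer"))

setValidity("RelationshipSpec", function(object) {
  if (!object@label %in% .CLASS_LEVELS) return("unknown relationship label")
  k <- object@kappa
  if (length(k) != 3L || any(k < 0 | k > 1)) return("kappa must be 3 probabilities")
  if (abs(sum(k) - 1) > 1e-12) return("kappa must sum to 1")
  TRUE
})

#' PairObservation: two individuals' genotypes on a panel
#'
#' Genotypes are alternative-allele dosages in \{0, 1, 2\} (NA for missing,
#' which only occurs for data read from files). For simulated pairs the phased
#' haplotype dosages and the true IBD segment track are retained.
#'
#' @slot genotypesA,genotypesB integer vectors, one entry per panel marker.
#' @slot panel the [SNPPanel-class] the genotypes are aligned to.
#' @slot trueIBD data.frame of true IBD segments with columns `chrom`,
#'   `start_cm`, `end_cm`, `start_bp`, `end_bp`, `level` (1 = half-identical,
#'   2 = fully identical), or NULL for real data.
#' @slot haplotypesA,haplotypesB optional 2-row 0/1 matrices of phased
#'   haplotype alleles (NULL when phase is unknown, e.g. after error
#'   injection).
#'
#' @seealso [simulatePair()], [simulateUnrelatedPair()], [readVcfPair()]
#' @export
setClass("PairObservation",
         representation(genotypesA = "integer", genotypesB = "integer",
                        panel = "SNPPanel", trueIBD = "ANY",
                        haplotypesA = "ANY", haplotypesB = "ANY"))

setValidity("PairObservation", function(object) {
  n <- nMarkers(object@panel)
  ga <- object@genotypesA; gb <- object@genotypesB
  if (length(ga) != n || length(gb) != n)
    return("genotype vectors must match the panel marker count")
  ok <- function(g) all(is.na(g) | (g >= 0L & g <= 2L))
  if (!ok(ga) || !ok(gb)) return("genotype codes must be 0, 1, 2 or NA")
  TRUE
})

#' ErrorModel: per-marker genotyping error rates
#'
#' Errors are applied independently per marker to one individual of a pair:
#' a homozygote can turn heterozygote, a homozygote can turn into the
#' opposite homozygote, and a heterozygote can collapse to a homozygote
#' (either one with probability 1/2).
#'
#' @slot homToHet,homToOpp probabilities applied to homozygous markers.
#' @slot hetToHom probability applied to heterozygous markers.
#'
#' @seealso [errorModel()], [injectErrors()], [errorRateTable()]
#' @export
setClass("ErrorModel",
         representation(homToHet = "numeric", homToOpp = "numeric",
                        hetToHom = "numeric"))

setValidity("ErrorModel", function(object) {
  r <- c(object@homToHet, object@homToOpp, object@hetToHom)
  if (length(r) != 3L || any(r < 0 | r > 1)) return("rates must lie in [0, 1]")
  if (object@homToHet + object@homToOpp > 1)
    return("homToHet + homToOpp must not exceed 1")
  TRUE
})
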