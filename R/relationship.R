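# Relationship classes, closed-form and enumerated Cotterman coefficients.

.REL_REGISTRY <- list(
  S1 = list(degree = 1L, meioses = 2, gens = NA_integer_, nca = 2L),
  S2 = list(degree = 3L, meioses = 4, gens = 1L, nca = 2L),
  S3 = list(degree = 5L, meioses = 6, gens = 2L, nca = 2L),
  S4 = list(degree = 7L, meioses = 8, gens = 3L, nca = 2L),
  Un = list(degree = NA_integer_, meioses = NA_real_, gens = NA_integer_,
            nca = 0L))

#' Closed-form Cotterman coefficients for a study class
#'
#' Full siblings have kappa (1/4, 1/2, 1/4). For the unilineal classes
#' connected through a common-ancestor couple by `m` meioses (first cousins
#' m = 4, second cousins m = 6, third cousins m = 8), kappa1 = 2^(2 - m) and
#' kappa2 = 0. Unrelated pairs have kappa (1, 0, 0).
#'
#' @param label one of "S1", "S2", "S3", "S4", "Un".
#' @return numeric(3): (kappa0, kappa1, kappa2).
#' @examples
#' kappaClosedForm("S2")  # c(0.75, 0.25, 0)
#' @export
kappaClosedForm <- function(label) {
  label <- match.arg(label, .CLASS_LEVELS)
  switch(label,
         S1 = c(0.25, 0.5, 0.25),
         Un = c(1, 0, 0),
         {
           m <- .REL_REGISTRY[[label]]$meioses
           k1 <- 2^(2 - m)
           c(1 - k1, k1, 0)
         })
}

#' Construct a RelationshipSpec
#'
#' @param label one of "S1" (full siblings), "S2" (first cousins),
#'   "S3" (second cousins), "S4" (third cousins), "Un" (unrelated).
#' @return a [RelationshipSpec-class] carrying the class degree, closed-form
#'   pedigree kappa vector and meiosis structure.
#' @examples
#' relationshipSpec("S3")
#' @export
relationshipSpec <- function(label) {
  label <- match.arg(label, .CLASS_LEVELS)
  r <- .REL_REGISTRY[[label]]
  new("RelationshipSpec", label = label, degree = r$degree,
      kappa = kappaClosedForm(label), meioses = r$meioses,
      nCommonAncestors = r$nca)
}

setMethod("show", "RelationshipSpec", function(object) {
  cat(sprintf("RelationshipSpec %s (degree %s): kappa = (%s)\n",
              object@label,
              ifelse(is.na(object@degree), ">7", object@degree),
              paste(signif(object@kappa, 6), collapse = ", ")))
})

.asSpec <- function(spec) {
  if (is(spec, "RelationshipSpec")) spec else relationshipSpec(spec)
}

# Lineage transmission bits -> single-locus IBD state.
#
# All pedigrees connect the pair through a founder couple with haplotype
# labels 1:4. Each meiosis at a single locus is one bit (which parental
# haplotype is transmitted). Returns the IBD state given a matrix of bits,
# one column per meiosis, encoded as the pair's lineage founder-allele labels.
.singleLocusLabels <- function(label, bits) {
  # bits: n x m matrix of 0/1 draws, columns in a fixed meiosis order.
  # Returns list(a1, a2, b1, b2) of founder labels (0 = private/unrelated).
  pickA <- function(b) 1L + b        # gamete from founder A: haplotype 1 or 2
  pickB <- function(b) 3L + b        # gamete from founder B: haplotype 3 or 4
  if (label == "S1") {
    # bits: sibX from father, sibX from mother (4 meioses)
    list(a1 = pickA(bits[, 1L]), a2 = pickB(bits[, 2L]),
         b1 = pickA(bits[, 3L]), b2 = pickB(bits[, 4L]))
  } else {
    gens <- .REL_REGISTRY[[label]]$gens
    # Children of the founder couple: C1, C2, each with haplotypes
    # (from A, from B); one meiosis per gamete.
    c1 <- cbind(pickA(bits[, 1L]), pickB(bits[, 2L]))
    c2 <- cbind(pickA(bits[, 3L]), pickB(bits[, 4L]))
    col <- 5L
    for (g in seq_len(gens)) {
      # lineage gamete from current carrier; spouse side is unrelated (0)
      pick <- function(cc, b) cc[cbind(seq_len(nrow(cc)), 1L + b)]
      c1 <- cbind(pick(c1, bits[, col]), 0L)
      c2 <- cbind(pick(c2, bits[, col + 1L]), 0L)
      col <- col + 2L
    }
    list(a1 = c1[, 1L], a2 = c1[, 2L], b1 = c2[, 1L], b2 = c2[, 2L])
  }
}

.ibdFromLabels <- function(lab) {
  eq <- function(x, y) (x == y) & x != 0L
  m1 <- eq(lab$a1, lab$b1) + eq(lab$a2, lab$b2)
  m2 <- eq(lab$a1, lab$b2) + eq(lab$a2, lab$b1)
  pmax(m1, m2)
}

.nMeiosisBits <- function(label) {
  if (label == "S1") 4L else 4L + 2L * .REL_REGISTRY[[label]]$gens
}

#' Exact single-locus IBD-state probabilities by enumeration
#'
#' Enumerates every inheritance vector (one bit per meiosis) through the
#' explicit pedigree connecting the pair via a common-ancestor couple and
#' tallies the IBD state of the pair at a single locus. This is an exact,
#' deterministic computation of the Cotterman coefficients from the pedigree
#' structure itself.
#'
#' @param spec a [RelationshipSpec-class] or class label.
#' @return numeric(3): exact (kappa0, kappa1, kappa2).
#' @examples
#' kappaExact("S2")  # c(0.75, 0.25, 0)
#' @export
kappaExact <- function(spec) {
  spec <- .asSpec(spec)
  if (spec@label == "Un") return(c(kappa0 = 1, kappa1 = 0, kappa2 = 0))
  nb <- .nMeiosisBits(spec@label)
  grid <- as.matrix(expand.grid(rep(list(0:1), nb)))
  ibd <- .ibdFromLabels(.singleLocusLabels(spec@label, grid))
  p <- tabulate(ibd + 1L, 3L) / nrow(grid)
  c(kappa0 = p[1L], kappa1 = p[2L], kappa2 = p[3L])
}

#' Single-locus gene-dropping estimate of the Cotterman coefficients
#'
#' Drops alleles through the pedigree at one unlinked locus `n` times and
#' returns the empirical IBD-state frequencies. Used as a Monte-Carlo check
#' that the transmission machinery reproduces the closed-form kappas.
#'
#' @param spec a [RelationshipSpec-class] or class label.
#' @param n number of replicate loci.
#' @param seed optional integer seed.
#' @return numeric(3) of empirical (kappa0, kappa1, kappa2).
#' @export
kappaGeneDrop <- function(spec, n = 1e5, seed = NULL) {
  spec <- .asSpec(spec)
  if (!is.null(seed)) set.seed(seed)
  if (spec@label == "Un") return(c(kappa0 = 1, kappa1 = 0, kappa2 = 0))
  nb <- .nMeiosisBits(spec@label)
  bits <- matrix(sample(0:1, n * nb, replace = TRUE), ncol = nb)
  ibd <- .ibdFromLabels(.singleLocusLabels(spec@label, bits))
  p <- tabulate(ibd + 1L, 3L) / n
  c(kappa0 = p[1L], kappa1 = p[2L], kappa2 = p[3L])
}
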