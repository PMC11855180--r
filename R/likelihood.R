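# Pairwise relationship likelihoods: unlinked (composite) and linked
# (hidden Markov model over IBD states along the genetic map).

#' Joint genotype-pair probability conditional on the IBD state
#'
#' The standard Cotterman decomposition: conditional on sharing `k` alleles
#' identical by descent at a biallelic locus with alternative-allele
#' frequency `p`, the joint probability of the ordered genotype pair
#' (dosages 0/1/2) is the product of Hardy-Weinberg draws for the non-shared
#' alleles. For example P(0, 0 | k = 0) = (1-p)^4 and
#' P(0, 0 | k = 1) = (1-p)^3; the k = 2 table is diagonal.
#'
#' @param gA,gB genotype codes in \{0, 1, 2\} (vectorised).
#' @param p alternative-allele frequency in (0, 1).
#' @param k IBD state: 0, 1 or 2.
#' @return numeric vector of probabilities.
#' @examples
#' genotypePairProb(0, 0, p = 0.5, k = 0)  # 0.0625
#' @export
genotypePairProb <- function(gA, gB, p, k) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(!k %in% 0:2)) stop("k must be 0, 1 or 2")
  bad <- function(g) any(is.na(g)) || any(!g %in% 0:2)
  if (bad(gA) || bad(gB)) stop("genotype codes must be 0, 1 or 2")
  q <- 1 - p
  hw <- function(g) ifelse(g == 0, q^2, ifelse(g == 1, 2 * p * q, p^2))
  # P(g | one allele fixed to z): z = alt or ref
  gAlt <- function(g) ifelse(g == 0, 0, ifelse(g == 1, q, p))
  gRef <- function(g) ifelse(g == 0, q, ifelse(g == 1, p, 0))
  out <- numeric(length(gA) * 0 + max(length(gA), length(gB), length(p)))
  k <- rep_len(k, length(out))
  gA <- rep_len(gA, length(out)); gB <- rep_len(gB, length(out))
  p <- rep_len(p, length(out)); q <- 1 - p
  i0 <- k == 0; i1 <- k == 1; i2 <- k == 2
  if (any(i0)) out[i0] <- (hw(gA) * hw(gB))[i0]
  if (any(i1)) out[i1] <- (p * gAlt(gA) * gAlt(gB) + q * gRef(gA) * gRef(gB))[i1]
  if (any(i2)) out[i2] <- (hw(gA) * (gA == gB))[i2]
  out
}

# Per-marker emission tables: 9 x M matrix per IBD state, rows indexed by
# code = gA * 3 + gB + 1.
.emissionTables <- function(p) {
  q <- 1 - p
  hw0 <- q^2; hw1 <- 2 * p * q; hw2 <- p^2
  T0 <- rbind(hw0 * hw0, hw0 * hw1, hw0 * hw2,
              hw1 * hw0, hw1 * hw1, hw1 * hw2,
              hw2 * hw0, hw2 * hw1, hw2 * hw2)
  # k = 1: shared allele z ~ Bernoulli(p); P(g|z=alt): (0, q, p); ref: (q, p, 0)
  a0 <- 0; a1 <- q; a2 <- p
  r0 <- q; r1 <- p; r2 <- 0
  T1 <- rbind(p * a0 * a0 + q * r0 * r0, p * a0 * a1 + q * r0 * r1,
              p * a0 * a2 + q * r0 * r2,
              p * a1 * a0 + q * r1 * r0, p * a1 * a1 + q * r1 * r1,
              p * a1 * a2 + q * r1 * r2,
              p * a2 * a0 + q * r2 * r0, p * a2 * a1 + q * r2 * r1,
              p * a2 * a2 + q * r2 * r2)
  zero <- numeric(length(p))
  T2 <- rbind(hw0, zero, zero, zero, hw1, zero, zero, zero, hw2)
  list(T0 = T0, T1 = T1, T2 = T2)
}

.pairCodes <- function(obs) {
  code <- obs@genotypesA * 3L + obs@genotypesB + 1L
  code
}

#' Composite (unlinked) pairwise log-likelihood
#'
#' Treats markers as independent: the log-likelihood is the sum over markers
#' of log of the kappa mixture of conditional genotype-pair probabilities.
#' Markers with a missing genotype in either individual are skipped.
#'
#' If an observation is impossible under the supplied kappa (for instance
#' opposite homozygotes under kappa = (0, 0, 1)), the function returns `-Inf`
#' with attribute `n_zero_markers` giving the number of impossible markers.
#'
#' @param obs a [PairObservation-class].
#' @param kappa numeric(3) Cotterman coefficients, or a
#'   [RelationshipSpec-class] / class label.
#' @param freqs optional per-marker frequencies (defaults to the panel's).
#' @return log-likelihood (scalar).
#' @export
unlinkedLogLik <- function(obs, kappa, freqs = NULL) {
  if (is.character(kappa) || is(kappa, "RelationshipSpec"))
    kappa <- .asSpec(kappa)@kappa
  stopifnot(length(kappa) == 3L, abs(sum(kappa) - 1) < 1e-9)
  p <- if (is.null(freqs)) obs@panel@markers$freq else freqs
  keep <- !is.na(obs@genotypesA) & !is.na(obs@genotypesB)
  if (!any(keep)) return(0)
  p <- p[keep]
  tb <- .emissionTables(p)
  code <- (obs@genotypesA[keep] * 3L + obs@genotypesB[keep] + 1L)
  idx <- cbind(code, seq_along(code))
  lik <- kappa[1L] * tb$T0[idx] + kappa[2L] * tb$T1[idx] + kappa[3L] * tb$T2[idx]
  nz <- sum(lik == 0)
  if (nz > 0L) return(structure(-Inf, n_zero_markers = nz))
  sum(log(lik))
}

# Continuous reversion-to-stationarity transition matrix for the pairwise
# IBD process: P(d) = Pi + exp(-a d) (I - Pi), rows of Pi equal the
# stationary vector; a = meioses / 100 per cM.
.ibdTransition <- function(d, stationary, a) {
  ns <- length(stationary)
  Pi <- matrix(stationary, ns, ns, byrow = TRUE)
  Pi + exp(-a * d) * (diag(ns) - Pi)
}

# Batch forward log-likelihood. GA, GB: n x M genotype matrices (no NAs).
# Returns n-vector of log-likelihoods under `spec`.
.linkedLogLikBatch <- function(GA, GB, panel, spec) {
  spec <- .asSpec(spec)
  m <- panel@markers
  n <- nrow(GA)
  ll <- numeric(n)
  for (ch in unique(m$chrom)) {
    j <- which(m$chrom == ch)
    p <- m$freq[j]; cm <- m$cM[j]
    if (is.unsorted(cm)) stop("markers must be ordered along the map")
    tb <- .emissionTables(p)
    off <- 9L * (seq_along(j) - 1L)
    code <- GA[, j, drop = FALSE] * 3L + GB[, j, drop = FALSE] + 1L
    idx <- as.vector(sweep(code, 2L, off, "+"))
    E0 <- matrix(tb$T0[idx], n); E1 <- matrix(tb$T1[idx], n)
    if (spec@label == "Un") {
      ll <- ll + rowSums(log(E0))
      next
    }
    d <- diff(cm)
    if (spec@label == "S1") {
      E2 <- matrix(tb$T2[idx], n)
      a <- spec@meioses / 100          # 2 meioses per parental chain
      ed <- exp(-a * d)
      # two independent two-state chains (paternal, maternal), each with
      # stationary (1/2, 1/2); state columns (c1, c2): 00, 10, 01, 11
      a00 <- 0.25 * E0[, 1L]; a10 <- 0.25 * E1[, 1L]
      a01 <- 0.25 * E1[, 1L]; a11 <- 0.25 * E2[, 1L]
      s <- a00 + a10 + a01 + a11
      llc <- log(s)
      a00 <- a00 / s; a10 <- a10 / s; a01 <- a01 / s; a11 <- a11 / s
      for (t in seq_along(d)) {
        e <- ed[t]
        # chain 1 update (mix toward 1/2 within each c2 layer)
        m0 <- a00 + a10; m1 <- a01 + a11
        a00 <- 0.5 * (1 - e) * m0 + e * a00
        a10 <- 0.5 * (1 - e) * m0 + e * a10
        a01 <- 0.5 * (1 - e) * m1 + e * a01
        a11 <- 0.5 * (1 - e) * m1 + e * a11
        # chain 2 update (mix within each c1 layer)
        m0 <- a00 + a01; m1 <- a10 + a11
        a00 <- 0.5 * (1 - e) * m0 + e * a00
        a01 <- 0.5 * (1 - e) * m0 + e * a01
        a10 <- 0.5 * (1 - e) * m1 + e * a10
        a11 <- 0.5 * (1 - e) * m1 + e * a11
        k <- t + 1L
        a00 <- a00 * E0[, k]
        a10 <- a10 * E1[, k]; a01 <- a01 * E1[, k]
        a11 <- a11 * E2[, k]
        s <- a00 + a10 + a01 + a11
        llc <- llc + log(s)
        a00 <- a00 / s; a10 <- a10 / s; a01 <- a01 / s; a11 <- a11 / s
      }
      ll <- ll + llc
    } else {
      # two-state chain over IBD in {0, 1}
      k0 <- spec@kappa[1L]; k1 <- spec@kappa[2L]
      a <- spec@meioses / 100
      ed <- exp(-a * d)
      al0 <- k0 * E0[, 1L]; al1 <- k1 * E1[, 1L]
      s <- al0 + al1
      llc <- log(s)
      al0 <- al0 / s; al1 <- al1 / s
      for (t in seq_along(d)) {
        e <- ed[t]
        n0 <- k0 * (1 - e) + e * al0
        n1 <- k1 * (1 - e) + e * al1
        k <- t + 1L
        al0 <- n0 * E0[, k]; al1 <- n1 * E1[, k]
        s <- al0 + al1
        llc <- llc + log(s)
        al0 <- al0 / s; al1 <- al1 / s
      }
      ll <- ll + llc
    }
  }
  ll
}

#' Linked pairwise log-likelihood (IBD hidden Markov model)
#'
#' Evaluates the pair's genotype likelihood under a relationship hypothesis
#' while accounting for genetic linkage (but not linkage disequilibrium).
#' The latent IBD state along each chromosome follows a Markov process with
#' stationary distribution equal to the relationship's kappa vector and
#' reversion rate m/100 per cM, where m is the number of meioses separating
#' the pair; full siblings are modelled exactly as two independent per-parent
#' two-state chains with 2 meioses each. Chromosomes are independent (the
#' chain restarts at stationarity) and the forward pass is scaled per marker,
#' so the result is returned in log space.
#'
#' In the limit of 100 cM marker spacing this reduces to [unlinkedLogLik()].
#'
#' @param obs a [PairObservation-class] (markers with missing genotypes are
#'   dropped before the forward pass).
#' @param spec a [RelationshipSpec-class] or class label.
#' @param map unused for simulated panels (marker cM positions come from the
#'   panel); accepted for interface symmetry.
#' @param freqs optional per-marker frequencies (defaults to the panel's).
#' @return log-likelihood (scalar).
#' @export
linkedLogLik <- function(obs, spec, map = NULL, freqs = NULL) {
  keep <- !is.na(obs@genotypesA) & !is.na(obs@genotypesB)
  panel <- obs@panel
  if (!all(keep)) {
    panel <- new("SNPPanel", name = panel@name,
                 markers = panel@markers[keep, , drop = FALSE])
  }
  if (!is.null(freqs)) panel@markers$freq <- freqs[keep]
  if (nMarkers(panel) == 0L) return(0)
  GA <- matrix(obs@genotypesA[keep], 1L)
  GB <- matrix(obs@genotypesB[keep], 1L)
  .linkedLogLikBatch(GA, GB, panel, spec)[1L]
}

#' Maximum-likelihood relationship classification
#'
#' Computes the log-likelihood of the genotype pair under each of the five
#' relationship hypotheses (S1, S2, S3, S4, Un) -- with the linked model or
#' the unlinked composite likelihood -- and reports the class with the
#' highest likelihood. Ties are broken toward the more distant class. An
#' optional likelihood-ratio buffer declares the call inconclusive when the
#' best hypothesis does not beat the runner-up by at least `lrThreshold`.
#'
#' @param obs a [PairObservation-class].
#' @param mode "linked" or "unlinked".
#' @param map optional [GeneticMap-class] (interface symmetry).
#' @param freqs optional per-marker frequencies.
#' @param lrThreshold optional ratio (not log) the best hypothesis must
#'   exceed over the second best; NULL (default) disables the buffer.
#' @return list with `call` (character class or "INCONCLUSIVE") and
#'   `loglik` (named numeric(5)).
#' @export
lrClassify <- function(obs, mode = c("linked", "unlinked"), map = NULL,
                       freqs = NULL, lrThreshold = NULL) {
  mode <- match.arg(mode)
  ll <- vapply(.CLASS_LEVELS, function(h) {
    if (mode == "linked") linkedLogLik(obs, h, map = map, freqs = freqs)
    else as.numeric(unlinkedLogLik(obs, h, freqs = freqs))
  }, numeric(1))
  call <- .argmaxDistant(ll)
  if (!is.null(lrThreshold)) {
    o <- sort(ll, decreasing = TRUE)
    if (is.finite(o[2L]) && exp(o[1L] - o[2L]) < lrThreshold)
      call <- .INCONCLUSIVE
  }
  list(call = call, loglik = ll)
}

# argmax over the class order S1 < S2 < S3 < S4 < Un, ties toward the more
# distant class (larger index).
.argmaxDistant <- function(ll, tol = 1e-9) {
  best <- max(ll)
  .CLASS_LEVELS[max(which(ll >= best - tol))]
}
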