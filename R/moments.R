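# Method-of-moments kinship (KING-robust), ML kappa estimation (EM), and
# their classifiers.

#' Identity-by-state count summary for a pair
#'
#' Tallies, over markers where both genotypes are non-missing: the number of
#' markers where both individuals are heterozygous, the number of opposite
#' homozygotes, and each individual's heterozygote count.
#'
#' @param obs a [PairObservation-class].
#' @return list of class `IBSCounts` with elements `nHetHet`, `nOppHom`,
#'   `nHetA`, `nHetB`, `nMarkers`.
#' @export
ibsCounts <- function(obs) {
  ga <- obs@genotypesA; gb <- obs@genotypesB
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  structure(list(
    nHetHet = sum(ga == 1L & gb == 1L),
    nOppHom = sum((ga == 0L & gb == 2L) | (ga == 2L & gb == 0L)),
    nHetA = sum(ga == 1L),
    nHetB = sum(gb == 1L),
    nMarkers = length(ga)), class = "IBSCounts")
}

#' KING-robust kinship estimator
#'
#' Method-of-moments kinship estimate from IBS count summaries:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{2 N^{(i)}_{Aa}}
#'   + \frac12 - \frac{N^{(i)}_{Aa} + N^{(j)}_{Aa}}{4 N^{(i)}_{Aa}}}
#' where \eqn{N^{(i)}_{Aa}} is the heterozygote count of the reference
#' individual. When called on an `IBSCounts` object, individual A is the
#' reference. When called on a [PairObservation-class], the reference is
#' chosen by the `reference` convention; the default ("higher"
#' heterozygosity) is the convention that recovers a mean estimate of 0.25
#' on simulated full-sibling pairs (both conventions do on frequency-matched
#' data, and both are exposed).
#'
#' The estimator needs no allele frequencies. A self-comparison (identical
#' genotypes) gives exactly 0.5; unrelated pairs are centred at 0.
#'
#' @param x an `IBSCounts` list (from [ibsCounts()]) or a
#'   [PairObservation-class].
#' @param reference "higher" (default) or "lower": which individual's
#'   heterozygote count is the denominator \eqn{N^{(i)}_{Aa}}.
#' @return kinship estimate (scalar); NA with a warning when the reference
#'   individual has no heterozygous markers.
#' @examples
#' kingRobustPhi(structure(list(nHetHet = 100, nOppHom = 10, nHetA = 200,
#'                              nHetB = 300, nMarkers = 1000),
#'                         class = "IBSCounts"))  # 0.075
#' @export
kingRobustPhi <- function(x, reference = c("higher", "lower")) {
  reference <- match.arg(reference)
  if (is(x, "PairObservation")) {
    cnt <- ibsCounts(x)
    swap <- (reference == "higher") == (cnt$nHetB > cnt$nHetA)
    if (swap) {
      tmp <- cnt$nHetA; cnt$nHetA <- cnt$nHetB; cnt$nHetB <- tmp
    }
    x <- cnt
  }
  if (x$nHetA == 0L) {
    warning("reference individual has no heterozygous markers; phi undefined")
    return(NA_real_)
  }
  (x$nHetHet - 2 * x$nOppHom) / (2 * x$nHetA) + 0.5 -
    (x$nHetA + x$nHetB) / (4 * x$nHetA)
}

#' Maximum-likelihood estimation of the Cotterman coefficients
#'
#' Maximises the composite (linkage-ignoring) log-likelihood
#' \eqn{\sum_m \log \sum_k \kappa_k P(g_a, g_b | k, p_m)} over the
#' 2-simplex with an EM algorithm: the E-step computes the per-marker
#' posterior over the IBD state, the M-step averages it. The composite
#' log-likelihood is non-decreasing across iterations. The EM is
#' warm-started from the KING-robust kinship estimate (an interior simplex
#' point consistent with the method-of-moments relatedness), which shortens
#' the slow boundary approach when a true kappa component is 0.
#'
#' @param obs a [PairObservation-class].
#' @param freqs optional per-marker frequencies (defaults to the panel's).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return list with `kappa` (numeric(3)), `loglik`, `iterations`,
#'   `converged`, `n_markers`.
#' @export
mlKappa <- function(obs, freqs = NULL, tol = 1e-8, maxIter = 500L) {
  p <- if (is.null(freqs)) obs@panel@markers$freq else freqs
  keep <- !is.na(obs@genotypesA) & !is.na(obs@genotypesB)
  p <- p[keep]
  if (length(p) < 2L) stop("need at least 2 markers")
  tb <- .emissionTables(p)
  code <- obs@genotypesA[keep] * 3L + obs@genotypesB[keep] + 1L
  idx <- cbind(code, seq_along(code))
  P <- rbind(tb$T0[idx], tb$T1[idx], tb$T2[idx])
  phi <- suppressWarnings(kingRobustPhi(obs))
  kap <- if (is.na(phi)) rep(1 / 3, 3) else {
    phi <- max(0, min(0.49, phi))
    k <- c(0, max(0.02, min(0.96, 4 * phi)), max(0.01, 4 * phi^2))
    k[1L] <- max(0.02, 1 - k[2L] - k[3L])
    k / sum(k)
  }
  llOld <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    W <- kap * P
    s <- colSums(W)
    ll <- sum(log(s))
    kap <- rowMeans(W / rep(s, each = 3L))
    if (is.finite(llOld) && (ll - llOld) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    llOld <- ll
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations; last iterate returned")
  list(kappa = c(kappa0 = kap[1L], kappa1 = kap[2L], kappa2 = kap[3L]),
       loglik = ll, iterations = it, converged = converged,
       n_markers = length(p))
}

#' Kinship-threshold relationship classifier
#'
#' Bins a kinship estimate into the five study classes using geometric
#' midpoints between the expected kinship values
#' (phi = kappa1/4 + kappa2/2: 0.25, 0.0625, 0.015625, 0.00390625 for
#' S1--S4). Boundaries are 0.125, 0.03125, 0.0078125 and 0.001953125 (the
#' geometric ladder continued one step below S4); values at a boundary are
#' assigned to the more distant class, so the bins partition the whole line.
#'
#' @param phi kinship estimate(s).
#' @return character vector of class calls.
#' @examples
#' phiThresholdClassify(c(0.25, 0))  # "S1", "Un"
#' @export
phiThresholdClassify <- function(phi) {
  b <- c(2^-3, 2^-5, 2^-7, 2^-9)
  out <- ifelse(phi > b[1L], "S1",
         ifelse(phi > b[2L], "S2",
         ifelse(phi > b[3L], "S3",
         ifelse(phi > b[4L], "S4", "Un"))))
  out[is.na(phi)] <- .INCONCLUSIVE
  out
}

#' Expected kappa vectors used for distance classification
#'
#' `source = "published"` returns the class summary table as commonly
#' printed in the relationship-inference literature, verbatim (its
#' third-cousin row (0.97, 0.0312, 0) differs from the closed-form pedigree
#' value (0.984375, 0.015625, 0) -- kept as printed, not corrected);
#' `source = "pedigree"` returns closed-form values.
#'
#' @param source "published" or "pedigree".
#' @return 5 x 3 matrix, rows S1..Un.
#' @export
kappaReferenceTable <- function(source = c("published", "pedigree")) {
  source <- match.arg(source)
  if (source == "pedigree") {
    out <- t(vapply(.CLASS_LEVELS, kappaClosedForm, numeric(3)))
  } else {
    out <- rbind(S1 = c(0.25, 0.5, 0.25),
                 S2 = c(0.75, 0.25, 0),
                 S3 = c(0.9375, 0.0625, 0),
                 S4 = c(0.97, 0.0312, 0),
                 Un = c(1, 0, 0))
  }
  colnames(out) <- c("kappa0", "kappa1", "kappa2")
  out
}

#' Kappa-distance relationship classifier
#'
#' Assigns the class whose expected kappa vector minimises the Euclidean
#' distance to the estimate; ties go to the more distant class.
#'
#' @param kappa numeric(3) estimate (e.g. from [mlKappa()]).
#' @param source reference table, see [kappaReferenceTable()].
#' @return single class call.
#' @examples
#' kappaDistanceClassify(c(0.75, 0.25, 0))  # "S2"
#' @export
kappaDistanceClassify <- function(kappa, source = c("published", "pedigree")) {
  stopifnot(length(kappa) == 3L)
  ref <- kappaReferenceTable(match.arg(source))
  d <- sqrt(rowSums(sweep(ref, 2L, kappa)^2))
  .CLASS_LEVELS[max(which(d <= min(d) + 1e-12))]
}
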