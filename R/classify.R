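# Classification of method outputs into relationship classes, consensus
# calling, classification-rate matrices and the error-impact experiment.

#' Expected total shared cM per relationship class
#'
#' Class means of total half-identical sharing (>= 5 cM segments) on the
#' default 3280 cM map: 2460 (S1), 818 (S2), 298 (S3), 49 (S4), and 10 cM of
#' chance sharing for unrelated pairs.
#'
#' @return named numeric(5).
#' @export
expectedSharedCM <- function() {
  c(S1 = 2460, S2 = 818, S3 = 298, S4 = 49, Un = 10)
}

#' Total-cM relationship classifier
#'
#' Bins a total shared cM value into the five classes using geometric
#' midpoints between adjacent class means (boundaries approximately 1419,
#' 494, 121 and 22 cM). A value exactly at a boundary is assigned to the
#' more distant class; the bins partition [0, Inf).
#'
#' @param totalCM total shared cM value(s), >= 0.
#' @param classMeans optional alternative class means (named as
#'   [expectedSharedCM()]), e.g. user-substituted reference tables.
#' @return character vector of class calls.
#' @examples
#' cmClassify(c(2460, 0))  # "S1", "Un"
#' @export
cmClassify <- function(totalCM, classMeans = expectedSharedCM()) {
  stopifnot(all(totalCM >= 0))
  b <- sqrt(classMeans[-length(classMeans)] * classMeans[-1L])
  out <- ifelse(totalCM > b[1L], "S1",
         ifelse(totalCM > b[2L], "S2",
         ifelse(totalCM > b[3L], "S3",
         ifelse(totalCM > b[4L], "S4", "Un"))))
  unname(out)
}

#' Build the segment-feature reference for distance classification
#'
#' Simulates `nReps` pairs per relationship class, summarises each pair's
#' true IBD track (>= `minCM` cM, half-identical union) into the number of
#' segments and the mean segment length, and stores the per-class feature
#' means together with pooled standard deviations. Unrelated pairs have the
#' (0, 0) centroid by construction.
#'
#' @param map a [GeneticMap-class].
#' @param nReps simulated pairs per class.
#' @param minCM segment length cutoff in cM (default 5).
#' @param seed optional integer seed.
#' @return list of class `SegmentFeatureReference` with `centroids`
#'   (5 x 2 matrix), `pooledSD` (numeric(2)), `nReps`, `minCM`.
#' @export
buildSegmentFeatureReference <- function(map, nReps = 10000L, minCM = 5,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feats <- list()
  for (cl in c("S1", "S2", "S3", "S4")) {
    x <- matrix(0, nReps, 2L)
    for (i in seq_len(nReps)) {
      st <- trueIBDStats(simulateIBDTracks(cl, map)$segments, minCM = minCM)
      x[i, ] <- c(st$n_segments, st$mean_segment_cm)
    }
    feats[[cl]] <- x
  }
  centroids <- rbind(t(vapply(feats, colMeans, numeric(2))),
                     Un = c(0, 0))
  vars <- t(vapply(feats, function(x) apply(x, 2L, stats::var), numeric(2)))
  pooled <- sqrt(colMeans(vars))
  colnames(centroids) <- names(pooled) <- c("n_segments", "mean_segment_cm")
  structure(list(centroids = centroids, pooledSD = pooled,
                 nReps = nReps, minCM = minCM),
            class = "SegmentFeatureReference")
}

#' Segment-feature relationship classifier
#'
#' Classifies a pair from two summary features of its called segments --
#' the segment count and the mean segment length -- by minimum Euclidean
#' distance to per-class centroids, after z-scoring each feature by the
#' reference's pooled standard deviation (the two features live on
#' incommensurate scales). Ties go to the more distant class.
#'
#' @param nSegments observed number of segments.
#' @param meanSegmentCM observed mean segment length in cM.
#' @param ref a `SegmentFeatureReference`, see
#'   [buildSegmentFeatureReference()].
#' @return single class call.
#' @export
segmentFeatureClassify <- function(nSegments, meanSegmentCM, ref) {
  if (!inherits(ref, "SegmentFeatureReference"))
    stop("ref must be a SegmentFeatureReference")
  z <- c(nSegments, meanSegmentCM) / ref$pooledSD
  zc <- sweep(ref$centroids, 2L, ref$pooledSD, "/")
  d <- sqrt(rowSums(sweep(zc, 2L, z)^2))
  .CLASS_LEVELS[max(which(d <= min(d) + 1e-12))]
}

#' Consensus classification across methods
#'
#' Returns the modal class when its multiplicity reaches `kRequired`,
#' otherwise "INCONCLUSIVE". Inconclusive inputs never count toward
#' agreement; a tie between modal classes at or above the threshold goes to
#' the more distant class.
#'
#' @param calls character vector of class calls (possibly "INCONCLUSIVE").
#' @param kRequired minimum number of agreeing methods (2 <= k <= length).
#' @return single class call or "INCONCLUSIVE".
#' @examples
#' consensusClassify(c("S2", "S2", "S3"), 2)  # "S2"
#' @export
consensusClassify <- function(calls, kRequired = 2L) {
  stopifnot(kRequired >= 2L, kRequired <= length(calls))
  calls <- calls[calls %in% .CLASS_LEVELS]
  if (!length(calls)) return(.INCONCLUSIVE)
  tab <- table(factor(calls, levels = .CLASS_LEVELS))
  if (max(tab) < kRequired) return(.INCONCLUSIVE)
  .CLASS_LEVELS[max(which(tab == max(tab)))]
}

#' Classification-rate matrix
#'
#' Tallies predicted against true classes and converts counts to row-wise
#' rates; rows (true classes) sum to 1 over the predicted classes plus the
#' inconclusive column. The diagonal holds the correct-classification rate
#' per class.
#'
#' @param truths character vector of true classes.
#' @param calls character vector of predicted classes (may contain
#'   "INCONCLUSIVE").
#' @return list of class `ClassRateMatrix` with `counts` and `rates`
#'   matrices (rows = true class, columns = predicted class).
#' @export
classificationMatrix <- function(truths, calls) {
  if (length(truths) != length(calls))
    stop("truths and calls must have equal length")
  lev <- c(.CLASS_LEVELS, .INCONCLUSIVE)
  counts <- table(factor(truths, levels = .CLASS_LEVELS),
                  factor(calls, levels = lev))
  counts <- unclass(counts)
  rates <- counts / pmax(rowSums(counts), 1L)
  structure(list(counts = counts, rates = rates), class = "ClassRateMatrix")
}

#' @export
print.ClassRateMatrix <- function(x, ...) {
  cat("Classification rates (rows = true class):\n")
  print(round(x$rates, 3))
  invisible(x)
}

#' Fraction of pairs whose true IBD contains no panel marker
#'
#' For each pair's true IBD track, checks whether any panel marker falls
#' inside any true IBD segment; returns the fraction of pairs with none
#' (either genetically unrelated in practice, or sharing only regions the
#' panel does not cover).
#'
#' @param tracks list of true-IBD segment data.frames (the `segments`
#'   element of [simulateIBDTracks()] or the `trueIBD` slot).
#' @param panel a [SNPPanel-class].
#' @return fraction in [0, 1].
#' @export
zeroIBDFraction <- function(tracks, panel) {
  m <- panel@markers
  if (nrow(m) == 0L) return(1)
  none <- vapply(tracks, function(seg) {
    if (is.null(seg) || nrow(seg) == 0L) return(TRUE)
    for (i in seq_len(nrow(seg))) {
      j <- m$chrom == seg$chrom[i] & m$cM >= seg$start_cm[i] &
        m$cM <= seg$end_cm[i]
      if (any(j)) return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(none)
}

# Classify a list of PairObservations with one method. Internal driver used
# by the evaluation and error-impact experiments.
.classifyPairs <- function(pairs, method = c("segment", "windowed", "king",
                                             "lr", "lr_unlinked", "mlkappa"),
                           map = NULL, segParams = NULL, winParams = NULL,
                           refCM = expectedSharedCM()) {
  method <- match.arg(method)
  panel <- pairs[[1L]]@panel
  if (method %in% c("lr", "lr_unlinked")) {
    GA <- do.call(rbind, lapply(pairs, function(o) o@genotypesA))
    GB <- do.call(rbind, lapply(pairs, function(o) o@genotypesB))
    if (method == "lr") {
      ll <- vapply(.CLASS_LEVELS, function(h)
        .linkedLogLikBatch(GA, GB, panel, h), numeric(length(pairs)))
    } else {
      ll <- vapply(.CLASS_LEVELS, function(h) {
        kap <- kappaClosedForm(h)
        tbless <- vapply(seq_along(pairs), function(i)
          as.numeric(unlinkedLogLik(pairs[[i]], kap)), numeric(1))
        tbless
      }, numeric(length(pairs)))
    }
    return(apply(ll, 1L, .argmaxDistant))
  }
  vapply(pairs, function(obs) {
    switch(method,
      segment = cmClassify(totalSharedCM(
        callSegments(obs, map = map,
                     params = if (is.null(segParams))
                       segmentCallParams(minSnps = defaultMinSnps(panel, map = map))
                     else segParams)), classMeans = refCM),
      windowed = cmClassify(totalSharedCM(
        windowedSegments(obs, map = map,
                         params = if (is.null(winParams))
                           windowParams(windowSize = windowSizeFor(panel))
                         else winParams)), classMeans = refCM),
      king = phiThresholdClassify(kingRobustPhi(obs)),
      mlkappa = kappaDistanceClassify(suppressWarnings(mlKappa(obs))$kappa))
  }, character(1))
}

#' Error-impact experiment
#'
#' Simulates `nPairs` pairs per relationship class once, then, for each row
#' of the error-rate table, injects genotyping errors into individual A of
#' every pair (paired design: the same simulated pairs and the same
#' injection seeds are reused across error rows) and re-classifies with the
#' linked likelihood ratio, the windowed-kinship approach and the plain
#' segment approach -- the methods of the sensitivity study (the
#' method-of-moments and ML-kappa estimators are exempt). A zero-error
#' baseline row is always included and reproduces the error-free
#' classification exactly.
#'
#' @param panel a [SNPPanel-class].
#' @param map a [GeneticMap-class].
#' @param classes true classes to simulate (default S1--S4 plus unrelated).
#' @param nPairs simulated pairs per class.
#' @param errorRates data.frame of error rows (columns `homToHet`,
#'   `homToOpp`, `hetToHom`); defaults to [errorRateTable()].
#' @param methods subset of c("lr", "windowed", "segment").
#' @param seed integer seed controlling the whole experiment.
#' @return list of class `ErrorImpactResult`: one element per error row
#'   (`baseline` first), each a named list of `ClassRateMatrix` per method;
#'   attribute `config` echoes the configuration.
#' @export
errorImpactExperiment <- function(panel, map, classes = .CLASS_LEVELS,
                                  nPairs = 100L,
                                  errorRates = errorRateTable(),
                                  methods = c("lr", "windowed", "segment"),
                                  seed = 1L) {
  methods <- match.arg(methods, c("lr", "windowed", "segment"),
                       several.ok = TRUE)
  set.seed(seed)
  simSeeds <- sample.int(.Machine$integer.max - 1L, nPairs * length(classes))
  injSeeds <- sample.int(.Machine$integer.max - 1L, nPairs * length(classes))
  truths <- rep(classes, each = nPairs)
  pairs <- vector("list", length(truths))
  for (i in seq_along(truths)) {
    pairs[[i]] <- if (truths[i] == "Un")
      simulateUnrelatedPair(panel, map, seed = simSeeds[i])
    else simulatePair(truths[i], panel, map, seed = simSeeds[i])
  }
  rows <- rbind(data.frame(homToHet = 0, homToOpp = 0, hetToHom = 0),
                errorRates)
  rowNames <- c("baseline", sprintf("hom2het=%g,hom2opp=%g,het2hom=%g",
                                    errorRates$homToHet, errorRates$homToOpp,
                                    errorRates$hetToHom))
  out <- vector("list", nrow(rows))
  names(out) <- rowNames
  for (r in seq_len(nrow(rows))) {
    em <- errorModel(rows$homToHet[r], rows$homToOpp[r], rows$hetToHom[r])
    perturbed <- lapply(seq_along(pairs), function(i)
      injectErrors(pairs[[i]], em, seed = injSeeds[i]))
    out[[r]] <- lapply(stats::setNames(methods, methods), function(mm)
      classificationMatrix(truths,
                           .classifyPairs(perturbed, method = mm, map = map)))
  }
  structure(out, class = "ErrorImpactResult",
            config = list(classes = classes, nPairs = nPairs, seed = seed,
                          methods = methods, errorRates = rows))
}
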