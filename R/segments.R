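# IBD segment detection from genotype pairs: plain half-identical runs and
# windowed kinship calling.

.ibs0 <- function(ga, gb) {
  out <- (ga == 0L & gb == 2L) | (ga == 2L & gb == 0L)
  out[is.na(out)] <- FALSE   # missing genotypes never break a run
  out
}

#' Default minimum SNP count per called segment
#'
#' The plain segment caller needs a per-panel minimum marker count to
#' suppress chance half-identical runs, which become long when the
#' per-marker opposite-homozygote probability is small. The default is
#' chosen by a bias-balance rule: using the panel's mean opposite-homozygote
#' probability q (under Hardy-Weinberg for unrelated individuals) and marker
#' density, pick the count for which the expected chance-run length gained
#' equals the expected true length lost for a first-cousin reference pair
#' (segment lengths approximated as exponential with mean 100/m cM). The
#' result is clamped to [16, 500]; at very low densities the chosen count
#' exceeds what a chromosome can hold, which effectively disables segment
#' calling (appropriately, since sparse panels are unsuited to the segment
#' approach).
#'
#' @param panel a [SNPPanel-class].
#' @param minCM minimum segment length in cM (default 5).
#' @param map optional [GeneticMap-class] used for the genome length;
#'   defaults to the span of the panel's marker positions.
#' @return integer minimum SNP count.
#' @export
defaultMinSnps <- function(panel, minCM = 5, map = NULL) {
  m <- panel@markers
  G <- if (!is.null(map)) totalCM(map) else {
    sum(vapply(split(m$cM, m$chrom), function(x) max(x) - min(x), numeric(1)))
  }
  if (G <= 0) return(16L)
  q <- mean(2 * m$freq^2 * (1 - m$freq)^2)
  dens <- nrow(m) / G
  lam <- 100 / 4                       # first-cousin mean segment length
  k1 <- 0.25
  n <- 16:500
  s <- pmax(minCM, n / dens)
  retained <- k1 * G * (1 + s / lam) * exp(-s / lam)
  false <- (1 - k1) * G * (1 + n * q) * exp(-n * q)
  as.integer(n[which.min(abs(retained + false - k1 * G))])
}

#' Parameters for the plain segment caller
#'
#' @param minCM minimum segment genetic length in cM (default 5).
#' @param minSnps minimum number of markers per segment (panel-density
#'   dependent; see [defaultMinSnps()]).
#' @return list of class `SegmentCallParams`.
#' @export
segmentCallParams <- function(minCM = 5, minSnps = 16L) {
  stopifnot(minCM > 0, minSnps >= 2L)
  structure(list(minCM = minCM, minSnps = as.integer(minSnps)),
            class = "SegmentCallParams")
}

#' Call IBD segments as maximal half-identical marker runs
#'
#' Scans each chromosome for maximal runs of consecutive markers with no
#' opposite-homozygote (IBS0) site -- within a true IBD region at least one
#' allele is always shared, so (absent genotype errors) IBS0 is impossible
#' there. A run is reported as an IBD segment when its span (cM of first to
#' last marker) reaches `minCM` and it contains at least `minSnps` markers.
#' There is zero tolerance for IBS0 inside a run.
#'
#' @param obs a [PairObservation-class].
#' @param map optional [GeneticMap-class] (marker cM positions come from the
#'   panel; accepted for interface symmetry).
#' @param params a `SegmentCallParams` list, see [segmentCallParams()].
#' @return data.frame of called segments: `chrom`, `start_cm`, `end_cm`,
#'   `n_snps`, `source` = "segment".
#' @export
callSegments <- function(obs, map = NULL,
                         params = segmentCallParams(
                           minSnps = defaultMinSnps(obs@panel, map = map))) {
  m <- obs@panel@markers
  ib0 <- .ibs0(obs@genotypesA, obs@genotypesB)
  out <- list()
  for (ch in unique(m$chrom)) {
    j <- which(m$chrom == ch)
    cm <- m$cM[j]
    bad <- ib0[j]
    # run ids: increments at each IBS0 marker; IBS0 markers excluded
    run <- cumsum(bad)
    keep <- !bad
    if (!any(keep)) next
    for (r in split(seq_along(j)[keep], run[keep])) {
      span <- cm[r[length(r)]] - cm[r[1L]]
      if (span >= params$minCM && length(r) >= params$minSnps) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_cm = cm[r[1L]], end_cm = cm[r[length(r)]],
          n_snps = length(r), source = "segment")
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), n_snps = integer(0),
                      source = character(0)))
  do.call(rbind, out)
}

#' Default window size for the windowed-kinship caller
#'
#' Anchored at 60 markers for the 9618-marker (Kintelligence-sized) panel --
#' the published window size for that panel -- and scaled proportionally
#' with panel size, clamped to [30, 300].
#'
#' @param panel a [SNPPanel-class].
#' @return integer window size in markers.
#' @export
windowSizeFor <- function(panel) {
  as.integer(min(300L, max(30L, round(60 * nMarkers(panel) / 9618))))
}

#' Parameters for the windowed-kinship caller
#'
#' @param windowSize window size in markers (default 60, the published value
#'   for a ~10,000-marker panel; see [windowSizeFor()]).
#' @param fMin minimum fraction of window markers with at least one shared
#'   allele (IBS >= 1) for a window to seed a segment (default 0.95).
#' @param aMin minimum pooled window kinship for a merged superwindow to be
#'   called IBD (default 0.23).
#' @param minCM minimum reported superwindow span in cM (default 5).
#' @return list of class `WindowParams`.
#' @export
windowParams <- function(windowSize = 60L, fMin = 0.95, aMin = 0.23,
                         minCM = 5) {
  stopifnot(windowSize >= 10L, fMin > 0, fMin < 1, aMin > 0, aMin < 1)
  structure(list(windowSize = as.integer(windowSize), fMin = fMin,
                 aMin = aMin, minCM = minCM), class = "WindowParams")
}

.windowPhi <- function(ga, gb) {
  # KING-robust phi restricted to a marker subset; reference = higher het
  nhh <- sum(ga == 1L & gb == 1L, na.rm = TRUE)
  nop <- sum((ga == 0L & gb == 2L) | (ga == 2L & gb == 0L), na.rm = TRUE)
  na_ <- sum(ga == 1L, na.rm = TRUE); nb <- sum(gb == 1L, na.rm = TRUE)
  ni <- max(na_, nb); nj <- min(na_, nb)
  if (ni == 0L) return(-Inf)
  (nhh - 2 * nop) / (2 * ni) + 0.5 - (ni + nj) / (4 * ni)
}

#' Call IBD segments with the windowed-kinship approach
#'
#' Splits each chromosome into consecutive non-overlapping windows of
#' `windowSize` markers (the trailing remainder joins the last window). A
#' window seeds a segment when its fraction of markers with at least one
#' shared allele reaches `fMin` (within a true IBD region at least one
#' allele is always shared, so the fraction is 1 there up to genotype
#' errors). Adjacent seed windows are merged into superwindows; a
#' superwindow is called IBD when the KING-robust kinship computed over its
#' pooled markers, or over any member window, reaches `aMin` -- seed
#' chaining can append non-IBD neighbours to a superwindow, and the
#' member-window clause keeps that dilution from masking a genuine IBD core.
#' Called superwindows are reported when their marker span reaches `minCM`.
#' The kinship screen is what rejects chance half-identical stretches, which
#' the plain segment caller cannot.
#'
#' @param obs a [PairObservation-class].
#' @param map optional [GeneticMap-class] (interface symmetry).
#' @param params a `WindowParams` list, see [windowParams()].
#' @return data.frame of called segments: `chrom`, `start_cm`, `end_cm`,
#'   `n_snps`, `source` = "windowed".
#' @export
windowedSegments <- function(obs, map = NULL,
                             params = windowParams(
                               windowSize = windowSizeFor(obs@panel))) {
  m <- obs@panel@markers
  ga <- obs@genotypesA; gb <- obs@genotypesB
  W <- params$windowSize
  out <- list()
  for (ch in unique(m$chrom)) {
    j <- which(m$chrom == ch)
    nm <- length(j)
    if (nm < W) next
    nw <- nm %/% W
    wid <- pmin(ceiling(seq_len(nm) / W), nw)   # remainder joins last window
    ib0 <- .ibs0(ga[j], gb[j])
    f <- 1 - vapply(split(ib0, wid), mean, numeric(1))
    seed <- f >= params$fMin
    if (!any(seed)) next
    aWin <- vapply(split(seq_len(nm), wid), function(ii)
      .windowPhi(ga[j][ii], gb[j][ii]), numeric(1))
    sw <- split(seq_len(nw)[seed], cumsum(!seed)[seed])
    for (wins in sw) {
      idx <- j[wid %in% wins]
      a <- max(.windowPhi(ga[idx], gb[idx]), aWin[wins])
      if (a < params$aMin) next
      span <- m$cM[idx[length(idx)]] - m$cM[idx[1L]]
      if (span < params$minCM) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_cm = m$cM[idx[1L]], end_cm = m$cM[idx[length(idx)]],
        n_snps = length(idx), source = "windowed")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), n_snps = integer(0),
                      source = character(0)))
  do.call(rbind, out)
}

#' Total shared centiMorgans of a set of called segments
#'
#' @param segments data.frame with `start_cm` and `end_cm` columns (from
#'   [callSegments()], [windowedSegments()] or a true-IBD union).
#' @return total length in cM.
#' @examples
#' totalSharedCM(data.frame(start_cm = c(0, 20), end_cm = c(10, 25.5)))
#' @export
totalSharedCM <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  sum(segments$end_cm - segments$start_cm)
}
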