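# Gamete dropping through pairwise pedigrees with true-IBD tracking.
#
# A haplotype along one chromosome is a piecewise-constant function of
# genetic position, represented as list(brk, lab): `brk` are the interior
# breakpoints (cM, sorted) and `lab` the founder-haplotype labels of the
# length(brk) + 1 pieces. Founder haplotypes carry globally unique labels,
# so identity of labels between two individuals means identity by descent.

#' Sample crossover positions along a chromosome
#'
#' Under the default gamma-renewal model, inter-crossover distances follow a
#' stationary Gamma(shape = `nu`, mean = 100 cM) renewal process (the
#' chi-square crossover-interference model; the first event is drawn from
#' the exact equilibrium delay distribution). The default `nu = 2.63`
#' is the refined Housworth-Stahl interference strength estimated for human
#' meiosis. `interference = "poisson"` gives the
#' Haldane model: count Poisson with mean `lengthCM / 100`, positions
#' uniform (`nu = 1` in the gamma mode is equivalent).
#'
#' @param lengthCM chromosome genetic length in cM (> 0).
#' @param interference "gamma" (default, interference) or "poisson".
#' @param nu gamma shape parameter (interference strength); nu = 1 recovers
#'   the Poisson process.
#' @param seed optional integer seed.
#' @return sorted numeric vector of crossover positions in cM.
#' @examples
#' sampleCrossovers(100, seed = 1)
#' @export
sampleCrossovers <- function(lengthCM, interference = c("gamma", "poisson"),
                             nu = 2.63, seed = NULL) {
  if (length(lengthCM) != 1L || lengthCM <= 0) stop("lengthCM must be positive")
  interference <- match.arg(interference)
  if (!is.null(seed)) set.seed(seed)
  .drawCrossovers(lengthCM, interference, nu)
}

.drawCrossovers <- function(L, interference, nu) {
  if (interference == "poisson") {
    n <- stats::rpois(1L, L / 100)
    if (n == 0L) return(numeric(0))
    return(sort(stats::runif(n, 0, L)))
  }
  # stationary renewal: equilibrium delay X1 = U * I with I length-biased
  x1 <- stats::runif(1L) * stats::rgamma(1L, nu + 1, nu / 100)
  if (x1 > L) return(numeric(0))
  out <- x1
  k <- max(4, ceiling((L - x1) / 100 * 2 + 6))
  repeat {
    gaps <- stats::rgamma(k, nu, nu / 100)
    pts <- out[length(out)] + cumsum(gaps)
    out <- c(out, pts[pts <= L])
    if (pts[length(pts)] > L) break
  }
  out
}

.newHap <- function(label) list(brk = numeric(0), lab = as.integer(label))

.labAt <- function(hap, x) hap$lab[findInterval(x, hap$brk) + 1L]

# One meiosis: recombine a parent's two chromosome haplotypes.
.meiosis <- function(h1, h2, lengthCM, interference = "gamma", nu = 2.63) {
  xo <- .drawCrossovers(lengthCM, interference, nu)
  start <- sample.int(2L, 1L)
  if (length(xo) == 0L && length(h1$brk) == 0L && length(h2$brk) == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  cuts <- sort(unique(c(xo, h1$brk, h2$brk)))
  bounds <- c(0, cuts, lengthCM)
  mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  useFirst <- (findInterval(mids, xo) + start) %% 2L == 1L
  lab <- ifelse(useFirst, .labAt(h1, mids), .labAt(h2, mids))
  keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
  list(brk = cuts[keep[-1L]], lab = as.integer(lab[keep]))
}

# IBD level track between two individuals on one chromosome.
# hapsA, hapsB: lists of two haplotypes each. Labels <= 0 are private.
.pairIBDTrack <- function(hapsA, hapsB, lengthCM) {
  cuts <- sort(unique(c(hapsA[[1L]]$brk, hapsA[[2L]]$brk,
                        hapsB[[1L]]$brk, hapsB[[2L]]$brk)))
  bounds <- c(0, cuts, lengthCM)
  mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  a1 <- .labAt(hapsA[[1L]], mids); a2 <- .labAt(hapsA[[2L]], mids)
  b1 <- .labAt(hapsB[[1L]], mids); b2 <- .labAt(hapsB[[2L]], mids)
  eq <- function(x, y) (x == y) & x > 0L
  ibd <- pmax(eq(a1, b1) + eq(a2, b2), eq(a1, b2) + eq(a2, b1))
  keep <- c(TRUE, ibd[-1L] != ibd[-length(ibd)])
  starts <- bounds[-length(bounds)][keep]
  ends <- c(starts[-1L], lengthCM)
  lev <- ibd[keep]
  i <- lev >= 1L
  data.frame(start_cm = starts[i], end_cm = ends[i], level = lev[i])
}

# Drop one chromosome through the pedigree for a relationship class.
# Returns list(hapsA = list(h, h), hapsB = list(h, h)).
.dropChromosome <- function(label, lengthCM, interference = "gamma",
                            nu = 2.63) {
  F1 <- list(.newHap(1L), .newHap(2L))
  F2 <- list(.newHap(3L), .newHap(4L))
  gam <- function(p) .meiosis(p[[1L]], p[[2L]], lengthCM, interference, nu)
  if (label == "S1") {
    return(list(hapsA = list(gam(F1), gam(F2)),
                hapsB = list(gam(F1), gam(F2))))
  }
  gens <- .REL_REGISTRY[[label]]$gens
  c1 <- list(gam(F1), gam(F2))
  c2 <- list(gam(F1), gam(F2))
  spouse <- -1L
  for (g in seq_len(gens)) {
    c1 <- list(gam(c1), .newHap(spouse)); spouse <- spouse - 1L
    c2 <- list(gam(c2), .newHap(spouse)); spouse <- spouse - 1L
  }
  list(hapsA = c1, hapsB = c2)
}

#' Simulate the true IBD segment track for a pair of relatives
#'
#' Drops gametes chromosome by chromosome through the pedigree connecting the
#' pair via a common-ancestor couple and records where the pair's haplotypes
#' carry identical founder alleles. This produces the exact true-IBD track
#' without simulating any genotypes, which is what the segment-sharing
#' summaries need.
#'
#' @param spec a [RelationshipSpec-class] or class label ("S1".."S4", "Un").
#' @param map a [GeneticMap-class].
#' @param seed optional integer seed.
#' @param interference,nu crossover model, see [sampleCrossovers()].
#' @return list with `segments` (data.frame chrom, start_cm, end_cm,
#'   start_bp, end_bp, level) and `haps` (per-chromosome haplotype
#'   structures, used internally for genotype superposition).
#' @examples
#' trk <- simulateIBDTracks("S2", buildDefaultMap(), seed = 1)
#' head(trk$segments)
#' @export
simulateIBDTracks <- function(spec, map, seed = NULL,
                              interference = c("gamma", "poisson"),
                              nu = 2.63) {
  spec <- .asSpec(spec)
  interference <- match.arg(interference)
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengthsCM(map)
  chroms <- names(lens)
  if (spec@label == "Un") {
    seg <- data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), start_bp = numeric(0),
                      end_bp = numeric(0), level = integer(0))
    return(list(segments = seg, haps = NULL))
  }
  haps <- vector("list", length(chroms))
  names(haps) <- chroms
  segs <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    d <- .dropChromosome(spec@label, lens[[i]], interference, nu)
    haps[[i]] <- d
    tr <- .pairIBDTrack(d$hapsA, d$hapsB, lens[[i]])
    if (nrow(tr)) {
      tr$chrom <- chroms[i]
      segs[[i]] <- tr
    }
  }
  seg <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(seg)) {
    seg <- data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), level = integer(0))
  }
  seg$start_bp <- numeric(nrow(seg))
  seg$end_bp <- numeric(nrow(seg))
  for (ch in unique(seg$chrom)) {
    i <- seg$chrom == ch
    seg$start_bp[i] <- cmToBp(map, ch, seg$start_cm[i])
    seg$end_bp[i] <- cmToBp(map, ch, seg$end_cm[i])
  }
  seg <- seg[c("chrom", "start_cm", "end_cm", "start_bp", "end_bp", "level")]
  rownames(seg) <- NULL
  list(segments = seg, haps = haps)
}

# Superimpose genotypes on a haplotype drop for the markers of one panel.
# Founder haplotype alleles are drawn i.i.d. per marker from the panel
# frequencies (linkage equilibrium). Returns 2-row 0/1 matrices per person.
.superimposeGenotypes <- function(haps, panel) {
  m <- panel@markers
  M <- nrow(m)
  hA <- matrix(0L, 2L, M); hB <- matrix(0L, 2L, M)
  for (ch in unique(m$chrom)) {
    i <- which(m$chrom == ch)
    pos <- m$cM[i]; p <- m$freq[i]
    d <- haps[[ch]]
    labs <- cbind(.labAt(d$hapsA[[1L]], pos), .labAt(d$hapsA[[2L]], pos),
                  .labAt(d$hapsB[[1L]], pos), .labAt(d$hapsB[[2L]], pos))
    u <- sort(unique(as.vector(labs)))
    # allele draws: one Bernoulli(p_m) per founder haplotype per marker
    A <- matrix(stats::rbinom(length(u) * length(i), 1L,
                              rep(p, each = length(u))),
                nrow = length(u))
    idx <- matrix(match(labs, u), nrow = length(i))
    hA[1L, i] <- A[cbind(idx[, 1L], seq_along(i))]
    hA[2L, i] <- A[cbind(idx[, 2L], seq_along(i))]
    hB[1L, i] <- A[cbind(idx[, 3L], seq_along(i))]
    hB[2L, i] <- A[cbind(idx[, 4L], seq_along(i))]
  }
  list(hA = hA, hB = hB)
}

#' Simulate a pair of relatives on a SNP panel
#'
#' Combines [simulateIBDTracks()] with genotype superposition: founder
#' haplotype alleles are drawn independently per marker from the panel allele
#' frequencies (linkage equilibrium), then propagated along the dropped
#' haplotypes, so the genotypes are consistent with the true IBD track by
#' construction.
#'
#' @param spec a [RelationshipSpec-class] or one of "S1", "S2", "S3", "S4".
#' @param panel a [SNPPanel-class].
#' @param map a [GeneticMap-class]; panel markers must lie inside it.
#' @param seed optional integer seed.
#' @param interference,nu crossover model, see [sampleCrossovers()].
#' @return a [PairObservation-class] with phased haplotypes and true IBD.
#' @examples
#' map <- buildDefaultMap(2, 200)
#' pan <- makeFixturePanels(map, sizes = 500, seed = 1)[[1]]
#' obs <- simulatePair("S1", pan, map, seed = 2)
#' @export
simulatePair <- function(spec, panel, map, seed = NULL,
                         interference = c("gamma", "poisson"), nu = 2.63) {
  spec <- .asSpec(spec)
  if (spec@label == "Un")
    stop("use simulateUnrelatedPair() for unrelated pairs")
  interference <- match.arg(interference)
  lens <- chromLengthsCM(map)
  m <- panel@markers
  if (!all(m$chrom %in% names(lens)))
    stop("panel contains chromosomes absent from the map")
  if (any(m$cM > lens[m$chrom] + 1e-9))
    stop("panel markers lie outside the map coordinates")
  trk <- simulateIBDTracks(spec, map, seed = seed,
                           interference = interference, nu = nu)
  g <- .superimposeGenotypes(trk$haps, panel)
  new("PairObservation",
      genotypesA = as.integer(colSums(g$hA)),
      genotypesB = as.integer(colSums(g$hB)),
      panel = panel, trueIBD = trk$segments,
      haplotypesA = g$hA, haplotypesB = g$hB)
}

#' Simulate an unrelated pair on a SNP panel
#'
#' Draws two independent Hardy-Weinberg genotype vectors from the panel
#' allele frequencies. The true IBD track is empty by construction (this is
#' a frequency draw, not a finite population sample, so chance background
#' relatedness is absent).
#'
#' @inheritParams simulatePair
#' @return a [PairObservation-class] with an empty true IBD track.
#' @export
simulateUnrelatedPair <- function(panel, map = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- panel@markers$freq
  M <- length(p)
  hA <- matrix(stats::rbinom(2L * M, 1L, rep(p, each = 2L)), 2L, M)
  hB <- matrix(stats::rbinom(2L * M, 1L, rep(p, each = 2L)), 2L, M)
  empty <- data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), start_bp = numeric(0),
                      end_bp = numeric(0), level = integer(0))
  new("PairObservation",
      genotypesA = as.integer(colSums(hA)),
      genotypesB = as.integer(colSums(hB)),
      panel = panel, trueIBD = empty, haplotypesA = hA, haplotypesB = hB)
}

#' Construct an ErrorModel
#'
#' @param homToHet probability a homozygote turns heterozygote.
#' @param homToOpp probability a homozygote turns into the opposite
#'   homozygote.
#' @param hetToHom probability a heterozygote collapses to a homozygote
#'   (either one with probability 1/2).
#' @return an [ErrorModel-class].
#' @export
errorModel <- function(homToHet = 0, homToOpp = 0, hetToHom = 0) {
  new("ErrorModel", homToHet = homToHet, homToOpp = homToOpp,
      hetToHom = hetToHom)
}

#' Genotyping error rates of the sensitivity study
#'
#' The six error configurations used in the error-impact experiment:
#' hom-to-het at 2% and 0.5%, het-to-hom at 0.5% and 2%, and hom-to-opposite-
#' hom at 0.1% and 1%.
#'
#' @return data.frame with columns `homToHet`, `homToOpp`, `hetToHom`.
#' @export
errorRateTable <- function() {
  data.frame(
    homToHet = c(0.02, 0.005, 0, 0, 0, 0),
    homToOpp = c(0, 0, 0, 0, 0.001, 0.01),
    hetToHom = c(0, 0, 0.005, 0.02, 0, 0))
}

#' Inject genotyping errors into one individual of a pair
#'
#' Mutates individual A's genotypes marker by marker, independently, with the
#' rates of the [ErrorModel-class]: a homozygote turns heterozygote
#' (one allele replaced), a homozygote turns opposite homozygote (both
#' replaced), a heterozygote collapses to either homozygote with probability
#' 1/2 each. The true IBD track is untouched; stored phase for individual A
#' is dropped because errors are genotype-level events.
#'
#' With all rates zero the input object is returned unchanged (and no random
#' numbers are consumed).
#'
#' @param obs a [PairObservation-class].
#' @param em an [ErrorModel-class].
#' @param seed optional integer seed.
#' @return a [PairObservation-class].
#' @export
injectErrors <- function(obs, em, seed = NULL) {
  stopifnot(is(em, "ErrorModel"))
  if (em@homToHet == 0 && em@homToOpp == 0 && em@hetToHom == 0) return(obs)
  if (!is.null(seed)) set.seed(seed)
  g <- obs@genotypesA
  M <- length(g)
  u <- stats::runif(M)
  coin <- stats::runif(M)
  hom <- !is.na(g) & g != 1L
  het <- !is.na(g) & g == 1L
  out <- g
  toHet <- hom & u < em@homToHet
  toOpp <- hom & u >= em@homToHet & u < em@homToHet + em@homToOpp
  toHom <- het & u < em@hetToHom
  out[toHet] <- 1L
  out[toOpp] <- 2L - g[toOpp]
  out[toHom] <- ifelse(coin[toHom] < 0.5, 0L, 2L)
  new("PairObservation", genotypesA = out, genotypesB = obs@genotypesB,
      panel = obs@panel, trueIBD = obs@trueIBD,
      haplotypesA = NULL, haplotypesB = obs@haplotypesB)
}

# Merge the half-identical union (IBD level >= 1 counted once) of a segment
# track, per chromosome. Returns data.frame(chrom, start_cm, end_cm).
.halfIdenticalUnion <- function(seg) {
  if (is.null(seg) || nrow(seg) == 0L)
    return(data.frame(chrom = character(0), start_cm = numeric(0),
                      end_cm = numeric(0)))
  out <- lapply(split(seg, seg$chrom), function(x) {
    x <- x[order(x$start_cm), , drop = FALSE]
    s <- x$start_cm; e <- x$end_cm
    ns <- s[1L]; ne <- e[1L]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= ne + 1e-9) ne <- max(ne, e[i])
      else { rs <- c(rs, ns); re <- c(re, ne); ns <- s[i]; ne <- e[i] }
    }
    data.frame(chrom = x$chrom[1L], start_cm = c(rs, ns), end_cm = c(re, ne))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summaries of a pair's true IBD sharing
#'
#' Computes the half-identical union of the true IBD track (level-1 and
#' level-2 regions counted once), drops segments shorter than `minCM`, and
#' returns the total shared length, segment count, mean segment length and
#' the number of panel markers falling inside retained segments.
#'
#' @param obs a [PairObservation-class] with a true IBD track, or the
#'   `segments` data.frame of [simulateIBDTracks()] (then supply `panel`).
#' @param minCM minimum retained segment length in cM (default 5).
#' @param panel optional [SNPPanel-class] when `obs` is a plain segment table.
#' @return list(total_cm, n_segments, mean_segment_cm, n_panel_snps_in_ibd).
#' @export
trueIBDStats <- function(obs, minCM = 5, panel = NULL) {
  if (is(obs, "PairObservation")) {
    seg <- obs@trueIBD
    if (is.null(seg)) stop("no true IBD track: this looks like real data")
    panel <- obs@panel
  } else {
    seg <- obs
  }
  u <- .halfIdenticalUnion(seg)
  len <- u$end_cm - u$start_cm
  keep <- len >= minCM
  u <- u[keep, , drop = FALSE]; len <- len[keep]
  nsnp <- 0L
  if (!is.null(panel) && nrow(u)) {
    m <- panel@markers
    for (i in seq_len(nrow(u))) {
      j <- m$chrom == u$chrom[i] & m$cM >= u$start_cm[i] & m$cM <= u$end_cm[i]
      nsnp <- nsnp + sum(j)
    }
  }
  list(total_cm = sum(len), n_segments = nrow(u),
       mean_segment_cm = if (nrow(u)) mean(len) else 0,
       n_panel_snps_in_ibd = nsnp)
}
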