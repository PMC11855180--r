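# SNP panel construction, fixture panels, and panel/frequency file IO.

#' Construct a SNPPanel
#'
#' @param name panel label.
#' @param markers data.frame with columns `chrom`, `bp`, `cM`, `freq`
#'   (sorted by chromosome and position).
#' @return a [SNPPanel-class].
#' @export
snpPanel <- function(name, markers) {
  new("SNPPanel", name = name,
      markers = markers[c("chrom", "bp", "cM", "freq")])
}

#' @describeIn snpPanel number of markers in the panel.
#' @param panel a [SNPPanel-class].
#' @export
nMarkers <- function(panel) nrow(panel@markers)

#' @describeIn snpPanel the panel's marker table.
#' @export
panelMarkers <- function(panel) panel@markers

setMethod("show", "SNPPanel", function(object) {
  cat(sprintf("SNPPanel '%s': %d markers on %d chromosome(s)\n",
              object@name, nMarkers(object),
              length(unique(object@markers$chrom))))
})

setMethod("show", "PairObservation", function(object) {
  n <- nMarkers(object@panel)
  hasIBD <- !is.null(object@trueIBD)
  cat(sprintf("PairObservation on panel '%s' (%d markers); true IBD %s\n",
              object@panel@name, n,
              if (hasIBD) sprintf("track with %d segment(s)",
                                  nrow(object@trueIBD)) else "absent"))
})

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: hom->het %.4g, hom->opp hom %.4g, het->hom %.4g\n",
    object@homToHet, object@homToOpp, object@hetToHom))
})

# Rejection-sample allele frequencies from Beta(0.8, 0.8) truncated to
# [lo, hi] (SNP-array-like ascertainment: intermediate and extreme common
# frequencies, no rare variants).
.sampleFreqs <- function(n, shape = 0.8, lo = 0.05, hi = 0.95) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(n, shape, shape)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate schematic fixture panels
#'
#' Builds panels with the requested marker counts: marker genetic positions
#' are uniform over the map (assigned to chromosomes proportionally to their
#' cM length), physical positions follow from the map, and allele
#' frequencies are drawn from Beta(0.8, 0.8) truncated to [0.05, 0.95].
#' Deterministic under `seed`. The default sizes reproduce the filtered
#' marker counts of six published forensic/genealogy SNP panels
#' (Signature, FORCE, Kintelligence, 25K, 95K, pruned GSA).
#'
#' @param map a [GeneticMap-class].
#' @param sizes integer vector of marker counts.
#' @param seed optional integer seed.
#' @param names optional panel names (default "panel<size>").
#' @return list of [SNPPanel-class] objects.
#' @examples
#' panels <- makeFixturePanels(buildDefaultMap(2, 200), sizes = c(50, 100),
#'                             seed = 1)
#' @export
makeFixturePanels <- function(map, sizes = c(92, 4073, 9618, 17231, 53593,
                                             142350),
                              seed = NULL, names = NULL) {
  stopifnot(all(sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengthsCM(map)
  cum <- cumsum(lens)
  tot <- sum(lens)
  if (is.null(names)) names <- sprintf("panel%d", sizes)
  out <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    n <- sizes[s]
    pos <- sort(stats::runif(n, 0, tot))
    ci <- findInterval(pos, cum, left.open = TRUE) + 1L
    cm <- pos - c(0, cum)[ci]
    chrom <- names(lens)[ci]
    bp <- numeric(n)
    for (ch in unique(chrom)) {
      i <- chrom == ch
      bp[i] <- round(cmToBp(map, ch, cm[i]))
    }
    # enforce unique physical positions within chromosome
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      while (anyDuplicated(bp[i])) bp[i] <- bp[i] + cumsum(duplicated(bp[i]))
    }
    m <- data.frame(chrom = chrom, bp = bp, cM = cm,
                    freq = .sampleFreqs(n))
    m <- m[order(match(m$chrom, names(lens)), m$bp), ]
    rownames(m) <- NULL
    out[[s]] <- snpPanel(names[s], m)
  }
  names(out) <- names
  out
}

#' Read / write a SNP panel as TSV
#'
#' Tab-separated table with header `chrom bp cM freq`. Validation rejects
#' unsorted positions and frequencies outside (0, 1), naming the offending
#' line.
#'
#' @param path file path.
#' @param panel a [SNPPanel-class].
#' @param name panel name for the object read back.
#' @return `readPanel()` returns a [SNPPanel-class]; `writePanel()` returns
#'   `path` invisibly.
#' @export
readPanel <- function(path, name = basename(path)) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "bp", "cM", "freq")
  if (!all(need %in% names(x)))
    stop("panel file must have columns chrom, bp, cM, freq")
  bad <- which(x$freq <= 0 | x$freq >= 1)
  if (length(bad))
    stop(sprintf("allele frequency out of (0,1) at line %d of %s",
                 bad[1L] + 1L, path))
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    ooo <- which(diff(x$bp[i]) <= 0)
    if (length(ooo))
      stop(sprintf("markers not sorted by position at line %d of %s",
                   i[ooo[1L] + 1L] + 1L, path))
  }
  snpPanel(name, x)
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
  utils::write.table(panel@markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency table
#'
#' Tab-separated table with header `chrom bp freq`; used to attach
#' population frequencies to user-supplied genotype data.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `bp`, `freq`.
#' @export
readFreqs <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "bp", "freq")
  if (!all(need %in% names(x)))
    stop("frequency file must have columns chrom, bp, freq")
  bad <- which(x$freq <= 0 | x$freq >= 1)
  if (length(bad))
    stop(sprintf("allele frequency out of (0,1) at line %d of %s",
                 bad[1L] + 1L, path))
  x[need]
}
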