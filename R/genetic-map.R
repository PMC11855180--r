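# Genetic map construction and bp <-> cM interpolation.

# Autosome genetic lengths (sex-averaged, cM) in the style of the deCODE map;
# used only as a relative length profile, rescaled to the requested total.
.AUTOSOME_PROFILE <- c(
  286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0, 166.4, 181.1,
  158.2, 174.7, 125.9, 120.8, 141.9, 134.0, 128.5, 117.2, 107.9, 108.3,
  62.8, 74.1)

#' Build the default genetic map
#'
#' Constructs a schematic sex-averaged genetic map with `nChrom` chromosomes
#' whose cM lengths are proportional to a bundled deCODE-like autosome length
#' profile, rescaled so the terminal cM positions sum to `totalCM`. Physical
#' positions are assigned at a constant 1 Mb per cM, so each chromosome has
#' two anchors: (1 bp, 0 cM) and (L Mb, L cM).
#'
#' The default total of 3280 cM is the genome length implied by the expected
#' full-sibling half-identical sharing of 2460 cM (0.75 of the genome).
#'
#' @param nChrom number of chromosomes (1--22); 22 gives the full autosome set.
#' @param totalCM total sex-averaged map length in centiMorgans.
#' @return a [GeneticMap-class].
#' @examples
#' map <- buildDefaultMap()
#' totalCM(map)
#' @export
buildDefaultMap <- function(nChrom = 22L, totalCM = 3280) {
  if (length(nChrom) != 1L || nChrom < 1L) stop("nChrom must be >= 1")
  if (length(totalCM) != 1L || totalCM <= 0) stop("totalCM must be positive")
  nChrom <- as.integer(nChrom)
  if (nChrom > length(.AUTOSOME_PROFILE))
    stop("at most ", length(.AUTOSOME_PROFILE), " chromosomes supported")
  prof <- .AUTOSOME_PROFILE[seq_len(nChrom)]
  len <- prof / sum(prof) * totalCM
  anchors <- data.frame(
    chrom = rep(sprintf("chr%d", seq_len(nChrom)), each = 2L),
    bp = as.vector(rbind(1, pmax(2, round(len * 1e6)))),
    cM = as.vector(rbind(0, len)))
  new("GeneticMap", anchors = anchors)
}

#' @describeIn GeneticMap-utils chromosome names, in map order.
#' @export
chromNames <- function(map) unique(map@anchors$chrom)

#' Genetic map summaries and coordinate interpolation
#'
#' `chromLengthsCM()` returns the terminal cM position per chromosome,
#' `totalCM()` their sum, `bpToCm()`/`cmToBp()` interpolate coordinates
#' linearly between the map anchors.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome identifier (recycled against positions).
#' @param bp,cm positions to convert.
#' @name GeneticMap-utils
NULL

#' @describeIn GeneticMap-utils named vector of chromosome cM lengths.
#' @export
chromLengthsCM <- function(map) {
  a <- map@anchors
  out <- vapply(split(a$cM, a$chrom), max, numeric(1))
  out[chromNames(map)]
}

#' @describeIn GeneticMap-utils total map length in cM.
#' @export
totalCM <- function(map) sum(chromLengthsCM(map))

.mapChrom <- function(map, chrom) {
  a <- map@anchors[map@anchors$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown chromosome: ", chrom)
  a
}

#' @describeIn GeneticMap-utils convert base pairs to centiMorgans.
#' @export
bpToCm <- function(map, chrom, bp) {
  a <- .mapChrom(map, chrom)
  stats::approx(a$bp, a$cM, xout = bp, rule = 2)$y
}

#' @describeIn GeneticMap-utils convert centiMorgans to base pairs.
#' @export
cmToBp <- function(map, chrom, cm) {
  a <- .mapChrom(map, chrom)
  stats::approx(a$cM, a$bp, xout = cm, rule = 2)$y
}

setMethod("show", "GeneticMap", function(object) {
  len <- chromLengthsCM(object)
  cat(sprintf("GeneticMap: %d chromosome(s), %.1f cM total\n",
              length(len), sum(len)))
  cat("  lengths (cM): ", paste(sprintf("%.1f", len), collapse = ", "), "\n",
      sep = "")
})

#' Read / write a genetic map as TSV
#'
#' The file format is a tab-separated table with header `chrom bp cM`, one
#' anchor point per row. `readGeneticMap()` validates monotonicity and
#' reports the first offending line on failure.
#'
#' @param path file path.
#' @param map a [GeneticMap-class].
#' @return `readGeneticMap()` returns a [GeneticMap-class]; `writeGeneticMap()`
#'   returns `path` invisibly.
#' @export
readGeneticMap <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(x))) stop("map file must have columns chrom, bp, cM")
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    bad <- which(diff(x$cM[i]) <= 0 | diff(x$bp[i]) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone anchors on %s at line %d of %s",
                   ch, i[bad[1L] + 1L] + 1L, path))
  }
  new("GeneticMap", anchors = x[need])
}

#' @rdname readGeneticMap
#' @export
writeGeneticMap <- function(map, path) {
  utils::write.table(map@anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
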