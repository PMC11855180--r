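# VCF input/output for genotype pairs, and the run manifest.

#' Write a pair of genotypes as a minimal VCF 4.2 file
#'
#' One record per panel marker with synthetic REF/ALT alleles (A/G) and a GT
#' field for the two samples. Phased genotypes (pipe separator) are written
#' when haplotypes are stored on the object; otherwise an arbitrary-phase
#' unphased encoding (slash) is used.
#'
#' @param obs a [PairObservation-class].
#' @param path output path (plain text).
#' @param sampleNames character(2) sample identifiers.
#' @return `path`, invisibly.
#' @export
writePairVcf <- function(obs, path, sampleNames = c("IND_A", "IND_B")) {
  m <- obs@panel@markers
  gtOf <- function(g, hap, i) {
    if (!is.null(hap)) return(paste(hap[1L, i], hap[2L, i], sep = "|"))
    if (is.na(g[i])) return("./.")
    c("0/0", "0/1", "1/1")[g[i] + 1L]
  }
  gA <- vapply(seq_len(nrow(m)),
               function(i) gtOf(obs@genotypesA, obs@haplotypesA, i),
               character(1))
  gB <- vapply(seq_len(nrow(m)),
               function(i) gtOf(obs@genotypesB, obs@haplotypesB, i),
               character(1))
  contigs <- vapply(split(m$bp, m$chrom), max, numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pairkin",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs + 1)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleNames), collapse = "\t"))
  body <- paste(m$chrom, as.integer(m$bp), ".", "A", "G", ".", "PASS", ".",
                "GT", gA, gB, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pair of samples from a VCF into a PairObservation
#'
#' Reads the VCF (via the vcfR parser), keeps biallelic SNP records only
#' (multi-allelic records are dropped and counted), aligns records to the
#' panel markers by (chromosome, position), and converts GT fields to
#' alternative-allele dosages. Panel markers absent from the VCF, or with a
#' missing genotype in either sample, are set to NA and reported in the
#' `n_missing` attribute. Real data carry no true IBD track.
#'
#' @param path VCF path (plain or gzipped).
#' @param sampleA,sampleB sample identifiers in the VCF.
#' @param panel a [SNPPanel-class] to align to.
#' @return a [PairObservation-class] with attributes `n_multiallelic` and
#'   `n_missing`.
#' @export
readVcfPair <- function(path, sampleA, sampleB, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  for (s in c(sampleA, sampleB)) {
    if (!s %in% samples) stop("sample not present in VCF: ", s)
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  nMulti <- sum(multi)
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  m <- panel@markers
  hit <- match(paste(m$chrom, as.integer(m$bp)), key)
  if (all(is.na(hit)))
    stop("no overlap between VCF records and panel markers")
  dose <- function(s) {
    raw <- gt[, s][hit]
    g <- rep(NA_integer_, length(hit))
    ok <- !is.na(raw)
    al <- strsplit(sub(":.*$", "", raw[ok]), "[|/]")
    g[ok] <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    g
  }
  ga <- dose(sampleA); gb <- dose(sampleB)
  obs <- new("PairObservation", genotypesA = ga, genotypesB = gb,
             panel = panel, trueIBD = NULL,
             haplotypesA = NULL, haplotypesB = NULL)
  attr(obs, "n_multiallelic") <- nMulti
  attr(obs, "n_missing") <- sum(is.na(ga) | is.na(gb))
  obs
}

#' Write a true-IBD segment table as TSV
#'
#' Sidecar table for simulated pairs: pair id plus chromosomal coordinates
#' (physical and genetic) and IBD level per segment.
#'
#' @param segments true-IBD data.frame (the `trueIBD` slot).
#' @param path output path.
#' @param pairId identifier written in the first column.
#' @return `path`, invisibly.
#' @export
writeIBDTable <- function(segments, path, pairId = "pair1") {
  x <- cbind(pair_id = pairId,
             segments[c("chrom", "start_bp", "end_bp", "start_cm", "end_cm",
                        "level")])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records the configuration, seeds, package version and file digests of a
#' simulation/inference run so it can be reproduced exactly.
#'
#' @param config named list describing the run.
#' @param seeds named list or vector of every seed used.
#' @param files character vector of output file paths to digest (md5).
#' @return list of class `RunManifest`.
#' @export
runManifest <- function(config = list(), seeds = list(), files = character(0)) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  structure(list(
    package = "pairkin",
    version = as.character(utils::packageVersion("pairkin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds, digests = digests),
    class = "RunManifest")
}

#' @rdname runManifest
#' @param manifest a `RunManifest`.
#' @param path output JSON path.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
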