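# Shared fixtures: small maps and panels built in code.

tinyMap <- function() buildDefaultMap(nChrom = 2, totalCM = 180)

tinyPanel <- function(n = 400, seed = 101, map = tinyMap()) {
  makeFixturePanels(map, sizes = n, seed = seed)[[1L]]
}

# A panel with explicitly chosen markers on one 100 cM chromosome.
handPanel <- function(cm, freq = rep(0.5, length(cm))) {
  snpPanel("hand", data.frame(chrom = "chr1", bp = round(cm * 1e6) + 1,
                              cM = cm, freq = freq))
}

# PairObservation from raw genotype vectors on a given panel.
handObs <- function(ga, gb, panel) {
  new("PairObservation", genotypesA = as.integer(ga),
      genotypesB = as.integer(gb), panel = panel,
      trueIBD = NULL, haplotypesA = NULL, haplotypesB = NULL)
}

CLASSES <- c("S1", "S2", "S3", "S4", "Un")
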