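# One-row-per-pair summary across all inference methods.

#' Summarise a genotype pair with every inference method
#'
#' Runs the five approaches on one pair and returns a single-row
#' data.frame suitable for accumulation across pairs and TSV export:
#' the KING-robust kinship and its threshold call, the ML kappa estimate
#' and its distance call, the five linked (or unlinked) log-likelihoods
#' and the maximum-likelihood call, and the segment and windowed-kinship
#' total cM with their bin calls.
#'
#' @param obs a [PairObservation-class].
#' @param map optional [GeneticMap-class] passed to the segment callers.
#' @param pairId identifier written in the first column.
#' @param mode likelihood mode, "linked" (default) or "unlinked".
#' @return one-row data.frame.
#' @examples
#' map <- buildDefaultMap(2, 200)
#' pan <- makeFixturePanels(map, sizes = 800, seed = 1)[[1]]
#' pairSummary(simulatePair("S1", pan, map, seed = 2), map)
#' @export
pairSummary <- function(obs, map = NULL, pairId = "pair1",
                        mode = c("linked", "unlinked")) {
  mode <- match.arg(mode)
  phi <- suppressWarnings(kingRobustPhi(obs))
  kap <- suppressWarnings(mlKappa(obs))$kappa
  lr <- lrClassify(obs, mode = mode, map = map)
  segTot <- totalSharedCM(callSegments(obs, map = map))
  winTot <- totalSharedCM(windowedSegments(obs, map = map))
  out <- data.frame(
    pair_id = pairId,
    phi_hat = phi,
    kappa0 = unname(kap[1]), kappa1 = unname(kap[2]), kappa2 = unname(kap[3]),
    call_phi = phiThresholdClassify(phi),
    call_kappa = kappaDistanceClassify(kap),
    t(lr$loglik),
    call_lr = lr$call,
    mode = mode,
    total_cm_segment = segTot,
    call_segment = cmClassify(segTot),
    total_cm_windowed = winTot,
    call_windowed = cmClassify(winTot))
  names(out)[names(out) %in% c("S1", "S2", "S3", "S4", "Un")] <-
    paste0("logL_", c("S1", "S2", "S3", "S4", "Un"))
  out
}

#' Write a results table as TSV
#'
#' Thin wrapper used for the per-pair summaries, called-segment tables and
#' classification matrices the pipeline emits.
#'
#' @param x data.frame (or matrix) to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
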