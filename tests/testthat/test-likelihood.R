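test_that("genotype-pair probabilities match the Cotterman table", {
  expect_equal(genotypePairProb(0, 0, 0.5, 0), 0.0625)
  expect_equal(genotypePairProb(0, 0, 0.3, 1), 0.7^3)
  expect_equal(genotypePairProb(0, 2, 0.4, 2), 0)
  # full 9-entry tables sum to 1 for each state (enumeration)
  g <- expand.grid(a = 0:2, b = 0:2)
  for (k in 0:2) {
    expect_equal(sum(genotypePairProb(g$a, g$b, 0.3, k)), 1, info = k)
  }
  expect_error(genotypePairProb(3, 0, 0.5, 0), "genotype")
  expect_error(genotypePairProb(0, 0, 1.2, 0), "p must")
})

test_that("unlinked log-likelihood factorises and matches hand arithmetic", {
  pan <- handPanel(c(10, 30, 60), freq = c(0.5, 0.2, 0.7))
  obs <- handObs(c(0, 1, 2), c(0, 1, 1), pan)
  # kappa = (1,0,0): product of independent genotype probabilities
  ll <- unlinkedLogLik(obs, c(1, 0, 0))
  byHand <- sum(log(genotypePairProb(c(0, 1, 2), c(0, 1, 1),
                                     c(0.5, 0.2, 0.7), 0)))
  expect_equal(ll, byHand)
  # single marker under sib kappa
  pan1 <- handPanel(10, freq = 0.5)
  obs1 <- handObs(0, 0, pan1)
  expect_equal(unlinkedLogLik(obs1, c(0.25, 0.5, 0.25)),
               log(0.25 * 0.0625 + 0.5 * 0.125 + 0.25 * 0.25))
  # a hypothesis against itself has log-LR 0
  expect_equal(unlinkedLogLik(obs, "S2") - unlinkedLogLik(obs, "S2"), 0)
  # impossible observation flagged distinctly
  oppo <- handObs(c(0, 0, 0), c(2, 2, 2), pan)
  llz <- unlinkedLogLik(oppo, c(0, 0, 1))
  expect_identical(as.numeric(llz), -Inf)
  expect_equal(attr(llz, "n_zero_markers"), 3L)
})

# Independent oracle: exhaustive enumeration over IBD-state paths with
# transition matrices obtained by matrix exponentiation of the generator.
enumLogLik <- function(obs, label) {
  m <- panelMarkers(obs@panel)
  p <- m$freq; cm <- m$cM
  spec <- relationshipSpec(label)
  if (label == "S1") {
    states <- expand.grid(c1 = 0:1, c2 = 0:1)
    lev <- states$c1 + states$c2
    pi0 <- rep(0.25, 4)
    trans <- function(d) {
      Q1 <- 0.02 * (matrix(0.5, 2, 2) - diag(2))
      P1 <- as.matrix(Matrix::expm(Q1 * d))
      kronecker(P1, P1)   # (c2 varies fastest in expand.grid order)
    }
  } else if (label == "Un") {
    lev <- 0L; pi0 <- 1
    trans <- function(d) matrix(1, 1, 1)
  } else {
    lev <- 0:1
    pi0 <- spec@kappa[1:2]
    a <- spec@meioses / 100
    Pi <- matrix(pi0, 2, 2, byrow = TRUE)
    trans <- function(d) as.matrix(Matrix::expm(a * (Pi - diag(2)) * d))
  }
  M <- length(p)
  ns <- length(pi0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), M)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- pi0[s[1L]] *
      genotypePairProb(obs@genotypesA[1L], obs@genotypesB[1L], p[1L],
                       lev[s[1L]])
    if (M > 1L) for (t in 2:M) {
      P <- trans(cm[t] - cm[t - 1L])
      pr <- pr * P[s[t - 1L], s[t]] *
        genotypePairProb(obs@genotypesA[t], obs@genotypesB[t], p[t],
                         lev[s[t]])
    }
    tot <- tot + pr
  }
  log(tot)
}

test_that("linked likelihood equals exhaustive path enumeration", {
  skip_if_not_installed("Matrix")
  pan2 <- handPanel(c(10, 22), freq = c(0.5, 0.5))
  pan3 <- handPanel(c(5, 18, 40), freq = c(0.3, 0.6, 0.45))
  cases <- list(
    list(handObs(c(1, 1), c(1, 2), pan2), "S1"),
    list(handObs(c(0, 2), c(0, 2), pan2), "S2"),
    list(handObs(c(2, 1, 0), c(2, 1, 2), pan3), "S1"),
    list(handObs(c(0, 1, 2), c(1, 1, 2), pan3), "S2"),
    list(handObs(c(0, 1, 2), c(1, 1, 2), pan3), "S3"),
    list(handObs(c(0, 1, 2), c(1, 1, 2), pan3), "S4"),
    list(handObs(c(0, 1, 2), c(1, 1, 2), pan3), "Un"))
  for (cs in cases) {
    expect_equal(linkedLogLik(cs[[1]], cs[[2]]), enumLogLik(cs[[1]], cs[[2]]),
                 tolerance = 1e-9, info = cs[[2]])
  }
})

test_that("linked likelihood approaches the unlinked one as spacing grows", {
  set.seed(12)
  nm <- 30
  for (label in c("S1", "S3")) {
    for (gap in c(100, 1000)) {
      pan <- handPanel(seq(0, by = gap, length.out = nm) + 1,
                       freq = runif(nm, 0.2, 0.8))
      # keep markers on a single long chromosome
      pan@markers$chrom <- "chr1"
      g <- replicate(2, sample(0:2, nm, replace = TRUE,
                               prob = c(0.36, 0.48, 0.16)))
      obs <- handObs(g[, 1], g[, 2], pan)
      dPer <- abs(linkedLogLik(obs, label) -
                    as.numeric(unlinkedLogLik(obs, label))) / nm
      if (gap == 100) expect_lt(dPer, 0.02) else expect_lt(dPer, 1e-6)
    }
  }
})

test_that("degenerate chains: Un equals unlinked and d = 0 is the identity", {
  pan <- tinyPanel(200)
  obs <- simulateUnrelatedPair(pan, seed = 50)
  expect_equal(linkedLogLik(obs, "Un"),
               as.numeric(unlinkedLogLik(obs, c(1, 0, 0))))
  # transition sanity for the internal two-state kernel
  P0 <- pairkin:::.ibdTransition(0, c(0.75, 0.25), 0.04)
  expect_equal(P0, diag(2), tolerance = 1e-12)
  Pd <- pairkin:::.ibdTransition(37, c(0.75, 0.25), 0.04)
  expect_equal(rowSums(Pd), c(1, 1), tolerance = 1e-12)
  expect_equal(as.numeric(c(0.75, 0.25) %*% Pd), c(0.75, 0.25),
               tolerance = 1e-12)
  Pinf <- pairkin:::.ibdTransition(1e6, c(0.75, 0.25), 0.04)
  expect_equal(Pinf[1, ], Pinf[2, ], tolerance = 1e-12)
})

test_that("LR classification is calibrated and ties break toward distant", {
  # empty marker set: all likelihoods zero -> Un by tie-break
  emptyPan <- new("SNPPanel", name = "none",
                  markers = data.frame(chrom = "chr1", bp = 1, cM = 1,
                                       freq = 0.5)[0, ])
  emptyObs <- new("PairObservation", genotypesA = integer(0),
                  genotypesB = integer(0), panel = emptyPan, trueIBD = NULL,
                  haplotypesA = NULL, haplotypesB = NULL)
  res <- lrClassify(emptyObs, mode = "unlinked")
  expect_equal(res$call, "Un")
  expect_true(all(res$loglik == 0))
  # mean per-marker log-LR of the true class vs Un is positive and grows
  # with marker count
  map <- tinyMap()
  set.seed(21)
  lrPer <- vapply(c(150, 600), function(n) {
    pan <- tinyPanel(n, seed = 900 + n)
    mean(vapply(1:10, function(i) {
      obs <- simulatePair("S2", pan, map, seed = 6000 + 17 * i + n)
      (linkedLogLik(obs, "S2") - linkedLogLik(obs, "Un"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(lrPer > 0))
  expect_gt(lrPer[2], lrPer[1])
  # optional LR buffer declares near-ties inconclusive
  pan1 <- handPanel(10, freq = 0.5)
  obs1 <- handObs(1, 1, pan1)
  expect_equal(lrClassify(obs1, mode = "unlinked",
                          lrThreshold = 10)$call, "INCONCLUSIVE")
})
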