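test_that("IBS counts match a naive per-marker loop", {
  set.seed(33)
  pan <- tinyPanel(500)
  ga <- sample(0:2, 500, replace = TRUE)
  gb <- sample(0:2, 500, replace = TRUE)
  cnt <- ibsCounts(handObs(ga, gb, pan))
  naive <- c(0L, 0L, 0L, 0L)
  for (i in 1:500) {
    if (ga[i] == 1 && gb[i] == 1) naive[1] <- naive[1] + 1L
    if (abs(ga[i] - gb[i]) == 2) naive[2] <- naive[2] + 1L
    if (ga[i] == 1) naive[3] <- naive[3] + 1L
    if (gb[i] == 1) naive[4] <- naive[4] + 1L
  }
  expect_equal(c(cnt$nHetHet, cnt$nOppHom, cnt$nHetA, cnt$nHetB), naive)
  expect_equal(cnt$nMarkers, 500L)
  # identical all-heterozygous vectors
  cnt2 <- ibsCounts(handObs(rep(1, 10), rep(1, 10), handPanel(1:10)))
  expect_equal(c(cnt2$nHetHet, cnt2$nOppHom, cnt2$nHetA, cnt2$nHetB),
               c(10L, 0L, 10L, 10L))
  # all opposite homozygotes
  cnt3 <- ibsCounts(handObs(rep(0, 8), rep(2, 8), handPanel(1:8)))
  expect_equal(cnt3$nOppHom, 8L)
})

test_that("KING-robust kinship reproduces hand values and self-pairs", {
  # worked example
  cnt <- structure(list(nHetHet = 100, nOppHom = 10, nHetA = 200,
                        nHetB = 300, nMarkers = 1000), class = "IBSCounts")
  expect_equal(kingRobustPhi(cnt), 0.075)
  # a pair with itself: phi = 0.5 exactly
  set.seed(4)
  g <- sample(0:2, 400, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  self <- handObs(g, g, tinyPanel(400))
  expect_equal(kingRobustPhi(self), 0.5)
  # undefined without heterozygotes in the reference individual
  mono <- handObs(rep(0, 5), rep(0, 5), handPanel(1:5))
  expect_warning(out <- kingRobustPhi(mono), "undefined")
  expect_true(is.na(out))
})

test_that("KING-robust kinship is calibrated on simulated pairs", {
  map <- buildDefaultMap()
  pan <- makeFixturePanels(map, sizes = 4000, seed = 55)[[1]]
  set.seed(19)
  # full siblings centre at 0.25 under the default reference convention
  phiS1 <- vapply(1:30, function(i)
    kingRobustPhi(simulatePair("S1", pan, map, seed = 100 + i)), numeric(1))
  expect_lt(abs(mean(phiS1) - 0.25), 0.015)
  # unrelated pairs centre at 0
  phiUn <- vapply(1:40, function(i)
    kingRobustPhi(simulateUnrelatedPair(pan, map, seed = 500 + i)),
    numeric(1))
  expect_lt(abs(mean(phiUn)), 3 * sd(phiUn) / sqrt(40))
  # both reference conventions agree in expectation on matched data
  phiLow <- vapply(1:30, function(i)
    kingRobustPhi(simulatePair("S1", pan, map, seed = 100 + i),
                  reference = "lower"), numeric(1))
  expect_lt(abs(mean(phiLow) - 0.25), 0.015)
})

test_that("EM kappa estimation is consistent, monotone and matches a grid", {
  # vertex consistency: data from unrelated pairs
  map <- buildDefaultMap()
  pan <- makeFixturePanels(map, sizes = 50000, seed = 66)[[1]]
  obs <- simulateUnrelatedPair(pan, map, seed = 3)
  est <- suppressWarnings(mlKappa(obs))
  expect_gte(est$kappa[1], 0.99)
  # tiny instance: EM optimum matches a 0.001-resolution simplex grid search
  pan3 <- handPanel(c(5, 30, 70), freq = c(0.4, 0.6, 0.25))
  obs3 <- handObs(c(1, 2, 0), c(1, 2, 1), pan3)
  est3 <- suppressWarnings(mlKappa(obs3))
  k0 <- rep(seq(0, 1, by = 0.001), each = 1001)
  k1 <- rep(seq(0, 1, by = 0.001), times = 1001)
  ok <- k0 + k1 <= 1
  G <- cbind(k0[ok], k1[ok], 1 - k0[ok] - k1[ok])
  P <- vapply(1:3, function(m)
    genotypePairProb(rep(obs3@genotypesA[m], 3), rep(obs3@genotypesB[m], 3),
                     panelMarkers(pan3)$freq[m], 0:2), numeric(3))
  gridLL <- rowSums(log(G %*% P))
  expect_gte(est3$loglik, max(gridLL) - 1e-6)
  # EM monotonicity of the composite log-likelihood
  pan2 <- tinyPanel(200, seed = 77)
  obs2 <- simulateUnrelatedPair(pan2, seed = 11)
  tb <- pairkin:::.emissionTables(panelMarkers(pan2)$freq)
  idx <- cbind(obs2@genotypesA * 3L + obs2@genotypesB + 1L, 1:200)
  P2 <- rbind(tb$T0[idx], tb$T1[idx], tb$T2[idx])
  kap <- rep(1 / 3, 3)
  lls <- numeric(30)
  for (it in 1:30) {
    W <- kap * P2
    s <- colSums(W)
    lls[it] <- sum(log(s))
    kap <- rowMeans(W / rep(s, each = 3))
  }
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("kappa recovery is unbiased across classes at realistic density", {
  map <- buildDefaultMap()
  pan <- makeFixturePanels(map, sizes = 10000, seed = 88)[[1]]
  set.seed(14)
  for (cl in c("S1", "S3")) {
    est <- t(vapply(1:12, function(i) {
      obs <- simulatePair(cl, pan, map, seed = 2000 + i)
      suppressWarnings(mlKappa(obs))$kappa
    }, numeric(3)))
    expect_true(all(abs(colMeans(est) - kappaClosedForm(cl)) < 0.05),
                info = cl)
  }
})

test_that("kinship threshold bins partition the line with the stated ties", {
  expect_equal(phiThresholdClassify(c(0.25, 0.0625, 0.015625, 0.0039, 0)),
               c("S1", "S2", "S3", "S4", "Un"))
  # exact boundary goes to the more distant class
  expect_equal(phiThresholdClassify(0.125), "S2")
  expect_equal(phiThresholdClassify(2^-9), "Un")
  expect_equal(phiThresholdClassify(-0.07), "Un")
  # every value maps to exactly one class
  xs <- seq(-0.2, 0.6, by = 0.001)
  expect_true(all(phiThresholdClassify(xs) %in% CLASSES))
})

test_that("kappa-distance classification uses the published table", {
  expect_equal(kappaDistanceClassify(c(0.75, 0.25, 0)), "S2")
  expect_equal(kappaDistanceClassify(c(1, 0, 0)), "Un")
  # nearest of S2/S3 decided by explicit distances
  k <- c(0.85, 0.15, 0)
  ref <- kappaReferenceTable()
  d <- sqrt(rowSums(sweep(ref, 2, k)^2))
  expect_equal(kappaDistanceClassify(k), names(which.min(d)))
  expect_equal(kappaDistanceClassify(k), "S3")
})
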