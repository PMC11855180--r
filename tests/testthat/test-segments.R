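test_that("identical genotype vectors give one segment per chromosome", {
  pan <- handPanel(seq(1, 99, by = 1))
  g <- rep(c(0L, 1L, 2L), length.out = 99)
  obs <- handObs(g, g, pan)
  seg <- callSegments(obs, params = segmentCallParams(minCM = 5, minSnps = 10))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_cm, 1)
  expect_equal(seg$end_cm, 99)
  expect_equal(seg$n_snps, 99L)
})

test_that("a single opposite-homozygote marker splits a run in two", {
  pan <- handPanel(seq(1, 99, by = 1))
  ga <- rep(1L, 99); gb <- rep(1L, 99)
  ga[50] <- 0L; gb[50] <- 2L
  seg <- callSegments(handObs(ga, gb, pan),
                      params = segmentCallParams(minCM = 5, minSnps = 10))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start_cm, c(1, 51))
  expect_equal(seg$end_cm, c(49, 99))
})

test_that("called segments never contain an IBS0 site", {
  map <- tinyMap()
  pan <- tinyPanel(800, seed = 5)
  m <- panelMarkers(pan)
  for (s in 1:5) {
    obs <- simulatePair("S2", pan, map, seed = 40 + s)
    obs <- injectErrors(obs, errorModel(homToOpp = 0.01), seed = s)
    seg <- callSegments(obs, params = segmentCallParams(minCM = 5,
                                                        minSnps = 5))
    ib0 <- (obs@genotypesA == 0L & obs@genotypesB == 2L) |
      (obs@genotypesA == 2L & obs@genotypesB == 0L)
    for (i in seq_len(nrow(seg))) {
      inside <- m$chrom == seg$chrom[i] & m$cM >= seg$start_cm[i] &
        m$cM <= seg$end_cm[i]
      expect_false(any(ib0[inside]))
    }
  }
})

test_that("raising either threshold never increases the total called cM", {
  map <- tinyMap()
  pan <- tinyPanel(800, seed = 6)
  for (s in 1:4) {
    obs <- simulatePair("S1", pan, map, seed = 60 + s)
    tots <- vapply(c(5, 10, 20), function(mc)
      totalSharedCM(callSegments(obs, params = segmentCallParams(
        minCM = mc, minSnps = 5))), numeric(1))
    expect_true(all(diff(tots) <= 1e-9))
    totsN <- vapply(c(5L, 20L, 60L), function(ms)
      totalSharedCM(callSegments(obs, params = segmentCallParams(
        minCM = 5, minSnps = ms))), numeric(1))
    expect_true(all(diff(totsN) <= 1e-9))
  }
})

test_that("every qualifying true segment is covered by a called segment", {
  map <- tinyMap()
  pan <- tinyPanel(900, seed = 7)
  m <- panelMarkers(pan)
  params <- segmentCallParams(minCM = 5, minSnps = 10)
  for (s in 1:5) {
    obs <- simulatePair("S2", pan, map, seed = 80 + s)
    seg <- callSegments(obs, params = params)
    tru <- pairkin:::.halfIdenticalUnion(obs@trueIBD)
    for (i in seq_len(nrow(tru))) {
      inside <- which(m$chrom == tru$chrom[i] & m$cM >= tru$start_cm[i] &
                      m$cM <= tru$end_cm[i])
      if (length(inside) < params$minSnps) next
      span <- m$cM[inside[length(inside)]] - m$cM[inside[1L]]
      if (span < params$minCM) next
      covered <- any(seg$chrom == tru$chrom[i] &
                     seg$start_cm <= m$cM[inside[1L]] + 1e-9 &
                     seg$end_cm >= m$cM[inside[length(inside)]] - 1e-9)
      expect_true(covered)
    }
  }
})

test_that("the default minimum SNP count scales sensibly with density", {
  map <- buildDefaultMap()
  panels <- makeFixturePanels(map, sizes = c(92, 9618, 142350), seed = 9)
  n92 <- defaultMinSnps(panels[[1]], map = map)
  n10k <- defaultMinSnps(panels[[2]], map = map)
  n142k <- defaultMinSnps(panels[[3]], map = map)
  # mid-density panel needs fewer markers per segment than the dense panel
  expect_lt(n10k, n142k)
  expect_true(n10k >= 16L && n10k <= 500L)
  # sparse panel: the requirement exceeds any chromosome's marker count,
  # disabling segment calling (the panel is unsuited to the approach)
  perChrom <- table(panelMarkers(panels[[1]])$chrom)
  expect_gt(n92, max(perChrom))
})

test_that("windowed caller recovers unbroken sharing and totals add up", {
  pan <- handPanel(seq(0.5, 99.5, by = 0.5))  # 199 markers, one chromosome
  g <- rep(1L, 199)
  obs <- handObs(g, g, pan)
  seg <- windowedSegments(obs, params = windowParams(windowSize = 30))
  expect_equal(nrow(seg), 1L)   # one superwindow spanning the chromosome
  expect_equal(seg$source, "windowed")
  expect_gte(seg$end_cm - seg$start_cm, 95)
  expect_equal(totalSharedCM(seg), seg$end_cm - seg$start_cm)
  # totals
  expect_equal(totalSharedCM(data.frame(start_cm = c(0, 20),
                                        end_cm = c(10, 25.5))), 15.5)
  expect_equal(totalSharedCM(NULL), 0)
})

test_that("windowed and plain segment totals agree on sibling pairs", {
  map <- buildDefaultMap()
  pan <- makeFixturePanels(map, sizes = 9618, seed = 10)[[1]]
  set.seed(23)
  tot <- t(vapply(1:15, function(i) {
    obs <- simulatePair("S1", pan, map, seed = 700 + i)
    c(seg = totalSharedCM(callSegments(obs, map = map)),
      win = totalSharedCM(windowedSegments(obs, map = map)))
  }, numeric(2)))
  # the two callers over-extend differently at chance-run boundaries, so
  # agreement is close but not exact
  expect_lt(abs(mean(tot[, "seg"]) - mean(tot[, "win"])) / mean(tot[, "seg"]),
            0.1)
})

test_that("windowed caller tolerates heterozygote errors via its f slack", {
  map <- tinyMap()
  pan <- tinyPanel(900, seed = 12)
  obs <- simulatePair("S1", pan, map, seed = 3)
  base <- totalSharedCM(windowedSegments(obs, map = map))
  pert <- injectErrors(obs, errorModel(homToHet = 0.02), seed = 4)
  expect_equal(totalSharedCM(windowedSegments(pert, map = map)), base,
               tolerance = 0.1)
})
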