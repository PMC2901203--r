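test_that("founder population is Bernoulli(0.5) and reproducible", {
  map <- locusMap(200L, 0.01)
  pop <- initPopulation(map, size = 500L, seed = 11)
  h <- haplotypes(pop)
  expect_identical(dim(h), c(1000L, 200L))
  expect_true(all(h %in% 0:1))
  expect_identical(generation(pop), 0L)
  # each locus frequency is Binomial(1000, 0.5)/1000; 5 sigma band
  expect_true(all(abs(colMeans(h) - 0.5) < 5 * sqrt(0.25 / 1000)))
  # overall mean has se ~ 0.5/sqrt(200000)
  expect_lt(abs(mean(h) - 0.5), 0.01)

  pop2 <- initPopulation(map, size = 500L, seed = 11)
  expect_identical(haplotypes(pop), haplotypes(pop2))

  tiny <- initPopulation(locusMap(10L), 1L, seed = 3)
  expect_identical(dim(haplotypes(tiny)), c(2L, 10L))
  expect_error(initPopulation(map, 0L), "positive")
})

test_that("random mating is neutral: allele frequencies are a martingale", {
  map <- locusMap(100L, 0.01)
  set.seed(21)
  pop <- initPopulation(map, 300L)
  f0 <- colMeans(haplotypes(pop))
  nxt <- advanceGeneration(pop, map, 300L, mutationRate = 0)
  f1 <- colMeans(haplotypes(nxt))
  expect_identical(generation(nxt), 1L)
  # drift is mean-zero: per-locus change has sd sqrt(f(1-f)/600)
  expect_lt(abs(mean(f1 - f0)), 4 * sqrt(mean(f0 * (1 - f0)) / 600 / 100))
})

test_that("heterozygosity decays as H0 (1 - 1/(2N))^t under pure drift", {
  map <- locusMap(200L, 0.01)
  N <- 30L; tGen <- 60L; nRep <- 20L
  hetRatio <- numeric(nRep)
  set.seed(31)
  for (r in seq_len(nRep)) {
    pop <- initPopulation(map, N)
    f0 <- colMeans(haplotypes(pop))
    h0 <- mean(2 * f0 * (1 - f0))
    for (t in seq_len(tGen)) pop <- advanceGeneration(pop, map, N, 0)
    ft <- colMeans(haplotypes(pop))
    hetRatio[r] <- mean(2 * ft * (1 - ft)) / h0
  }
  expected <- (1 - 1 / (2 * N))^tGen
  se <- sd(hetRatio) / sqrt(nRep)
  expect_lt(abs(mean(hetRatio) - expected), 3 * se + 0.005)
})

test_that("two-phase history has the right census and degenerate phases", {
  map <- locusMap(50L, 0.01)
  demo <- demographyConfig(50L, 4L, 20L, 2L, mutationRate = 1e-4)
  pop <- runHistory(map, demo, seed = 5)
  expect_identical(nrow(haplotypes(pop)), 40L)
  expect_identical(populationSize(pop), 20L)

  demo0 <- demographyConfig(10L, 0L, 10L, 0L)
  set.seed(7)
  pop0 <- runHistory(map, demo0, seed = 7)
  set.seed(7)
  init <- initPopulation(map, 10L)
  expect_identical(haplotypes(pop0), haplotypes(init))
})

test_that("full history keeps most bins segregating and shows LD decay", {
  map <- locusMap(2000L, 0.01)
  segFrac <- r2cor <- numeric(2)
  for (r in 1:2) {
    pop <- runHistory(map, demographyConfig(), seed = 100 + r)
    f <- colMeans(haplotypes(pop))
    seg <- f > 0 & f < 1
    bins <- split(seg & lociRoles(map) == "marker",
                  rep(1:200, each = 10))
    segFrac[r] <- mean(vapply(bins, any, logical(1)))

    # r^2 between segregating marker pairs decreases with map distance
    idx <- which(seg)
    idx <- idx[seq(1, length(idx), length.out = min(60, length(idx)))]
    h <- haplotypes(pop)[, idx]
    r2 <- cor(h)^2
    d <- abs(outer(positionsCM(map)[idx], positionsCM(map)[idx], "-"))
    up <- upper.tri(r2)
    r2cor[r] <- cor(d[up], r2[up], method = "spearman")
  }
  expect_gt(mean(segFrac), 0.9)   # segregating marker available per bin
  expect_lt(mean(r2cor), -0.2)    # LD decays with distance
})

test_that("panel selection follows the argmin-|f - 0.5| and tie rules", {
  # 30 bins; make bin 1 frequencies known, put the best QTL mid-segment
  freqs <- rep(0.5, 300)
  freqs[1:10] <- c(0.1, 0.48, 0.9, 0.7, 0.2, 0.3, 0.65, 0.8, 0.15, 0.45)
  qtlLoci <- seq(10, 300, by = 10)
  freqs[qtlLoci] <- 0.2
  freqs[150] <- 0.5           # bin 15 QTL: frequency exactly 0.5 -> chosen
  set.seed(13)
  pop <- makePopWithFreqs(freqs, size = 50L)
  map <- locusMap(300L, 0.01)
  panel <- selectMarkersAndQtl(pop, map)

  expect_identical(panel@binMarkers[1], 2L)     # 0.48 closest to 0.5
  expect_identical(panel@qtlIndex, 150L)
  expect_identical(panel@qtlBin, 15L)
  # window: 11 markers, QTL 0.3 cM right of the first, bins 12..22
  expect_identical(length(windowMarkers(panel)), 11L)
  expect_identical(panel@windowBins, 12:22)
  expect_equal(positionsCM(panel), seq(0, 1, by = 0.1))
  expect_equal(qtlPositionCM(panel), 0.3)

  # tie: two markers equidistant from 0.5 -> lowest index deterministically
  freqs2 <- rep(0.5, 300); freqs2[qtlLoci] <- 0.3
  freqs2[150] <- 0.5
  freqs2[11:19] <- 0.2
  freqs2[13] <- 0.6; freqs2[17] <- 0.4   # both |f - 0.5| = 0.1
  pop2 <- makePopWithFreqs(freqs2, size = 50L)
  expect_identical(selectMarkersAndQtl(pop2, map)@binMarkers[2], 13L)
})

test_that("panel construction fails cleanly on degenerate final populations", {
  map <- locusMap(300L, 0.01)
  # all loci fixed -> monomorphic QTL
  freqs <- rep(1, 300)
  expect_error(selectMarkersAndQtl(makePopWithFreqs(freqs, 10L), map),
               class = "bgf_panel_error")
  # QTL segregating but a window bin monomorphic
  freqs2 <- rep(0.5, 300)
  freqs2[seq(10, 300, by = 10)] <- 0.3
  freqs2[150] <- 0.5
  freqs2[111:119] <- 0            # bin 12 (first window bin) fixed
  expect_error(selectMarkersAndQtl(makePopWithFreqs(freqs2, 10L), map),
               class = "bgf_panel_error")
  # chosen QTL too close to the segment edge for the window
  freqs3 <- rep(0.5, 300)
  freqs3[seq(10, 300, by = 10)] <- 0.3
  freqs3[10] <- 0.5               # best QTL in bin 1
  expect_error(selectMarkersAndQtl(makePopWithFreqs(freqs3, 10L), map),
               class = "bgf_panel_error")
})

test_that("study sampling preserves pool allele frequencies", {
  map <- locusMap(300L, 0.01)
  pop <- runHistory(map, demographyConfig(60L, 40L, 60L, 0L,
                                          mutationRate = 0), seed = 42)
  panel <- selectMarkersAndQtl(pop, map)
  n <- 20000L
  study <- sampleStudyPopulation(pop, panel, map, n, mutationRate = 0)
  expect_identical(nIndividuals(study), n)
  poolF <- colMeans(haplotypes(pop))[windowMarkers(panel)]
  sampF <- (colMeans(maternalHaplotypes(study)) +
              colMeans(paternalHaplotypes(study))) / 2
  se <- sqrt(poolF * (1 - poolF) / (2 * n))
  expect_true(all(abs(sampF - poolF) < 4 * se + 1e-9))
  # QTL genotype is the sum of the two gamete alleles by construction
  expect_true(all(qtlGenotypes(study) %in% 0:2))

  set.seed(99); s1 <- sampleStudyPopulation(pop, panel, map, 50L)
  set.seed(99); s2 <- sampleStudyPopulation(pop, panel, map, 50L)
  expect_identical(maternalHaplotypes(s1), maternalHaplotypes(s2))
})

test_that("phenotypes carry the requested QTL variance fraction", {
  # algebra: f = 0.05, p = 0.5 -> mu = sqrt(0.1)
  n <- 100000L
  set.seed(51)
  g <- rbinom(n, 2L, 0.5)
  st <- makeStudy(matrix(0L, n, 2), matrix(0L, n, 2), qtlGeno = g,
                  poolFreq = 0.5)
  st <- simulatePhenotypes(st, 0.05)
  muTrue <- sqrt(0.05 / (2 * 0.5 * 0.5))
  expect_equal(muTrue, sqrt(0.1))
  fit <- coef(lm(phenotypes(st) ~ g))
  expect_lt(abs(fit[2] - muTrue), 0.01)
  fracHat <- var(g * muTrue) / var(phenotypes(st))
  expect_lt(abs(fracHat - 0.05), 3 * 0.05 * sqrt(2 / n) + 0.002)

  st0 <- simulatePhenotypes(st, 0)
  expect_lt(abs(var(phenotypes(st0)) - 1), 0.02)

  bad <- makeStudy(matrix(0L, 10, 2), matrix(0L, 10, 2),
                   qtlGeno = rep(0L, 10), poolFreq = 0)
  expect_error(simulatePhenotypes(bad, 0.05),
               class = "bgf_degenerate_qtl")
  expect_error(simulatePhenotypes(st, 1.2), "qtlVarianceFraction")
})

test_that("window geometry gives markers - 1 candidate brackets", {
  for (sp in c(0.01, 0.005, 0.002)) {
    nWin <- as.integer(round(1 / (10 * sp))) + 1L
    st <- makeStudy(matrix(rbinom(20 * nWin, 1, 0.5), 20, nWin),
                    matrix(rbinom(20 * nWin, 1, 0.5), 20, nWin),
                    positions = (seq_len(nWin) - 1) * 10 * sp)
    expect_identical(length(candidatePositions(st, 1L)), as.integer(nWin))
    expect_identical(length(candidatePositions(st, 2L)), nWin - 1L)
  }
})
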