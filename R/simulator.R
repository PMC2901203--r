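#' Initialize a founder population in linkage equilibrium
#'
#' Every allele is an independent Bernoulli(0.5) draw, which puts the founder
#' generation in Hardy-Weinberg and linkage equilibrium with expected allele
#' frequency 0.5 at every locus.
#'
#' @param map a [LocusMap-class].
#' @param size census size (number of diploid individuals).
#' @param seed optional RNG seed.
#' @return A [PopulationHaplotypes-class] at generation 0.
#' @examples
#' pop <- initPopulation(locusMap(100), size = 20, seed = 1)
#' mean(haplotypes(pop))
#' @export
initPopulation <- function(map, size, seed = NULL) {
  stopifnot(is(map, "LocusMap"))
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("size must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  h <- matrix(rbinom(2L * size * nLoci(map), 1L, 0.5),
              nrow = 2L * size, ncol = nLoci(map))
  storage.mode(h) <- "integer"
  new("PopulationHaplotypes", haplotypes = h, generation = 0L,
      populationSize = size)
}

#' Advance a population by one generation of random mating
#'
#' Each of `nextSize` offspring is formed from two parents drawn uniformly
#' with replacement (selfing allowed). Each transmitted gamete is produced by
#' a meiosis in which crossovers fall as a Poisson process along the genetic
#' map (rate = map length in Morgans, no interference), so adjacent loci
#' `d` cM apart recombine with probability ~`d/100`. Each transmitted allele
#' then flips with probability `mutationRate`.
#'
#' @param pop a [PopulationHaplotypes-class].
#' @param map the [LocusMap-class] the population lives on.
#' @param nextSize census size of the offspring generation.
#' @param mutationRate per-locus per-gamete allele flip probability.
#' @return The offspring [PopulationHaplotypes-class].
#' @export
advanceGeneration <- function(pop, map, nextSize, mutationRate = 2.5e-5) {
  stopifnot(is(pop, "PopulationHaplotypes"), is(map, "LocusMap"))
  nextSize <- as.integer(nextSize)
  if (is.na(nextSize) || nextSize < 1L)
    stop("nextSize must be a positive integer")
  h <- t(.cppAdvance(t(haplotypes(pop)), positionsCM(map) / 100,
                     nextSize, mutationRate))
  new("PopulationHaplotypes", haplotypes = h,
      generation = generation(pop) + 1L, populationSize = nextSize)
}

#' Run the two-phase random-mating history
#'
#' Applies [advanceGeneration()] for `phase1Generations` generations at
#' `phase1Size`, then `phase2Generations` at `phase2Size`, and returns the
#' final generation. With the default configuration (500 individuals for
#' 1000 generations, then 100 for 50, mutation rate 2.5e-5, founder allele
#' frequencies 0.5) the segment approaches mutation-drift equilibrium and
#' carries the LD structure the fine-mapping methods exploit.
#'
#' @param map a [LocusMap-class].
#' @param demo a [DemographyConfig-class].
#' @param seed optional RNG seed.
#' @return The final-generation [PopulationHaplotypes-class].
#' @export
runHistory <- function(map, demo = demographyConfig(), seed = NULL) {
  stopifnot(is(map, "LocusMap"), is(demo, "DemographyConfig"))
  if (!is.null(seed)) set.seed(seed)
  pop <- initPopulation(map, demo@phase1Size)
  sizes <- c(rep(demo@phase1Size, demo@phase1Generations),
             rep(demo@phase2Size, demo@phase2Generations))
  if (length(sizes) == 0L) return(pop)
  h <- t(.cppRunHistory(t(haplotypes(pop)), positionsCM(map) / 100,
                        as.integer(sizes), demo@mutationRate))
  new("PopulationHaplotypes", haplotypes = h,
      generation = length(sizes), populationSize = as.integer(sizes[length(sizes)]))
}

#' Select the marker panel and QTL, and place the analysis window
#'
#' In the final generation, each bin of 10 consecutive loci contributes the
#' segregating marker whose allele frequency is closest to 0.5 (ties broken
#' toward the lowest locus index). Among the QTL loci (one per bin), the one
#' with frequency closest to 0.5 is chosen. The 1 cM analysis window consists
#' of consecutive selected markers positioned so that the chosen QTL lies
#' exactly 0.3 cM to the right of the window's first marker on the analysis
#' grid: window marker `j` (0-based) sits at `j * s` cM, where `s` is the
#' marker spacing (10 x locus spacing), giving 11, 21 or 51 window markers
#' for spacings 0.1, 0.05 and 0.02 cM.
#'
#' @param pop final-generation [PopulationHaplotypes-class].
#' @param map the [LocusMap-class].
#' @param windowCM window length in cM (default 1).
#' @param qtlOffsetCM distance of the QTL from the first window marker
#'   (default 0.3 cM).
#' @return A [MarkerPanel-class].
#' @section Errors: if the chosen QTL is monomorphic, its window would
#'   overrun the segment, or a required bin has no segregating marker, a
#'   condition of class `bgf_panel_error` is signalled; callers should
#'   resimulate the history with a new seed.
#' @export
selectMarkersAndQtl <- function(pop, map, windowCM = 1, qtlOffsetCM = 0.3) {
  stopifnot(is(pop, "PopulationHaplotypes"), is(map, "LocusMap"))
  freq <- colMeans(haplotypes(pop))
  nBins <- nLoci(map) %/% 10L
  bin <- rep(seq_len(nBins), each = 10L)
  role <- lociRoles(map)

  # per-bin marker: segregating, |freq - 0.5| minimal, ties -> lowest index
  binMarkers <- rep(NA_integer_, nBins)
  for (b in seq_len(nBins)) {
    idx <- which(bin == b & role == "marker" & freq > 0 & freq < 1)
    if (length(idx))
      binMarkers[b] <- idx[which.min(abs(freq[idx] - 0.5))]
  }

  qtlLoci <- which(role == "qtl")
  qtlIndex <- qtlLoci[which.min(abs(freq[qtlLoci] - 0.5))]
  if (freq[qtlIndex] <= 0 || freq[qtlIndex] >= 1)
    .panelError("chosen QTL is monomorphic in the final generation")
  qtlBin <- bin[qtlIndex]

  markerSpacing <- 10 * map@spacingCM
  offsetBins <- as.integer(round(qtlOffsetCM / markerSpacing))
  nWin <- as.integer(round(windowCM / markerSpacing)) + 1L
  firstBin <- qtlBin - offsetBins
  lastBin <- firstBin + nWin - 1L
  if (firstBin < 1L || lastBin > nBins)
    .panelError("analysis window around the chosen QTL overruns the segment")
  windowBins <- seq(firstBin, lastBin)
  if (anyNA(binMarkers[windowBins]))
    .panelError("a window bin has no segregating marker")

  new("MarkerPanel",
      binMarkers = binMarkers,
      qtlIndex = as.integer(qtlIndex),
      qtlBin = as.integer(qtlBin),
      windowBins = as.integer(windowBins),
      windowMarkerIndices = binMarkers[windowBins],
      windowPositionsCM = (seq_len(nWin) - 1) * markerSpacing,
      qtlPositionCM = qtlOffsetCM,
      markerSpacingCM = markerSpacing)
}

.panelError <- function(msg) {
  stop(structure(class = c("bgf_panel_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Draw a study sample of unrelated individuals from the final population
#'
#' Each study individual is formed from two gametes; each gamete is produced
#' by one additional meiosis (recombination and mutation as in
#' [advanceGeneration()]) from an individual drawn uniformly with replacement
#' from the final generation. This preserves the population's
#' haplotype-frequency distribution while allowing the sample size to exceed
#' the final census.
#'
#' @param pop final-generation [PopulationHaplotypes-class].
#' @param panel the [MarkerPanel-class] defining the window and QTL.
#' @param map the [LocusMap-class].
#' @param n number of study individuals.
#' @param mutationRate per-locus per-gamete mutation probability for the
#'   extra meiosis.
#' @return A [StudyData-class] with phased window haplotypes and hidden QTL
#'   genotypes; phenotypes are left empty (see [simulatePhenotypes()]).
#' @export
sampleStudyPopulation <- function(pop, panel, map, n, mutationRate = 2.5e-5) {
  stopifnot(is(pop, "PopulationHaplotypes"), is(panel, "MarkerPanel"),
            is(map, "LocusMap"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  gam <- .cppDropGametes(t(haplotypes(pop)), positionsCM(map) / 100,
                         2L * n, mutationRate)  # loci x gametes
  matCols <- seq(1L, 2L * n, by = 2L)
  patCols <- matCols + 1L
  widx <- windowMarkers(panel)
  maternal <- t(gam[widx, matCols, drop = FALSE])
  paternal <- t(gam[widx, patCols, drop = FALSE])
  qg <- as.integer(gam[panel@qtlIndex, matCols] + gam[panel@qtlIndex, patCols])
  new("StudyData",
      maternal = maternal, paternal = paternal, qtlGenotype = qg,
      phenotypes = numeric(0),
      X = matrix(1, nrow = n, ncol = 1,
                 dimnames = list(NULL, "intercept")),
      qtlVarianceFraction = NA_real_,
      markerPositionsCM = positionsCM(panel),
      qtlPositionCM = qtlPositionCM(panel),
      poolQtlFreq = mean(haplotypes(pop)[, panel@qtlIndex]))
}

#' Simulate phenotypes with an additive QTL of given variance
#'
#' Phenotypes are `y_i = g_i * mu + e_i` with `e_i ~ N(0, 1 - f)`, where
#' `g_i` is the QTL genotype copy number, `f` is the fraction of phenotypic
#' variance explained by the QTL and `mu = sqrt(f / (2 p (1 - p)))` with `p`
#' the QTL allele frequency in the sampling pool, so that the additive QTL
#' variance `2 p (1 - p) mu^2` equals `f` and the total phenotypic variance
#' is approximately 1. With `f = 0` the phenotypes are pure unit-variance
#' noise (the null used for critical-value calibration).
#'
#' @param study a [StudyData-class] from [sampleStudyPopulation()].
#' @param qtlVarianceFraction fraction of phenotypic variance explained by
#'   the QTL (0, 0.02 or 0.05 in the evaluation settings).
#' @return The [StudyData-class] with phenotypes filled in.
#' @section Errors: a pool QTL frequency of 0 or 1 with a non-null fraction
#'   signals a condition of class `bgf_degenerate_qtl`; callers should
#'   resimulate.
#' @export
simulatePhenotypes <- function(study, qtlVarianceFraction) {
  stopifnot(is(study, "StudyData"))
  f <- qtlVarianceFraction
  if (f < 0 || f >= 1)
    stop("qtlVarianceFraction must lie in [0, 1)")
  n <- nIndividuals(study)
  if (f == 0) {
    y <- rnorm(n)
  } else {
    p <- study@poolQtlFreq
    if (is.na(p) || p <= 0 || p >= 1)
      stop(structure(class = c("bgf_degenerate_qtl", "error", "condition"),
                     list(message = "pool QTL frequency is 0 or 1",
                          call = sys.call())))
    muTrue <- sqrt(f / (2 * p * (1 - p)))
    y <- study@qtlGenotype * muTrue + rnorm(n, sd = sqrt(1 - f))
  }
  study@phenotypes <- y
  study@qtlVarianceFraction <- f
  validObject(study)
  study
}

#' Simulate one complete study replicate
#'
#' Convenience wrapper: fresh LD history, panel selection, study sample and
#' phenotypes. Panel construction failures (monomorphic QTL/bins, window at
#' the segment edge) trigger resimulation of the whole history with a new
#' derived seed, up to `maxTries` attempts.
#'
#' @param spacingCM locus spacing in cM (0.01, 0.005 or 0.002, giving marker
#'   spacings of 0.1, 0.05 or 0.02 cM).
#' @param n number of study individuals.
#' @param qtlVarianceFraction fraction of phenotypic variance from the QTL
#'   (0 for a null replicate).
#' @param demo a [DemographyConfig-class].
#' @param seed RNG seed for the replicate.
#' @param history optional [PopulationHaplotypes-class] to reuse instead of
#'   simulating a fresh LD history (its map must match `spacingCM`).
#' @param maxTries maximum number of history attempts.
#' @return A list with elements `study` ([StudyData-class]), `panel`
#'   ([MarkerPanel-class]), `map`, `history`, and `seedUsed`.
#' @export
simulateStudy <- function(spacingCM = 0.01, n = 500L,
                          qtlVarianceFraction = 0.05,
                          demo = demographyConfig(), seed = NULL,
                          history = NULL, maxTries = 20L) {
  map <- locusMap(2000L, spacingCM)
  if (!is.null(seed)) set.seed(seed)
  tries <- if (is.null(history)) maxTries else 1L
  seeds <- sample.int(.Machine$integer.max - 1L, tries)
  for (i in seq_len(tries)) {
    pop <- if (is.null(history)) runHistory(map, demo, seed = seeds[i])
           else history
    panel <- tryCatch(selectMarkersAndQtl(pop, map),
                      bgf_panel_error = function(e) NULL)
    if (is.null(panel)) next
    study <- sampleStudyPopulation(pop, panel, map, n, demo@mutationRate)
    study <- tryCatch(simulatePhenotypes(study, qtlVarianceFraction),
                      bgf_degenerate_qtl = function(e) NULL)
    if (is.null(study)) next
    return(list(study = study, panel = panel, map = map, history = pop,
                seedUsed = seeds[i]))
  }
  stop("no usable panel after ", tries, " simulated histories")
}
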