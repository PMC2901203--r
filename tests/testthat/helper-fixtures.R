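# Fixtures are built in code; nothing is read from disk.

# Assemble a StudyData object directly from its pieces.
makeStudy <- function(maternal, paternal, y = numeric(0),
                      positions = NULL, qtlGeno = integer(0),
                      poolFreq = NA_real_, qtlPos = NA_real_) {
  maternal <- as.matrix(maternal)
  paternal <- as.matrix(paternal)
  storage.mode(maternal) <- "integer"
  storage.mode(paternal) <- "integer"
  if (is.null(positions)) positions <- (seq_len(ncol(maternal)) - 1) * 0.1
  new("StudyData",
      maternal = maternal, paternal = paternal,
      qtlGenotype = as.integer(qtlGeno), phenotypes = as.numeric(y),
      X = matrix(1, nrow(maternal), 1, dimnames = list(NULL, "intercept")),
      qtlVarianceFraction = NA_real_, markerPositionsCM = positions,
      qtlPositionCM = qtlPos, poolQtlFreq = poolFreq)
}

# Synthetic strong-LD study: marker `j0` is associated with the QTL through
# conditional frequencies `piTrue` (gamete allele a at j0 carries Q2 with
# probability piTrue[a + 1]); all other markers are independent noise. The
# QTL explains fraction `f` of unit phenotypic variance.
makeLDStudy <- function(n, piTrue = c(0.05, 0.95), f = 0.05, j0 = 4L,
                        nMarkers = 11L, spacing = 0.1) {
  maternal <- matrix(rbinom(n * nMarkers, 1L, 0.5), n, nMarkers)
  paternal <- matrix(rbinom(n * nMarkers, 1L, 0.5), n, nMarkers)
  qm <- rbinom(n, 1L, piTrue[maternal[, j0] + 1L])
  qp <- rbinom(n, 1L, piTrue[paternal[, j0] + 1L])
  pbar <- mean(piTrue)
  muTrue <- sqrt(f / (2 * pbar * (1 - pbar)))
  y <- (qm + qp) * muTrue + rnorm(n, sd = sqrt(1 - f))
  st <- makeStudy(maternal, paternal, y,
                  positions = (seq_len(nMarkers) - 1) * spacing,
                  qtlGeno = qm + qp, poolFreq = pbar,
                  qtlPos = (j0 - 1) * spacing)
  list(study = st, muTrue = muTrue, j0 = j0)
}

# Population with exactly prescribed per-locus allele frequencies (on a
# gamete grid of size 2 * size); used for deterministic panel-selection
# tests.
makePopWithFreqs <- function(freqs, size = 10L) {
  g <- 2L * size
  h <- vapply(freqs, function(f) {
    ones <- round(f * g)
    sample(rep(c(1L, 0L), c(ones, g - ones)))
  }, integer(g))
  new("PopulationHaplotypes", haplotypes = h, generation = 1L,
      populationSize = as.integer(size))
}

# Independent brute-force evaluation of the joint MH block's log target on
# the sampling scale x = logit(pi): likelihood x N(x) x N(mu). Terms that
# cancel in the block's ratio (residual-variance prior, uniform location
# prior) are omitted. Written without the package's likelihood functions.
bruteLogTargetX <- function(study, state, prior, k) {
  m <- if (k == 1L) {
    l <- state@location
    cbind(maternalHaplotypes(study)[, l], paternalHaplotypes(study)[, l])
  } else {
    l <- state@location
    cbind(2L * maternalHaplotypes(study)[, l] +
            maternalHaplotypes(study)[, l + 1L],
          2L * paternalHaplotypes(study)[, l] +
            paternalHaplotypes(study)[, l + 1L])
  }
  pim <- state@pi[m[, 1] + 1L]
  pip <- state@pi[m[, 2] + 1L]
  mn <- drop(designMatrix(study) %*% state@beta) + (pim + pip) * state@mu
  vr <- state@sigma2e +
    (pim * (1 - pim) + pip * (1 - pip)) * state@mu^2
  ll <- sum(-0.5 * log(2 * pi * vr) - (phenotypes(study) - mn)^2 / (2 * vr))
  x <- log(state@pi / (1 - state@pi))
  ll + sum(-0.5 * log(2 * pi * prior@sigma2X) - x^2 / (2 * prior@sigma2X)) +
    (-0.5 * log(2 * pi * prior@sigma2Mu) -
       state@mu^2 / (2 * prior@sigma2Mu))
}

# Independent brute-force evaluation of the unnormalized log posterior
# (likelihood x priors, pi scale), written from the model definition
# without using the package's likelihood/prior functions.
bruteLogPosterior <- function(study, state, prior, k) {
  m <- if (k == 1L) {
    l <- state@location
    cbind(maternalHaplotypes(study)[, l], paternalHaplotypes(study)[, l])
  } else {
    l <- state@location
    cbind(2L * maternalHaplotypes(study)[, l] +
            maternalHaplotypes(study)[, l + 1L],
          2L * paternalHaplotypes(study)[, l] +
            paternalHaplotypes(study)[, l + 1L])
  }
  pim <- state@pi[m[, 1] + 1L]
  pip <- state@pi[m[, 2] + 1L]
  mn <- drop(designMatrix(study) %*% state@beta) + (pim + pip) * state@mu
  vr <- state@sigma2e +
    (pim * (1 - pim) + pip * (1 - pip)) * state@mu^2
  ll <- sum(-0.5 * log(2 * pi * vr) - (phenotypes(study) - mn)^2 / (2 * vr))
  x <- log(state@pi / (1 - state@pi))
  lpPi <- sum(-0.5 * log(2 * pi * prior@sigma2X) -
                x^2 / (2 * prior@sigma2X)) -
    sum(log(state@pi * (1 - state@pi)))
  lpMu <- -0.5 * log(2 * pi * prior@sigma2Mu) -
    state@mu^2 / (2 * prior@sigma2Mu)
  nu <- prior@nuE; S2 <- prior@s2E
  lpE <- 0.5 * nu * log(nu * S2 / 2) - lgamma(nu / 2) -
    (nu / 2 + 1) * log(state@sigma2e) - nu * S2 / (2 * state@sigma2e)
  nLoc <- if (k == 1L) nMarkers(study) else nMarkers(study) - 1L
  ll + lpPi + lpMu + lpE - log(nLoc)
}
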