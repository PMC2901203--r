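#' Locus map for the simulated chromosomal segment
#'
#' Describes the simulated segment: equally spaced biallelic loci, every tenth
#' locus a QTL, the rest markers. With the default 2000 loci the segment holds
#' 200 bins of 10 consecutive loci; the last locus of each bin is its QTL.
#'
#' @slot nLoci number of loci on the segment.
#' @slot spacingCM distance between adjacent loci in centimorgans.
#' @slot positionsCM locus positions in cM, `(0:(nLoci-1)) * spacingCM`.
#' @slot role `"marker"` or `"qtl"` per locus.
#'
#' @seealso [locusMap()]
#' @export
setClass("LocusMap",
  representation(
    nLoci = "integer",
    spacingCM = "numeric",
    positionsCM = "numeric",
    role = "character"
  ),
  validity = function(object) {
    msg <- NULL
    if (object@spacingCM <= 0) msg <- c(msg, "spacingCM must be positive")
    if (length(object@positionsCM) != object@nLoci)
      msg <- c(msg, "positionsCM length must equal nLoci")
    if (is.unsorted(object@positionsCM, strictly = TRUE))
      msg <- c(msg, "positionsCM must be strictly increasing")
    if (!all(object@role %in% c("marker", "qtl")))
      msg <- c(msg, "role entries must be 'marker' or 'qtl'")
    if (object@nLoci %% 10L == 0L &&
        sum(object@role == "qtl") != object@nLoci %/% 10L)
      msg <- c(msg, "exactly one locus in ten must be a QTL")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a locus map
#'
#' @param nLoci number of loci (default 2000, i.e. 200 bins of 10).
#' @param spacingCM spacing between adjacent loci in cM (0.01, 0.005 or 0.002
#'   give marker spacings of 0.1, 0.05 or 0.02 cM after per-bin selection).
#'
#' @return A [LocusMap-class] object.
#' @examples
#' map <- locusMap(nLoci = 100, spacingCM = 0.01)
#' table(lociRoles(map))
#' @export
locusMap <- function(nLoci = 2000L, spacingCM = 0.01) {
  nLoci <- as.integer(nLoci)
  if (nLoci < 10L || nLoci %% 10L != 0L)
    stop("nLoci must be a positive multiple of 10")
  role <- rep("marker", nLoci)
  role[seq(10L, nLoci, by = 10L)] <- "qtl"
  new("LocusMap",
    nLoci = nLoci, spacingCM = spacingCM,
    positionsCM = (seq_len(nLoci) - 1) * spacingCM, role = role)
}

#' Demographic history configuration
#'
#' Two-phase random-mating history: a larger population for many generations
#' to approach mutation-drift equilibrium, then a bottleneck phase mimicking
#' the reduction of effective population size during breed formation.
#'
#' @slot phase1Size,phase1Generations census size and duration of phase 1.
#' @slot phase2Size,phase2Generations census size and duration of phase 2.
#' @slot mutationRate per-locus, per-transmitted-gamete allele flip
#'   probability.
#' @seealso [demographyConfig()], [runHistory()]
#' @export
setClass("DemographyConfig",
  representation(
    phase1Size = "integer", phase1Generations = "integer",
    phase2Size = "integer", phase2Generations = "integer",
    mutationRate = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (object@phase1Size < 1L || object@phase2Size < 1L)
      msg <- c(msg, "population sizes must be positive")
    if (object@phase1Generations < 0L || object@phase2Generations < 0L)
      msg <- c(msg, "generation counts must be non-negative")
    if (object@mutationRate < 0 || object@mutationRate >= 1)
      msg <- c(msg, "mutationRate must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a demographic history configuration
#'
#' Defaults are a population of 500 for 1000 generations followed by 100 for
#' 50 generations with a mutation rate of 2.5e-5, which together with initial
#' allele frequencies of 0.5 brings the segment close to mutation-drift
#' equilibrium.
#'
#' @param phase1Size,phase1Generations size and length of the first phase.
#' @param phase2Size,phase2Generations size and length of the second phase.
#' @param mutationRate per-locus per-gamete allele flip probability.
#' @return A [DemographyConfig-class] object.
#' @export
demographyConfig <- function(phase1Size = 500L, phase1Generations = 1000L,
                             phase2Size = 100L, phase2Generations = 50L,
                             mutationRate = 2.5e-5) {
  new("DemographyConfig",
    phase1Size = as.integer(phase1Size),
    phase1Generations = as.integer(phase1Generations),
    phase2Size = as.integer(phase2Size),
    phase2Generations = as.integer(phase2Generations),
    mutationRate = mutationRate)
}

#' Population of phased haplotypes
#'
#' A generation of a randomly mating population: one row per gamete (two per
#' individual), one column per locus, alleles coded 0/1.
#'
#' @slot haplotypes integer matrix in \{0,1\}, `2 * populationSize` rows.
#' @slot generation generation index (0 = founder generation).
#' @slot populationSize census size.
#' @export
setClass("PopulationHaplotypes",
  representation(
    haplotypes = "matrix",
    generation = "integer",
    populationSize = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@haplotypes) != 2L * object@populationSize)
      msg <- c(msg, "haplotypes must have 2 * populationSize rows")
    if (length(object@haplotypes) &&
        !all(object@haplotypes == 0L | object@haplotypes == 1L))
      msg <- c(msg, "haplotype entries must be 0 or 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' Marker panel and analysis window
#'
#' Result of per-bin marker selection and QTL identification in the final
#' generation: one marker per bin (the segregating locus with allele frequency
#' closest to 0.5), the QTL locus with frequency closest to 0.5, and a 1 cM
#' analysis window of consecutive selected markers positioned so that the QTL
#' sits exactly 0.3 cM to the right of the window's first marker on the
#' analysis grid.
#'
#' Window markers are assigned idealized grid positions `0, s, 2s, ..., 1` cM
#' (s = marker spacing); the QTL's true position on that grid is 0.3 cM.
#'
#' @slot binMarkers selected locus index per bin (`NA` if the bin had no
#'   segregating marker).
#' @slot qtlIndex locus index of the chosen QTL.
#' @slot qtlBin bin index (1-based) containing the chosen QTL.
#' @slot windowBins indices of the bins contributing the window markers.
#' @slot windowMarkerIndices locus indices of the window markers.
#' @slot windowPositionsCM idealized window-local marker positions in cM.
#' @slot qtlPositionCM true QTL position on the window grid (0.3 cM).
#' @slot markerSpacingCM spacing of the selected markers in cM.
#' @export
setClass("MarkerPanel",
  representation(
    binMarkers = "integer",
    qtlIndex = "integer",
    qtlBin = "integer",
    windowBins = "integer",
    windowMarkerIndices = "integer",
    windowPositionsCM = "numeric",
    qtlPositionCM = "numeric",
    markerSpacingCM = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (length(object@windowMarkerIndices) != length(object@windowPositionsCM))
      msg <- c(msg, "window indices and positions must have equal length")
    if (anyNA(object@windowMarkerIndices))
      msg <- c(msg, "window markers must all be selected (no NA)")
    if (is.unsorted(object@windowPositionsCM, strictly = TRUE))
      msg <- c(msg, "window positions must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  }
)

#' Study data: phased window haplotypes and phenotypes
#'
#' Phased marker haplotypes of unrelated study individuals over the analysis
#' window, with the (hidden) QTL genotype retained as simulation truth, the
#' phenotypes, and the fixed-effect design matrix.
#'
#' @slot maternal,paternal integer matrices in \{0,1\},
#'   individuals x window markers.
#' @slot qtlGenotype integer vector in \{0,1,2\} (simulation truth; not used
#'   by any analysis).
#' @slot phenotypes numeric vector (length 0 until phenotypes are simulated
#'   or supplied).
#' @slot X fixed-effect design matrix (default a single intercept column).
#' @slot qtlVarianceFraction fraction of phenotypic variance explained by the
#'   QTL in simulation (`NA` for real data).
#' @slot markerPositionsCM window-local marker positions in cM.
#' @slot qtlPositionCM true QTL position in cM (`NA` for real data).
#' @slot poolQtlFreq QTL allele frequency in the sampling pool (`NA` for
#'   real data).
#' @export
setClass("StudyData",
  representation(
    maternal = "matrix",
    paternal = "matrix",
    qtlGenotype = "integer",
    phenotypes = "numeric",
    X = "matrix",
    qtlVarianceFraction = "numeric",
    markerPositionsCM = "numeric",
    qtlPositionCM = "numeric",
    poolQtlFreq = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@maternal)
    if (!identical(dim(object@maternal), dim(object@paternal)))
      msg <- c(msg, "maternal and paternal matrices must have equal dimensions")
    if (length(object@maternal) &&
        !all(object@maternal %in% 0:1 & object@paternal %in% 0:1))
      msg <- c(msg, "haplotype alleles must be coded 0/1 (phased)")
    if (length(object@phenotypes) && length(object@phenotypes) != n)
      msg <- c(msg, "phenotypes length must equal the number of individuals")
    if (nrow(object@X) != n)
      msg <- c(msg, "X must have one row per individual")
    if (qr(object@X)$rank < ncol(object@X))
      msg <- c(msg, "X must have full column rank")
    if (ncol(object@maternal) != length(object@markerPositionsCM))
      msg <- c(msg, "markerPositionsCM length must match marker columns")
    if (is.null(msg)) TRUE else msg
  }
)

#' One point in the BGF parameter space
#'
#' @slot beta fixed-effect vector.
#' @slot pi conditional probabilities of QTL allele Q2 on each of the `2^k`
#'   marker haplotypes at the current candidate location; strictly inside
#'   (0, 1).
#' @slot mu QTL allele substitution effect.
#' @slot location candidate-location index (1-based; markers for k = 1,
#'   adjacent brackets for k = 2).
#' @slot sigma2e residual variance.
#' @seealso [bgfState()]
#' @export
setClass("BGFState",
  representation(
    beta = "numeric", pi = "numeric", mu = "numeric",
    location = "integer", sigma2e = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (!length(object@pi) %in% c(2L, 4L))
      msg <- c(msg, "pi must have length 2 (k = 1) or 4 (k = 2)")
    if (any(object@pi <= 0 | object@pi >= 1))
      msg <- c(msg, "pi elements must lie strictly in (0, 1)")
    if (object@sigma2e <= 0) msg <- c(msg, "sigma2e must be positive")
    if (object@location < 1L) msg <- c(msg, "location must be >= 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname BGFState-class
#' @param beta,pi,mu,location,sigma2e see the corresponding slots.
#' @return A [BGFState-class] object.
#' @export
bgfState <- function(beta, pi, mu, location, sigma2e) {
  new("BGFState", beta = as.numeric(beta), pi = as.numeric(pi),
      mu = as.numeric(mu), location = as.integer(location),
      sigma2e = as.numeric(sigma2e))
}

#' Prior configuration for the BGF sampler
#'
#' Flat prior on fixed effects; scaled inverse chi-square on the residual
#' variance; normal with null mean on the QTL effect; logit-normal with null
#' mean and diagonal covariance on the conditional frequencies; discrete
#' uniform on the candidate location.
#'
#' @slot sigma2Mu prior variance of the QTL effect.
#' @slot nuE,s2E degrees of freedom and scale of the scaled inverse
#'   chi-square prior on the residual variance.
#' @slot sigma2X prior variance of each element of `x = logit(pi)`.
#' @seealso [priorConfig()]
#' @export
setClass("PriorConfig",
  representation(sigma2Mu = "numeric", nuE = "numeric", s2E = "numeric",
                 sigma2X = "numeric"),
  validity = function(object) {
    if (any(c(object@sigma2Mu, object@nuE, object@s2E, object@sigma2X) <= 0))
      "all prior hyperparameters must be positive" else TRUE
  }
)

#' @rdname PriorConfig-class
#' @param sigma2Mu,nuE,s2E,sigma2X see the corresponding slots. Defaults are
#'   weakly informative for phenotypes standardized to unit variance; the
#'   logit-scale variance of 4 (sd 2) lets the conditional frequencies reach
#'   the near-degenerate values (~0.02-0.98) that strong LD implies, which a
#'   unit variance would effectively forbid.
#' @return A [PriorConfig-class] object.
#' @export
priorConfig <- function(sigma2Mu = 1, nuE = 4, s2E = 0.5, sigma2X = 4) {
  new("PriorConfig", sigma2Mu = sigma2Mu, nuE = nuE, s2E = s2E,
      sigma2X = sigma2X)
}

#' Random-walk proposal configuration
#'
#' All proposals are symmetric random walks on their sampling scales: normal
#' on `x = logit(pi)`, on the QTL effect and on the residual variance, and a
#' uniform draw over all candidate locations. Variances should be small
#' enough that proposals stay in the neighborhood of the current sample;
#' with `adapt = TRUE` they are tuned during burn-in toward acceptance rates
#' of 0.2-0.5 and then frozen, so the sampling phase uses fixed proposals.
#'
#' @slot sigma2XProp random-walk variance on the logit scale.
#' @slot sigma2MuProp random-walk variance for the QTL effect.
#' @slot sigma2EProp random-walk variance for the residual variance.
#' @slot adapt tune proposal variances during burn-in.
#' @seealso [proposalConfig()]
#' @export
setClass("ProposalConfig",
  representation(sigma2XProp = "numeric", sigma2MuProp = "numeric",
                 sigma2EProp = "numeric", adapt = "logical"),
  validity = function(object) {
    if (any(c(object@sigma2XProp, object@sigma2MuProp,
              object@sigma2EProp) <= 0))
      "all proposal variances must be positive" else TRUE
  }
)

#' @rdname ProposalConfig-class
#' @param sigma2XProp,sigma2MuProp,sigma2EProp,adapt see the slots.
#' @return A [ProposalConfig-class] object.
#' @export
proposalConfig <- function(sigma2XProp = 0.25, sigma2MuProp = 0.01,
                           sigma2EProp = 0.01, adapt = TRUE) {
  new("ProposalConfig", sigma2XProp = sigma2XProp,
      sigma2MuProp = sigma2MuProp, sigma2EProp = sigma2EProp, adapt = adapt)
}

#' Chain length configuration
#'
#' @slot nIterations total sweeps.
#' @slot burnIn sweeps discarded (also the adaptation window).
#' @slot thinning keep every `thinning`-th post-burn-in sweep.
#' @slot seed RNG seed (`NA` to leave the RNG state untouched).
#' @seealso [chainConfig()]
#' @export
setClass("ChainConfig",
  representation(nIterations = "integer", burnIn = "integer",
                 thinning = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@burnIn >= object@nIterations)
      msg <- c(msg, "burnIn must be smaller than nIterations")
    if (object@thinning < 1L) msg <- c(msg, "thinning must be >= 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname ChainConfig-class
#' @param nIterations,burnIn,thinning,seed see the slots.
#' @return A [ChainConfig-class] object.
#' @export
chainConfig <- function(nIterations = 20000L, burnIn = 5000L, thinning = 5L,
                        seed = NA_integer_) {
  new("ChainConfig", nIterations = as.integer(nIterations),
      burnIn = as.integer(burnIn), thinning = as.integer(thinning),
      seed = as.integer(seed))
}

#' Retained MCMC samples of the BGF posterior
#'
#' @slot samples matrix of retained states, one row per kept sweep; columns
#'   `beta*`, `pi*`, `mu`, `l`, `sigma2e`, `vq` (the marginal QTL-variance
#'   functional `2 pbar (1 - pbar) mu^2`) and `vexp` (the marker-explained
#'   QTL variance `mu^2 Var_i(E(Q_i | M))`, the detection statistic).
#' @slot acceptance per-block acceptance rates over the sampling phase.
#' @slot k markers per haplotype (1 or 2).
#' @slot positionsCM candidate-location positions in cM.
#' @slot nIterations,burnIn,thinning chain geometry.
#' @slot proposalFinal proposal standard deviations in force after burn-in.
#' @export
setClass("PosteriorChain",
  representation(
    samples = "matrix", acceptance = "numeric", k = "integer",
    positionsCM = "numeric", nIterations = "integer", burnIn = "integer",
    thinning = "integer", proposalFinal = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    expected <- (object@nIterations - object@burnIn) %/% object@thinning
    if (nrow(object@samples) != expected)
      msg <- c(msg, "sample count must be (nIterations - burnIn) / thinning")
    if (any(object@acceptance < 0 | object@acceptance > 1))
      msg <- c(msg, "acceptance rates must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Result of a positional scan
#'
#' Per-candidate-position statistics and the estimated QTL location, from
#' either the BGF sampler ([summarizeChain()]) or the least-squares
#' regression scan ([lsrScan()]).
#'
#' @slot method one of `"BGF1"`, `"BGF2"`, `"LSR1"`, `"LSR2"`.
#' @slot table per-position data frame (`index`, `positionCM`, then
#'   method-specific columns such as `F`, `df1`, `df2`, `p` or posterior
#'   frequencies).
#' @slot estimatedIndex index of the estimated location.
#' @slot estimatedPositionCM estimated QTL position in cM.
#' @slot statistic the scalar detection statistic (largest F for LSR;
#'   posterior mean QTL variance for BGF).
#' @slot details method-specific extras (posterior summaries, tie sets, ...).
#' @export
setClass("ScanResult",
  representation(
    method = "character", table = "data.frame", estimatedIndex = "integer",
    estimatedPositionCM = "numeric", statistic = "numeric", details = "list"
  )
)

#' Aggregated power/precision experiment result
#'
#' @slot methods methods evaluated on shared replicate datasets.
#' @slot criticalValues upper-quantile critical value per method from the
#'   null replicates.
#' @slot power per-method proportion of non-null replicates whose statistic
#'   exceeds the critical value.
#' @slot mae,maeSe per-method mean absolute error of the estimated QTL
#'   position (cM) and its standard error.
#' @slot nullStats,altStats per-replicate statistics (replicates x methods).
#' @slot estimates per-replicate estimated positions for non-null replicates.
#' @slot truePositionCM true QTL position on the window grid.
#' @slot config the experiment settings used.
#' @export
setClass("ExperimentResult",
  representation(
    methods = "character", criticalValues = "numeric", power = "numeric",
    mae = "numeric", maeSe = "numeric", nullStats = "matrix",
    altStats = "matrix", estimates = "matrix", truePositionCM = "numeric",
    config = "list"
  )
)
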