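#' Haplotype codes at a candidate location
#'
#' For `k = 1`, the haplotype of a gamete at candidate location `l` is the
#' allele (0/1) of the window marker `l`. For `k = 2`, candidate `l` is the
#' bracket between adjacent window markers `l` and `l + 1`, and the haplotype
#' code is `2 * left + right` over the two flanking SNP alleles, i.e. codes
#' 0, 1, 2, 3 for haplotypes 00, 01, 10, 11. Phase is taken as known;
#' [StudyData-class] stores phased gametes.
#'
#' @param study a [StudyData-class].
#' @param location candidate index (1-based; a marker for `k = 1`, a bracket
#'   for `k = 2`).
#' @param k markers per haplotype (1 or 2).
#' @return A list with integer vectors `mat` and `pat` of codes in
#'   `0:(2^k - 1)`.
#' @export
hapCodesAt <- function(study, location, k = 1L) {
  stopifnot(is(study, "StudyData"), k %in% c(1L, 2L))
  m <- nMarkers(study)
  if (k == 1L) {
    if (location < 1L || location > m) stop("location out of range")
    list(mat = study@maternal[, location], pat = study@paternal[, location])
  } else {
    if (location < 1L || location > m - 1L) stop("location out of range")
    list(mat = 2L * study@maternal[, location] + study@maternal[, location + 1L],
         pat = 2L * study@paternal[, location] + study@paternal[, location + 1L])
  }
}

#' Candidate QTL locations for a study window
#'
#' The candidate grid of the 1-SNP model is the window marker positions; the
#' 2-SNP model restricts the QTL position to the midpoints between adjacent
#' markers.
#'
#' @inheritParams hapCodesAt
#' @return Numeric vector of candidate positions in cM.
#' @export
candidatePositions <- function(study, k = 1L) {
  stopifnot(is(study, "StudyData"), k %in% c(1L, 2L))
  pos <- positionsCM(study)
  if (k == 1L) pos else (pos[-length(pos)] + pos[-1]) / 2
}

#' Sample haplotype frequencies at a candidate location
#'
#' Pooled (maternal + paternal) relative frequencies of the `2^k` haplotype
#' codes at candidate `location`.
#'
#' @inheritParams hapCodesAt
#' @return Numeric vector of length `2^k` summing to 1.
#' @export
windowHapFreqs <- function(study, location, k = 1L) {
  codes <- hapCodesAt(study, location, k)
  tabulate(c(codes$mat, codes$pat) + 1L, nbins = 2L^k) /
    (2L * nIndividuals(study))
}

#' Conditional probability of QTL allele Q2 given a founder haplotype
#'
#' A pure lookup of the disequilibrium parameter `pi_j` for the gamete's
#' haplotype code: the probability that a founder gamete with marker
#' haplotype `H_j` carries QTL allele Q2. Under linkage equilibrium all
#' `pi_j` are equal and the lookup is independent of the haplotype.
#'
#' @param code integer haplotype code(s) in `0:(2^k - 1)`.
#' @param pi numeric vector of length `2^k` with elements strictly in (0, 1).
#' @return Numeric vector of conditional probabilities.
#' @export
conditionalQtlProb <- function(code, pi) {
  if (any(code < 0L | code >= length(pi)))
    stop("haplotype code out of range for pi of length ", length(pi))
  pi[code + 1L]
}

#' Conditional mean of the QTL genotype given marker haplotypes
#'
#' The QTL copy number of an individual is the sum of two Bernoulli
#' indicators (maternal and paternal gamete each carrying Q2), so its
#' conditional mean is `pi[maternal] + pi[paternal]`. These values form the
#' rows of `E(Q | M)`. When all `pi_j` equal the QTL frequency `p`, every
#' individual gets the constant `2 p` and marker data carry no information
#' about the QTL.
#'
#' @param matCode,patCode integer haplotype codes of the maternal and
#'   paternal gametes.
#' @inheritParams conditionalQtlProb
#' @return Numeric vector in (0, 2).
#' @export
conditionalMeanQ <- function(matCode, patCode, pi) {
  conditionalQtlProb(matCode, pi) + conditionalQtlProb(patCode, pi)
}

#' Gametic variance of one gamete's QTL contribution
#'
#' The gametic value is `mu` times a Bernoulli variable with success
#' probability `pi_h`, so its variance is `pi_h (1 - pi_h) mu^2`. When all
#' `pi` are 0 or 1 (complete LD) the gametic variances vanish and the
#' residuals are homogeneous - the regime in which the gene-frequency model
#' and least-squares regression coincide.
#'
#' @param code integer haplotype code(s).
#' @inheritParams conditionalQtlProb
#' @param mu QTL substitution effect.
#' @return Non-negative numeric vector.
#' @export
gameticVariance <- function(code, pi, mu) {
  p <- conditionalQtlProb(code, pi)
  p * (1 - p) * mu^2
}

#' Per-individual heterogeneous residual variance
#'
#' For unrelated individuals the gametic deviations are uncorrelated and are
#' merged into the residual, so the residual covariance matrix is diagonal
#' with elements `sigma2e + Var(maternal gamete) + Var(paternal gamete)`.
#'
#' @inheritParams conditionalMeanQ
#' @inheritParams gameticVariance
#' @param sigma2e residual variance component (must be positive).
#' @return Positive numeric vector, each element `>= sigma2e`.
#' @export
residualVariance <- function(matCode, patCode, pi, mu, sigma2e) {
  if (sigma2e <= 0) stop("sigma2e must be positive")
  sigma2e + gameticVariance(matCode, pi, mu) +
    gameticVariance(patCode, pi, mu)
}

#' Log-likelihood of the gene-frequency model
#'
#' Given the candidate location in `state`, each individual's phenotype is
#' normal with mean `x_i' beta + E(Q_i | M) mu` and variance equal to its
#' heterogeneous residual variance; unrelated individuals are independent, so
#' the joint density is the product of univariate normal densities.
#'
#' @param study a [StudyData-class] with phenotypes.
#' @param state a [BGFState-class]; its `location` selects the window SNP
#'   (`k = 1`) or SNP bracket (`k = 2`).
#' @param k markers per haplotype (inferred from `length(state@pi)` by
#'   default).
#' @return The log-likelihood value.
#' @export
gfLogLikelihood <- function(study, state, k = NULL) {
  stopifnot(is(study, "StudyData"), is(state, "BGFState"))
  if (is.null(k)) k <- if (length(state@pi) == 2L) 1L else 2L
  codes <- hapCodesAt(study, state@location, k)
  mn <- drop(designMatrix(study) %*% state@beta) +
    conditionalMeanQ(codes$mat, codes$pat, state@pi) * state@mu
  vr <- residualVariance(codes$mat, codes$pat, state@pi, state@mu,
                         state@sigma2e)
  if (any(vr <= 0)) stop("non-positive residual variance")
  sum(dnorm(phenotypes(study), mean = mn, sd = sqrt(vr), log = TRUE))
}

#' Additive QTL variance implied by the disequilibrium parameters
#'
#' Marginalizing the conditional frequencies over the haplotype distribution
#' gives the QTL allele frequency `pbar = sum(hapFreqs * pi)`; under random
#' union of gametes the additive variance of the biallelic QTL is
#' `2 pbar (1 - pbar) mu^2`. The posterior mean of this statistic is the
#' detection statistic of the BGF scan.
#'
#' @param pi conditional Q2 probabilities per haplotype.
#' @param hapFreqs haplotype relative frequencies (same length as `pi`,
#'   summing to 1).
#' @param mu QTL substitution effect.
#' @return Non-negative scalar.
#' @export
qtlVarianceStatistic <- function(pi, hapFreqs, mu) {
  if (length(hapFreqs) != length(pi))
    stop("hapFreqs and pi must have equal length")
  if (abs(sum(hapFreqs) - 1) > 1e-8)
    stop("hapFreqs must sum to 1")
  pbar <- sum(hapFreqs * pi)
  2 * pbar * (1 - pbar) * mu^2
}
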