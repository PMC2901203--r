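#' Empirical upper-quantile critical value from null replicates
#'
#' The critical value at significance level `level` is the
#' `ceiling((1 - level) * R)`-th order statistic of the `R` null-replicate
#' statistics (inverse-empirical-CDF convention; quantile conventions differ,
#' so the rule is fixed here).
#'
#' @param nullStats numeric vector of per-replicate statistics simulated
#'   under no QTL (largest F for LSR, posterior-mean QTL variance for BGF).
#' @param level significance level (default 0.10).
#' @return The critical value.
#' @examples
#' criticalValue(1:10, level = 0.10)  # 9
#' @export
criticalValue <- function(nullStats, level = 0.10) {
  nullStats <- nullStats[!is.na(nullStats)]
  R <- length(nullStats)
  if (R < 10L) stop("at least 10 null statistics are required")
  sort(nullStats)[ceiling((1 - level) * R)]
}

#' Empirical power at a critical value
#'
#' @param altStats per-replicate statistics from datasets simulated with a
#'   QTL.
#' @param critical the null-calibrated critical value.
#' @return Fraction of statistics strictly greater than `critical`.
#' @export
detectionPower <- function(altStats, critical) {
  altStats <- altStats[!is.na(altStats)]
  if (!length(altStats)) stop("no statistics supplied")
  mean(altStats > critical)
}

#' Mean absolute error of estimated QTL positions
#'
#' @param estimatedCM per-replicate estimated positions in cM.
#' @param trueCM the true QTL position in cM.
#' @return A list with `mae` (mean absolute error) and `se` (standard
#'   deviation of the absolute errors divided by `sqrt(R)`).
#' @export
locationMae <- function(estimatedCM, trueCM) {
  estimatedCM <- estimatedCM[!is.na(estimatedCM)]
  if (!length(estimatedCM)) stop("no estimates supplied")
  ae <- abs(estimatedCM - trueCM)
  list(mae = mean(ae),
       se = if (length(ae) > 1L) sd(ae) / sqrt(length(ae)) else 0)
}

# run one configured method on one study; returns stat + estimated position
.runMethod <- function(method, study, prior, proposal, chain) {
  k <- as.integer(substring(method, 4L))
  if (startsWith(method, "LSR")) {
    sc <- lsrScan(study, k)
  } else {
    ch <- runBgfChain(study, k, prior, proposal, chain)
    sc <- summarizeChain(ch)
  }
  c(stat = detectionStatistic(sc), est = estimatedPositionCM(sc))
}

#' Run a power/precision experiment
#'
#' For each replicate, simulates an LD history (or reuses one), selects the
#' marker panel, draws a study sample and phenotypes, runs the configured
#' method(s), and records the detection statistic and estimated QTL
#' location. Null replicates (no QTL) calibrate the upper-`level` critical
#' value per method; power is the fraction of non-null replicate statistics
#' exceeding it; precision is the mean absolute error of the estimated
#' position over non-null replicates. All methods are evaluated on the same
#' replicate datasets, so comparisons are paired.
#'
#' @param methods character vector among `"BGF1"`, `"BGF2"`, `"LSR1"`,
#'   `"LSR2"`.
#' @param qtlVarianceFraction fraction of phenotypic variance explained by
#'   the QTL in the non-null replicates (0.02 or 0.05 in the study
#'   settings).
#' @param markerSpacingCM marker spacing (0.1, 0.05 or 0.02 cM); locus
#'   spacing is one tenth of this.
#' @param n study sample size per replicate.
#' @param nNullReps,nPowerReps numbers of null and non-null replicates
#'   (`nPowerReps` defaults to `nNullReps`).
#' @param demo a [DemographyConfig-class].
#' @param seed master seed; per-replicate seeds are drawn from it and
#'   recorded in the result.
#' @param reuseHistory reuse a single LD history across replicates (faster;
#'   fresh study samples and phenotypes per replicate) instead of the
#'   default fresh history per replicate.
#' @param level significance level of the calibration (default 0.10).
#' @param prior,proposal,chain BGF sampler settings (ignored for LSR).
#' @param verbose print per-replicate progress to stderr.
#' @return An [ExperimentResult-class].
#' @export
runExperiment <- function(methods = "LSR1", qtlVarianceFraction = 0.05,
                          markerSpacingCM = 0.1, n = 200L,
                          nNullReps = 100L, nPowerReps = nNullReps,
                          demo = demographyConfig(), seed = NULL,
                          reuseHistory = FALSE, level = 0.10,
                          prior = priorConfig(), proposal = proposalConfig(),
                          chain = chainConfig(6000L, 1500L, 5L),
                          verbose = FALSE) {
  stopifnot(all(methods %in% c("BGF1", "BGF2", "LSR1", "LSR2")),
            nNullReps >= 0L, nPowerReps >= 0L)
  if (!markerSpacingCM %in% c(0.1, 0.05, 0.02))
    warning("markerSpacingCM outside the study settings 0.1/0.05/0.02")
  spacingCM <- markerSpacingCM / 10
  if (!is.null(seed)) set.seed(seed)
  nRep <- nNullReps + nPowerReps
  repSeeds <- sample.int(.Machine$integer.max - 1L, nRep + 1L)

  history <- NULL
  if (reuseHistory) {
    h <- simulateStudy(spacingCM, n = 2L, qtlVarianceFraction = 0,
                       demo = demo, seed = repSeeds[nRep + 1L])
    history <- h$history
  }

  M <- length(methods)
  nullStats <- matrix(NA_real_, max(nNullReps, 0L), M,
                      dimnames = list(NULL, methods))
  altStats <- matrix(NA_real_, max(nPowerReps, 0L), M,
                     dimnames = list(NULL, methods))
  estimates <- matrix(NA_real_, max(nPowerReps, 0L), M,
                      dimnames = list(NULL, methods))
  truePos <- NA_real_

  for (r in seq_len(nRep)) {
    isNull <- r <= nNullReps
    f <- if (isNull) 0 else qtlVarianceFraction
    sim <- simulateStudy(spacingCM, n = n, qtlVarianceFraction = f,
                         demo = demo, seed = repSeeds[r], history = history)
    truePos <- qtlPositionCM(sim$study)
    for (m in seq_len(M)) {
      out <- .runMethod(methods[m], sim$study, prior, proposal, chain)
      if (isNull) {
        nullStats[r, m] <- out["stat"]
      } else {
        altStats[r - nNullReps, m] <- out["stat"]
        estimates[r - nNullReps, m] <- out["est"]
      }
    }
    if (verbose)
      message(sprintf("replicate %d/%d (%s) done", r, nRep,
                      if (isNull) "null" else "QTL"))
  }

  crit <- power <- mae <- maeSe <- setNames(rep(NA_real_, M), methods)
  for (m in seq_len(M)) {
    if (nNullReps >= 10L)
      crit[m] <- criticalValue(nullStats[, m], level)
    if (nPowerReps > 0L && !is.na(crit[m]))
      power[m] <- detectionPower(altStats[, m], crit[m])
    if (nPowerReps > 0L) {
      mm <- locationMae(estimates[, m], truePos)
      mae[m] <- mm$mae
      maeSe[m] <- mm$se
    }
  }
  new("ExperimentResult",
      methods = methods, criticalValues = crit, power = power, mae = mae,
      maeSe = maeSe, nullStats = nullStats, altStats = altStats,
      estimates = estimates, truePositionCM = truePos,
      config = list(qtlVarianceFraction = qtlVarianceFraction,
                    markerSpacingCM = markerSpacingCM, n = n,
                    nNullReps = nNullReps, nPowerReps = nPowerReps,
                    level = level, seed = seed, repSeeds = repSeeds,
                    reuseHistory = reuseHistory))
}
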