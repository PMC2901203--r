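#' Haplotype-regression F-test at one candidate position
#'
#' Regresses phenotypes on the individuals' haplotype copy numbers at the
#' SNP (`k = 1`, haplotypes 0/1) or SNP bracket (`k = 2`, haplotypes
#' 00/01/10/11) and tests equality of all haplotype effects against the
#' intercept-only model with an F-test. Haplotypes unobserved in the sample
#' are dropped from the design and the numerator degrees of freedom adjust
#' accordingly: `df1 = #observed haplotypes - 1`,
#' `df2 = n - #observed haplotypes`.
#'
#' @param study a [StudyData-class] with phenotypes.
#' @param location candidate index (marker for `k = 1`, bracket for
#'   `k = 2`).
#' @param k markers per haplotype.
#' @return A list with `F`, `df1`, `df2`, `p`, and `skipped` (`TRUE` with
#'   `NA` statistics when the position is monomorphic).
#' @export
lsrFitPosition <- function(study, location, k = 1L) {
  stopifnot(is(study, "StudyData"), k %in% c(1L, 2L))
  y <- phenotypes(study)
  if (!length(y)) stop("study has no phenotypes")
  codes <- hapCodesAt(study, location, k)
  n <- length(y)
  counts <- tabulate(codes$mat + 1L, nbins = 2L^k) +
    tabulate(codes$pat + 1L, nbins = 2L^k)
  observed <- which(counts > 0L)
  h <- length(observed)
  if (h < 2L)
    return(list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = NA_real_, skipped = TRUE))
  # copy-number design, one column per observed haplotype; columns sum to 2
  # rowwise, so the model spans the intercept and has h free parameters
  G <- matrix(0, n, h)
  for (j in seq_len(h)) {
    code <- observed[j] - 1L
    G[, j] <- (codes$mat == code) + (codes$pat == code)
  }
  fit <- stats::lm.fit(G, y)
  rss1 <- sum(fit$residuals^2)
  rank <- fit$rank
  rss0 <- sum((y - mean(y))^2)
  df1 <- rank - 1L
  df2 <- n - rank
  if (df1 < 1L || df2 < 1L)
    return(list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = NA_real_, skipped = TRUE))
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE), skipped = FALSE)
}

#' Least-squares regression scan over the analysis window
#'
#' Fits [lsrFitPosition()] at every window marker (`k = 1`) or adjacent
#' bracket (`k = 2`). The estimated QTL location is the candidate with the
#' smallest p-value; when several p-values are numerically zero (below
#' 1e-15), the middle of the zero-p candidates is chosen (the lower of the
#' two middle candidates when their count is even). Monomorphic positions
#' are skipped.
#'
#' @inheritParams lsrFitPosition
#' @return A [ScanResult-class] whose table has columns `index`,
#'   `positionCM`, `F`, `df1`, `df2`, `p`; the detection statistic is the F
#'   value at the estimated location.
#' @examples
#' \donttest{
#' sim <- simulateStudy(n = 200, qtlVarianceFraction = 0.05, seed = 11)
#' lsrScan(sim$study, k = 1)
#' }
#' @export
lsrScan <- function(study, k = 1L) {
  pos <- candidatePositions(study, k)
  fits <- lapply(seq_along(pos), function(l) lsrFitPosition(study, l, k))
  tab <- data.frame(
    index = seq_along(pos), positionCM = pos,
    F = vapply(fits, `[[`, numeric(1), "F"),
    df1 = vapply(fits, function(f) as.numeric(f$df1), numeric(1)),
    df2 = vapply(fits, function(f) as.numeric(f$df2), numeric(1)),
    p = vapply(fits, `[[`, numeric(1), "p"))
  usable <- which(!is.na(tab$p))
  if (!length(usable)) stop("all candidate positions were monomorphic")
  zero <- usable[tab$p[usable] < 1e-15]
  est <- if (length(zero)) zero[ceiling(length(zero) / 2)]
         else usable[which.min(tab$p[usable])]
  new("ScanResult",
      method = paste0("LSR", k),
      table = tab,
      estimatedIndex = as.integer(est),
      estimatedPositionCM = pos[est],
      statistic = tab$F[est],
      details = list(zeroP = zero))
}
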