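#' Log prior density of a BGF state
#'
#' Sum of the log prior contributions: flat on the fixed effects (0), scaled
#' inverse chi-square on the residual variance, normal with null mean on the
#' QTL effect, discrete uniform (`-log(L)`) on the location, and logit-normal
#' on the conditional frequencies - the normal log density of
#' `x = logit(pi)` plus the change-of-variables Jacobian
#' `sum(-log(pi * (1 - pi)))`.
#'
#' @param state a [BGFState-class].
#' @param prior a [PriorConfig-class].
#' @param nLocations number of candidate locations `L`.
#' @return Log prior density (log of an unnormalized density for the flat
#'   fixed-effect block).
#' @export
logBgfPrior <- function(state, prior, nLocations) {
  stopifnot(is(state, "BGFState"), is(prior, "PriorConfig"))
  if (any(state@pi <= 0 | state@pi >= 1))
    stop("pi must lie strictly in (0, 1)")
  x <- stats::qlogis(state@pi)
  lpPi <- sum(dnorm(x, 0, sqrt(prior@sigma2X), log = TRUE)) +
    sum(-log(state@pi * (1 - state@pi)))
  lpMu <- dnorm(state@mu, 0, sqrt(prior@sigma2Mu), log = TRUE)
  lpE <- .logScaledInvChisq(state@sigma2e, prior@nuE, prior@s2E)
  lpPi + lpMu + lpE - log(nLocations)
}

# scaled inverse chi-square log density (normalized)
.logScaledInvChisq <- function(s2, nu, S2) {
  if (s2 <= 0) return(-Inf)
  0.5 * nu * log(nu * S2 / 2) - lgamma(nu / 2) -
    (nu / 2 + 1) * log(s2) - nu * S2 / (2 * s2)
}

#' Log posterior density (up to the constant of proportionality)
#'
#' `gfLogLikelihood + logBgfPrior`: the joint posterior density of the
#' state on the `pi` scale, useful for diagnostics and for comparing
#' states. Note that Metropolis-Hastings ratios for moves that propose on
#' the logit scale are formed on that scale (likelihood times normal
#' densities of `x` and `mu`): the logit Jacobian in this pi-scale density
#' cancels against the Jacobian of the pi-scale proposal density, so using
#' ratios of this function there would double-count it.
#'
#' @inheritParams gfLogLikelihood
#' @inheritParams logBgfPrior
#' @return Log posterior density up to an additive constant.
#' @export
logBgfPosterior <- function(study, state, prior, k = NULL) {
  if (is.null(k)) k <- if (length(state@pi) == 2L) 1L else 2L
  nLoc <- length(candidatePositions(study, k))
  gfLogLikelihood(study, state, k) + logBgfPrior(state, prior, nLoc)
}

# Unnormalized log target on the sampling scale x = logit(pi): likelihood
# times the normal base densities of x and mu. This is the quantity whose
# ratios drive the MH moves that propose in x-space; the pi-scale Jacobian
# cancels between prior and proposal density and must not appear here.
.logTargetX <- function(study, state, prior, k, x = stats::qlogis(state@pi)) {
  gfLogLikelihood(study, state, k) +
    sum(dnorm(x, 0, sqrt(prior@sigma2X), log = TRUE)) +
    dnorm(state@mu, 0, sqrt(prior@sigma2Mu), log = TRUE)
}

#' Gibbs draw of the fixed effects
#'
#' The full conditional of `beta` is multivariate normal with mean the
#' generalized least-squares solution of
#' `X' R*^-1 X beta = X' R*^-1 (y - Qhat mu)` and covariance
#' `(X' R*^-1 X)^-1`, where `R*` is the diagonal heterogeneous residual
#' covariance. With unrelated individuals and the polygenic term merged into
#' the residual, the mixed-model coefficient matrix reduces to these weighted
#' normal equations.
#'
#' @inheritParams gfLogLikelihood
#' @return The updated [BGFState-class] (new `beta` draw).
#' @export
sampleBeta <- function(study, state, k = NULL) {
  if (is.null(k)) k <- if (length(state@pi) == 2L) 1L else 2L
  codes <- hapCodesAt(study, state@location, k)
  w <- 1 / residualVariance(codes$mat, codes$pat, state@pi, state@mu,
                            state@sigma2e)
  X <- designMatrix(study)
  yAdj <- phenotypes(study) -
    conditionalMeanQ(codes$mat, codes$pat, state@pi) * state@mu
  C <- crossprod(X, X * w)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular weighted normal equations (X' R*^-1 X)"))
  mean <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * yAdj)))
  # draw: mean + R^-1 z with C = R'R
  z <- rnorm(ncol(X))
  state@beta <- drop(mean + backsolve(ch, z))
  state
}

#' Joint Metropolis-Hastings update of (pi, mu, l)
#'
#' Proposes `x* ~ N(x, sigma2XProp I)` on the logit scale (mapped back to
#' `pi*`), `mu* ~ N(mu, sigma2MuProp)`, and `l*` uniform over all candidate
#' locations, and accepts the block jointly with probability `min(1, alpha)`.
#' Because the random walk is symmetric in `x` - not in `pi` - the logit
#' Jacobian of the prior cancels exactly against the Jacobian hidden in the
#' pi-scale proposal density, so `alpha` reduces to the ratio of
#' `likelihood x N(x; 0, Sigma_x) x N(mu; 0, sigma2Mu)` between candidate
#' and current state (the uniform location prior and proposal cancel too).
#' Evaluating the ratio with the pi-scale prior density instead would count
#' the Jacobian twice and target a distorted posterior. When a new location
#' is proposed, the (current or proposed) `pi` vector is interpreted with
#' respect to the haplotypes of the SNP(s) at that location; the vector's
#' dimension does not change.
#'
#' @inheritParams gfLogLikelihood
#' @param prior a [PriorConfig-class].
#' @param proposal a [ProposalConfig-class].
#' @return A list with `state` (updated [BGFState-class]), `accepted`
#'   (logical), `logAlpha`, and `candidate` (the proposed [BGFState-class],
#'   useful for verifying acceptance ratios).
#' @export
mhUpdatePiMuL <- function(study, state, prior, proposal, k = NULL) {
  if (is.null(k)) k <- if (length(state@pi) == 2L) 1L else 2L
  nLoc <- length(candidatePositions(study, k))
  x <- stats::qlogis(state@pi)
  xStar <- x + rnorm(length(x), 0, sqrt(proposal@sigma2XProp))
  cand <- state
  cand@pi <- stats::plogis(xStar)
  cand@mu <- state@mu + rnorm(1, 0, sqrt(proposal@sigma2MuProp))
  cand@location <- sample.int(nLoc, 1L)
  logAlpha <- .logTargetX(study, cand, prior, k, xStar) -
    .logTargetX(study, state, prior, k, x)
  accepted <- log(runif(1)) < logAlpha
  list(state = if (accepted) cand else state, accepted = accepted,
       logAlpha = logAlpha, candidate = cand)
}

#' Metropolis-Hastings update of the residual variance
#'
#' The heterogeneous residual covariance makes the full conditional of
#' `sigma2e` non-standard (not inverse chi-square), so a normal random-walk
#' proposal is used. Non-positive candidates have zero prior support and are
#' rejected outright; otherwise the usual likelihood x prior ratio applies.
#'
#' @inheritParams mhUpdatePiMuL
#' @return A list with `state`, `accepted`, `logAlpha` and `candidate` (the
#'   proposed residual variance).
#' @export
mhUpdateSigma2e <- function(study, state, prior, proposal, k = NULL) {
  if (is.null(k)) k <- if (length(state@pi) == 2L) 1L else 2L
  s2Star <- state@sigma2e + rnorm(1, 0, sqrt(proposal@sigma2EProp))
  if (s2Star <= 0)
    return(list(state = state, accepted = FALSE, logAlpha = -Inf,
                candidate = s2Star))
  cand <- state
  cand@sigma2e <- s2Star
  logAlpha <- gfLogLikelihood(study, cand, k) -
    gfLogLikelihood(study, state, k) +
    .logScaledInvChisq(s2Star, prior@nuE, prior@s2E) -
    .logScaledInvChisq(state@sigma2e, prior@nuE, prior@s2E)
  accepted <- log(runif(1)) < logAlpha
  list(state = if (accepted) cand else state, accepted = accepted,
       logAlpha = logAlpha, candidate = s2Star)
}

#' Run the BGF Metropolis-Hastings within blocked Gibbs sampler
#'
#' Each sweep updates three blocks in order: (1) a Gibbs draw of the fixed
#' effects from their multivariate-normal full conditional, (2) a joint
#' Metropolis-Hastings update of the conditional frequencies, QTL effect and
#' location, followed by mode-jumping independence proposals of
#' `(location, pi, mu)` centered at per-location least-squares anchors and a
#' Gibbs draw of the location from its full conditional (the joint posterior
#' is multimodal across candidate locations, and the random-walk block alone
#' cannot cross between those basins), (3) a Metropolis-Hastings update of
#' the residual variance. Chains start from the dominant anchor. During
#' burn-in the random-walk proposal standard deviations are tuned toward
#' acceptance rates of 0.2-0.5 (measured on same-location proposals) and
#' then frozen, so the sampling phase runs with fixed proposals. Each
#' retained sample records both QTL-variance functionals: the marginal
#' `2 pbar (1 - pbar) mu^2` (`vq`) and the marker-explained
#' `mu^2 Var_i(E(Q_i|M))` (`vexp`).
#'
#' @param study a [StudyData-class] with phenotypes.
#' @param k markers per haplotype (1 or 2).
#' @param prior a [PriorConfig-class].
#' @param proposal a [ProposalConfig-class].
#' @param chain a [ChainConfig-class].
#' @param engine `"cpp"` (default, compiled sweep loop) or `"R"` (reference
#'   loop over [sampleBeta()], [mhUpdatePiMuL()] and [mhUpdateSigma2e()];
#'   slower, used for cross-validation).
#' @return A [PosteriorChain-class].
#' @examples
#' \donttest{
#' sim <- simulateStudy(n = 200, qtlVarianceFraction = 0.05, seed = 7)
#' ch <- runBgfChain(sim$study, k = 1,
#'                   chain = chainConfig(4000, 1000, 5, seed = 1))
#' summarizeChain(ch)
#' }
#' @export
runBgfChain <- function(study, k = 1L, prior = priorConfig(),
                        proposal = proposalConfig(),
                        chain = chainConfig(), engine = c("cpp", "R")) {
  stopifnot(is(study, "StudyData"), k %in% c(1L, 2L),
            is(prior, "PriorConfig"), is(proposal, "ProposalConfig"),
            is(chain, "ChainConfig"))
  engine <- match.arg(engine)
  if (!length(phenotypes(study)))
    stop("study has no phenotypes")
  if (!is.na(chain@seed)) set.seed(chain@seed)

  k <- as.integer(k)
  npi <- 2L^k
  pos <- candidatePositions(study, k)
  nLoc <- length(pos)
  n <- nIndividuals(study)
  matCodes <- vapply(seq_len(nLoc),
                     function(l) hapCodesAt(study, l, k)$mat, integer(n))
  patCodes <- vapply(seq_len(nLoc),
                     function(l) hapCodesAt(study, l, k)$pat, integer(n))
  hapFreqs <- vapply(seq_len(nLoc),
                     function(l) windowHapFreqs(study, l, k), numeric(npi))

  anchors <- .locationAnchors(study, k, nLoc)
  init <- .initState(study, k, nLoc, anchors)

  if (engine == "cpp") {
    res <- .cppRunBgfChain(
      phenotypes(study), designMatrix(study),
      matCodes, patCodes, hapFreqs,
      init@beta, init@pi, init@mu, init@location - 1L, init@sigma2e,
      prior@sigma2Mu, prior@nuE, prior@s2E, prior@sigma2X,
      sqrt(proposal@sigma2XProp), sqrt(proposal@sigma2MuProp),
      sqrt(proposal@sigma2EProp), proposal@adapt,
      anchors$xhat, anchors$muhat, .hopSdX, .hopSdMu,
      chain@nIterations, chain@burnIn, chain@thinning)
    samples <- res$samples
    acc <- res$acceptance
    propFinal <- res$proposalFinal
  } else {
    res <- .runBgfChainR(study, k, prior, proposal, chain, init,
                         hapFreqs, nLoc, anchors)
    samples <- res$samples
    acc <- res$acceptance
    propFinal <- res$proposalFinal
  }
  colnames(samples) <- c(paste0("beta", seq_len(ncol(designMatrix(study)))),
                         paste0("pi", seq_len(npi)), "mu", "l", "sigma2e",
                         "vq", "vexp")
  new("PosteriorChain", samples = samples,
      acceptance = c(piMuL = acc[1], sigma2e = acc[2]),
      k = k, positionsCM = pos, nIterations = chain@nIterations,
      burnIn = chain@burnIn, thinning = chain@thinning,
      proposalFinal = c(sdX = propFinal[1], sdMu = propFinal[2],
                        sdE = propFinal[3]))
}

# Data-informed deterministic starting state. The joint posterior over
# (location, pi, mu) is typically multimodal - each candidate location
# carries its own basin - and random-walk chains almost never cross between
# basins within a practical run. Starting from the dominant basin (the
# candidate whose haplotype copy-number regression explains the most
# variance, with pi and mu matched to the fitted haplotype effects by the
# moment relation a_j ~ const + mu * pi_j) removes that start-up lottery;
# the within-sweep Gibbs location draw still allows moves to competing
# basins whenever the current pi vector supports them.
.initState <- function(study, k, nLoc,
                       anchors = .locationAnchors(study, k, nLoc)) {
  l0 <- which.min(anchors$rss)
  pi0 <- stats::plogis(anchors$xhat[, l0])
  mu0 <- anchors$muhat[l0]
  codes <- hapCodesAt(study, l0, k)
  y <- phenotypes(study)
  yAdj <- y - (pi0[codes$mat + 1L] + pi0[codes$pat + 1L]) * mu0
  beta0 <- drop(qr.solve(designMatrix(study), yAdj))
  bgfState(beta = beta0, pi = pi0, mu = mu0, location = l0,
           sigma2e = max(anchors$rss[l0] / length(y), 1e-4))
}

# Per-location moment anchors used for initialization and for the
# mode-jumping independence proposal: at each candidate, regress phenotypes
# on haplotype copy numbers; the fitted per-haplotype effects a_j satisfy
# a_j ~ const + mu * pi_j, so pi anchors are the effects rescaled to their
# range and mu's anchor is that range (oriented positive).
.locationAnchors <- function(study, k, nLoc) {
  y <- phenotypes(study)
  n <- length(y)
  npi <- 2L^k
  xhat <- matrix(0, npi, nLoc)
  muhat <- numeric(nLoc)
  rss <- numeric(nLoc)
  for (l in seq_len(nLoc)) {
    codes <- hapCodesAt(study, l, k)
    counts <- tabulate(c(codes$mat, codes$pat) + 1L, nbins = npi)
    obs <- which(counts > 0L)
    G <- vapply(obs, function(j)
      (codes$mat == j - 1L) + (codes$pat == j - 1L), numeric(n))
    fit <- stats::lm.fit(as.matrix(G), y)
    rss[l] <- sum(fit$residuals^2)
    a <- rep(mean(y) / 2, npi)
    a[obs] <- ifelse(is.na(fit$coefficients), mean(y) / 2, fit$coefficients)
    rng <- max(a) - min(a)
    if (rng < 1e-8) {
      pi0 <- rep(0.5, npi)
      muhat[l] <- 0.01
    } else {
      pi0 <- pmin(pmax((a - min(a)) / rng, 0.1), 0.9)
      muhat[l] <- rng
    }
    xhat[, l] <- stats::qlogis(pi0)
  }
  list(xhat = xhat, muhat = muhat, rss = rss)
}

# Mode-jumping independence move: propose a uniformly drawn location
# together with (x, mu) drawn around that location's anchors, and accept
# with the full Metropolis-Hastings ratio (posterior ratio times reverse/
# forward proposal densities). This lets the chain cross between the deep
# per-location basins that defeat the random-walk block.
.hopSdX <- 0.6
.hopSdMu <- 0.2
.hopMove <- function(study, state, prior, k, nLoc, anchors) {
  lStar <- sample.int(nLoc, 1L)
  xStar <- rnorm(nrow(anchors$xhat), anchors$xhat[, lStar], .hopSdX)
  muStar <- rnorm(1L, anchors$muhat[lStar], .hopSdMu)
  cand <- state
  cand@pi <- stats::plogis(xStar)
  cand@mu <- muStar
  cand@location <- lStar
  x <- stats::qlogis(state@pi)
  qFwd <- sum(dnorm(xStar, anchors$xhat[, lStar], .hopSdX, log = TRUE)) +
    dnorm(muStar, anchors$muhat[lStar], .hopSdMu, log = TRUE)
  qRev <- sum(dnorm(x, anchors$xhat[, state@location], .hopSdX,
                    log = TRUE)) +
    dnorm(state@mu, anchors$muhat[state@location], .hopSdMu, log = TRUE)
  # both proposal and target evaluated on the x scale, so no Jacobians
  logAlpha <- .logTargetX(study, cand, prior, k, xStar) -
    .logTargetX(study, state, prior, k, x) + qRev - qFwd
  if (log(runif(1)) < logAlpha) cand else state
}

# Gibbs draw of the location from its full conditional: the location prior
# is uniform and the likelihood is cheap at every candidate, so l can be
# sampled exactly given (beta, pi, mu, sigma2e). Composing this with the
# joint MH block keeps the same stationary distribution while restoring
# location mixing when the random-walk block rarely accepts joint moves.
.gibbsLocation <- function(study, state, k, nLoc) {
  ll <- vapply(seq_len(nLoc), function(l) {
    s <- state; s@location <- l
    gfLogLikelihood(study, s, k)
  }, numeric(1))
  w <- exp(ll - max(ll))
  state@location <- sample.int(nLoc, 1L, prob = w)
  state
}

# Reference R implementation of the sweep loop (block functions above).
.runBgfChainR <- function(study, k, prior, proposal, chain, state,
                          hapFreqs, nLoc, anchors) {
  nKeep <- (chain@nIterations - chain@burnIn) %/% chain@thinning
  p <- ncol(designMatrix(study))
  npi <- 2L^k
  matCodes <- vapply(seq_len(nLoc),
                     function(l) hapCodesAt(study, l, k)$mat,
                     integer(nIndividuals(study)))
  patCodes <- vapply(seq_len(nLoc),
                     function(l) hapCodesAt(study, l, k)$pat,
                     integer(nIndividuals(study)))
  samples <- matrix(NA_real_, nKeep, p + npi + 5L)
  acc <- c(0L, 0L)
  kept <- 0L
  prop <- proposal
  winAcc <- c(0L, 0L)
  att2 <- 0L
  for (it in seq_len(chain@nIterations)) {
    state <- sampleBeta(study, state, k)
    stateBefore2 <- state@location
    up2 <- mhUpdatePiMuL(study, state, prior, prop, k)
    state <- up2$state
    for (hop in 1:4)
      state <- .hopMove(study, state, prior, k, nLoc, anchors)
    state <- .gibbsLocation(study, state, k, nLoc)
    up3 <- mhUpdateSigma2e(study, state, prior, prop, k)
    state <- up3$state
    if (it <= chain@burnIn) {
      # adapt the (pi, mu) scales only on same-location proposals;
      # cross-location rejections say nothing about the random-walk scale
      sameL <- up2$candidate@location == stateBefore2
      att2 <- att2 + sameL
      winAcc <- winAcc + c(up2$accepted && sameL, up3$accepted)
      if (prop@adapt && it %% 100L == 0L) {
        r3 <- winAcc[2] / 100
        sc3 <- if (r3 < 0.2) 0.7 else if (r3 > 0.5) 1.4 else 1
        prop@sigma2EProp <- min(max(prop@sigma2EProp * sc3^2, 0.005^2), 1.5^2)
        if (att2 >= 10L) {
          r2 <- winAcc[1] / att2
          sc2 <- if (r2 < 0.2) 0.7 else if (r2 > 0.5) 1.4 else 1
          prop@sigma2XProp <- min(max(prop@sigma2XProp * sc2^2, 0.02^2), 3^2)
          prop@sigma2MuProp <- min(max(prop@sigma2MuProp * sc2^2, 0.01^2),
                                   1.5^2)
          winAcc[1] <- 0L
          att2 <- 0L
        }
        winAcc[2] <- 0L
      }
    } else {
      acc <- acc + c(up2$accepted, up3$accepted)
      if ((it - chain@burnIn) %% chain@thinning == 0L) {
        kept <- kept + 1L
        vq <- qtlVarianceStatistic(state@pi, hapFreqs[, state@location],
                                   state@mu)
        qhat <- state@pi[matCodes[, state@location] + 1L] +
          state@pi[patCodes[, state@location] + 1L]
        vexp <- state@mu^2 * mean((qhat - mean(qhat))^2)
        samples[kept, ] <- c(state@beta, state@pi, state@mu,
                             state@location, state@sigma2e, vq, vexp)
      }
    }
  }
  nPost <- chain@nIterations - chain@burnIn
  list(samples = samples, acceptance = acc / nPost,
       proposalFinal = sqrt(c(prop@sigma2XProp, prop@sigma2MuProp,
                              prop@sigma2EProp)))
}

#' @describeIn summarizeChain Posterior summaries of a BGF chain: the
#'   estimated location is the posterior mode of `l` (ties broken toward the
#'   lower index); `mu`, `|mu|`, `pi` and `sigma2e` are summarized by their
#'   posterior means; the detection statistic is the posterior mean of the
#'   per-sample marker-explained QTL variance `mu^2 Var_i(E(Q_i | M))`
#'   (the posterior mean of the marginal statistic
#'   `2 pbar (1 - pbar) mu^2` is reported in `details$vqMean`). The QTL
#'   effect's sign is not identifiable jointly with a flip of `pi`, so
#'   `|mu|` is reported alongside `mu`.
#' @export
setMethod("summarizeChain", "PosteriorChain", function(object, ...) {
  s <- object@samples
  if (nrow(s) == 0L) stop("empty chain")
  nLoc <- length(object@positionsCM)
  counts <- tabulate(s[, "l"], nbins = nLoc)
  lHat <- which.max(counts)  # which.max takes the first (lowest) mode
  piCols <- grep("^pi", colnames(s))
  tab <- data.frame(index = seq_len(nLoc),
                    positionCM = object@positionsCM,
                    postProb = counts / nrow(s))
  new("ScanResult",
      method = paste0("BGF", object@k),
      table = tab,
      estimatedIndex = as.integer(lHat),
      estimatedPositionCM = object@positionsCM[lHat],
      statistic = mean(s[, "vexp"]),
      details = list(
        muMean = mean(s[, "mu"]), muAbsMean = mean(abs(s[, "mu"])),
        muSd = sd(s[, "mu"]),
        piMean = colMeans(s[, piCols, drop = FALSE]),
        sigma2eMean = mean(s[, "sigma2e"]),
        vqMean = mean(s[, "vq"]),
        locationPostProb = counts / nrow(s)))
})
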