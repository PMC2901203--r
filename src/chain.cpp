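#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Compiled sweep loop of the blocked Gibbs / Metropolis-Hastings sampler.
// Parameterization and block order mirror the R reference implementation:
//   block 1: Gibbs draw of beta from its weighted-normal full conditional
//   block 2: joint MH update of (x = logit(pi), mu, l)
//   block 3: MH update of sigma2e with a normal random walk
// All randomness flows through R's RNG, so chains are reproducible from
// set.seed() on the R side.

static double logLik(const arma::vec &y, const arma::vec &xb,
                     const IntegerMatrix &matC, const IntegerMatrix &patC,
                     int l, const arma::vec &pi, double mu, double s2e) {
  const int n = y.n_elem;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double pm = pi[matC(i, l)], pp = pi[patC(i, l)];
    double mn = xb[i] + (pm + pp) * mu;
    double vr = s2e + (pm * (1 - pm) + pp * (1 - pp)) * mu * mu;
    double d = y[i] - mn;
    ll += -0.5 * (std::log(2.0 * M_PI * vr) + d * d / vr);
  }
  return ll;
}

static inline double logInvChisq(double s2, double nu, double S2) {
  // unnormalized: constants cancel in MH ratios
  return -(nu / 2.0 + 1.0) * std::log(s2) - nu * S2 / (2.0 * s2);
}

// [[Rcpp::export(name = ".cppRunBgfChain")]]
List cppRunBgfChain(NumericVector yR, NumericMatrix XR,
                    IntegerMatrix matC, IntegerMatrix patC,
                    NumericMatrix hapFreqs,
                    NumericVector beta0, NumericVector pi0, double mu0,
                    int l0, double s2e0,
                    double sigma2Mu, double nuE, double s2E, double sigma2X,
                    double sdX, double sdMu, double sdE, bool adapt,
                    NumericMatrix xhat, NumericVector muhat,
                    double hopSdX, double hopSdMu,
                    int nIter, int burnIn, int thin) {
  arma::vec y(yR.begin(), yR.size(), false);
  arma::mat X(XR.begin(), XR.nrow(), XR.ncol(), false);
  const int n = y.n_elem, p = X.n_cols;
  const int nLoc = matC.ncol(), npi = pi0.size();

  arma::vec beta(beta0.begin(), p);
  arma::vec pi(pi0.begin(), npi), x(npi);
  for (int j = 0; j < npi; ++j) x[j] = std::log(pi[j] / (1 - pi[j]));
  double mu = mu0, s2e = s2e0;
  int l = l0;  // 0-based

  arma::vec xb = X * beta;
  const int nKeep = (nIter - burnIn) / thin;
  NumericMatrix samples(nKeep, p + npi + 5);
  long acc2 = 0, acc3 = 0, win2 = 0, win3 = 0, att2 = 0;
  int kept = 0;

  arma::vec w(n), yAdj(n), pis(npi), xs(npi);
  double curLL = logLik(y, xb, matC, patC, l, pi, mu, s2e);

  for (int it = 1; it <= nIter; ++it) {
    // --- block 1: beta | rest (Gibbs) ---
    for (int i = 0; i < n; ++i) {
      double pm = pi[matC(i, l)], pp = pi[patC(i, l)];
      double vr = s2e + (pm * (1 - pm) + pp * (1 - pp)) * mu * mu;
      w[i] = 1.0 / vr;
      yAdj[i] = y[i] - (pm + pp) * mu;
    }
    arma::mat Xw = X.each_col() % w;
    arma::mat C = X.t() * Xw;
    arma::vec rhs = Xw.t() * yAdj;
    arma::mat R = arma::chol(C);  // C = R'R
    arma::vec mn = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), rhs));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    beta = mn + arma::solve(arma::trimatu(R), z);
    xb = X * beta;
    curLL = logLik(y, xb, matC, patC, l, pi, mu, s2e);

    // --- block 2: (x, mu, l) joint MH ---
    double lpCur = 0.0, lpProp = 0.0;
    for (int j = 0; j < npi; ++j) {
      xs[j] = x[j] + norm_rand() * sdX;
      pis[j] = 1.0 / (1.0 + std::exp(-xs[j]));
      lpCur += -x[j] * x[j] / (2.0 * sigma2X);
      lpProp += -xs[j] * xs[j] / (2.0 * sigma2X);
    }
    double mus = mu + norm_rand() * sdMu;
    int ls = (int) (unif_rand() * nLoc);
    if (ls >= nLoc) ls = nLoc - 1;
    lpCur += -mu * mu / (2.0 * sigma2Mu);
    lpProp += -mus * mus / (2.0 * sigma2Mu);
    double propLL = logLik(y, xb, matC, patC, ls, pis, mus, s2e);
    double logA = propLL + lpProp - curLL - lpCur;
    // adaptation watches only same-location proposals: cross-location
    // moves are mostly rejected for reasons unrelated to the random-walk
    // scale, and would otherwise drive the scales to zero
    bool sameL = (ls == l);
    if (it <= burnIn && sameL) ++att2;
    if (std::log(unif_rand()) < logA) {
      x = xs; pi = pis; mu = mus; l = ls; curLL = propLL;
      if (it > burnIn) ++acc2;
      else if (sameL) ++win2;
    }

    // --- block 2b: mode-jumping independence moves over (l, x, mu) ---
    // proposal centered at the proposed location's moment anchors; the MH
    // ratio carries the reverse/forward proposal densities. Acceptance is
    // low by design (independence proposals), so several attempts are made
    // per sweep; each is O(n).
    for (int hop = 0; hop < 4; ++hop) {
      int ls = (int) (unif_rand() * nLoc);
      if (ls >= nLoc) ls = nLoc - 1;
      double qf = 0.0, qr = 0.0, lpC = 0.0, lpP = 0.0;
      double musH = muhat[ls] + norm_rand() * hopSdMu;
      for (int j = 0; j < npi; ++j) {
        xs[j] = xhat(j, ls) + norm_rand() * hopSdX;
        pis[j] = 1.0 / (1.0 + std::exp(-xs[j]));
        double df = xs[j] - xhat(j, ls), dr = x[j] - xhat(j, l);
        qf += -df * df / (2.0 * hopSdX * hopSdX);
        qr += -dr * dr / (2.0 * hopSdX * hopSdX);
        lpC += -x[j] * x[j] / (2.0 * sigma2X);
        lpP += -xs[j] * xs[j] / (2.0 * sigma2X);
      }
      double dfm = musH - muhat[ls], drm = mu - muhat[l];
      qf += -dfm * dfm / (2.0 * hopSdMu * hopSdMu);
      qr += -drm * drm / (2.0 * hopSdMu * hopSdMu);
      lpC += -mu * mu / (2.0 * sigma2Mu);
      lpP += -musH * musH / (2.0 * sigma2Mu);
      double propLL = logLik(y, xb, matC, patC, ls, pis, musH, s2e);
      double logA = propLL + lpP - curLL - lpC + qr - qf;
      if (std::log(unif_rand()) < logA) {
        x = xs; pi = pis; mu = musH; l = ls; curLL = propLL;
      }
    }

    // --- block 2c: Gibbs draw of l from its full conditional ---
    // P(l | rest) ~ likelihood x uniform prior; restores location mixing
    // when the random-walk block rarely accepts joint moves
    {
      std::vector<double> ql(nLoc);
      double mx = -INFINITY;
      for (int j = 0; j < nLoc; ++j) {
        ql[j] = logLik(y, xb, matC, patC, j, pi, mu, s2e);
        if (ql[j] > mx) mx = ql[j];
      }
      double tot = 0.0;
      for (int j = 0; j < nLoc; ++j) { ql[j] = std::exp(ql[j] - mx); tot += ql[j]; }
      double u = unif_rand() * tot, acc = 0.0;
      int lNew = nLoc - 1;
      for (int j = 0; j < nLoc; ++j) {
        acc += ql[j];
        if (u <= acc) { lNew = j; break; }
      }
      l = lNew;
      curLL = mx + std::log(ql[l]);
    }

    // --- block 3: sigma2e MH ---
    double s2s = s2e + norm_rand() * sdE;
    if (s2s > 0) {
      double propLL3 = logLik(y, xb, matC, patC, l, pi, mu, s2s);
      double logA3 = propLL3 - curLL +
        logInvChisq(s2s, nuE, s2E) - logInvChisq(s2e, nuE, s2E);
      if (std::log(unif_rand()) < logA3) {
        s2e = s2s; curLL = propLL3;
        if (it > burnIn) ++acc3; else ++win3;
      }
    }

    if (it <= burnIn) {
      if (adapt && it % 100 == 0) {
        double r3 = win3 / 100.0;
        double f3 = (r3 < 0.2) ? 0.7 : (r3 > 0.5 ? 1.4 : 1.0);
        sdE = std::min(std::max(sdE * f3, 0.005), 1.5);
        if (att2 >= 10) {
          double r2 = (double) win2 / att2;
          double f2 = (r2 < 0.2) ? 0.7 : (r2 > 0.5 ? 1.4 : 1.0);
          sdX = std::min(std::max(sdX * f2, 0.02), 3.0);
          sdMu = std::min(std::max(sdMu * f2, 0.01), 1.5);
          win2 = att2 = 0;
        }
        win3 = 0;
      }
    } else if ((it - burnIn) % thin == 0) {
      double pbar = 0.0;
      for (int j = 0; j < npi; ++j) pbar += hapFreqs(j, l) * pi[j];
      double vq = 2.0 * pbar * (1.0 - pbar) * mu * mu;
      // marker-explained QTL variance: mu^2 * Var_i(E(Q_i | M))
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double q = pi[matC(i, l)] + pi[patC(i, l)];
        s += q; ss += q * q;
      }
      double vexp = (ss / n - (s / n) * (s / n)) * mu * mu;
      int c = 0;
      for (int j = 0; j < p; ++j) samples(kept, c++) = beta[j];
      for (int j = 0; j < npi; ++j) samples(kept, c++) = pi[j];
      samples(kept, c++) = mu;
      samples(kept, c++) = l + 1;  // 1-based for R
      samples(kept, c++) = s2e;
      samples(kept, c++) = vq;
      samples(kept, c++) = vexp;
      ++kept;
    }
    if (it % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  double nPost = nIter - burnIn;
  return List::create(
    _["samples"] = samples,
    _["acceptance"] = NumericVector::create(acc2 / nPost, acc3 / nPost),
    _["proposalFinal"] = NumericVector::create(sdX, sdMu, sdE));
}
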