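#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Matrices are loci x gametes here (one contiguous column per gamete);
// R wrappers transpose to the user-facing gametes x loci orientation.

// Form one gamete from the two haplotypes of `parent` (columns 2*parent and
// 2*parent+1). Crossovers are a Poisson process along the map (positions in
// Morgans), no interference; each transmitted allele flips with probability
// `mu`.
static void meiosis(const int *h0, const int *h1, int L,
                    const double *posM, double totalM, double mu, int *out) {
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  int k = (int) R::rpois(totalM);
  if (k == 0) {
    std::memcpy(out, cur ? h1 : h0, L * sizeof(int));
  } else {
    std::vector<double> xo(k);
    for (int i = 0; i < k; ++i) xo[i] = unif_rand() * totalM;
    std::sort(xo.begin(), xo.end());
    int idx = 0;
    for (int j = 0; j < L; ++j) {
      while (idx < k && xo[idx] <= posM[j]) { cur ^= 1; ++idx; }
      out[j] = cur ? h1[j] : h0[j];
    }
  }
  if (mu > 0) {
    int nmut = (int) R::rbinom((double) L, mu);
    for (int i = 0; i < nmut; ++i) {
      int j = (int) (unif_rand() * L);
      if (j >= L) j = L - 1;
      out[j] ^= 1;
    }
  }
}

// Draw `nGametes` gametes, each by one meiosis from a parent drawn uniformly
// with replacement (random mating, selfing allowed).
// [[Rcpp::export(name = ".cppDropGametes")]]
IntegerMatrix cppDropGametes(const IntegerMatrix &pop, NumericVector posM,
                             int nGametes, double mu) {
  int L = pop.nrow();
  int N = pop.ncol() / 2;
  double totalM = posM[L - 1] - posM[0];
  IntegerMatrix out(L, nGametes);
  const int *popPtr = pop.begin();
  int *outPtr = out.begin();
  for (int g = 0; g < nGametes; ++g) {
    int parent = (int) (unif_rand() * N);
    if (parent >= N) parent = N - 1;
    meiosis(popPtr + (size_t)(2 * parent) * L,
            popPtr + (size_t)(2 * parent + 1) * L,
            L, posM.begin(), totalM, mu, outPtr + (size_t) g * L);
  }
  return out;
}

// One generation of random mating: `nextSize` offspring, two independent
// parents each.
// [[Rcpp::export(name = ".cppAdvance")]]
IntegerMatrix cppAdvance(const IntegerMatrix &pop, NumericVector posM,
                         int nextSize, double mu) {
  return cppDropGametes(pop, posM, 2 * nextSize, mu);
}

// Byte-buffer meiosis used by the multi-generation loop (identical draw
// sequence to the int version above).
static void meiosis8(const unsigned char *h0, const unsigned char *h1, int L,
                     const double *posM, double totalM, double mu,
                     unsigned char *out) {
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  int k = (int) R::rpois(totalM);
  if (k == 0) {
    std::memcpy(out, cur ? h1 : h0, L);
  } else {
    std::vector<double> xo(k);
    for (int i = 0; i < k; ++i) xo[i] = unif_rand() * totalM;
    std::sort(xo.begin(), xo.end());
    int idx = 0;
    for (int j = 0; j < L; ++j) {
      while (idx < k && xo[idx] <= posM[j]) { cur ^= 1; ++idx; }
      out[j] = cur ? h1[j] : h0[j];
    }
  }
  if (mu > 0) {
    int nmut = (int) R::rbinom((double) L, mu);
    for (int i = 0; i < nmut; ++i) {
      int j = (int) (unif_rand() * L);
      if (j >= L) j = L - 1;
      out[j] ^= 1;
    }
  }
}

// Full multi-generation history; `sizes[t]` is the census size of
// generation t+1.
// [[Rcpp::export(name = ".cppRunHistory")]]
IntegerMatrix cppRunHistory(const IntegerMatrix &init, NumericVector posM,
                            IntegerVector sizes, double mu) {
  int L = init.nrow();
  double totalM = posM[L - 1] - posM[0];
  int maxG = 2 * init.ncol() / 2;
  for (int t = 0; t < sizes.size(); ++t)
    maxG = std::max(maxG, 2 * sizes[t]);
  std::vector<unsigned char> cur((size_t) L * maxG), nxt((size_t) L * maxG);
  int nGam = init.ncol();
  for (size_t i = 0; i < (size_t) L * nGam; ++i)
    cur[i] = (unsigned char) init.begin()[i];
  for (int t = 0; t < sizes.size(); ++t) {
    int ns = sizes[t];
    int N = nGam / 2;
    for (int g = 0; g < 2 * ns; ++g) {
      int parent = (int) (unif_rand() * N);
      if (parent >= N) parent = N - 1;
      meiosis8(cur.data() + (size_t)(2 * parent) * L,
               cur.data() + (size_t)(2 * parent + 1) * L,
               L, posM.begin(), totalM, mu, nxt.data() + (size_t) g * L);
    }
    cur.swap(nxt);
    nGam = 2 * ns;
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out(L, nGam);
  for (size_t i = 0; i < (size_t) L * nGam; ++i)
    out.begin()[i] = cur[i];
  return out;
}
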