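#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted beta mean nearest taxon distance between all sample pairs.
//
// D    : tip x tip patristic distance matrix (S x S)
// F    : sample x taxon weight matrix (S columns); rows are within-sample
//        relative abundances (weighted mode) or uniform weights over present
//        taxa (unweighted mode). Zero marks absence.
// perm : taxon -> tip assignment (0-based). The identity gives the observed
//        value; a random permutation gives one taxa-shuffle null draw.
//
// bMNTD(k,m) = 0.5 * ( sum_i F(k,i) * min_{j in m} d(i,j)
//                    + sum_j F(m,j) * min_{i in k} d(j,i) )
// [[Rcpp::export(rng = false)]]
NumericMatrix bmntd_kernel(const NumericMatrix& D, const NumericMatrix& F,
                           const IntegerVector& perm) {
  const int n = F.nrow();
  const int S = F.ncol();
  if (D.nrow() != S || D.ncol() != S)
    stop("distance matrix dimension does not match taxon count");
  if (perm.size() != S) stop("perm length must equal taxon count");

  // present-taxon index lists per sample
  std::vector<std::vector<int>> present(n);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < S; ++i)
      if (F(k, i) > 0.0) present[k].push_back(i);

  // mind[m][i] = distance from taxon i to its nearest taxon in sample m
  std::vector<std::vector<double>> mind(n, std::vector<double>(S));
  for (int m = 0; m < n; ++m) {
    const std::vector<int>& idx = present[m];
    if (idx.empty()) stop("sample with zero total abundance");
    for (int i = 0; i < S; ++i) {
      const double* drow = &D(0, 0) + (R_xlen_t)perm[i] * S;
      double best = R_PosInf;
      for (size_t a = 0; a < idx.size(); ++a) {
        double d = drow[perm[idx[a]]];
        if (d < best) best = d;
      }
      mind[m][i] = best;
    }
  }

  NumericMatrix out(n, n);
  for (int k = 0; k < n; ++k) {
    for (int m = k + 1; m < n; ++m) {
      double s1 = 0.0, s2 = 0.0;
      for (int i : present[k]) s1 += F(k, i) * mind[m][i];
      for (int j : present[m]) s2 += F(m, j) * mind[k][j];
      double v = 0.5 * (s1 + s2);
      out(k, m) = v;
      out(m, k) = v;
    }
  }
  return out;
}

// One null assemblage for the abundance-based Raup-Crick metric: draw
// `richness` distinct taxa with probability proportional to `occ`
// (occurrence frequency), seed each with one individual, then distribute the
// remaining total - richness individuals multinomially with probability
// proportional to the regional relative abundance `reg` of the drawn taxa.
static void rc_null_draw(int richness, int total,
                         const std::vector<double>& occ,
                         const std::vector<double>& reg,
                         std::vector<int>& chosen, std::vector<int>& abund) {
  const int S = (int)occ.size();
  chosen.clear();
  // Efraimidis-Spirakis: smallest Exp(1)/w keys win
  static std::vector<std::pair<double, int>> keys;
  keys.clear();
  keys.reserve(S);
  for (int i = 0; i < S; ++i) {
    if (occ[i] > 0.0) keys.push_back(std::make_pair(exp_rand() / occ[i], i));
  }
  if ((int)keys.size() < richness)
    stop("null draw: richness exceeds number of occurring taxa");
  std::partial_sort(keys.begin(), keys.begin() + richness, keys.end());
  double regsum = 0.0;
  for (int a = 0; a < richness; ++a) {
    chosen.push_back(keys[a].second);
    regsum += reg[keys[a].second];
  }
  abund.assign(richness, 1);
  int remaining = total - richness;
  if (remaining > 0 && regsum > 0.0) {
    // sequential binomial construction of a multinomial draw
    double psum = regsum;
    for (int a = 0; a < richness - 1 && remaining > 0; ++a) {
      double p = reg[chosen[a]] / psum;
      if (p > 1.0) p = 1.0;
      int x = (int)R::rbinom((double)remaining, p);
      abund[a] += x;
      remaining -= x;
      psum -= reg[chosen[a]];
      if (psum <= 0.0) break;
    }
    abund[richness - 1] += remaining;
  }
}

static double bray_curtis_sparse(const std::vector<int>& ia,
                                 const std::vector<int>& ca,
                                 const std::vector<int>& ib,
                                 const std::vector<int>& cb,
                                 std::vector<int>& scratch) {
  // scratch: S-length workspace of zeros, restored before return
  double shared = 0.0;
  double ta = 0.0, tb = 0.0;
  for (size_t a = 0; a < ia.size(); ++a) {
    scratch[ia[a]] = ca[a];
    ta += ca[a];
  }
  for (size_t b = 0; b < ib.size(); ++b) {
    int mn = std::min(scratch[ib[b]], cb[b]);
    shared += mn;
    tb += cb[b];
  }
  for (size_t a = 0; a < ia.size(); ++a) scratch[ia[a]] = 0;
  if (ta + tb == 0.0) return 0.0;
  return 1.0 - 2.0 * shared / (ta + tb);
}

// Raup-Crick (Bray-Curtis) for all sample pairs.
// counts : sample x taxon integer matrix
// n_null : number of null community pairs per sample pair
// Returns matrix in [-1, 1]. Uses the R RNG (seed with set.seed()).
// [[Rcpp::export]]
NumericMatrix rcbray_kernel(const IntegerMatrix& counts, int n_null) {
  const int n = counts.nrow();
  const int S = counts.ncol();
  if (n < 2) stop("Raup-Crick requires at least two samples");
  if (n_null < 99) stop("n_null must be at least 99");

  std::vector<double> occ(S, 0.0), reg(S, 0.0);
  double grand = 0.0;
  for (int i = 0; i < S; ++i) {
    for (int k = 0; k < n; ++k) {
      if (counts(k, i) > 0) occ[i] += 1.0;
      reg[i] += counts(k, i);
      grand += counts(k, i);
    }
  }
  if (grand <= 0) stop("empty table");
  for (int i = 0; i < S; ++i) reg[i] /= grand;

  std::vector<int> richness(n), total(n);
  for (int k = 0; k < n; ++k) {
    int r = 0, t = 0;
    for (int i = 0; i < S; ++i) {
      if (counts(k, i) > 0) ++r;
      t += counts(k, i);
    }
    if (t == 0) stop("sample with zero total abundance");
    richness[k] = r;
    total[k] = t;
  }

  NumericMatrix out(n, n);
  std::vector<int> scratch(S, 0);
  std::vector<int> ia, ca, ib, cb;
  for (int k = 0; k < n; ++k) {
    for (int m = k + 1; m < n; ++m) {
      // observed Bray-Curtis
      double shared = 0.0;
      for (int i = 0; i < S; ++i)
        shared += std::min(counts(k, i), counts(m, i));
      double obs = 1.0 - 2.0 * shared / (double)(total[k] + total[m]);
      double less = 0.0, ties = 0.0;
      for (int rep = 0; rep < n_null; ++rep) {
        rc_null_draw(richness[k], total[k], occ, reg, ia, ca);
        rc_null_draw(richness[m], total[m], occ, reg, ib, cb);
        double bc = bray_curtis_sparse(ia, ca, ib, cb, scratch);
        if (bc < obs) less += 1.0;
        else if (bc == obs) ties += 1.0;
      }
      double rc = ((less + 0.5 * ties) / (double)n_null - 0.5) * 2.0;
      out(k, m) = rc;
      out(m, k) = rc;
    }
  }
  return out;
}
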