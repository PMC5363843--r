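// Permutation and bootstrap engine for the threshold-indicator analysis.
//
// Sample units are assumed sorted by gradient; candidate split sizes k are
// counts of units with gradient <= candidate change point (k ascending).
// Permutations exploit sparsity: only the nonzero counts need new
// positions, drawn by a partial Fisher-Yates, which is distributionally
// identical to shuffling the full unit vector. Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>
using namespace Rcpp;

// IndVal for split size k given left-side sum cs and presence count cp.
static inline double ivpair(double cs, int cp, int k, int n, double tot,
                            int totp, bool* left = 0) {
  double mL = cs / k;
  double mR = (tot - cs) / (n - k);
  double d = mL + mR;
  double ivL = 100.0 * (mL / d) * ((double)cp / k);
  double ivR = 100.0 * (mR / d) * ((double)(totp - cp) / (n - k));
  if (left) *left = ivL >= ivR;
  return ivL >= ivR ? ivL : ivR;
}

// Max IndVal over candidates for one random placement of the m nonzero
// values among n positions. arr is a persistent permutation workspace of
// 0..n-1; buf holds (position, value) pairs.
static double perm_stat(std::vector<int>& arr, int n,
                        const std::vector<double>& vals, int m,
                        const std::vector<int>& k, double tot, int totp,
                        std::vector<std::pair<int, double> >& buf) {
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    std::swap(arr[i], arr[j]);
    buf[i] = std::make_pair(arr[i], vals[i]);
  }
  std::sort(buf.begin(), buf.begin() + m);
  double bestv = -1.0;
  size_t pi = 0;
  double cs = 0.0;
  int cp = 0;
  for (size_t j = 0; j < k.size(); ++j) {
    while (pi < (size_t)m && buf[pi].first < k[j]) {
      cs += buf[pi].second;
      ++cp;
      ++pi;
    }
    double v = ivpair(cs, cp, k[j], n, tot, totp);
    if (v > bestv) bestv = v;
  }
  return bestv;
}

// Observed max IndVal over candidates for y (sorted by gradient); reports
// argmax candidate index and side.
static double obs_stat(const std::vector<double>& y,
                       const std::vector<int>& k, double tot, int totp,
                       int* best, bool* leftbest) {
  int n = (int)y.size();
  double bestv = -1.0;
  int bi = -1;
  bool bl = true;
  size_t pos = 0;
  double cs = 0.0;
  int cp = 0;
  for (size_t j = 0; j < k.size(); ++j) {
    while (pos < (size_t)k[j]) {
      cs += y[pos];
      if (y[pos] > 0) ++cp;
      ++pos;
    }
    bool left;
    double v = ivpair(cs, cp, k[j], n, tot, totp, &left);
    if (v > bestv) {
      bestv = v;
      bi = (int)j;
      bl = left;
    }
  }
  if (best) *best = bi;
  if (leftbest) *leftbest = bl;
  return bestv;
}

// [[Rcpp::export]]
NumericVector cpp_perm_max(NumericVector y, IntegerVector kvec, int n_perm) {
  int n = y.size();
  std::vector<int> k(kvec.begin(), kvec.end());
  std::vector<double> vals;
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) vals.push_back(y[i]);
    tot += y[i];
  }
  int m = (int)vals.size();
  std::vector<int> arr(n);
  for (int i = 0; i < n; ++i) arr[i] = i;
  std::vector<std::pair<int, double> > buf(m);
  NumericVector out(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p)
    out[p] = perm_stat(arr, n, vals, m, k, tot, m, buf);
  return out;
}

// Bootstrap units with replacement, rerun the full candidate selection per
// resample, and compute a within-resample permutation p for the selected
// statistic. Returns change point, direction (1 = left/negative) and p per
// resample (NA when the resample has no usable candidates).
// [[Rcpp::export]]
List cpp_titan_boot(NumericVector y, NumericVector g, int n_boot,
                    int n_perm, int min_split) {
  int n = y.size();
  NumericVector cpb(n_boot, NA_REAL);
  IntegerVector dirb(n_boot, NA_INTEGER);
  NumericVector pb(n_boot, NA_REAL);
  std::vector<int> idx(n), arr(n);
  for (int i = 0; i < n; ++i) arr[i] = i;
  std::vector<double> yb(n), gb(n);
  RNGScope scope;
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = (int)(unif_rand() * n);
    std::sort(idx.begin(), idx.end());
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      yb[i] = y[idx[i]];
      gb[i] = g[idx[i]];
      tot += yb[i];
    }
    if (tot <= 0) continue;
    std::vector<double> pres;
    for (int i = 0; i < n; ++i)
      if (yb[i] > 0) pres.push_back(gb[i]);
    std::sort(pres.begin(), pres.end());
    pres.erase(std::unique(pres.begin(), pres.end()), pres.end());
    if (pres.size() < 2) continue;
    std::vector<double> cand;
    std::vector<int> kv;
    for (size_t j = 0; j + 1 < pres.size(); ++j) {
      double c = (pres[j] + pres[j + 1]) / 2.0;
      int k = (int)(std::upper_bound(gb.begin(), gb.end(), c) - gb.begin());
      if (k >= min_split && (n - k) >= min_split) {
        cand.push_back(c);
        kv.push_back(k);
      }
    }
    if (cand.empty()) continue;
    int totp = 0;
    std::vector<double> vals;
    for (int i = 0; i < n; ++i)
      if (yb[i] > 0) {
        ++totp;
        vals.push_back(yb[i]);
      }
    int bi;
    bool bl;
    double obs = obs_stat(yb, kv, tot, totp, &bi, &bl);
    cpb[b] = cand[bi];
    dirb[b] = bl ? 1 : 0;
    int ge = 0;
    std::vector<std::pair<int, double> > buf(totp);
    for (int p = 0; p < n_perm; ++p)
      if (perm_stat(arr, n, vals, totp, kv, tot, totp, buf) >= obs) ++ge;
    pb[b] = (1.0 + ge) / (n_perm + 1.0);
  }
  return List::create(_["cp"] = cpb, _["dir"] = dirb, _["p"] = pb);
}
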