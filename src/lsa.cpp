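#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local similarity dynamic program. Because each cell (i, j) only looks at
// its diagonal predecessor (i-1, j-1), the DP decomposes into independent
// one-dimensional passes, one per delay d = i - j with |d| <= D:
//   P = max(0, P + x_i * y_{i-d})   (positive association)
//   N = max(0, N - x_i * y_{i-d})   (negative association)
// LS = (best cell of max(P, N)) / n. Ties are broken by smaller |d|, then
// positive sign, then earlier window start in x, then in y.

struct LSBest {
  double score;
  int sign;     // +1 or -1
  int delay;    // d = start_x - start_y
  int sx, sy;   // 1-based window starts
  int len;
};

static inline bool ls_better(const LSBest &a, const LSBest &b) {
  const double eps = 1e-12;
  if (a.score > b.score + eps) return true;
  if (a.score < b.score - eps) return false;
  int ad = std::abs(a.delay), bd = std::abs(b.delay);
  if (ad != bd) return ad < bd;
  if (a.sign != b.sign) return a.sign > b.sign;
  if (a.sx != b.sx) return a.sx < b.sx;
  return a.sy < b.sy;
}

static LSBest ls_core(const double *x, const double *y, int n, int D) {
  LSBest best = {0.0, 1, 0, 1, 1, 0};
  for (int d = -D; d <= D; ++d) {
    // x index i runs where j = i - d is also in range (0-based)
    int i0 = d > 0 ? d : 0;
    int i1 = d > 0 ? n : n + d;
    double p = 0.0, npr = 0.0;
    int pstart = i0, nstart = i0;  // start (in x) of the current run
    for (int i = i0; i < i1; ++i) {
      double prod = x[i] * y[i - d];
      if (p <= 0.0) pstart = i;
      p += prod;
      if (p < 0.0) p = 0.0;
      if (npr <= 0.0) nstart = i;
      npr -= prod;
      if (npr < 0.0) npr = 0.0;
      LSBest cand = {p, 1, d, pstart + 1, pstart + 1 - d, i - pstart + 1};
      if (ls_better(cand, best)) best = cand;
      LSBest cand2 = {npr, -1, d, nstart + 1, nstart + 1 - d, i - nstart + 1};
      if (ls_better(cand2, best)) best = cand2;
    }
  }
  return best;
}

// score-only variant used inside permutation loops
static double ls_max_score(const double *x, const double *y, int n, int D) {
  double best = 0.0;
  for (int d = -D; d <= D; ++d) {
    int i0 = d > 0 ? d : 0;
    int i1 = d > 0 ? n : n + d;
    double p = 0.0, npr = 0.0;
    for (int i = i0; i < i1; ++i) {
      double prod = x[i] * y[i - d];
      p += prod;
      if (p < 0.0) p = 0.0; else if (p > best) best = p;
      npr -= prod;
      if (npr < 0.0) npr = 0.0; else if (npr > best) best = npr;
    }
  }
  return best;
}

// average ranks with ties (O(k^2); series are short)
static void avg_rank(const double *v, int k, double *r) {
  for (int i = 0; i < k; ++i) {
    int less = 0, eq = 0;
    for (int j = 0; j < k; ++j) {
      if (v[j] < v[i]) ++less;
      else if (v[j] == v[i]) ++eq;
    }
    r[i] = less + 0.5 * (eq + 1);
  }
}

// Spearman rho of x_i vs y_{i-d} on the overlap; 0 if either side constant
static double spearman_at_delay(const double *x, const double *y, int n,
                                int d) {
  int i0 = d > 0 ? d : 0;
  int i1 = d > 0 ? n : n + d;
  int k = i1 - i0;
  if (k < 3) return NA_REAL;
  std::vector<double> xa(k), ya(k), rx(k), ry(k);
  for (int i = 0; i < k; ++i) {
    xa[i] = x[i0 + i];
    ya[i] = y[i0 + i - d];
  }
  avg_rank(xa.data(), k, rx.data());
  avg_rank(ya.data(), k, ry.data());
  double mx = 0, my = 0;
  for (int i = 0; i < k; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= k; my /= k;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < k; ++i) {
    double a = rx[i] - mx, b = ry[i] - my;
    sxy += a * b; sxx += a * a; syy += b * b;
  }
  if (sxx <= 0 || syy <= 0) return 0.0;
  return sxy / std::sqrt(sxx * syy);
}

static List ls_as_list(const LSBest &b, int n) {
  return List::create(
    _["score"] = b.score / n,
    _["sign"] = b.sign,
    _["delay"] = b.delay,
    _["start_x"] = b.sx,
    _["start_y"] = b.sy,
    _["length"] = b.len);
}

// [[Rcpp::export]]
List ls_dp_cpp(NumericVector x, NumericVector y, int D) {
  int n = x.size();
  if ((int)y.size() != n) stop("series lengths differ");
  if (n < 1) stop("empty series");
  if (D < 0 || D >= n) stop("invalid delay limit");
  LSBest b = ls_core(REAL(x), REAL(y), n, D);
  return ls_as_list(b, n);
}

// [[Rcpp::export]]
double ls_score_cpp(NumericVector x, NumericVector y, int D) {
  int n = x.size();
  return ls_max_score(REAL(x), REAL(y), n, D) / n;
}

// [[Rcpp::export]]
double spearman_shift_cpp(NumericVector x, NumericVector y, int d) {
  return spearman_at_delay(REAL(x), REAL(y), x.size(), d);
}

// Permutation p-value for |LS| only (time order of y shuffled with the
// R RNG, so results follow set.seed()).
// [[Rcpp::export]]
double ls_perm_p_cpp(NumericVector x, NumericVector y, int D, int n_perm) {
  int n = x.size();
  if ((int)y.size() != n) stop("series lengths differ");
  if (n_perm < 1) stop("n_perm must be >= 1");
  double obs = ls_max_score(REAL(x), REAL(y), n, D);
  int hits = 0;
  for (int b = 0; b < n_perm; ++b) {
    NumericVector yp = Rcpp::sample(y, n, false);
    if (ls_max_score(REAL(x), REAL(yp), n, D) >= obs - 1e-12) ++hits;
  }
  return (1.0 + hits) / (1.0 + n_perm);
}

// Full association workup of one pair: observed LS (with traceback),
// Spearman at the LS-optimal delay, and permutation p-values for both
// statistics from one stream of y-shuffles.
// [[Rcpp::export]]
List ls_assoc_perm_cpp(NumericVector x, NumericVector y, int D, int n_perm) {
  int n = x.size();
  if ((int)y.size() != n) stop("series lengths differ");
  if (n_perm < 1) stop("n_perm must be >= 1");
  LSBest obs = ls_core(REAL(x), REAL(y), n, D);
  double obs_score = obs.score;
  double rho = spearman_at_delay(REAL(x), REAL(y), n, obs.delay);
  int ls_hits = 0, sscc_hits = 0;
  for (int b = 0; b < n_perm; ++b) {
    NumericVector yp = Rcpp::sample(y, n, false);
    if (ls_max_score(REAL(x), REAL(yp), n, D) >= obs_score - 1e-12)
      ++ls_hits;
    double rp = spearman_at_delay(REAL(x), REAL(yp), n, obs.delay);
    if (std::abs(rp) >= std::abs(rho) - 1e-12) ++sscc_hits;
  }
  List out = ls_as_list(obs, n);
  out["ls_p"] = (1.0 + ls_hits) / (1.0 + n_perm);
  out["sscc"] = rho;
  out["sscc_p"] = (1.0 + sscc_hits) / (1.0 + n_perm);
  return out;
}
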