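// Maximal information coefficient (MIC) via the ApproxMaxMI heuristic:
// for each grid shape (kx, ky) within the budget B = max(4, floor(n^b)),
// one axis is equipartitioned into rows (ties never split) and the other
// axis is optimized over clump boundaries with a dynamic program that
// maximizes H(P) - H(P,Q); both orientations are taken.  MIC is the max
// over shapes of I / log2(min(kx, ky)).
//
// A reusable workspace keeps the inner loops allocation-free so that
// permutation nulls over many OTU pairs stay cheap.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -1e300;

struct MicWorkspace {
  std::vector<int> ordx, ordy, rowSorted, rowOf, clumpOfSorted, scRow;
  std::vector<double> xs, ys, fake, F, lut;
  std::vector<int> cum, csz, rowCnt;
  void reserve(int n, int B) {
    ordx.resize(n); ordy.resize(n); rowSorted.resize(n); rowOf.resize(n);
    clumpOfSorted.resize(n); scRow.resize(n);
    xs.resize(n); ys.resize(n); fake.resize(n);
    int nrmax = B / 2 + 1;
    cum.resize((size_t)(n + 1) * nrmax);
    csz.resize(n + 1);
    F.resize((size_t)(n + 1) * (B + 1));
    rowCnt.resize(nrmax);
    // lut[k] = (k/n) * log2(k/n): every entropy term has an integer
    // count in the numerator, so the DP runs on table lookups
    lut.resize(n + 1);
    lut[0] = 0.0;
    for (int k = 1; k <= n; ++k)
      lut[k] = ((double)k / n) * std::log2((double)k / n);
  }
};

// Assign n sorted values to at most k rows, as evenly as possible,
// never splitting ties.  Writes 1-based row ids; returns rows used.
static int equipartition_sorted(const double* v, int n, int k, int* row) {
  int i = 0, currRow = 1, rowSize = 0;
  double desired = (double)n / k;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    int run = j - i;
    double t1 = std::fabs((double)rowSize + run - desired);
    double t2 = std::fabs((double)rowSize - desired);
    if (rowSize != 0 && t1 >= t2 && currRow < k) {
      ++currRow;
      rowSize = 0;
      desired = (double)(n - i) / (k - currRow + 1);
    }
    for (int t = i; t < j; ++t) row[t] = currRow;
    rowSize += run;
    i = j;
  }
  return currRow;
}

static inline double xlog2x(double p) {
  return (p > 0.0) ? p * std::log2(p) : 0.0;
}

// One orientation: rows from the value vector `yv` (equipartitioned
// into ky rows, using its precomputed ascending order `ordy`), columns
// optimized over clumps of `xv` (precomputed order `ordx`).
static void optimize_axis(const std::vector<double>& xv,
                          const std::vector<int>& ordx,
                          const std::vector<double>& yv,
                          const std::vector<int>& ordy,
                          int ky, int kxmax, int cfac,
                          MicWorkspace& ws, double& best) {
  int n = (int)xv.size();

  for (int i = 0; i < n; ++i) ws.ys[i] = yv[ordy[i]];
  int nrows = equipartition_sorted(ws.ys.data(), n, ky, ws.rowSorted.data());
  if (nrows < 2) return;
  for (int i = 0; i < n; ++i) ws.rowOf[ordy[i]] = ws.rowSorted[i] - 1;

  std::fill(ws.rowCnt.begin(), ws.rowCnt.begin() + nrows, 0);
  for (int i = 0; i < n; ++i) ++ws.rowCnt[ws.rowOf[i]];
  const double* lut = ws.lut.data();
  double hq = 0.0;
  for (int q = 0; q < nrows; ++q) hq -= lut[ws.rowCnt[q]];

  // clumps: maximal runs of tied x in x-sorted order
  int T = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && xv[ordx[i]] != xv[ordx[i - 1]]) ++T;
    ws.clumpOfSorted[i] = T;
  }
  ++T;
  if (T < 2) return;

  // superclumps: cap candidate boundaries at cfac * kxmax
  int khat = cfac * kxmax;
  if (T > khat) {
    for (int i = 0; i < n; ++i) ws.fake[i] = (double)ws.clumpOfSorted[i];
    int used = equipartition_sorted(ws.fake.data(), n, khat, ws.scRow.data());
    for (int i = 0; i < n; ++i) ws.clumpOfSorted[i] = ws.scRow[i] - 1;
    T = used;
  }

  // cumulative per-row counts over clumps 1..t (flat (T+1) x nrows)
  int* cum = ws.cum.data();
  int* csz = ws.csz.data();
  std::fill(cum, cum + (size_t)(T + 1) * nrows, 0);
  for (int i = 0; i < n; ++i) {
    int c = ws.clumpOfSorted[i];
    cum[(size_t)(c + 1) * nrows + ws.rowOf[ordx[i]]] += 1;
  }
  csz[0] = 0;
  for (int t = 1; t <= T; ++t) {
    int tot = 0;
    for (int q = 0; q < nrows; ++q) {
      cum[(size_t)t * nrows + q] += cum[(size_t)(t - 1) * nrows + q];
      tot += cum[(size_t)t * nrows + q];
    }
    csz[t] = tot;
  }

  int lmax = std::min(kxmax, T);
  // F[t*(lmax+1)+l]: best H(P)-H(P,Q) over partitions of clumps 1..t
  // into exactly l columns
  double* F = ws.F.data();
  int stride = lmax + 1;
  for (int t = 1; t <= T; ++t) {
    const int* ct = cum + (size_t)t * nrows;
    double val = -lut[csz[t]];
    for (int q = 0; q < nrows; ++q) val += lut[ct[q]];
    F[t * stride + 1] = val;
  }
  for (int l = 2; l <= lmax; ++l) {
    for (int t = l; t <= T; ++t) {
      const int* ct = cum + (size_t)t * nrows;
      double bestv = NEG_INF;
      for (int s = l - 1; s < t; ++s) {
        const int* cs = cum + (size_t)s * nrows;
        double phi = -lut[csz[t] - csz[s]];
        for (int q = 0; q < nrows; ++q)
          phi += lut[ct[q] - cs[q]];
        double v = F[s * stride + l - 1] + phi;
        if (v > bestv) bestv = v;
      }
      F[t * stride + l] = bestv;
    }
  }
  for (int l = 2; l <= lmax; ++l) {
    double I = hq + F[T * stride + l];
    if (I < 0) I = 0;
    double val = I / std::log2((double)std::min(l, ky));
    if (val > best) best = val;
  }
}

static void sort_order(const std::vector<double>& v, std::vector<int>& ord) {
  int n = (int)v.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.begin() + n,
            [&](int a, int b) { return v[a] < v[b]; });
}

static double mic_core(const std::vector<double>& x,
                       const std::vector<double>& y,
                       int B, int cfac, MicWorkspace& ws) {
  int n = (int)x.size();
  bool xconst = true, yconst = true;
  for (int i = 1; i < n; ++i) {
    if (x[i] != x[0]) xconst = false;
    if (y[i] != y[0]) yconst = false;
  }
  if (xconst || yconst) return 0.0;
  sort_order(x, ws.ordx);
  sort_order(y, ws.ordy);
  double best = 0.0;
  for (int ky = 2; 2 * ky <= B; ++ky) {
    int kxmax = B / ky;
    if (kxmax < 2) break;
    optimize_axis(x, ws.ordx, y, ws.ordy, ky, kxmax, cfac, ws, best);
    optimize_axis(y, ws.ordy, x, ws.ordx, ky, kxmax, cfac, ws, best);
  }
  if (best > 1.0) best = 1.0;
  return best;
}

static int grid_budget(int n, double b_exponent) {
  int B = (int)std::floor(std::pow((double)n, b_exponent));
  return std::max(B, 4);
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, double b_exponent,
               int clumps_factor) {
  int n = x.size();
  int B = grid_budget(n, b_exponent);
  MicWorkspace ws; ws.reserve(n, B);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return mic_core(xv, yv, B, clumps_factor, ws);
}

// Same but with an explicit grid budget (oracle comparisons).
// [[Rcpp::export]]
double mic_budget_cpp(NumericVector x, NumericVector y, int B,
                      int clumps_factor) {
  int n = x.size();
  MicWorkspace ws; ws.reserve(n, B);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return mic_core(xv, yv, B, clumps_factor, ws);
}

// Fisher-Yates shuffle driven by R's RNG (so set.seed() governs it)
static void shuffle_inplace(std::vector<double>& v) {
  int n = (int)v.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export]]
double mic_perm_pvalue_cpp(NumericVector x, NumericVector y,
                           double b_exponent, int clumps_factor,
                           int n_perm) {
  int n = x.size();
  int B = grid_budget(n, b_exponent);
  MicWorkspace ws; ws.reserve(n, B);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double obs = mic_core(xv, yv, B, clumps_factor, ws);
  int ge = 0;
  std::vector<double> perm(yv);
  for (int r = 0; r < n_perm; ++r) {
    shuffle_inplace(perm);
    if (mic_core(xv, perm, B, clumps_factor, ws) >= obs - 1e-12) ++ge;
  }
  return (1.0 + ge) / (1.0 + n_perm);
}

// All unordered row pairs of an OTU-by-sample matrix: MIC, Pearson r,
// permutation p-value.  Rows are OTUs; columns are samples.
// [[Rcpp::export]]
List mic_all_pairs_cpp(NumericMatrix tab, double b_exponent,
                       int clumps_factor, int n_perm) {
  int m = tab.nrow(), n = tab.ncol();
  int B = grid_budget(n, b_exponent);
  MicWorkspace ws; ws.reserve(n, B);
  int npair = m * (m - 1) / 2;
  IntegerVector ia(npair), ib(npair);
  NumericVector mic(npair), rr(npair), pval(npair);
  std::vector<std::vector<double> > rows(m, std::vector<double>(n));
  std::vector<double> mean(m, 0.0), sd(m, 0.0);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) { rows[i][j] = tab(i, j); mean[i] += tab(i, j); }
    mean[i] /= n;
    for (int j = 0; j < n; ++j)
      sd[i] += (rows[i][j] - mean[i]) * (rows[i][j] - mean[i]);
    sd[i] = std::sqrt(sd[i]);
  }
  int k = 0;
  std::vector<double> perm(n);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j, ++k) {
      ia[k] = i + 1; ib[k] = j + 1;
      double obs = mic_core(rows[i], rows[j], B, clumps_factor, ws);
      mic[k] = obs;
      double r = 0.0;
      if (sd[i] > 0 && sd[j] > 0) {
        for (int t = 0; t < n; ++t)
          r += (rows[i][t] - mean[i]) * (rows[j][t] - mean[j]);
        r /= sd[i] * sd[j];
      }
      rr[k] = r;
      int ge = 0;
      perm = rows[j];
      for (int rep = 0; rep < n_perm; ++rep) {
        shuffle_inplace(perm);
        if (mic_core(rows[i], perm, B, clumps_factor, ws) >= obs - 1e-12)
          ++ge;
      }
      pval[k] = (1.0 + ge) / (1.0 + n_perm);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = ia, _["j"] = ib, _["mic"] = mic,
                      _["pearson_r"] = rr, _["p_value"] = pval);
}
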