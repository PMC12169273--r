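#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Segmented least-squares machinery shared by the trend (p = 2) and seasonal
// (p = 4 harmonic) components: interval RSS via prefix cross-products and a
// small packed Cholesky, exact dynamic-programming segmentation, and the
// residual-bootstrap loop for break-date confidence intervals.
//
// The normal-equation matrix of every interval depends only on the design
// and the observation times, so its Cholesky factors are computed once
// (`cpp_seg_prepare`) and reused across responses: alternation iterations,
// bootstrap replicates, and all pixels sharing one time axis.

static inline int packidx(int k, int l) { return k * (k + 1) / 2 + l; }

// Cholesky of packed symmetric A (p*(p+1)/2 entries) -> packed L.
static bool chol_small(int p, const double* A, double* L, double tol) {
  for (int k = 0; k < p; ++k) {
    for (int l = 0; l <= k; ++l) {
      double s = A[packidx(k, l)];
      for (int m = 0; m < l; ++m) s -= L[packidx(k, m)] * L[packidx(l, m)];
      if (k == l) {
        if (s <= tol) return false;
        L[packidx(k, k)] = std::sqrt(s);
      } else {
        L[packidx(k, l)] = s / L[packidx(l, l)];
      }
    }
  }
  return true;
}

// RSS = yty - b' A^{-1} b via the cached forward solve.
static inline double rss_from_chol(int p, const double* L, const double* b,
                                   double yty) {
  double w[8];
  double acc = 0.0;
  for (int k = 0; k < p; ++k) {
    double s = b[k];
    for (int m = 0; m < k; ++m) s -= L[packidx(k, m)] * w[m];
    w[k] = s / L[packidx(k, k)];
    acc += w[k] * w[k];
  }
  double r = yty - acc;
  return r > 0.0 ? r : 0.0;
}

struct SegPrep {
  int n, p, pp, min_len;
  std::vector<double> X;        // column-major n x p copy of the design
  std::vector<unsigned char> valid;  // n x n (i + j*n)
  std::vector<double> Lc;            // cached Cholesky, (i + j*n) * pp
  std::vector<int> t;
};

static void build_prep(SegPrep& sp, const NumericMatrix& X,
                       const IntegerVector& t, int min_len) {
  sp.n = X.nrow(); sp.p = X.ncol(); sp.pp = sp.p * (sp.p + 1) / 2;
  sp.min_len = min_len;
  int n = sp.n, p = sp.p, pp = sp.pp;
  sp.X.assign(X.begin(), X.end());
  sp.t.assign(t.begin(), t.end());
  // prefix cross-products G[q][r]
  std::vector<double> G((size_t)pp * (n + 1), 0.0);
  for (int r = 0; r < n; ++r)
    for (int k = 0; k < p; ++k)
      for (int l = 0; l <= k; ++l) {
        size_t id = (size_t)packidx(k, l) * (n + 1);
        G[id + r + 1] = G[id + r] +
          sp.X[(size_t)k * n + r] * sp.X[(size_t)l * n + r];
      }
  sp.valid.assign((size_t)n * n, 0);
  sp.Lc.assign((size_t)n * n * pp, 0.0);
  double A[36];
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      if (sp.t[j] - sp.t[i] + 1 < min_len || j - i + 1 < p) continue;
      double dmax = 0.0;
      for (int q = 0; q < pp; ++q) {
        size_t id = (size_t)q * (n + 1);
        A[q] = G[id + j + 1] - G[id + i];
      }
      for (int k = 0; k < p; ++k) dmax = std::max(dmax, A[packidx(k, k)]);
      size_t cell = (size_t)i + (size_t)j * n;
      if (chol_small(p, A, &sp.Lc[cell * pp], 1e-10 * (dmax + 1.0)))
        sp.valid[cell] = 1;
    }
}

// Fill an n x n interval-cost array for response y using the cached factors.
static void cost_for_response(const SegPrep& sp, const double* y,
                              double* cost) {
  int n = sp.n, p = sp.p, pp = sp.pp;
  std::vector<double> g((size_t)p * (n + 1), 0.0), yy(n + 1, 0.0);
  for (int r = 0; r < n; ++r) {
    yy[r + 1] = yy[r] + y[r] * y[r];
    for (int k = 0; k < p; ++k) {
      size_t id = (size_t)k * (n + 1);
      g[id + r + 1] = g[id + r] + sp.X[(size_t)k * n + r] * y[r];
    }
  }
  double b[8];
  std::fill(cost, cost + (size_t)n * n, R_PosInf);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      size_t cell = (size_t)i + (size_t)j * n;
      if (!sp.valid[cell]) continue;
      for (int k = 0; k < p; ++k) {
        size_t id = (size_t)k * (n + 1);
        b[k] = g[id + j + 1] - g[id + i];
      }
      cost[cell] = rss_from_chol(p, &sp.Lc[cell * pp], b,
                                 yy[j + 1] - yy[i]);
    }
}

struct DPResult {
  std::vector<double> rss;
  std::vector<std::vector<int> > breaks;
};

// Exact DP over segment ends; ties resolved toward earlier break positions
// (ascending scan with strict improvement keeps the smallest index).
static DPResult dp_core(const double* cost, int n, int max_breaks) {
  int K = max_breaks;
  std::vector<double> F((size_t)(K + 1) * n, R_PosInf);
  std::vector<int> prev((size_t)(K + 1) * n, -1);
  for (int j = 0; j < n; ++j) F[j] = cost[(size_t)j * n];  // cost(0, j)
  for (int k = 1; k <= K; ++k) {
    for (int j = 0; j < n; ++j) {
      double best = R_PosInf;
      int arg = -1;
      const double* Fp = &F[(size_t)(k - 1) * n];
      const double* cj = &cost[(size_t)j * n];
      for (int i = 0; i < j; ++i) {
        double v = Fp[i] + cj[i + 1];
        if (v < best) { best = v; arg = i; }
      }
      F[(size_t)k * n + j] = best;
      prev[(size_t)k * n + j] = arg;
    }
  }
  DPResult out;
  out.rss.resize(K + 1);
  out.breaks.resize(K + 1);
  for (int k = 0; k <= K; ++k) {
    out.rss[k] = F[(size_t)k * n + (n - 1)];
    if (!R_FINITE(out.rss[k])) continue;
    std::vector<int> br;
    int j = n - 1;
    for (int kk = k; kk >= 1; --kk) {
      int i = prev[(size_t)kk * n + j];
      br.push_back(i);
      j = i;
    }
    std::reverse(br.begin(), br.end());
    out.breaks[k] = br;
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_seg_prepare(NumericMatrix X, IntegerVector t, int min_len) {
  if (t.size() != X.nrow()) stop("X, t size mismatch");
  if (X.ncol() > 8) stop("at most 8 regressors supported");
  XPtr<SegPrep> ptr(new SegPrep(), true);
  build_prep(*ptr, X, t, min_len);
  return ptr;
}

// [[Rcpp::export]]
NumericMatrix cpp_seg_cost_prep(SEXP prep, NumericVector y) {
  XPtr<SegPrep> sp(prep);
  if (y.size() != sp->n) stop("response length mismatch");
  NumericMatrix cost(sp->n, sp->n);
  cost_for_response(*sp, REAL(y), REAL(cost));
  return cost;
}

// One-shot interval-cost matrix (used by tests and one-off fits).
// [[Rcpp::export]]
NumericMatrix cpp_seg_cost(NumericMatrix X, NumericVector y, IntegerVector t,
                           int min_len) {
  SegPrep sp;
  build_prep(sp, X, t, min_len);
  if (y.size() != sp.n) stop("response length mismatch");
  NumericMatrix cost(sp.n, sp.n);
  cost_for_response(sp, REAL(y), REAL(cost));
  return cost;
}

// [[Rcpp::export]]
List cpp_dp(NumericMatrix cost, int max_breaks) {
  int n = cost.nrow();
  DPResult r = dp_core(REAL(cost), n, max_breaks);
  List breaks(max_breaks + 1);
  NumericVector rss(max_breaks + 1);
  for (int k = 0; k <= max_breaks; ++k) {
    rss[k] = r.rss[k];
    if (R_FINITE(r.rss[k])) {
      IntegerVector b(r.breaks[k].size());
      for (size_t m = 0; m < r.breaks[k].size(); ++m) b[m] = r.breaks[k][m] + 1;
      breaks[k] = b;
    } else {
      breaks[k] = R_NilValue;
    }
  }
  return List::create(Named("rss") = rss, Named("breaks") = breaks);
}

// Cost + DP in one call against a prepared design.
// [[Rcpp::export]]
List cpp_dp_prep(SEXP prep, NumericVector y, int max_breaks) {
  XPtr<SegPrep> sp(prep);
  if (y.size() != sp->n) stop("response length mismatch");
  std::vector<double> cost((size_t)sp->n * sp->n);
  cost_for_response(*sp, REAL(y), &cost[0]);
  DPResult r = dp_core(&cost[0], sp->n, max_breaks);
  List breaks(max_breaks + 1);
  NumericVector rss(max_breaks + 1);
  for (int k = 0; k <= max_breaks; ++k) {
    rss[k] = r.rss[k];
    if (R_FINITE(r.rss[k])) {
      IntegerVector b(r.breaks[k].size());
      for (size_t m = 0; m < r.breaks[k].size(); ++m) b[m] = r.breaks[k][m] + 1;
      breaks[k] = b;
    } else {
      breaks[k] = R_NilValue;
    }
  }
  return List::create(Named("rss") = rss, Named("breaks") = breaks);
}

// Residual bootstrap for break dates of one component, holding the other
// component fixed: y* = fitted + resampled residuals, then DP with exactly
// k breaks. Returns reps x k matrix of break row indices (1-based), NA when
// a replicate admits no k-break segmentation. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_boot_breaks(SEXP prep, NumericVector fitted,
                              NumericVector resid, int k, int reps) {
  XPtr<SegPrep> sp(prep);
  int n = sp->n;
  if (fitted.size() != n) stop("fitted length mismatch");
  if (k < 1) stop("k must be >= 1");
  int nres = resid.size();
  std::vector<double> cost((size_t)n * n), ystar(n);
  IntegerMatrix out(reps, k);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int r = 0; r < reps; ++r) {
    for (int m = 0; m < n; ++m) {
      int id = (int)(unif_rand() * nres);
      if (id >= nres) id = nres - 1;
      ystar[m] = fitted[m] + resid[id];
    }
    cost_for_response(*sp, &ystar[0], &cost[0]);
    DPResult dr = dp_core(&cost[0], n, k);
    if (R_FINITE(dr.rss[k])) {
      for (int m = 0; m < k; ++m) out(r, m) = dr.breaks[k][m] + 1;
    }
  }
  return out;
}
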