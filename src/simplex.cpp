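#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dense two-phase primal simplex for
//
//     min / max  c'v   s.t.   A v = b,   l <= v <= u
//
// Lower bounds must be finite (callers clamp open uptake bounds to a large
// box); upper bounds may be +Inf.  Variables are shifted to x = v - l >= 0
// and finite ranges d = u - l enter as slack rows x_j + s_j = d_j, so the
// bound rows come with a ready-made basic variable and artificials are only
// needed on the structural rows.  Entering/leaving choices follow Bland's
// rule: deterministic and cycle-free, which matters more than speed at the
// problem sizes handled here (tens of reactions).

static const double PIV_TOL = 1e-9;   // pivot / reduced-cost tolerance
static const double FEAS_TOL = 1e-7;  // phase-1 infeasibility threshold

// [[Rcpp::export]]
List simplex_core(NumericVector cvec, NumericMatrix Amat, NumericVector bvec,
                  NumericVector lower, NumericVector upper, bool maximize) {
  const int n = Amat.ncol();
  const int m = Amat.nrow();
  const double INF = std::numeric_limits<double>::infinity();

  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(lower[j]))
      stop("simplex_core: lower bounds must be finite");
    if (upper[j] < lower[j])
      stop("simplex_core: lower bound exceeds upper bound");
  }

  // shifted problem data
  std::vector<double> d(n);
  std::vector<int> bnd_row(n, -1);   // which bound row (if any) a var owns
  int ns = 0;
  for (int j = 0; j < n; ++j) {
    d[j] = upper[j] - lower[j];
    if (std::isfinite(d[j])) bnd_row[j] = ns++;
  }

  const int nrows = m + ns;
  const int ncols = n + ns + m;      // x vars, bound slacks, artificials
  const int rhs = ncols;             // rhs column index

  // tableau rows + two cost rows (phase 1, phase 2)
  std::vector< std::vector<double> > T(nrows, std::vector<double>(ncols + 1, 0.0));
  std::vector<int> basis(nrows, -1);
  std::vector<bool> active(nrows, true);

  // structural rows: A x = b - A l, artificial basic
  for (int i = 0; i < m; ++i) {
    double bi = bvec[i];
    for (int j = 0; j < n; ++j) bi -= Amat(i, j) * lower[j];
    double sgn = (bi < 0.0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) T[i][j] = sgn * Amat(i, j);
    T[i][rhs] = sgn * bi;
    T[i][n + ns + i] = 1.0;
    basis[i] = n + ns + i;
  }
  // bound rows: x_j + s = d_j, slack basic
  for (int j = 0; j < n; ++j) {
    if (bnd_row[j] < 0) continue;
    int i = m + bnd_row[j];
    T[i][j] = 1.0;
    T[i][n + bnd_row[j]] = 1.0;
    T[i][rhs] = d[j];
    basis[i] = n + bnd_row[j];
  }

  std::vector<double> z(ncols + 1, 0.0);   // current reduced-cost row

  // helper: one simplex pivot loop over the active rows for cost row z,
  // with entering columns restricted to [0, maxcol). Returns:
  //  0 optimal, 1 unbounded.
  auto run = [&](int maxcol) -> int {
    for (;;) {
      int enter = -1;
      for (int j = 0; j < maxcol; ++j) {
        if (z[j] < -PIV_TOL) { enter = j; break; }   // Bland: smallest index
      }
      if (enter < 0) return 0;
      int leave = -1;
      double best = INF;
      for (int i = 0; i < nrows; ++i) {
        if (!active[i] || T[i][enter] <= PIV_TOL) continue;
        double ratio = T[i][rhs] / T[i][enter];
        if (ratio < best - PIV_TOL ||
            (ratio < best + PIV_TOL && (leave < 0 || basis[i] < basis[leave])))
        { best = ratio; leave = i; }
      }
      if (leave < 0) return 1;
      // pivot on (leave, enter)
      double piv = T[leave][enter];
      for (int j = 0; j <= ncols; ++j) T[leave][j] /= piv;
      for (int i = 0; i < nrows; ++i) {
        if (i == leave || !active[i]) continue;
        double f = T[i][enter];
        if (f == 0.0) continue;
        for (int j = 0; j <= ncols; ++j) T[i][j] -= f * T[leave][j];
        T[i][enter] = 0.0;
      }
      double fz = z[enter];
      if (fz != 0.0) {
        for (int j = 0; j <= ncols; ++j) z[j] -= fz * T[leave][j];
        z[enter] = 0.0;
      }
      basis[leave] = enter;
      if (T[leave][rhs] < 0.0 && T[leave][rhs] > -1e-11) T[leave][rhs] = 0.0;
    }
  };

  // ---- phase 1: min sum of artificials --------------------------------
  for (int i = 0; i < m; ++i) z[n + ns + i] = 1.0;
  for (int i = 0; i < m; ++i)           // zero out the basic artificials
    for (int j = 0; j <= ncols; ++j) z[j] -= T[i][j];

  run(n + ns);                          // artificials never re-enter
  double phase1 = -z[rhs];
  if (phase1 > FEAS_TOL) {
    return List::create(_["status"] = "infeasible",
                        _["objective"] = NA_REAL,
                        _["x"] = NumericVector(0));
  }

  // drive leftover artificials out of the basis; drop redundant rows
  for (int i = 0; i < nrows; ++i) {
    if (!active[i] || basis[i] < n + ns) continue;
    int piv_col = -1;
    for (int j = 0; j < n + ns; ++j)
      if (std::fabs(T[i][j]) > PIV_TOL) { piv_col = j; break; }
    if (piv_col < 0) { active[i] = false; continue; }
    double piv = T[i][piv_col];
    for (int j = 0; j <= ncols; ++j) T[i][j] /= piv;
    for (int k = 0; k < nrows; ++k) {
      if (k == i || !active[k]) continue;
      double f = T[k][piv_col];
      if (f == 0.0) continue;
      for (int j = 0; j <= ncols; ++j) T[k][j] -= f * T[i][j];
      T[k][piv_col] = 0.0;
    }
    basis[i] = piv_col;
  }

  // ---- phase 2 ---------------------------------------------------------
  std::fill(z.begin(), z.end(), 0.0);
  double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < n; ++j) z[j] = sgn * cvec[j];
  for (int i = 0; i < nrows; ++i) {
    if (!active[i]) continue;
    double f = z[basis[i]];
    if (f == 0.0) continue;
    for (int j = 0; j <= ncols; ++j) z[j] -= f * T[i][j];
    z[basis[i]] = 0.0;
  }

  int code = run(n + ns);
  if (code == 1) {
    return List::create(_["status"] = "unbounded",
                        _["objective"] = NA_REAL,
                        _["x"] = NumericVector(0));
  }

  NumericVector x(n);
  for (int i = 0; i < nrows; ++i) {
    if (!active[i]) continue;
    if (basis[i] < n) x[basis[i]] = T[i][rhs];
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) {
    x[j] += lower[j];                // back to original variables
    obj += cvec[j] * x[j];
  }
  return List::create(_["status"] = "optimal",
                      _["objective"] = obj,
                      _["x"] = x);
}
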