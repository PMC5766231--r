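#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dense bounded-variable primal simplex, two phases, Bland's rule throughout.
// Solves: maximize c'x subject to A x = b, lb <= x <= ub.
// Callers add slack/surplus columns for inequality rows. Lower bounds must be
// finite; upper bounds may be +Inf. Status: 0 optimal, 1 infeasible,
// 2 unbounded, 3 iteration limit.

static const double DUAL_TOL = 1e-9;
static const double PIV_TOL = 1e-8;
static const double INF = std::numeric_limits<double>::infinity();

enum VarStat { BASIC = 0, AT_LB = 1, AT_UB = 2 };

struct SimplexState {
  int m, n, N; // rows, structural cols, total cols (incl. artificials)
  std::vector<double> T;   // m x N tableau, column-major: B^{-1} A
  std::vector<double> x;   // current values, length N
  std::vector<double> lo, hi;
  std::vector<int> basis;  // length m, column basic in each row
  std::vector<int> stat;   // length N
  double &t(int i, int j) { return T[(size_t)j * m + i]; }
};

// One simplex phase under cost vector cc; columns with eligible[j]==0 never
// enter the basis. Returns 0 optimal, 2 unbounded, 3 maxit.
static int run_phase(SimplexState &S, const std::vector<double> &cc,
                     const std::vector<char> &eligible, int maxit) {
  int m = S.m, N = S.N;
  std::vector<double> cB(m);
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < m; ++i) cB[i] = cc[S.basis[i]];
    // Bland: first eligible improving column by index
    int enter = -1, dir = 0;
    for (int j = 0; j < N; ++j) {
      if (S.stat[j] == BASIC || !eligible[j]) continue;
      if (S.hi[j] - S.lo[j] < 1e-15) continue; // fixed variable
      double d = cc[j];
      const double *col = &S.T[(size_t)j * m];
      for (int i = 0; i < m; ++i) d -= cB[i] * col[i];
      if (S.stat[j] == AT_LB && d > DUAL_TOL) { enter = j; dir = 1; break; }
      if (S.stat[j] == AT_UB && d < -DUAL_TOL) { enter = j; dir = -1; break; }
    }
    if (enter < 0) return 0;

    const double *w = &S.T[(size_t)enter * m];
    double tmax = S.hi[enter] - S.lo[enter]; // bound-flip limit (may be Inf)
    int leave = -1, leave_to = AT_LB;
    for (int i = 0; i < m; ++i) {
      if (std::fabs(w[i]) < PIV_TOL) continue;
      double delta = -dir * w[i]; // rate of change of basic var i
      int bi = S.basis[i];
      double lim;
      int hit;
      if (delta > 0) {
        if (S.hi[bi] == INF) continue;
        lim = (S.hi[bi] - S.x[bi]) / delta;
        hit = AT_UB;
      } else {
        lim = (S.x[bi] - S.lo[bi]) / (-delta);
        hit = AT_LB;
      }
      if (lim < 0) lim = 0;
      if (lim < tmax - 1e-12 ||
          (lim < tmax + 1e-12 && leave >= 0 && bi < S.basis[leave])) {
        tmax = lim;
        leave = i;
        leave_to = hit;
      }
    }
    if (tmax == INF) return 2;
    if (tmax < 0) tmax = 0;

    // update variable values
    S.x[enter] += dir * tmax;
    for (int i = 0; i < m; ++i) S.x[S.basis[i]] -= dir * tmax * w[i];

    if (leave < 0) { // bound flip, basis unchanged
      S.stat[enter] = (dir > 0) ? AT_UB : AT_LB;
      S.x[enter] = (dir > 0) ? S.hi[enter] : S.lo[enter];
      continue;
    }
    int lv = S.basis[leave];
    S.x[lv] = (leave_to == AT_UB) ? S.hi[lv] : S.lo[lv];
    S.stat[lv] = leave_to;
    // pivot tableau on (leave, enter)
    double piv = S.t(leave, enter);
    for (int j = 0; j < N; ++j) S.t(leave, j) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = S.t(i, enter);
      if (std::fabs(f) < 1e-14) continue;
      for (int j = 0; j < N; ++j) S.t(i, j) -= f * S.t(leave, j);
    }
    S.basis[leave] = enter;
    S.stat[enter] = BASIC;
  }
  return 3;
}

// [[Rcpp::export(".simplex_bounded")]]
List simplex_bounded(NumericMatrix A, NumericVector b, NumericVector c,
                     NumericVector lb, NumericVector ub, int maxit = 50000) {
  int m = A.nrow(), n = A.ncol();
  SimplexState S;
  S.m = m;
  S.n = n;
  S.N = n + m;
  S.T.assign((size_t)S.N * m, 0.0);
  S.x.assign(S.N, 0.0);
  S.lo.assign(S.N, 0.0);
  S.hi.assign(S.N, INF);
  S.basis.assign(m, 0);
  S.stat.assign(S.N, AT_LB);

  for (int j = 0; j < n; ++j) {
    S.lo[j] = lb[j];
    S.hi[j] = ub[j];
    if (!std::isfinite(S.lo[j]))
      stop("simplex: lower bounds must be finite");
    // park non-basic structurals at the finite bound nearest zero
    if (std::isfinite(S.hi[j]) && std::fabs(S.hi[j]) < std::fabs(S.lo[j])) {
      S.x[j] = S.hi[j];
      S.stat[j] = AT_UB;
    } else {
      S.x[j] = S.lo[j];
      S.stat[j] = AT_LB;
    }
  }

  // residuals and artificial columns
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < n; ++j) r -= A(i, j) * S.x[j];
    double s = (r >= 0) ? 1.0 : -1.0;
    for (int j = 0; j < n; ++j) S.t(i, j) = s * A(i, j);
    S.t(i, n + i) = 1.0;
    S.x[n + i] = std::fabs(r);
    S.basis[i] = n + i;
    S.stat[n + i] = BASIC;
  }

  std::vector<char> eligible(S.N, 1);
  std::vector<double> cc(S.N, 0.0);

  // phase 1: minimize sum of artificials
  for (int i = 0; i < m; ++i) cc[n + i] = -1.0;
  int st = run_phase(S, cc, eligible, maxit);
  if (st == 3) return List::create(_["status"] = 3);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += S.x[n + i];
  if (infeas > 1e-7)
    return List::create(_["status"] = 1, _["infeasibility"] = infeas);

  // phase 2: artificials pinned to zero, real objective
  for (int i = 0; i < m; ++i) {
    S.hi[n + i] = 0.0;
    S.x[n + i] = 0.0;
    eligible[n + i] = 0;
    cc[n + i] = 0.0;
  }
  for (int j = 0; j < n; ++j) cc[j] = c[j];
  st = run_phase(S, cc, eligible, maxit);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector xs(n);
  double obj = 0.0;
  for (int j = 0; j < n; ++j) {
    double v = S.x[j];
    if (v < lb[j]) v = lb[j];
    if (std::isfinite(ub[j]) && v > ub[j]) v = ub[j];
    xs[j] = v;
    obj += c[j] * v;
  }
  return List::create(_["status"] = 0, _["x"] = xs, _["objective"] = obj);
}
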