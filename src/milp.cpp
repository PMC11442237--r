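// Exact solver for the small 0/1 mixed-integer programs behind shadow-test
// assembly: a bounded-variable primal simplex (big-M start) for the LP
// relaxations, wrapped in depth-first branch and bound over the binary
// variables. Problems here are dense counting constraints over a few hundred
// variables, so a full-tableau simplex is adequate and fully deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <cstring>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum VarStatus { AT_LB = 0, AT_UB = 1, BASIC = 2 };

struct LPResult {
  int status;              // 0 optimal, 1 infeasible, 2 unbounded, 3 numerical
  double obj;
  std::vector<double> x;   // structural variables only
};

// Maximize c'x subject to A x (sense) b, lb <= x <= ub.
// sense: -1 "<=", 0 "=", +1 ">=".  All structural bounds finite.
static LPResult lp_solve(const std::vector<double>& Aflat, int m, int n,
                         const std::vector<int>& sense,
                         const std::vector<double>& b,
                         const std::vector<double>& c,
                         const std::vector<double>& lbs,
                         const std::vector<double>& ubs) {
  LPResult res;
  res.status = 3;
  res.obj = -INF;

  double cmax = 1.0, bmax = 1.0;
  for (double v : c) cmax = std::max(cmax, std::fabs(v));
  for (double v : b) bmax = std::max(bmax, std::fabs(v));
  const double bigM = 1e7 * std::max(cmax, bmax);
  const double dtol = 1e-9 * std::max(1.0, cmax);
  const double ptol = 1e-9;
  const double btol = 1e-7;

  // column layout: [0,n) structural, [n, n+m) slacks, then artificials
  int ncols = n + m;
  std::vector<double> lb(lbs), ub(ubs), cost(c);
  lb.resize(ncols); ub.resize(ncols); cost.resize(ncols, 0.0);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    if (sense[i] < 0)      { lb[j] = 0.0;  ub[j] = INF; }
    else if (sense[i] > 0) { lb[j] = -INF; ub[j] = 0.0; }
    else                   { lb[j] = 0.0;  ub[j] = 0.0; }
  }

  // initial structural point: each variable at its lower bound
  std::vector<double> resid(b);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      resid[i] -= Aflat[(size_t)i * n + j] * lb[j];

  std::vector<int> artrow;            // row of each artificial column
  std::vector<double> artsign;
  std::vector<int> basis(m);
  std::vector<double> beta(m);
  std::vector<int> vstat;             // per column
  vstat.assign(ncols, AT_LB);
  // nonbasic columns must rest at a finite bound: ">=" slacks live in
  // (-inf, 0], so their resting place is the upper bound 0
  for (int i = 0; i < m; ++i)
    if (sense[i] > 0) vstat[n + i] = AT_UB;

  for (int i = 0; i < m; ++i) {
    bool ok;
    if (sense[i] < 0)      ok = resid[i] >= -btol;
    else if (sense[i] > 0) ok = resid[i] <= btol;
    else                   ok = std::fabs(resid[i]) <= btol;
    if (ok) {
      basis[i] = n + i;
      beta[i] = resid[i];
      vstat[n + i] = BASIC;
    } else {
      artrow.push_back(i);
      artsign.push_back(resid[i] > 0 ? 1.0 : -1.0);
      basis[i] = -1;  // patched below once artificial columns are laid out
    }
  }
  int nart = (int)artrow.size();
  int tot = ncols + nart;
  lb.resize(tot, 0.0); ub.resize(tot, INF); cost.resize(tot, -bigM);
  vstat.resize(tot, AT_LB);
  for (int k = 0; k < nart; ++k) {
    int i = artrow[k];
    basis[i] = ncols + k;
    beta[i] = std::fabs(resid[i]);
    vstat[ncols + k] = BASIC;
  }

  // tableau T = B^{-1} [A | I | Art]; initial basis is diagonal +-1
  std::vector<double> T((size_t)m * tot, 0.0);
  for (int i = 0; i < m; ++i) {
    double s = 1.0;
    // row sign flips when its basic artificial has coefficient -1
    for (int k = 0; k < nart; ++k)
      if (artrow[k] == i && artsign[k] < 0) s = -1.0;
    double* row = &T[(size_t)i * tot];
    for (int j = 0; j < n; ++j) row[j] = s * Aflat[(size_t)i * n + j];
    row[n + i] = s;
  }
  for (int k = 0; k < nart; ++k)
    T[(size_t)artrow[k] * tot + (ncols + k)] = 1.0;

  // reduced costs d = cost - cost_B' T
  std::vector<double> d(cost);
  for (int i = 0; i < m; ++i) {
    double cb = cost[basis[i]];
    if (cb != 0.0) {
      const double* row = &T[(size_t)i * tot];
      for (int j = 0; j < tot; ++j) d[j] -= cb * row[j];
    }
  }

  std::vector<char> is_art(tot, 0);
  for (int k = 0; k < nart; ++k) is_art[ncols + k] = 1;

  const long maxit = 20000L + 60L * (m + tot);
  long stall = 0;
  bool bland = false;
  double zprev = -INF;

  for (long it = 0; it < maxit; ++it) {
    // entering variable
    int jin = -1;
    double best = dtol;
    for (int j = 0; j < tot; ++j) {
      if (vstat[j] == BASIC) continue;
      if (is_art[j] && vstat[j] != BASIC) continue;     // never re-enter
      if (ub[j] - lb[j] < ptol) continue;                // fixed
      double score = (vstat[j] == AT_LB) ? d[j] : -d[j];
      if (score > best) {
        if (bland) { jin = j; break; }
        best = score; jin = j;
      }
    }
    if (jin < 0) { // optimal
      std::vector<double> x(n);
      for (int j = 0; j < n; ++j)
        x[j] = (vstat[j] == AT_UB) ? ub[j] : lb[j];
      for (int i = 0; i < m; ++i)
        if (basis[i] < n) x[basis[i]] = beta[i];
      // artificial residual => infeasible
      for (int i = 0; i < m; ++i)
        if (is_art[basis[i]] && std::fabs(beta[i]) > 1e-6) {
          res.status = 1; return res;
        }
      double z = 0.0;
      for (int j = 0; j < n; ++j) z += c[j] * x[j];
      res.status = 0; res.obj = z; res.x = x;
      return res;
    }

    double sigma = (vstat[jin] == AT_LB) ? 1.0 : -1.0;
    double tmax = ub[jin] - lb[jin];          // bound-flip limit (may be INF)
    int leave = -1;
    double pivbest = 0.0;
    for (int i = 0; i < m; ++i) {
      double alpha = sigma * T[(size_t)i * tot + jin];
      double bound;
      if (alpha > ptol)       bound = (beta[i] - lb[basis[i]]) / alpha;
      else if (alpha < -ptol) bound = (ub[basis[i]] - beta[i]) / (-alpha);
      else continue;
      if (bound < -1e-9) bound = 0.0;
      if (bound < tmax - 1e-10 ||
          (bound < tmax + 1e-10 && leave >= 0 &&
           std::fabs(alpha) > pivbest + 1e-12)) {
        tmax = bound; leave = i; pivbest = std::fabs(alpha);
      }
    }
    if (leave < 0 && !std::isfinite(tmax)) { res.status = 2; return res; }
    if (tmax < 0) tmax = 0.0;

    for (int i = 0; i < m; ++i)
      beta[i] -= sigma * tmax * T[(size_t)i * tot + jin];

    if (leave < 0) {                           // bound flip
      vstat[jin] = (vstat[jin] == AT_LB) ? AT_UB : AT_LB;
    } else {
      int jout = basis[leave];
      double enter_val = ((sigma > 0) ? lb[jin] : ub[jin]) + sigma * tmax;
      double alpha = sigma * T[(size_t)leave * tot + jin];
      vstat[jout] = (alpha > 0) ? AT_LB : AT_UB;
      beta[leave] = enter_val;
      basis[leave] = jin;
      vstat[jin] = BASIC;

      double p = T[(size_t)leave * tot + jin];
      double* prow = &T[(size_t)leave * tot];
      double invp = 1.0 / p;
      for (int j = 0; j < tot; ++j) prow[j] *= invp;
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        double f = T[(size_t)i * tot + jin];
        if (f != 0.0) {
          double* row = &T[(size_t)i * tot];
          for (int j = 0; j < tot; ++j) row[j] -= f * prow[j];
          row[jin] = 0.0;                      // kill roundoff
        }
      }
      double f = d[jin];
      if (f != 0.0) {
        for (int j = 0; j < tot; ++j) d[j] -= f * prow[j];
        d[jin] = 0.0;
      }
    }

    // stall / cycling guard
    double z = 0.0;
    for (int i = 0; i < m; ++i) if (basis[i] < n) z += c[basis[i]] * beta[i];
    if (z > zprev + 1e-11) { zprev = z; stall = 0; if (bland) bland = false; }
    else if (++stall > 2L * (m + tot)) bland = true;
  }
  res.status = 3;
  return res;
}

struct BBState {
  const std::vector<double>* A;
  int m, n;
  const std::vector<int>* sense;
  const std::vector<double>* b;
  const std::vector<double>* c;
  const std::vector<bool>* integer;
  std::vector<double> lb, ub;
  std::vector<double> bestx;
  double bestobj;
  bool have_incumbent;
  long nodes, node_limit;
  double t_end;
  bool limit_hit;
  int lp_fail;
  double int_tol, gap;
};

static double now_sec() {
  return (double)clock() / CLOCKS_PER_SEC;
}

static void bb_rec(BBState& S) {
  if (S.limit_hit) return;
  if (++S.nodes > S.node_limit || now_sec() > S.t_end) {
    S.limit_hit = true;
    return;
  }
  LPResult lp = lp_solve(*S.A, S.m, S.n, *S.sense, *S.b, *S.c, S.lb, S.ub);
  if (lp.status == 1) return;                  // infeasible node
  if (lp.status != 0) { S.lp_fail++; return; }
  if (S.have_incumbent && lp.obj <= S.bestobj + S.gap) return;

  // branch on the integer variable whose fraction is closest to one half
  int jb = -1;
  double bdist = 1.0;
  for (int j = 0; j < S.n; ++j) {
    if (!(*S.integer)[j]) continue;
    double fr = lp.x[j] - std::floor(lp.x[j]);
    if (fr > S.int_tol && fr < 1.0 - S.int_tol) {
      double dist = std::fabs(fr - 0.5);
      if (jb < 0 || dist < bdist - 1e-12) { jb = j; bdist = dist; }
    }
  }
  if (jb < 0) {                                // integral solution
    if (!S.have_incumbent || lp.obj > S.bestobj + 1e-9) {
      S.bestobj = lp.obj;
      S.bestx = lp.x;
      for (int j = 0; j < S.n; ++j)
        if ((*S.integer)[j]) S.bestx[j] = std::floor(S.bestx[j] + 0.5);
      S.have_incumbent = true;
    }
    return;
  }
  double v = lp.x[jb];
  double fl = std::floor(v), cl = fl + 1.0;
  double savelb = S.lb[jb], saveub = S.ub[jb];
  bool up_first = (v - fl) >= 0.5;
  for (int pass = 0; pass < 2; ++pass) {
    bool up = (pass == 0) ? up_first : !up_first;
    if (up) { S.lb[jb] = cl; S.ub[jb] = saveub; }
    else    { S.lb[jb] = savelb; S.ub[jb] = fl; }
    if (S.lb[jb] <= S.ub[jb] + 1e-12) bb_rec(S);
    S.lb[jb] = savelb; S.ub[jb] = saveub;
    if (S.limit_hit) return;
  }
}

// [[Rcpp::export]]
List milp_solve_cpp(NumericMatrix A, IntegerVector sense, NumericVector b,
                    NumericVector obj, LogicalVector integer,
                    NumericVector lb, NumericVector ub,
                    Nullable<NumericVector> warm_start = R_NilValue,
                    double time_limit = 5.0, double node_limit = 2e5) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> Af((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      Af[(size_t)i * n + j] = A(i, j);
  std::vector<int> sv(sense.begin(), sense.end());
  std::vector<double> bv(b.begin(), b.end()), cv(obj.begin(), obj.end());
  std::vector<bool> iv(integer.begin(), integer.end());

  BBState S;
  S.A = &Af; S.m = m; S.n = n; S.sense = &sv; S.b = &bv; S.c = &cv;
  S.integer = &iv;
  S.lb.assign(lb.begin(), lb.end());
  S.ub.assign(ub.begin(), ub.end());
  S.bestobj = -INF;
  S.have_incumbent = false;
  S.nodes = 0;
  S.node_limit = (long)node_limit;
  S.t_end = now_sec() + time_limit;
  S.limit_hit = false;
  S.lp_fail = 0;
  S.int_tol = 1e-6;
  S.gap = 1e-7;

  if (warm_start.isNotNull()) {
    NumericVector w(warm_start);
    if ((int)w.size() == n) {
      // accept only if feasible for all rows and bounds
      bool ok = true;
      for (int j = 0; j < n && ok; ++j)
        if (w[j] < S.lb[j] - 1e-9 || w[j] > S.ub[j] + 1e-9) ok = false;
      for (int i = 0; i < m && ok; ++i) {
        double lhs = 0.0;
        for (int j = 0; j < n; ++j) lhs += Af[(size_t)i * n + j] * w[j];
        if (sv[i] < 0 && lhs > bv[i] + 1e-7) ok = false;
        if (sv[i] > 0 && lhs < bv[i] - 1e-7) ok = false;
        if (sv[i] == 0 && std::fabs(lhs - bv[i]) > 1e-7) ok = false;
      }
      if (ok) {
        double z = 0.0;
        for (int j = 0; j < n; ++j) z += cv[j] * w[j];
        S.bestobj = z;
        S.bestx.assign(w.begin(), w.end());
        S.have_incumbent = true;
      }
    }
  }

  bb_rec(S);

  std::string status;
  if (S.lp_fail > 0 && !S.have_incumbent) status = "numerical";
  else if (S.limit_hit) status = S.have_incumbent ? "feasible_timeout"
                                                  : "timeout";
  else status = S.have_incumbent ? "optimal" : "infeasible";

  NumericVector x(n);
  double z = NA_REAL;
  if (S.have_incumbent) {
    for (int j = 0; j < n; ++j) x[j] = S.bestx[j];
    z = S.bestobj;
  }
  return List::create(_["status"] = status, _["x"] = x,
                      _["objective"] = z, _["nodes"] = (double)S.nodes);
}

// [[Rcpp::export]]
List lp_solve_cpp(NumericMatrix A, IntegerVector sense, NumericVector b,
                  NumericVector obj, NumericVector lb, NumericVector ub) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> Af((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      Af[(size_t)i * n + j] = A(i, j);
  std::vector<int> sv(sense.begin(), sense.end());
  std::vector<double> bv(b.begin(), b.end()), cv(obj.begin(), obj.end());
  std::vector<double> l(lb.begin(), lb.end()), u(ub.begin(), ub.end());
  LPResult r = lp_solve(Af, m, n, sv, bv, cv, l, u);
  NumericVector x(n);
  if (r.status == 0) for (int j = 0; j < n; ++j) x[j] = r.x[j];
  return List::create(_["status"] = r.status, _["x"] = x,
                      _["objective"] = r.status == 0 ? r.obj : NA_REAL);
}
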