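// Dense bounded-variable two-phase primal simplex with branch-and-bound.
// Sized for toy metabolic networks (tens of reactions); all arithmetic is
// dense double precision with explicit tolerances.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

const double INF = 1e30;
const double TOL_PIV = 1e-9;    // smallest usable pivot element
const double TOL_DJ = 1e-9;     // reduced-cost optimality tolerance
const double TOL_FEAS = 1e-7;   // phase-1 feasibility tolerance
const double TOL_INT = 1e-6;    // integrality tolerance for binaries

enum VStat { BASIC = 0, AT_LOWER = 1, AT_UPPER = 2, NB_FREE = 3 };

struct LP {
  int m;                 // rows (all equalities after slack augmentation)
  int n;                 // structural variables
  int nslack;
  int ntot;              // n + nslack + m artificials
  std::vector<double> T; // m x ntot tableau, row-major
  std::vector<double> z; // reduced-cost row, length ntot
  std::vector<double> xB;
  std::vector<int> basis;
  std::vector<int> vstat;
  std::vector<double> lo, hi;   // length ntot
  std::vector<char> allowed;    // may enter the basis
  std::vector<char> rowActive;  // false for redundant rows
  int status;                   // 0 opt, 1 infeasible, 2 unbounded, 3 iterlimit

  inline double &at(int i, int j) { return T[(size_t)i * ntot + j]; }

  double nbval(int j) const {
    if (vstat[j] == AT_LOWER) return lo[j];
    if (vstat[j] == AT_UPPER) return hi[j];
    return 0.0; // free nonbasic
  }

  // one simplex phase: minimize cost whose reduced costs are in z
  // (z maintained by pivoting); returns 0 opt, 2 unbounded, 3 iterlimit
  int iterate() {
    const int maxit = 20000 + 100 * (m + n);
    int degen = 0;
    bool bland = false;
    for (int it = 0; it < maxit; ++it) {
      // entering variable
      int q = -1, dir = 0;
      double best = TOL_DJ;
      for (int j = 0; j < ntot; ++j) {
        if (vstat[j] == BASIC || !allowed[j]) continue;
        double dj = z[j];
        int d = 0;
        if ((vstat[j] == AT_LOWER || vstat[j] == NB_FREE) && dj < -TOL_DJ) d = 1;
        else if ((vstat[j] == AT_UPPER || vstat[j] == NB_FREE) && dj > TOL_DJ) d = -1;
        if (!d) continue;
        if (bland) { q = j; dir = d; break; }
        if (std::fabs(dj) > best) { best = std::fabs(dj); q = j; dir = d; }
      }
      if (q < 0) return 0; // optimal

      // ratio test
      double tmax = (lo[q] > -INF / 2 && hi[q] < INF / 2) ? hi[q] - lo[q] : INF;
      double tbest = tmax;
      int r = -1;
      double rpiv = 0.0;
      for (int i = 0; i < m; ++i) {
        if (!rowActive[i]) continue;
        double a = dir * at(i, q);
        double ti;
        if (a > TOL_PIV) {
          double l = lo[basis[i]];
          if (l < -INF / 2) continue;
          ti = (xB[i] - l) / a;
        } else if (a < -TOL_PIV) {
          double u = hi[basis[i]];
          if (u > INF / 2) continue;
          ti = (u - xB[i]) / (-a);
        } else continue;
        if (ti < 0) ti = 0;
        if (ti < tbest - 1e-12 ||
            (ti < tbest + 1e-12 && r >= 0 &&
             std::fabs(at(i, q)) > std::fabs(rpiv) + 1e-12)) {
          tbest = ti; r = i; rpiv = at(i, q);
        } else if (r < 0 && ti <= tbest + 1e-12) {
          tbest = std::min(tbest, ti); r = i; rpiv = at(i, q);
        }
      }

      if (r < 0 && tbest >= INF / 2) return 2; // unbounded

      if (tbest < 1e-11) { if (++degen > 200) bland = true; }
      else { degen = 0; bland = false; }

      if (r < 0 || (tmax < tbest - 1e-12 && tmax < INF / 2)) {
        // bound flip of entering variable
        double t = tmax;
        for (int i = 0; i < m; ++i) {
          if (!rowActive[i]) continue;
          xB[i] -= dir * at(i, q) * t;
        }
        vstat[q] = (vstat[q] == AT_LOWER) ? AT_UPPER : AT_LOWER;
        continue;
      }

      // pivot on (r, q)
      double t = tbest;
      double enterval = nbval(q) + dir * t;
      for (int i = 0; i < m; ++i) {
        if (i == r || !rowActive[i]) continue;
        xB[i] -= dir * at(i, q) * t;
      }
      int leave = basis[r];
      vstat[leave] = (dir * at(r, q) > 0) ? AT_LOWER : AT_UPPER;
      if (lo[leave] < -INF / 2 && hi[leave] > INF / 2) vstat[leave] = NB_FREE;
      pivot(r, q);
      basis[r] = q;
      vstat[q] = BASIC;
      xB[r] = enterval;
    }
    return 3;
  }

  void pivot(int r, int q) {
    double p = at(r, q);
    double *rowr = &T[(size_t)r * ntot];
    double invp = 1.0 / p;
    for (int j = 0; j < ntot; ++j) rowr[j] *= invp;
    rowr[q] = 1.0;
    for (int i = 0; i < m; ++i) {
      if (i == r) continue;
      double f = at(i, q);
      if (std::fabs(f) < 1e-13) { at(i, q) = 0.0; continue; }
      double *rowi = &T[(size_t)i * ntot];
      for (int j = 0; j < ntot; ++j) rowi[j] -= f * rowr[j];
      rowi[q] = 0.0;
    }
    double fz = z[q];
    if (std::fabs(fz) > 1e-13) {
      for (int j = 0; j < ntot; ++j) z[j] -= fz * rowr[j];
      z[q] = 0.0;
    }
  }

  void set_costs(const std::vector<double> &c) {
    // z_j = c_j - c_B' T[,j], computed fresh
    std::vector<double> cB(m, 0.0);
    bool any = false;
    for (int i = 0; i < m; ++i) {
      cB[i] = (basis[i] < (int)c.size()) ? c[basis[i]] : 0.0;
      if (cB[i] != 0.0) any = true;
    }
    for (int j = 0; j < ntot; ++j) z[j] = (j < (int)c.size()) ? c[j] : 0.0;
    if (any) {
      for (int i = 0; i < m; ++i) {
        if (cB[i] == 0.0) continue;
        const double *rowi = &T[(size_t)i * ntot];
        for (int j = 0; j < ntot; ++j) z[j] -= cB[i] * rowi[j];
      }
    }
    for (int i = 0; i < m; ++i) z[basis[i]] = 0.0;
  }
};

// minimize c'x over  A x (sense) b,  lo <= x <= hi
// sense: -1 "<=", 0 "=", 1 ">="
int solve_lp_core(const std::vector<double> &c,
                  const std::vector<double> &Adense, int m, int n,
                  const std::vector<int> &sense,
                  const std::vector<double> &b,
                  const std::vector<double> &xlo,
                  const std::vector<double> &xhi,
                  std::vector<double> &xout, double &objout) {
  LP lp;
  lp.m = m; lp.n = n;
  lp.nslack = 0;
  for (int i = 0; i < m; ++i) if (sense[i] != 0) ++lp.nslack;
  lp.ntot = n + lp.nslack + m;
  lp.T.assign((size_t)m * lp.ntot, 0.0);
  lp.z.assign(lp.ntot, 0.0);
  lp.xB.assign(m, 0.0);
  lp.basis.assign(m, 0);
  lp.vstat.assign(lp.ntot, AT_LOWER);
  lp.lo.assign(lp.ntot, 0.0);
  lp.hi.assign(lp.ntot, INF);
  lp.allowed.assign(lp.ntot, 1);
  lp.rowActive.assign(m, 1);

  for (int j = 0; j < n; ++j) { lp.lo[j] = xlo[j]; lp.hi[j] = xhi[j]; }

  // structural columns
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      lp.at(i, j) = Adense[(size_t)i * n + j];
  // slack columns
  int sj = n;
  for (int i = 0; i < m; ++i) {
    if (sense[i] == -1) lp.at(i, sj++) = 1.0;
    else if (sense[i] == 1) lp.at(i, sj++) = -1.0;
  }
  // nonbasic statuses for structurals/slacks
  for (int j = 0; j < n + lp.nslack; ++j) {
    if (lp.lo[j] > -INF / 2) lp.vstat[j] = AT_LOWER;
    else if (lp.hi[j] < INF / 2) lp.vstat[j] = AT_UPPER;
    else lp.vstat[j] = NB_FREE;
  }
  // residuals and artificial basis
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    const double *rowi = &lp.T[(size_t)i * lp.ntot];
    for (int j = 0; j < n + lp.nslack; ++j) {
      if (rowi[j] != 0.0) r -= rowi[j] * lp.nbval(j);
    }
    if (r < 0) { // negate row so the artificial is nonnegative
      double *wi = &lp.T[(size_t)i * lp.ntot];
      for (int j = 0; j < n + lp.nslack; ++j) wi[j] = -wi[j];
      r = -r;
      // note: b is conceptually negated too; not stored
    }
    int aj = n + lp.nslack + i;
    lp.at(i, aj) = 1.0;
    lp.basis[i] = aj;
    lp.vstat[aj] = BASIC;
    lp.xB[i] = r;
  }

  // phase 1: minimize sum of artificials
  std::vector<double> c1(lp.ntot, 0.0);
  for (int i = 0; i < m; ++i) c1[n + lp.nslack + i] = 1.0;
  lp.set_costs(c1);
  int st = lp.iterate();
  if (st == 3) return 3;
  double p1 = 0.0;
  for (int i = 0; i < m; ++i)
    if (lp.basis[i] >= n + lp.nslack) p1 += lp.xB[i];
  if (p1 > TOL_FEAS) return 1; // infeasible

  // drive artificials out of the basis or deactivate redundant rows
  for (int i = 0; i < m; ++i) {
    if (lp.basis[i] < n + lp.nslack) continue;
    int q = -1;
    for (int j = 0; j < n + lp.nslack; ++j)
      if (std::fabs(lp.at(i, j)) > 1e-7) { q = j; break; }
    if (q < 0) { lp.rowActive[i] = 0; continue; }
    double val = lp.nbval(q);
    int art = lp.basis[i];
    lp.vstat[art] = AT_LOWER;
    lp.pivot(i, q);
    lp.basis[i] = q;
    lp.vstat[q] = BASIC;
    lp.xB[i] = val;
  }
  for (int i = 0; i < m; ++i) lp.allowed[n + lp.nslack + i] = 0;

  // phase 2
  std::vector<double> c2(lp.ntot, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = c[j];
  lp.set_costs(c2);
  st = lp.iterate();
  if (st != 0) return st;

  xout.assign(n, 0.0);
  std::vector<double> full(lp.ntot, 0.0);
  for (int j = 0; j < lp.ntot; ++j)
    if (lp.vstat[j] != BASIC) full[j] = lp.nbval(j);
  for (int i = 0; i < m; ++i) full[lp.basis[i]] = lp.xB[i];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) { xout[j] = full[j]; obj += c[j] * full[j]; }
  objout = obj;
  return 0;
}

struct BBState {
  const std::vector<double> *c; // maximize
  const std::vector<double> *A;
  int m, n;
  const std::vector<int> *sense;
  const std::vector<double> *b;
  std::vector<int> intvars;
  bool obj_integral;
  long node_limit, nodes;
  bool have_inc;
  double bestobj;
  std::vector<double> bestx;
  bool aborted;
};

void bb_rec(BBState &S, std::vector<double> lo, std::vector<double> hi) {
  if (S.aborted) return;
  if (++S.nodes > S.node_limit) { S.aborted = true; return; }
  std::vector<double> cneg(S.n);
  for (int j = 0; j < S.n; ++j) cneg[j] = -(*S.c)[j];
  std::vector<double> x; double obj;
  int st = solve_lp_core(cneg, *S.A, S.m, S.n, *S.sense, *S.b, lo, hi, x, obj);
  if (st == 1) return;           // infeasible node
  if (st != 0) { S.aborted = true; return; }
  double zmax = -obj;
  if (S.have_inc) {
    if (S.obj_integral) {
      if (std::floor(zmax + 1e-6) <= std::llround(S.bestobj)) return;
    } else if (zmax <= S.bestobj + 1e-9) return;
  }
  // find most fractional integer variable
  int bj = -1; double bfrac = TOL_INT;
  for (size_t k = 0; k < S.intvars.size(); ++k) {
    int j = S.intvars[k];
    double f = std::fabs(x[j] - std::floor(x[j] + 0.5));
    if (f > bfrac) { bfrac = f; bj = j; }
  }
  if (bj < 0) {
    double zi = S.obj_integral ? std::llround(zmax) : zmax;
    if (!S.have_inc || zi > S.bestobj + 1e-12) {
      S.have_inc = true; S.bestobj = zi; S.bestx = x;
    }
    return;
  }
  double first = (x[bj] >= 0.5) ? std::ceil(x[bj] - 0.5) : std::floor(x[bj] + 0.5);
  // binaries: branch value nearest the relaxation first
  for (int pass = 0; pass < 2; ++pass) {
    double v = pass == 0 ? first : (first > 0.5 ? 0.0 : 1.0);
    if (v < lo[bj] - 1e-9 || v > hi[bj] + 1e-9) continue;
    std::vector<double> lo2 = lo, hi2 = hi;
    lo2[bj] = v; hi2[bj] = v;
    bb_rec(S, lo2, hi2);
    if (S.aborted) return;
  }
}

std::vector<double> as_vec(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

} // namespace

// [[Rcpp::export(name = ".cpp_solve_lp")]]
List cpp_solve_lp(NumericVector obj, NumericMatrix mat, IntegerVector sense,
                  NumericVector rhs, NumericVector lower, NumericVector upper,
                  bool maximize) {
  int m = mat.nrow(), n = mat.ncol();
  std::vector<double> A((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = mat(i, j);
  std::vector<double> c = as_vec(obj);
  if (maximize) for (int j = 0; j < n; ++j) c[j] = -c[j];
  std::vector<double> lo = as_vec(lower), hi = as_vec(upper);
  for (int j = 0; j < n; ++j) {
    if (!R_finite(lo[j])) lo[j] = -INF;
    if (!R_finite(hi[j])) hi[j] = INF;
  }
  std::vector<int> sn(sense.begin(), sense.end());
  std::vector<double> bb = as_vec(rhs);
  std::vector<double> x; double val = NA_REAL;
  int st = solve_lp_core(c, A, m, n, sn, bb, lo, hi, x, val);
  NumericVector xout(n, NA_REAL);
  if (st == 0) {
    for (int j = 0; j < n; ++j) xout[j] = x[j];
    if (maximize) val = -val;
  }
  return List::create(_["status"] = st, _["x"] = xout, _["objval"] = val);
}

// [[Rcpp::export(name = ".cpp_solve_milp")]]
List cpp_solve_milp(NumericVector obj, NumericMatrix mat, IntegerVector sense,
                    NumericVector rhs, NumericVector lower, NumericVector upper,
                    IntegerVector int_vars, bool maximize, bool obj_integral,
                    double node_limit) {
  int m = mat.nrow(), n = mat.ncol();
  std::vector<double> A((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = mat(i, j);
  std::vector<double> c = as_vec(obj);
  if (maximize) { /* internal is maximize */ } else {
    for (int j = 0; j < n; ++j) c[j] = -c[j];
  }
  std::vector<double> lo = as_vec(lower), hi = as_vec(upper);
  for (int j = 0; j < n; ++j) {
    if (!R_finite(lo[j])) lo[j] = -INF;
    if (!R_finite(hi[j])) hi[j] = INF;
  }
  std::vector<int> sn(sense.begin(), sense.end());
  std::vector<double> bb = as_vec(rhs);

  BBState S;
  S.c = &c; S.A = &A; S.m = m; S.n = n; S.sense = &sn; S.b = &bb;
  S.intvars.assign(int_vars.begin(), int_vars.end()); // 0-based
  S.obj_integral = obj_integral;
  S.node_limit = (long)node_limit; S.nodes = 0;
  S.have_inc = false; S.bestobj = -std::numeric_limits<double>::infinity();
  S.aborted = false;
  bb_rec(S, lo, hi);

  int st;
  if (S.aborted) st = S.have_inc ? 4 : 5;
  else st = S.have_inc ? 0 : 1;
  NumericVector xout(n, NA_REAL);
  double val = NA_REAL;
  if (S.have_inc) {
    for (int j = 0; j < n; ++j) xout[j] = S.bestx[j];
    val = maximize ? S.bestobj : -S.bestobj;
  }
  return List::create(_["status"] = st, _["x"] = xout, _["objval"] = val,
                      _["nodes"] = (double)S.nodes);
}
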