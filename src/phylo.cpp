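// Felsenstein pruning log-likelihood for a GTR(+Gamma) nucleotide model and
// coordinate-ascent branch-length optimization (Brent per branch).
// Alignments arrive pattern-compressed; trees arrive as postorder edge lists
// (ape convention, 1-based node ids, root = nTip + 1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// P(t) = U diag(exp(vals * t)) Uinv, row-major 4x4.
static void pmat(const double* U, const double* Ui, const double* ev,
                 double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(ev[k] * t);
  for (int x = 0; x < 4; ++x) {
    for (int y = 0; y < 4; ++y) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += U[x + 4 * k] * e[k] * Ui[k + 4 * y];
      P[4 * x + y] = s > 0.0 ? s : 0.0;
    }
  }
}

struct TreeLik {
  // plain buffers (copied from the R objects once; the optimizer hot loop
  // re-evaluates the likelihood thousands of times)
  std::vector<int> states;       // nPat x nTip, tip-major per pattern
  std::vector<double> weights;
  std::vector<int> epar, echild;
  int nTip, nNode, nPat, nEdge, root;
  double U[16], Ui[16], vals[4], pi[4];
  std::vector<double> rates, ratew;
  std::vector<double> partial;   // nNode * 4 * nPat, one category at a time
  std::vector<double> sitelik;   // accumulated over categories

  TreeLik(const IntegerMatrix& states_, const NumericVector& weights_,
          const IntegerMatrix& edge_, int nTip_, const NumericMatrix& U_,
          const NumericMatrix& Ui_, const NumericVector& vals_,
          const NumericVector& pi_, const NumericVector& rates_,
          const NumericVector& ratew_)
    : nTip(nTip_) {
    nPat = states_.ncol();
    nEdge = edge_.nrow();
    states.resize((size_t)nTip * nPat);
    for (int r = 0; r < nTip; ++r)
      for (int s = 0; s < nPat; ++s) states[(size_t)r * nPat + s] = states_(r, s);
    weights.assign(weights_.begin(), weights_.end());
    epar.resize(nEdge); echild.resize(nEdge);
    int mx = nTip;
    for (int i = 0; i < nEdge; ++i) {
      epar[i] = edge_(i, 0); echild[i] = edge_(i, 1);
      if (epar[i] > mx) mx = epar[i];
      if (echild[i] > mx) mx = echild[i];
    }
    nNode = mx;
    root = nTip + 1;
    for (int k = 0; k < 16; ++k) { U[k] = U_[k]; Ui[k] = Ui_[k]; }
    for (int k = 0; k < 4; ++k) { vals[k] = vals_[k]; pi[k] = pi_[k]; }
    rates.assign(rates_.begin(), rates_.end());
    ratew.assign(ratew_.begin(), ratew_.end());
    partial.assign((size_t)nNode * 4 * nPat, 1.0);
    sitelik.assign(nPat, 0.0);
  }

  double loglik(const double* blen) {
    std::fill(sitelik.begin(), sitelik.end(), 0.0);
    int nCat = rates.size();
    std::vector<double> P(16);
    for (int c = 0; c < nCat; ++c) {
      // reset internal partials to 1; tips set inline
      for (int n = nTip; n < nNode; ++n)
        std::fill(partial.begin() + (size_t)n * 4 * nPat,
                  partial.begin() + (size_t)(n + 1) * 4 * nPat, 1.0);
      for (int i = 0; i < nEdge; ++i) {
        int par = epar[i] - 1, ch = echild[i] - 1;
        pmat(U, Ui, vals, blen[i] * rates[c], &P[0]);
        double* pp = &partial[(size_t)par * 4 * nPat];
        if (ch < nTip) {
          const int* strow = &states[(size_t)ch * nPat];
          for (int s = 0; s < nPat; ++s) {
            int st = strow[s];
            if (st < 0) continue;  // missing: factor 1
            for (int x = 0; x < 4; ++x) pp[4 * s + x] *= P[4 * x + st];
          }
        } else {
          const double* cp = &partial[(size_t)ch * 4 * nPat];
          for (int s = 0; s < nPat; ++s) {
            for (int x = 0; x < 4; ++x) {
              double f = P[4 * x + 0] * cp[4 * s + 0] +
                         P[4 * x + 1] * cp[4 * s + 1] +
                         P[4 * x + 2] * cp[4 * s + 2] +
                         P[4 * x + 3] * cp[4 * s + 3];
              pp[4 * s + x] *= f;
            }
          }
        }
      }
      const double* rp = &partial[(size_t)(root - 1) * 4 * nPat];
      for (int s = 0; s < nPat; ++s) {
        double L = pi[0] * rp[4 * s + 0] + pi[1] * rp[4 * s + 1] +
                   pi[2] * rp[4 * s + 2] + pi[3] * rp[4 * s + 3];
        sitelik[s] += ratew[c] * L;
      }
    }
    double ll = 0.0;
    for (int s = 0; s < nPat; ++s) {
      double L = sitelik[s];
      ll += weights[s] * std::log(L > 1e-300 ? L : 1e-300);
    }
    return ll;
  }
};

// [[Rcpp::export]]
double cpp_gtr_loglik(IntegerMatrix states, NumericVector weights,
                      IntegerMatrix edge, int nTip, NumericVector blen,
                      NumericMatrix U, NumericMatrix Ui, NumericVector vals,
                      NumericVector pi, NumericVector rates,
                      NumericVector ratew) {
  TreeLik tl(states, weights, edge, nTip, U, Ui, vals, pi, rates, ratew);
  std::vector<double> b(blen.begin(), blen.end());
  return tl.loglik(b.data());
}

// Brent maximization of f over [lo, hi] (golden section + parabolic steps).
template <typename F>
static double brent_max(F f, double lo, double hi, double tol, double* fbest) {
  const double gr = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gr * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 60; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol, tol2 = 2 * tol1;  // absolute tol (x is a log-length)
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gr * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fbest = fx;
  return x;
}

// [[Rcpp::export]]
List cpp_optimize_blens(IntegerMatrix states, NumericVector weights,
                        IntegerMatrix edge, int nTip, NumericVector blen0,
                        NumericMatrix U, NumericMatrix Ui, NumericVector vals,
                        NumericVector pi, NumericVector rates,
                        NumericVector ratew, double tol = 1e-6,
                        int max_pass = 5, double min_blen = 1e-8,
                        double max_blen = 5.0, double brent_tol = 1e-4) {
  TreeLik tl(states, weights, edge, nTip, U, Ui, vals, pi, rates, ratew);
  std::vector<double> blen(blen0.begin(), blen0.end());
  int nEdge = edge.nrow();
  double cur = tl.loglik(blen.data());
  int pass = 0;
  double llo = std::log(min_blen), lhi = std::log(max_blen);
  for (pass = 0; pass < max_pass; ++pass) {
    double before = cur;
    for (int i = 0; i < nEdge; ++i) {
      double old = blen[i];
      double fbest;
      auto f = [&](double lx) {
        blen[i] = std::exp(lx);
        return tl.loglik(blen.data());
      };
      double best = brent_max(f, llo, lhi, brent_tol, &fbest);
      if (fbest >= cur) {
        blen[i] = std::exp(best);
        cur = fbest;
      } else {  // numerical noise: keep the previous length
        blen[i] = old;
        cur = tl.loglik(blen.data());
      }
    }
    if (cur - before < tol) break;
  }
  return List::create(_["blen"] = NumericVector(blen.begin(), blen.end()),
                      _["logL"] = cur, _["passes"] = pass + 1);
}
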