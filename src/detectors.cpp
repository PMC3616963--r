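// Permutation cores for the intragenic recombination detectors: pairwise
// site compatibility (Phi / NSS), MaxChi breakpoint chi-square scans, and
// the GENECONV-style maximal-segment scan over polymorphic columns.
// Permutations draw from R's RNG so R-level seeds govern reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

static void rand_perm(std::vector<int>& idx) {
  int n = idx.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Pairwise incompatibility (Estabrook-McMorris) of alignment columns.
// Two characters are compatible iff the bipartite graph of observed state
// combinations is acyclic (edges <= vertices - components).
// [[Rcpp::export]]
NumericMatrix cpp_incompat_matrix(IntegerMatrix states) {
  int n = states.nrow(), s = states.ncol();
  NumericMatrix M(s, s);
  std::vector<int> combo(n);
  for (int i = 0; i < s; ++i) {
    for (int j = i + 1; j < s; ++j) {
      // collect distinct combos over rows with both states observed
      std::vector<int> ai, aj;
      std::vector<long> combos;
      for (int r = 0; r < n; ++r) {
        int x = states(r, i), y = states(r, j);
        if (x < 0 || y < 0) continue;
        combos.push_back((long)x * 64 + y);
      }
      std::sort(combos.begin(), combos.end());
      combos.erase(std::unique(combos.begin(), combos.end()), combos.end());
      // vertices: distinct states on each side
      std::vector<int> sx, sy;
      for (size_t k = 0; k < combos.size(); ++k) {
        sx.push_back((int)(combos[k] / 64));
        sy.push_back((int)(combos[k] % 64));
      }
      std::vector<int> ux(sx), uy(sy);
      std::sort(ux.begin(), ux.end());
      ux.erase(std::unique(ux.begin(), ux.end()), ux.end());
      std::sort(uy.begin(), uy.end());
      uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
      int V = ux.size() + uy.size();
      int E = combos.size();
      // components via union-find
      std::vector<int> parent(V);
      for (int v = 0; v < V; ++v) parent[v] = v;
      std::function<int(int)> find = [&](int v) {
        while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
        return v;
      };
      for (int k = 0; k < E; ++k) {
        int a = std::lower_bound(ux.begin(), ux.end(), sx[k]) - ux.begin();
        int b = (int)ux.size() +
                (std::lower_bound(uy.begin(), uy.end(), sy[k]) - uy.begin());
        int ra = find(a), rb = find(b);
        if (ra != rb) parent[ra] = rb;
      }
      int C = 0;
      for (int v = 0; v < V; ++v) if (find(v) == v) ++C;
      M(i, j) = M(j, i) = (E > V - C) ? 1.0 : 0.0;
    }
  }
  return M;
}

// mean incompatibility over informative-site pairs whose original
// alignment positions lie within `window` bp; `ord` assigns site contents
// to the fixed position list (identity = observed data).
static double banded_mean(const NumericMatrix& M, const std::vector<int>& ord,
                          const IntegerVector& pos, int window) {
  int s = ord.size();
  double sum = 0.0;
  long cnt = 0;
  for (int i = 0; i < s; ++i) {
    for (int j = i + 1; j < s && pos[j] - pos[i] <= window; ++j) {
      sum += M(ord[i], ord[j]);
      ++cnt;
    }
  }
  return cnt ? sum / cnt : 0.0;
}

// Phi: mean pairwise incompatibility of informative sites within a window
// (bp of the original alignment); recombination depresses it, so
// p = P(perm <= observed). The permutation shuffles which site content sits
// at which position, as in PhiPack.
// [[Rcpp::export]]
List cpp_phi_perm(NumericMatrix M, IntegerVector pos, int window, int nperm) {
  int s = M.nrow();
  std::vector<int> ord(s);
  for (int i = 0; i < s; ++i) ord[i] = i;
  double obs = banded_mean(M, ord, pos, window);
  int cnt = 0;
  std::vector<int> idx(s);
  for (int b = 0; b < nperm; ++b) {
    rand_perm(idx);
    if (banded_mean(M, idx, pos, window) <= obs + 1e-12) ++cnt;
  }
  return List::create(_["stat"] = obs,
                      _["p"] = (1.0 + cnt) / (nperm + 1.0));
}

// NSS: fraction of adjacent informative-site pairs that are compatible;
// recombination inflates it, so p = P(perm >= observed).
// [[Rcpp::export]]
List cpp_nss_perm(NumericMatrix M, int nperm) {
  int s = M.nrow();
  std::vector<int> ord(s);
  for (int i = 0; i < s; ++i) ord[i] = i;
  auto nss = [&](const std::vector<int>& o) {
    double sum = 0.0;
    for (int i = 0; i + 1 < s; ++i) sum += 1.0 - M(o[i], o[i + 1]);
    return sum / (s - 1);
  };
  double obs = nss(ord);
  int cnt = 0;
  std::vector<int> idx(s);
  for (int b = 0; b < nperm; ++b) {
    rand_perm(idx);
    if (nss(idx) >= obs - 1e-12) ++cnt;
  }
  return List::create(_["stat"] = obs,
                      _["p"] = (1.0 + cnt) / (nperm + 1.0));
}

// Windowed MaxChi statistic: for each pair, slide the breakpoint along the
// (permuted) column order and compare the `w` columns on each side of it in
// a 2x2 (differ/match) x (left/right half) chi-square without continuity
// correction; the statistic is the maximum over pairs and breakpoints.
static double maxchi_stat(const IntegerMatrix& diffs,
                          const std::vector<int>& ord, int w, int* best_pair,
                          int* best_k) {
  int np = diffs.nrow(), s = ord.size();
  double best = 0.0;
  if (best_pair) *best_pair = -1;
  if (best_k) *best_k = -1;
  std::vector<int> cs(s + 1, 0);
  for (int p = 0; p < np; ++p) {
    for (int t = 0; t < s; ++t) cs[t + 1] = cs[t] + diffs(p, ord[t]);
    for (int k = w; k + w <= s; ++k) {
      double a = cs[k] - cs[k - w];      // mismatches left half
      double c = cs[k + w] - cs[k];      // mismatches right half
      double b = w - a, d = w - c;
      double m3 = a + c, m4 = b + d;
      if (m3 <= 0 || m4 <= 0) continue;
      double num = 2.0 * w * (a * d - b * c) * (a * d - b * c);
      double chi = num / ((double)w * w * m3 * m4);
      if (chi > best) {
        best = chi;
        if (best_pair) *best_pair = p;
        if (best_k) *best_k = k;
      }
    }
  }
  return best;
}

// MaxChi: max windowed 2x2 chi-square over sequence pairs and breakpoints;
// the permutation shuffles column order globally. p = P(perm >= observed).
// [[Rcpp::export]]
List cpp_maxchi_perm(IntegerMatrix diffs, int w, int nperm) {
  int s = diffs.ncol();
  std::vector<int> ord(s);
  for (int i = 0; i < s; ++i) ord[i] = i;
  int bp, bk;
  double obs = maxchi_stat(diffs, ord, w, &bp, &bk);
  int cnt = 0;
  std::vector<int> idx(s);
  for (int b = 0; b < nperm; ++b) {
    rand_perm(idx);
    if (maxchi_stat(diffs, idx, w, nullptr, nullptr) >= obs - 1e-12) ++cnt;
  }
  return List::create(_["stat"] = obs, _["p"] = (1.0 + cnt) / (nperm + 1.0),
                      _["best_pair"] = bp + 1, _["best_break"] = bk);
}

static double kadane_max(const IntegerMatrix& m01, int row,
                         const std::vector<int>& ord, double penalty) {
  int s = ord.size();
  double best = 0.0, cur = 0.0;
  for (int t = 0; t < s; ++t) {
    double v = m01(row, ord[t]) ? 1.0 : -penalty;
    cur += v;
    if (cur < 0) cur = 0;
    if (cur > best) best = cur;
  }
  return best;
}

// All disjoint maximal positive-scoring segments (iterative Kadane split).
static void max_segments(const IntegerMatrix& m01, int row, double penalty,
                         int lo, int hi, std::vector<int>& st,
                         std::vector<int>& en, std::vector<double>& sc) {
  if (lo > hi) return;
  double best = 0.0, cur = 0.0;
  int cs = lo, bs = -1, be = -1;
  for (int t = lo; t <= hi; ++t) {
    double v = m01(row, t) ? 1.0 : -penalty;
    cur += v;
    if (cur <= 0) { cur = 0; cs = t + 1; }
    else if (cur > best) { best = cur; bs = cs; be = t; }
  }
  if (bs < 0 || best <= 0) return;
  // trim to polymorphic matches at the ends
  while (bs <= be && !m01(row, bs)) ++bs;
  while (be >= bs && !m01(row, be)) --be;
  if (bs > be) return;
  st.push_back(bs); en.push_back(be); sc.push_back(best);
  max_segments(m01, row, penalty, lo, bs - 2, st, en, sc);
  max_segments(m01, row, penalty, be + 2, hi, st, en, sc);
}

// GENECONV-style scan. m01: pairs x polymorphic-columns, 1 = pair matches.
// penalty: per-pair mismatch penalty. Returns observed fragments per pair
// (0-based polymorphic-column indices) and the per-pair permutation max
// segment scores (nperm x npairs).
// [[Rcpp::export]]
List cpp_geneconv_scan(IntegerMatrix m01, NumericVector penalty, int nperm) {
  int np = m01.nrow(), s = m01.ncol();
  List frags(np);
  for (int p = 0; p < np; ++p) {
    std::vector<int> st, en;
    std::vector<double> sc;
    max_segments(m01, p, penalty[p], 0, s - 1, st, en, sc);
    frags[p] = DataFrame::create(_["start_idx"] = wrap(st),
                                 _["end_idx"] = wrap(en),
                                 _["score"] = wrap(sc));
  }
  NumericMatrix permmax(nperm, np);
  std::vector<int> idx(s);
  for (int b = 0; b < nperm; ++b) {
    rand_perm(idx);
    for (int p = 0; p < np; ++p)
      permmax(b, p) = kadane_max(m01, p, idx, penalty[p]);
  }
  return List::create(_["frags"] = frags, _["permmax"] = permmax);
}
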