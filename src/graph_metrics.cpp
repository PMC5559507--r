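// Weighted graph measures for PLI connectivity matrices, plus an
// independent brute-force oracle (exhaustive simple-path enumeration and
// direct definition sums) used by the exhaustive self-verification sweep.
//
// Conventions (all matrices symmetric, zero diagonal, weights >= 0):
//   degree_i  = mean_j W_ij (j != i)          [reported per node]
//   strength_i = sum_j W_ij                   [used for Rw, Kw]
//   Ci        = sum_{k!=l} Wik Wil Wkl / sum_{k!=l} Wik Wil   (0 if denom 0)
//   Cw        = mean_i Ci
//   L_ij      = shortest path on edge lengths 1/W (infinite if w = 0)
//   Lw        = 1 / mean over ordered pairs of (1/L_ij)   (harmonic form)
//   Rw        = Pearson corr of endpoint strengths over ordered linked pairs
//   Kw        = <strength^2> / <strength>
//   radius    = min_i max_j L_ij ; diameter = max_i max_j L_ij
//   Gamma     = Cw / Cr, Lambda = Lw / Lr over weight-permuting surrogates;
//               exactly 1 when all off-diagonal weights are equal.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Core {
  std::vector<double> strength, degree, ci, dist;
  std::vector<double> rw_x, rw_y;   // scratch, reused across calls
  double cw, lw, rw, kw, radius, diameter;
  int n;
};

// ---------------- implementation side ----------------

static void impl_core(int n, const std::vector<double>& W, Core& out) {
  out.n = n;
  out.strength.assign(n, 0.0);
  out.degree.assign(n, 0.0);
  out.ci.assign(n, 0.0);
  out.dist.assign(n * n, INF);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) s += W[i * n + j];
    out.strength[i] = s;
    out.degree[i] = (n > 1) ? s / (n - 1) : 0.0;
  }

  // clustering: direct Table-2 sums over ordered (k, l)
  double cw = 0.0;
  for (int i = 0; i < n; ++i) {
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      double wik = W[i * n + k];
      if (wik == 0.0) continue;
      for (int l = 0; l < n; ++l) {
        if (l == i || l == k) continue;
        double wil = W[i * n + l];
        num += wik * wil * W[k * n + l];
        den += wik * wil;
      }
    }
    out.ci[i] = (den > 0.0) ? num / den : 0.0;
    cw += out.ci[i];
  }
  out.cw = (n > 0) ? cw / n : 0.0;

  // Floyd-Warshall on lengths 1/w
  std::vector<double>& D = out.dist;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) D[i * n + j] = 0.0;
      else {
        double w = W[i * n + j];
        D[i * n + j] = (w > 0.0) ? 1.0 / w : INF;
      }
    }
  }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double dik = D[i * n + k];
      if (dik == INF) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + D[k * n + j];
        if (alt < D[i * n + j]) D[i * n + j] = alt;
      }
    }

  // harmonic-mean path length, eccentricities
  double invsum = 0.0;
  double rad = INF, diam = 0.0;
  for (int i = 0; i < n; ++i) {
    double ecc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double d = D[i * n + j];
      invsum += (d == INF) ? 0.0 : 1.0 / d;
      if (d > ecc) ecc = d;
    }
    if (ecc < rad) rad = ecc;
    if (ecc > diam) diam = ecc;
  }
  double denom = (double)n * (n - 1);
  double invmean = (denom > 0.0) ? invsum / denom : 0.0;
  out.lw = (invmean > 0.0) ? 1.0 / invmean : INF;
  out.radius = (n > 1) ? rad : 0.0;
  out.diameter = (n > 1) ? diam : 0.0;

  // assortativity over ordered linked pairs, endpoint strengths
  double sx = 0.0, sy = 0.0, sxx = 0.0, syy = 0.0, sxy = 0.0;
  long m = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j || W[i * n + j] <= 0.0) continue;
      double x = out.strength[i], y = out.strength[j];
      sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
      ++m;
    }
  if (m < 2) out.rw = R_NaN;
  else {
    double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
    double cxy = sxy - sx * sy / m;
    out.rw = (vx > 1e-14 && vy > 1e-14) ? cxy / std::sqrt(vx * vy) : R_NaN;
  }

  // degree diversity from strengths
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) { s1 += out.strength[i]; s2 += out.strength[i] * out.strength[i]; }
  out.kw = (s1 > 0.0) ? (s2 / n) / (s1 / n) : R_NaN;
}

// ---------------- oracle side ----------------

// All simple paths between ordered node pairs, precomputed once and
// flattened per pair as [n_edges, cell_1, ..., cell_n_edges, n_edges, ...]
// where each cell indexes the weight matrix; distances by explicit
// minimisation over the enumeration.
struct PathTable {
  int n;
  std::vector<std::vector<int>> flat;  // one flattened path list per pair
};

static void dfs_paths(int n, int target, std::vector<int>& cur,
                      std::vector<bool>& used,
                      std::vector<std::vector<int>>& out) {
  int last = cur.back();
  if (last == target) { out.push_back(cur); return; }
  for (int nxt = 0; nxt < n; ++nxt) {
    if (used[nxt]) continue;
    used[nxt] = true; cur.push_back(nxt);
    dfs_paths(n, target, cur, used, out);
    cur.pop_back(); used[nxt] = false;
  }
}

static PathTable build_paths(int n) {
  PathTable t;
  t.n = n;
  t.flat.assign(n * n, {});
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      std::vector<int> cur{ i };
      std::vector<bool> used(n, false);
      used[i] = true;
      std::vector<std::vector<int>> node_paths;
      dfs_paths(n, j, cur, used, node_paths);
      std::vector<int>& f = t.flat[i * n + j];
      for (const auto& p : node_paths) {
        f.push_back((int)p.size() - 1);
        for (size_t s = 0; s + 1 < p.size(); ++s)
          f.push_back(p[s] * n + p[s + 1]);
      }
    }
  return t;
}

static void oracle_core(int n, const std::vector<double>& W,
                        const PathTable& pt, Core& out) {
  out.n = n;
  out.strength.assign(n, 0.0);
  out.degree.assign(n, 0.0);
  out.ci.assign(n, 0.0);
  out.dist.assign(n * n, INF);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) s += W[i * n + j];
    out.strength[i] = s;
    out.degree[i] = (n > 1) ? s / (n - 1) : 0.0;
  }

  // clustering via unordered pair enumeration (x2 for both orderings)
  double cw = 0.0;
  for (int i = 0; i < n; ++i) {
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      for (int l = k + 1; l < n; ++l) {
        if (l == i) continue;
        double p = W[i * n + k] * W[i * n + l];
        num += 2.0 * p * W[k * n + l];
        den += 2.0 * p;
      }
    }
    out.ci[i] = (den > 0.0) ? num / den : 0.0;
    cw += out.ci[i];
  }
  out.cw = (n > 0) ? cw / n : 0.0;

  // distances: minimum over every simple path of the sum of edge lengths
  for (int i = 0; i < n; ++i) {
    out.dist[i * n + i] = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double best = INF;
      const std::vector<int>& f = pt.flat[i * n + j];
      size_t pos = 0;
      while (pos < f.size()) {
        int ne = f[pos++];
        double len = 0.0;
        bool ok = true;
        for (int e = 0; e < ne; ++e) {
          double w = W[f[pos + e]];
          if (w <= 0.0) { ok = false; break; }
          len += 1.0 / w;
        }
        pos += ne;
        if (ok && len < best) best = len;
      }
      out.dist[i * n + j] = best;
    }
  }

  double invsum = 0.0, rad = INF, diam = 0.0;
  for (int i = 0; i < n; ++i) {
    double ecc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double d = out.dist[i * n + j];
      invsum += (d == INF) ? 0.0 : 1.0 / d;
      if (d > ecc) ecc = d;
    }
    if (ecc < rad) rad = ecc;
    if (ecc > diam) diam = ecc;
  }
  double denom = (double)n * (n - 1);
  double invmean = (denom > 0.0) ? invsum / denom : 0.0;
  out.lw = (invmean > 0.0) ? 1.0 / invmean : INF;
  out.radius = (n > 1) ? rad : 0.0;
  out.diameter = (n > 1) ? diam : 0.0;

  // assortativity: build vectors explicitly, two-pass Pearson
  std::vector<double>& xs = out.rw_x;
  std::vector<double>& ys = out.rw_y;
  xs.clear(); ys.clear();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W[i * n + j] > 0.0) {
        xs.push_back(out.strength[i]);
        ys.push_back(out.strength[j]);
      }
  size_t m = xs.size();
  if (m < 2) out.rw = R_NaN;
  else {
    double mx = 0.0, my = 0.0;
    for (size_t a = 0; a < m; ++a) { mx += xs[a]; my += ys[a]; }
    mx /= m; my /= m;
    double vx = 0.0, vy = 0.0, cxy = 0.0;
    for (size_t a = 0; a < m; ++a) {
      vx += (xs[a] - mx) * (xs[a] - mx);
      vy += (ys[a] - my) * (ys[a] - my);
      cxy += (xs[a] - mx) * (ys[a] - my);
    }
    out.rw = (vx > 1e-14 && vy > 1e-14) ? cxy / std::sqrt(vx * vy) : R_NaN;
  }

  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) { s1 += out.strength[i]; s2 += out.strength[i] * out.strength[i]; }
  out.kw = (s1 > 0.0) ? (s2 / n) / (s1 / n) : R_NaN;
}

// ---------------- helpers ----------------

static void fill_matrix(int n, const std::vector<double>& w,
                        const std::vector<int>& ei, const std::vector<int>& ej,
                        std::vector<double>& W) {
  std::fill(W.begin(), W.end(), 0.0);
  for (size_t e = 0; e < w.size(); ++e) {
    W[ei[e] * n + ej[e]] = w[e];
    W[ej[e] * n + ei[e]] = w[e];
  }
}

static bool all_equal_offdiag(const std::vector<double>& w) {
  for (size_t e = 1; e < w.size(); ++e)
    if (w[e] != w[0]) return false;
  return true;
}

// ratio with the all-equal -> exactly 1 convention applied by the caller
static double safe_ratio(double a, double b) {
  if (std::isinf(a) && std::isinf(b)) return R_NaN;
  return a / b;  // may be NaN for 0/0, Inf for x/0: documented
}

static double cmp(double a, double b) {
  bool na = ISNAN(a), nb = ISNAN(b);
  if (na && nb) return 0.0;
  if (na || nb) return INF;
  bool ia = std::isinf(a), ib = std::isinf(b);
  if (ia && ib) return (a == b) ? 0.0 : INF;
  if (ia || ib) return INF;
  return std::fabs(a - b);
}

// ---------------- exported ----------------

// [[Rcpp::export]]
List cpp_graph_core(NumericMatrix Wm) {
  int n = Wm.nrow();
  std::vector<double> W(Wm.begin(), Wm.end());
  Core c;
  impl_core(n, W, c);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D(i, j) = c.dist[i * n + j];
  return List::create(
    _["degree"] = NumericVector(c.degree.begin(), c.degree.end()),
    _["strength"] = NumericVector(c.strength.begin(), c.strength.end()),
    _["ci"] = NumericVector(c.ci.begin(), c.ci.end()),
    _["cw"] = c.cw, _["dist"] = D, _["lw"] = c.lw, _["rw"] = c.rw,
    _["kw"] = c.kw, _["radius"] = c.radius, _["diameter"] = c.diameter);
}

// Cw and Lw for each surrogate permutation (rows of `perms`, 1-based
// permutations of the upper-triangle weight slots).
// [[Rcpp::export]]
NumericMatrix cpp_surrogate_cl(NumericMatrix Wm, IntegerMatrix perms) {
  int n = Wm.nrow();
  int E = n * (n - 1) / 2;
  std::vector<int> ei, ej;
  std::vector<double> w0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      ei.push_back(i); ej.push_back(j); w0.push_back(Wm(i, j));
    }
  if (perms.ncol() != E) stop("perms must have n*(n-1)/2 columns");
  int S = perms.nrow();
  NumericMatrix out(S, 2);
  std::vector<double> W(n * n), w(E);
  Core c;
  for (int s = 0; s < S; ++s) {
    for (int e = 0; e < E; ++e) w[e] = w0[perms(s, e) - 1];
    fill_matrix(n, w, ei, ej, W);
    impl_core(n, W, c);
    out(s, 0) = c.cw;
    out(s, 1) = c.lw;
  }
  colnames(out) = CharacterVector::create("cw", "lw");
  return out;
}

// Exhaustive oracle-equivalence sweep: every assignment of `levels` to the
// n*(n-1)/2 edges of the complete graph on n nodes. For each graph the
// implementation core (Floyd-Warshall etc.) and the oracle core (simple-path
// enumeration, direct definition sums) are compared on all eight measures,
// including Gamma/Lambda computed from identical surrogate permutations.
// Returns the maximum absolute discrepancy per measure.
// [[Rcpp::export]]
List cpp_validate_graphs(int n, NumericVector levels, IntegerMatrix perms) {
  if (n < 2 || n > 6) stop("n must be in 2..6");
  int E = n * (n - 1) / 2;
  if (perms.ncol() != E) stop("perms must have n*(n-1)/2 columns");
  int L = levels.size(), S = perms.nrow();
  PathTable pt = build_paths(n);

  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { ei.push_back(i); ej.push_back(j); }

  std::vector<int> idx(E, 0);
  std::vector<double> w(E), wp(E), W(n * n), Wp(n * n);
  Core a, b, sa, sb;

  double d_degree = 0, d_ci = 0, d_cw = 0, d_dist = 0, d_lw = 0, d_rw = 0,
         d_kw = 0, d_radius = 0, d_diameter = 0, d_gamma = 0, d_lambda = 0;
  long n_graphs = 0;

  while (true) {
    for (int e = 0; e < E; ++e) w[e] = levels[idx[e]];
    fill_matrix(n, w, ei, ej, W);
    impl_core(n, W, a);
    oracle_core(n, W, pt, b);

    for (int i = 0; i < n; ++i) {
      d_degree = std::max(d_degree, cmp(a.degree[i], b.degree[i]));
      d_ci = std::max(d_ci, cmp(a.ci[i], b.ci[i]));
    }
    for (int i = 0; i < n * n; ++i)
      d_dist = std::max(d_dist, cmp(a.dist[i], b.dist[i]));
    d_cw = std::max(d_cw, cmp(a.cw, b.cw));
    d_lw = std::max(d_lw, cmp(a.lw, b.lw));
    d_rw = std::max(d_rw, cmp(a.rw, b.rw));
    d_kw = std::max(d_kw, cmp(a.kw, b.kw));
    d_radius = std::max(d_radius, cmp(a.radius, b.radius));
    d_diameter = std::max(d_diameter, cmp(a.diameter, b.diameter));

    // Gamma/Lambda with shared surrogate permutations
    double ga, la, gb, lb;
    if (all_equal_offdiag(w)) {
      ga = la = gb = lb = 1.0;
    } else {
      double cra = 0, lra_inv = 0, crb = 0, lrb_inv = 0;
      bool lra_inf = false, lrb_inf = false;
      double lra_sum = 0, lrb_sum = 0;
      for (int s = 0; s < S; ++s) {
        for (int e = 0; e < E; ++e) wp[e] = w[perms(s, e) - 1];
        fill_matrix(n, wp, ei, ej, Wp);
        impl_core(n, Wp, sa);
        oracle_core(n, Wp, pt, sb);
        cra += sa.cw; crb += sb.cw;
        if (std::isinf(sa.lw)) lra_inf = true; else lra_sum += sa.lw;
        if (std::isinf(sb.lw)) lrb_inf = true; else lrb_sum += sb.lw;
      }
      (void)lra_inv; (void)lrb_inv;
      double lra = lra_inf ? INF : lra_sum / S;
      double lrb = lrb_inf ? INF : lrb_sum / S;
      ga = safe_ratio(a.cw, cra / S);
      gb = safe_ratio(b.cw, crb / S);
      la = safe_ratio(a.lw, lra);
      lb = safe_ratio(b.lw, lrb);
    }
    d_gamma = std::max(d_gamma, cmp(ga, gb));
    d_lambda = std::max(d_lambda, cmp(la, lb));

    ++n_graphs;
    // odometer increment
    int e = 0;
    while (e < E) {
      if (++idx[e] < L) break;
      idx[e] = 0;
      ++e;
    }
    if (e == E) break;
    if (n_graphs % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["n_graphs"] = (double)n_graphs,
    _["max_abs_diff"] = NumericVector::create(
      _["degree"] = d_degree, _["ci"] = d_ci, _["cw"] = d_cw,
      _["dist"] = d_dist, _["lw"] = d_lw, _["rw"] = d_rw, _["kw"] = d_kw,
      _["radius"] = d_radius, _["diameter"] = d_diameter,
      _["gamma"] = d_gamma, _["lambda"] = d_lambda));
}
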