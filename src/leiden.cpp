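// Signed Leiden community detection on dense weighted graphs.
//
// Optimizes the layer-weighted signed modularity
//   Q = (2m+ Q+ - 2m- Q-) / (2m+ + 2m-),
// where Q+ (Q-) is the gamma-resolution Newman-Girvan modularity of the
// positive-weight (absolute-negative-weight) layer with its own null model.
// Weighting each layer by its share of the total weight (Gomez, Jensen &
// Arenas) makes the objective reduce to plain modularity when one layer is
// empty; an unweighted difference would let a near-empty negative layer's
// null term dominate and bias the optimum toward coarse partitions.
// The graph is dense (co-expression networks are complete), so all
// neighbourhood scans are O(n) row passes.
// Randomness: random initial assignment, random visit orders, and the
// refinement phase merges with probability proportional to exp(gain / beta).
// All randomness flows from one mt19937 seeded by the caller, so runs are
// reproducible bit-for-bit for a given seed.

#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

struct Graph {
  int n = 0;
  std::vector<double> wp, wn;  // n*n row-major, non-negative layers
  std::vector<double> kp, kn;  // strengths per layer (self-loops counted once)
  double mp2 = 0.0, mn2 = 0.0; // total layer weight = 2m

  void finalize() {
    kp.assign(n, 0.0);
    kn.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double sp = 0.0, sn = 0.0;
      const double *rp = &wp[(size_t)i * n], *rn = &wn[(size_t)i * n];
      for (int j = 0; j < n; ++j) { sp += rp[j]; sn += rn[j]; }
      kp[i] = sp; kn[i] = sn;
    }
    mp2 = std::accumulate(kp.begin(), kp.end(), 0.0);
    mn2 = std::accumulate(kn.begin(), kn.end(), 0.0);
  }
};

inline double unif01(std::mt19937 &rng) {
  return rng() * (1.0 / 4294967296.0);
}

inline int unif_int(std::mt19937 &rng, int k) {  // 0..k-1
  return (int)(rng() % (unsigned)k);
}

void shuffle_order(std::vector<int> &v, std::mt19937 &rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = unif_int(rng, i + 1);
    std::swap(v[i], v[j]);
  }
}

// Renumber labels to 0..K-1 by first appearance; returns K.
int compact_labels(std::vector<int> &m) {
  std::vector<int> map(m.size(), -1);
  int K = 0;
  for (size_t i = 0; i < m.size(); ++i) {
    if (map[m[i]] < 0) map[m[i]] = K++;
    m[i] = map[m[i]];
  }
  return K;
}

// Score of placing node v (removed from everywhere) into community t.
// Sp/Sn: weight from v to t (excluding v); Kpt/Knt: community strengths
// excluding v. Staying out of every community scores 0 by convention, so
// score differences are move gains.
inline double place_score(const Graph &g, int v, double gamma,
                          double Sp, double Kpt, double Sn, double Knt) {
  const double T = g.mp2 + g.mn2;
  if (T <= 0) return 0.0;
  double s = 0.0;
  if (g.mp2 > 0) s += (2.0 * Sp - 2.0 * gamma * g.kp[v] * Kpt / g.mp2) / T;
  if (g.mn2 > 0) s -= (2.0 * Sn - 2.0 * gamma * g.kn[v] * Knt / g.mn2) / T;
  return s;
}

const double EPS = 1e-12;

// Greedy local moving; memb must be compact on entry, stays compact-ish
// (new communities may be opened); returns true if any move was made.
bool local_move(const Graph &g, std::vector<int> &memb, double gamma,
                std::mt19937 &rng) {
  const int n = g.n;
  int K = compact_labels(memb);
  std::vector<double> Kp(K, 0.0), Kn(K, 0.0);
  for (int i = 0; i < n; ++i) { Kp[memb[i]] += g.kp[i]; Kn[memb[i]] += g.kn[i]; }
  std::vector<double> Sp(K, 0.0), Sn(K, 0.0);
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);

  bool any = false, moved = true;
  int pass = 0;
  while (moved && pass < 1000) {
    moved = false; ++pass;
    shuffle_order(order, rng);
    for (int oi = 0; oi < n; ++oi) {
      const int v = order[oi];
      const int c = memb[v];
      const double *rp = &g.wp[(size_t)v * n], *rn = &g.wn[(size_t)v * n];
      std::fill(Sp.begin(), Sp.end(), 0.0);
      std::fill(Sn.begin(), Sn.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == v) continue;
        Sp[memb[j]] += rp[j];
        Sn[memb[j]] += rn[j];
      }
      const double cur = place_score(g, v, gamma, Sp[c], Kp[c] - g.kp[v],
                                     Sn[c], Kn[c] - g.kn[v]);
      int best = c;
      double bestScore = cur;
      for (int t = 0; t < K; ++t) {
        if (t == c) continue;
        double s = place_score(g, v, gamma, Sp[t], Kp[t], Sn[t], Kn[t]);
        if (s > bestScore + EPS) { bestScore = s; best = t; }
      }
      if (bestScore < -EPS && cur < -EPS) {
        // a fresh singleton community (score 0) beats every option
        Kp.push_back(0.0); Kn.push_back(0.0);
        Sp.push_back(0.0); Sn.push_back(0.0);
        best = K++;
        bestScore = 0.0;
      }
      if (best != c && bestScore > cur + EPS) {
        Kp[c] -= g.kp[v]; Kn[c] -= g.kn[v];
        Kp[best] += g.kp[v]; Kn[best] += g.kn[v];
        memb[v] = best;
        moved = true; any = true;
      }
    }
  }
  compact_labels(memb);
  return any;
}

// Leiden refinement: start from singletons, let isolated nodes merge into
// refined communities inside their parent community, sampling among
// positive-gain targets with probability ~ exp(gain / theta).
std::vector<int> refine(const Graph &g, const std::vector<int> &memb,
                        double gamma, double theta, std::mt19937 &rng) {
  const int n = g.n;
  std::vector<int> r(n);
  std::iota(r.begin(), r.end(), 0);
  std::vector<double> Kp(g.kp), Kn(g.kn);
  std::vector<int> csize(n, 1);
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  shuffle_order(order, rng);

  std::vector<double> Sp(n, 0.0), Sn(n, 0.0);
  std::vector<int> touched; touched.reserve(64);
  std::vector<int> cand; cand.reserve(64);
  std::vector<double> gain; gain.reserve(64);

  for (int oi = 0; oi < n; ++oi) {
    const int v = order[oi];
    if (csize[r[v]] != 1) continue;  // only still-singleton nodes move
    const int parent = memb[v];
    const double *rp = &g.wp[(size_t)v * n], *rn = &g.wn[(size_t)v * n];
    touched.clear();
    for (int j = 0; j < n; ++j) {
      if (j == v || memb[j] != parent) continue;
      const int t = r[j];
      if (Sp[t] == 0.0 && Sn[t] == 0.0) touched.push_back(t);
      Sp[t] += rp[j];
      Sn[t] += rn[j];
    }
    cand.clear(); gain.clear();
    double gmax = 0.0;
    for (int t : touched) {
      if (t == r[v]) continue;
      double s = place_score(g, v, gamma, Sp[t], Kp[t], Sn[t], Kn[t]);
      if (s > EPS) {
        cand.push_back(t);
        gain.push_back(s);
        if (s > gmax) gmax = s;
      }
    }
    if (!cand.empty()) {
      int pick;
      if (theta > 0) {
        // staying put (gain 0) competes too
        double tot = std::exp((0.0 - gmax) / theta);
        std::vector<double> w(cand.size());
        for (size_t q = 0; q < cand.size(); ++q) {
          w[q] = std::exp((gain[q] - gmax) / theta);
          tot += w[q];
        }
        double u = unif01(rng) * tot, acc = 0.0;
        pick = -1;
        for (size_t q = 0; q < cand.size(); ++q) {
          acc += w[q];
          if (u < acc) { pick = (int)q; break; }
        }
      } else {
        pick = 0;
        for (size_t q = 1; q < cand.size(); ++q)
          if (gain[q] > gain[pick]) pick = (int)q;
      }
      if (pick >= 0) {
        const int old = r[v], t = cand[pick];
        Kp[old] -= g.kp[v]; Kn[old] -= g.kn[v]; csize[old]--;
        Kp[t] += g.kp[v]; Kn[t] += g.kn[v]; csize[t]++;
        r[v] = t;
      }
    }
    for (int t : touched) { Sp[t] = 0.0; Sn[t] = 0.0; }
  }
  return r;
}

Graph aggregate(const Graph &g, const std::vector<int> &r, int K) {
  Graph a;
  a.n = K;
  a.wp.assign((size_t)K * K, 0.0);
  a.wn.assign((size_t)K * K, 0.0);
  for (int i = 0; i < g.n; ++i) {
    const int ri = r[i];
    const double *rp = &g.wp[(size_t)i * g.n], *rn = &g.wn[(size_t)i * g.n];
    double *ap = &a.wp[(size_t)ri * K], *an = &a.wn[(size_t)ri * K];
    for (int j = 0; j < g.n; ++j) { ap[r[j]] += rp[j]; an[r[j]] += rn[j]; }
  }
  a.finalize();
  return a;
}

double quality(const Graph &g, const std::vector<int> &memb, double gamma) {
  int K = 0;
  for (int i = 0; i < g.n; ++i) K = std::max(K, memb[i] + 1);
  std::vector<double> Kp(K, 0.0), Kn(K, 0.0);
  double winp = 0.0, winn = 0.0;
  for (int i = 0; i < g.n; ++i) {
    Kp[memb[i]] += g.kp[i]; Kn[memb[i]] += g.kn[i];
    const double *rp = &g.wp[(size_t)i * g.n], *rn = &g.wn[(size_t)i * g.n];
    for (int j = 0; j < g.n; ++j)
      if (memb[j] == memb[i]) { winp += rp[j]; winn += rn[j]; }
  }
  const double T = g.mp2 + g.mn2;
  if (T <= 0) return 0.0;
  double q = 0.0;
  if (g.mp2 > 0) {
    double nul = 0.0;
    for (double x : Kp) nul += x * x;
    q += (winp - gamma * nul / g.mp2) / T;
  }
  if (g.mn2 > 0) {
    double nul = 0.0;
    for (double x : Kn) nul += x * x;
    q -= (winn - gamma * nul / g.mn2) / T;
  }
  return q;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector leiden_signed_cpp(NumericMatrix W, double gamma, double beta,
                                int n_iterations, int seed) {
  const int n = W.nrow();
  if (n != W.ncol()) stop("weight matrix must be square");
  if (n == 0) stop("empty network");

  Graph base;
  base.n = n;
  base.wp.resize((size_t)n * n);
  base.wn.resize((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      const double w = W(i, j);
      base.wp[(size_t)i * n + j] = w > 0 ? w : 0.0;
      base.wn[(size_t)i * n + j] = w < 0 ? -w : 0.0;
    }
  base.finalize();

  std::mt19937 rng((uint32_t)seed);

  // random initial configuration: an arbitrary number of arbitrary groups
  std::vector<int> memb(n);
  const int K0 = 1 + unif_int(rng, n);
  for (int i = 0; i < n; ++i) memb[i] = unif_int(rng, K0);
  compact_labels(memb);

  double bestQ = -std::numeric_limits<double>::infinity();
  if (n_iterations < 1) n_iterations = 1;

  for (int iter = 0; iter < n_iterations; ++iter) {
    // one full move/refine/aggregate cycle from the current assignment
    Graph cur = base;
    std::vector<int> m = memb;
    std::vector<int> orig2cur(n);
    std::iota(orig2cur.begin(), orig2cur.end(), 0);
    while (true) {
      local_move(cur, m, gamma, rng);
      std::vector<int> r = refine(cur, m, gamma, beta, rng);
      const int Kr = compact_labels(r);
      if (Kr == cur.n) break;
      std::vector<int> pm(Kr);
      for (int i = 0; i < cur.n; ++i) pm[r[i]] = m[i];
      compact_labels(pm);
      for (int i = 0; i < n; ++i) orig2cur[i] = r[orig2cur[i]];
      cur = aggregate(cur, r, Kr);
      m = pm;
    }
    for (int i = 0; i < n; ++i) memb[i] = m[orig2cur[i]];
    compact_labels(memb);
    const double Q = quality(base, memb, gamma);
    if (Q <= bestQ + EPS) break;
    bestQ = Q;
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = memb[i] + 1;
  return out;
}
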