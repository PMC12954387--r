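// Hot loops of the dynamic-connectivity layer: average-rank Spearman
// correlation, greedy data-driven windowing, per-sample meta-state
// assignment, LZ76 phrase counting, and Louvain community detection with
// signed (positive/negative two-null-term) modularity.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// average ranks (midranks for ties)
static std::vector<double> rank_avg(const double* x, int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
  return r;
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  int n = a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

static double spearman_vec(const double* x, const double* y, int n) {
  std::vector<double> rx = rank_avg(x, n), ry = rank_avg(y, n);
  return pearson(rx, ry);
}

// [[Rcpp::export]]
double cpp_spearman(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("length mismatch");
  return spearman_vec(x.begin(), y.begin(), x.size());
}

// column-wise average ranks of a matrix
// [[Rcpp::export]]
NumericMatrix cpp_rank_columns(NumericMatrix X) {
  int p = X.nrow(), t = X.ncol();
  NumericMatrix R(p, t);
  for (int j = 0; j < t; ++j) {
    std::vector<double> r = rank_avg(&X(0, j), p);
    for (int i = 0; i < p; ++i) R(i, j) = r[i];
  }
  return R;
}

// Greedy data-driven windowing over the columns of X (feature x time): the
// current window grows while the Spearman correlation between the incoming
// column and the running window mean stays >= threshold; it closes when the
// correlation drops, provided the window already has min_len samples and the
// boundary is at least `guard` samples away from both segment edges.
// Returns a 1-based window id per sample; a trailing window shorter than
// min_len is merged into its predecessor.
// [[Rcpp::export]]
IntegerVector cpp_greedy_windows(NumericMatrix X, double threshold,
                                 int min_len, int guard) {
  int p = X.nrow(), t = X.ncol();
  if (t < 1) stop("empty tensor");
  IntegerVector id(t);
  std::vector<double> acc(p, 0.0);
  int wstart = 0, wid = 1;
  for (int i = 0; i < p; ++i) acc[i] = X(i, 0);
  id[0] = wid;
  // pre-rank and standardize every sample column once
  std::vector<std::vector<double> > xr(t);
  std::vector<char> xconst(t, 0);
  for (int j = 0; j < t; ++j) {
    xr[j] = rank_avg(&X(0, j), p);
    double m = 0;
    for (int i = 0; i < p; ++i) m += xr[j][i];
    m /= p;
    double ss = 0;
    for (int i = 0; i < p; ++i) { xr[j][i] -= m; ss += xr[j][i] * xr[j][i]; }
    if (ss <= 0) { xconst[j] = 1; continue; }
    double inv = 1.0 / std::sqrt(ss);
    for (int i = 0; i < p; ++i) xr[j][i] *= inv;
  }
  std::vector<double> mean(p);
  for (int j = 1; j < t; ++j) {
    int len = j - wstart;
    for (int i = 0; i < p; ++i) mean[i] = acc[i] / len;
    std::vector<double> mr = rank_avg(mean.data(), p);
    double m = 0;
    for (int i = 0; i < p; ++i) m += mr[i];
    m /= p;
    double ss = 0;
    for (int i = 0; i < p; ++i) { mr[i] -= m; ss += mr[i] * mr[i]; }
    double r;
    if (ss <= 0 || xconst[j]) {
      r = NA_REAL;
    } else {
      double inv = 1.0 / std::sqrt(ss);
      r = 0;
      for (int i = 0; i < p; ++i) r += mr[i] * inv * xr[j][i];
    }
    bool stable = R_IsNA(r) ? true : (r >= threshold);
    bool can_break = (len >= min_len) && (j >= guard) && (j <= t - guard);
    if (!stable && can_break) {
      ++wid;
      wstart = j;
      std::fill(acc.begin(), acc.end(), 0.0);
    }
    for (int i = 0; i < p; ++i) acc[i] += X(i, j);
    id[j] = wid;
  }
  // merge a short trailing window into its predecessor
  if (wid > 1) {
    int last_len = 0;
    for (int j = t - 1; j >= 0 && id[j] == wid; --j) ++last_len;
    if (last_len < min_len) {
      for (int j = t - 1; j >= 0 && id[j] == wid; --j) id[j] = wid - 1;
    }
  }
  return id;
}

// Per-sample dominant meta-state: argmax over states of the Spearman
// correlation between the sample's connectivity vector (column of X) and the
// state topography (column of S). Ties resolve to the lowest state index.
// [[Rcpp::export]]
IntegerVector cpp_assign_states(NumericMatrix X, NumericMatrix S) {
  int p = X.nrow(), t = X.ncol(), k = S.ncol();
  if (S.nrow() != p) stop("state topographies must match the pair dimension");
  // pre-rank and standardize state columns
  std::vector<std::vector<double> > sr(k);
  std::vector<bool> s_const(k, false);
  for (int c = 0; c < k; ++c) {
    sr[c] = rank_avg(&S(0, c), p);
    double m = 0;
    for (int i = 0; i < p; ++i) m += sr[c][i];
    m /= p;
    double ss = 0;
    for (int i = 0; i < p; ++i) { sr[c][i] -= m; ss += sr[c][i] * sr[c][i]; }
    if (ss <= 0) { s_const[c] = true; continue; }
    double inv = 1.0 / std::sqrt(ss);
    for (int i = 0; i < p; ++i) sr[c][i] *= inv;
  }
  IntegerVector out(t);
  for (int j = 0; j < t; ++j) {
    std::vector<double> rx = rank_avg(&X(0, j), p);
    double m = 0;
    for (int i = 0; i < p; ++i) m += rx[i];
    m /= p;
    double ss = 0;
    for (int i = 0; i < p; ++i) { rx[i] -= m; ss += rx[i] * rx[i]; }
    double best = -2.0;
    int arg = 0;
    if (ss > 0) {
      double inv = 1.0 / std::sqrt(ss);
      for (int c = 0; c < k; ++c) {
        double r;
        if (s_const[c]) {
          r = 0.0;
        } else {
          r = 0;
          for (int i = 0; i < p; ++i) r += rx[i] * inv * sr[c][i];
        }
        if (r > best + 1e-12) { best = r; arg = c; }
      }
    }
    out[j] = arg + 1;
  }
  return out;
}

// LZ76 phrase count (Kaspar-Schuster scan); the symbol sequence is used
// directly, no binarization.
// [[Rcpp::export]]
int cpp_lz76(IntegerVector s) {
  int n = s.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Instantaneous amplitude correlation of every channel pair: for the pair
// (i, j), orthogonalize in both directions (on the analytic signals, using
// the precomputed real gram matrix G of the filtered signals), z-score the
// amplitude envelopes over the whole segment (population SD) and average the
// two products of z-scores. Rows of the result follow the column-major
// upper-triangle order. Pairs with a constant envelope come back as NaN.
// [[Rcpp::export]]
NumericMatrix cpp_iac_pairs(NumericMatrix AR, NumericMatrix AI,
                            NumericMatrix G) {
  int nc = AR.nrow(), nt = AR.ncol();
  int np = nc * (nc - 1) / 2;
  NumericMatrix out(np, nt);
  // z-scored plain envelopes
  std::vector<std::vector<double> > zenv(nc, std::vector<double>(nt));
  std::vector<char> envconst(nc, 0);
  std::vector<double> buf(nt);
  auto zscore = [&](std::vector<double>& v) -> bool {
    double m = 0;
    for (int t = 0; t < nt; ++t) m += v[t];
    m /= nt;
    double ss = 0;
    for (int t = 0; t < nt; ++t) { v[t] -= m; ss += v[t] * v[t]; }
    if (ss <= 0) return false;
    double inv = 1.0 / std::sqrt(ss / nt);
    for (int t = 0; t < nt; ++t) v[t] *= inv;
    return true;
  };
  for (int i = 0; i < nc; ++i) {
    for (int t = 0; t < nt; ++t)
      zenv[i][t] = std::sqrt(AR(i, t) * AR(i, t) + AI(i, t) * AI(i, t));
    if (!zscore(zenv[i])) envconst[i] = 1;
  }
  int k = 0;
  for (int j = 1; j < nc; ++j) {
    for (int i = 0; i < j; ++i, ++k) {
      if (G(i, i) == 0 || G(j, j) == 0 || envconst[i] || envconst[j]) {
        for (int t = 0; t < nt; ++t) out(k, t) = NA_REAL;
        continue;
      }
      // direction 1: envelope of j orthogonalized to i
      double cji = G(j, i) / G(i, i);
      for (int t = 0; t < nt; ++t) {
        double dr = AR(j, t) - cji * AR(i, t);
        double di = AI(j, t) - cji * AI(i, t);
        buf[t] = std::sqrt(dr * dr + di * di);
      }
      bool ok1 = zscore(buf);
      if (ok1) {
        for (int t = 0; t < nt; ++t) out(k, t) = zenv[i][t] * buf[t];
      }
      // direction 2: envelope of i orthogonalized to j
      double cij = G(i, j) / G(j, j);
      for (int t = 0; t < nt; ++t) {
        double dr = AR(i, t) - cij * AR(j, t);
        double di = AI(i, t) - cij * AI(j, t);
        buf[t] = std::sqrt(dr * dr + di * di);
      }
      bool ok2 = zscore(buf);
      if (!ok1 || !ok2) {
        for (int t = 0; t < nt; ++t) out(k, t) = NA_REAL;
      } else {
        for (int t = 0; t < nt; ++t)
          out(k, t) = 0.5 * (out(k, t) + zenv[j][t] * buf[t]);
      }
    }
  }
  return out;
}

// ---- signed-modularity Louvain -------------------------------------------

// Signed modularity (two-null-term): Q = wp * Q+ - wn * Q-, with Q+/Q- the
// plain modularities of the positive / negative parts and wp, wn their
// relative total weights.
// [[Rcpp::export]]
double cpp_modularity_signed(NumericMatrix A, IntegerVector membership) {
  int n = A.nrow();
  if (membership.size() != n) stop("membership length mismatch");
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, membership[i]);
  std::vector<double> sp(n, 0.0), sn(n, 0.0);
  double Mp = 0, Mn = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = A(i, j);
      if (w > 0) { sp[i] += w; Mp += w; }
      else if (w < 0) { sn[i] -= w; Mn -= w; }
    }
  std::vector<double> win_p(k, 0.0), win_n(k, 0.0), sc_p(k, 0.0), sc_n(k, 0.0);
  for (int i = 0; i < n; ++i) {
    int ci = membership[i] - 1;
    sc_p[ci] += sp[i]; sc_n[ci] += sn[i];
    for (int j = 0; j < n; ++j) {
      if (membership[j] != membership[i]) continue;
      double w = A(i, j);
      if (w > 0) win_p[ci] += w; else if (w < 0) win_n[ci] -= w;
    }
  }
  double Qp = 0, Qn = 0;
  for (int c = 0; c < k; ++c) {
    if (Mp > 0) Qp += win_p[c] / Mp - (sc_p[c] / Mp) * (sc_p[c] / Mp);
    if (Mn > 0) Qn += win_n[c] / Mn - (sc_n[c] / Mn) * (sc_n[c] / Mn);
  }
  double tot = Mp + Mn;
  if (tot <= 0) return 0.0;
  return (Mp / tot) * Qp - (Mn / tot) * Qn;
}

struct LevelResult {
  std::vector<int> membership;  // 0-based, compacted
  int n_comm;
};

// one Louvain level of local moves on a dense signed matrix; `init` (may be
// null) seeds the starting membership, otherwise singletons
static LevelResult louvain_level(const std::vector<double>& A, int n,
                                 std::mt19937& rng,
                                 const std::vector<int>* init = nullptr) {
  std::vector<double> sp(n, 0.0), sn(n, 0.0), selfp(n, 0.0), selfn(n, 0.0);
  double Mp = 0, Mn = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double w = A[i + (size_t)n * j];
      if (w > 0) { sp[i] += w; Mp += w; }
      else if (w < 0) { sn[i] -= w; Mn -= w; }
    }
    double d = A[i + (size_t)n * i];
    if (d > 0) selfp[i] = d; else selfn[i] = -d;
  }
  double tot = Mp + Mn;
  double wp = (tot > 0 && Mp > 0) ? Mp / tot : 0.0;
  double wn = (tot > 0 && Mn > 0) ? Mn / tot : 0.0;
  std::vector<int> comm(n);
  std::vector<int> csize(n, 0);
  std::vector<double> cs_p(n, 0.0), cs_n(n, 0.0);
  for (int i = 0; i < n; ++i) {
    comm[i] = init ? (*init)[i] : i;
    csize[comm[i]] += 1;
    cs_p[comm[i]] += sp[i];
    cs_n[comm[i]] += sn[i];
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  std::vector<double> kp(n), kn(n);
  bool improved_any = false, improved = true;
  int sweeps = 0;
  while (improved && sweeps < 100) {
    improved = false;
    ++sweeps;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int a = comm[i];
      // links of i to each community (excluding self-edge)
      std::fill(kp.begin(), kp.end(), 0.0);
      std::fill(kn.begin(), kn.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = A[i + (size_t)n * j];
        if (w > 0) kp[comm[j]] += w;
        else if (w < 0) kn[comm[j]] -= w;
      }
      // remove i from its community; insertion gain of community c (terms
      // constant over c dropped)
      cs_p[a] -= sp[i]; cs_n[a] -= sn[i];
      auto gain = [&](int c) {
        double gp = 0, gn = 0;
        if (Mp > 0) gp = 2.0 * kp[c] / Mp - 2.0 * cs_p[c] * sp[i] / (Mp * Mp);
        if (Mn > 0) gn = 2.0 * kn[c] / Mn - 2.0 * cs_n[c] * sn[i] / (Mn * Mn);
        return wp * gp - wn * gn;
      };
      csize[a] -= 1;
      double best_gain = gain(a);  // staying put wins ties
      int best_c = a;
      for (int c = 0; c < n; ++c) {
        if (c == a || (kp[c] == 0 && kn[c] == 0)) continue;
        double g = gain(c);
        if (g > best_gain + 1e-12) { best_gain = g; best_c = c; }
      }
      if (0.0 > best_gain + 1e-12) {
        // better off as a singleton: take any empty community slot
        for (int c = 0; c < n; ++c)
          if (csize[c] == 0) { best_c = c; best_gain = 0.0; break; }
      }
      cs_p[best_c] += sp[i]; cs_n[best_c] += sn[i];
      csize[best_c] += 1;
      if (best_c != a) { comm[i] = best_c; improved = true; improved_any = true; }
    }
  }
  // compact labels
  std::vector<int> remap(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i)
    if (remap[comm[i]] < 0) remap[comm[i]] = k++;
  LevelResult res;
  res.membership.resize(n);
  for (int i = 0; i < n; ++i) res.membership[i] = remap[comm[i]];
  res.n_comm = k;
  (void)improved_any;
  return res;
}

// classical multilevel pass (singleton init, aggregate, repeat)
static std::vector<int> louvain_multilevel(const std::vector<double>& A0,
                                           int n, std::mt19937& rng) {
  std::vector<double> A(A0);
  std::vector<int> global(n);
  for (int i = 0; i < n; ++i) global[i] = i;
  int cur_n = n;
  while (true) {
    LevelResult lvl = louvain_level(A, cur_n, rng);
    if (lvl.n_comm == cur_n) break;
    for (int i = 0; i < n; ++i) global[i] = lvl.membership[global[i]];
    int k = lvl.n_comm;
    std::vector<double> B((size_t)k * k, 0.0);
    for (int i = 0; i < cur_n; ++i)
      for (int j = 0; j < cur_n; ++j)
        B[lvl.membership[i] + (size_t)k * lvl.membership[j]] +=
            A[i + (size_t)cur_n * j];
    A.swap(B);
    cur_n = k;
    if (cur_n == 1) break;
  }
  return global;
}

static double modularity_flat(const std::vector<double>& A, int n,
                              const std::vector<int>& memb) {
  NumericMatrix M(n, n);
  std::copy(A.begin(), A.end(), M.begin());
  IntegerVector m(n);
  for (int i = 0; i < n; ++i) m[i] = memb[i] + 1;
  return cpp_modularity_signed(M, m);
}

// multilevel + flat refinement: re-run local moves on the original graph
// from the aggregated solution until modularity stops improving
static std::vector<int> louvain_run(const NumericMatrix& A0,
                                    std::mt19937& rng) {
  int n = A0.nrow();
  std::vector<double> A(A0.begin(), A0.end());
  std::vector<int> memb = louvain_multilevel(A, n, rng);
  double best_q = modularity_flat(A, n, memb);
  for (int pass = 0; pass < 10; ++pass) {
    LevelResult ref = louvain_level(A, n, rng, &memb);
    // multilevel on the aggregation of the refined flat partition
    int k = ref.n_comm;
    std::vector<double> B((size_t)k * k, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        B[ref.membership[i] + (size_t)k * ref.membership[j]] +=
            A[i + (size_t)n * j];
    std::vector<int> sub = louvain_multilevel(B, k, rng);
    std::vector<int> cand(n);
    for (int i = 0; i < n; ++i) cand[i] = sub[ref.membership[i]];
    double q = modularity_flat(A, n, cand);
    if (q > best_q + 1e-12) {
      best_q = q;
      memb = cand;
    } else {
      break;
    }
  }
  return memb;
}

// Louvain community detection with signed modularity; several random
// restarts (node orders seeded deterministically), best partition kept.
// [[Rcpp::export]]
List cpp_louvain_signed(NumericMatrix A, int n_restarts, int seed) {
  int n = A.nrow();
  if (A.ncol() != n) stop("adjacency must be square");
  double best_q = -1e300;
  IntegerVector best(n);
  for (int r = 0; r < n_restarts; ++r) {
    std::mt19937 rng((unsigned)(seed + 1000003 * r));
    std::vector<int> memb = louvain_run(A, rng);
    IntegerVector m(n);
    int k = 0;
    std::vector<int> remap(n, -1);
    for (int i = 0; i < n; ++i) {
      if (remap[memb[i]] < 0) remap[memb[i]] = k++;
      m[i] = remap[memb[i]] + 1;
    }
    double q = cpp_modularity_signed(A, m);
    if (q > best_q) { best_q = q; best = m; }
  }
  return List::create(_["membership"] = best, _["modularity"] = best_q);
}
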