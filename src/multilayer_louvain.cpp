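#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Multilayer modularity with ordinal (adjacent-layer) coupling:
//
//   Q = (1/2mu) [ sum_s sum_{i,j : g_is = g_js} (A_ijs - gamma k_is k_js / 2m_s)
//               + 2 omega sum_i sum_{s<T} 1{ g_is = g_i,s+1 } ]
//
// with k_is the strength of node i in layer s, 2m_s the total strength of
// layer s, and 2mu = sum_s 2m_s + 2 omega N (T-1).  The double sums run over
// ordered pairs (each undirected pair twice, i = j included in the null term).
// Layer weights must be non-negative (the caller applies the negative-weight
// policy before entry).

// Sliding-window Pearson correlation tensor.  x is T_scan x N (column-major),
// starts are 0-based window starts, all windows have the given width.  The
// cross-product matrix and column sums are updated incrementally between
// overlapping windows (one row leaves, `step` rows enter).
// [[Rcpp::export]]
NumericVector fc_tensor_cpp(NumericMatrix x, IntegerVector starts, int width) {
  const int Tscan = x.nrow(), N = x.ncol(), T = starts.size();
  if (T < 1) stop("no windows");
  NumericVector out(Dimension(N, N, T));
  double *o = REAL(out);
  const double *X = REAL(x);

  std::vector<double> P((size_t)N * N, 0.0), s(N, 0.0);
  int cur_lo = starts[0], cur_hi = starts[0];  // current half-open row range

  auto add_row = [&](int t, double sign) {
    for (int i = 0; i < N; ++i) {
      const double xi = X[t + (size_t)Tscan * i];
      s[i] += sign * xi;
      double *Pi = P.data() + (size_t)N * i;
      for (int j = 0; j <= i; ++j)
        Pi[j] += sign * xi * X[t + (size_t)Tscan * j];
    }
  };

  for (int w = 0; w < T; ++w) {
    const int lo = starts[w], hi = starts[w] + width;
    if (hi > Tscan) stop("window %d exceeds the scan", w + 1);
    // shrink/grow the maintained range to [lo, hi)
    for (; cur_lo < lo && cur_lo < cur_hi; ++cur_lo) add_row(cur_lo, -1.0);
    if (cur_hi < lo) { cur_lo = cur_hi = lo; }
    for (; cur_hi < hi; ++cur_hi) add_row(cur_hi, +1.0);

    double *layer = o + (size_t)N * N * w;
    std::vector<double> var(N);
    for (int i = 0; i < N; ++i) {
      var[i] = P[(size_t)N * i + i] - s[i] * s[i] / width;
      if (var[i] <= 1e-14 * width)
        stop("degenerate signal: node %d has zero variance in window [%d, %d)",
             i + 1, lo, hi);
    }
    for (int i = 0; i < N; ++i) {
      layer[(size_t)N * i + i] = 0.0;
      for (int j = 0; j < i; ++j) {
        const double cov = P[(size_t)N * i + j] - s[i] * s[j] / width;
        const double r = cov / std::sqrt(var[i] * var[j]);
        layer[(size_t)N * i + j] = r;
        layer[(size_t)N * j + i] = r;
      }
    }
  }
  return out;
}

static void layer_strengths(const double *A, int N, int T,
                            std::vector<double> &k, std::vector<double> &twom) {
  k.assign((size_t)N * T, 0.0);
  twom.assign(T, 0.0);
  for (int s = 0; s < T; ++s) {
    for (int i = 0; i < N; ++i) {
      const double *col = A + (size_t)N * i + (size_t)N * N * s;
      double ki = 0.0;
      for (int j = 0; j < N; ++j) ki += col[j];
      k[i + (size_t)N * s] = ki;
      twom[s] += ki;
    }
    if (!(twom[s] > 0.0))
      stop("degenerate layer: layer %d has zero total strength", s + 1);
  }
}

// [[Rcpp::export]]
double ml_modularity_cpp(NumericVector tensor, IntegerMatrix labels,
                         double gamma, double omega) {
  IntegerVector dims = tensor.attr("dim");
  const int N = dims[0], T = dims[2];
  if (labels.nrow() != N || labels.ncol() != T)
    stop("labels must be %d x %d", N, T);
  const double *A = REAL(tensor);

  std::vector<double> k, twom;
  layer_strengths(A, N, T, k, twom);
  double twomu = 0.0;
  for (int s = 0; s < T; ++s) twomu += twom[s];
  twomu += 2.0 * omega * N * (T - 1);

  double q = 0.0;
  // intra-layer term over ordered pairs, i = j included in the null term
  for (int s = 0; s < T; ++s) {
    for (int i = 0; i < N; ++i) {
      const int gi = labels(i, s);
      const double *col = A + (size_t)N * i + (size_t)N * N * s;
      const double ki = k[i + (size_t)N * s];
      for (int j = 0; j < N; ++j) {
        if (labels(j, s) == gi)
          q += col[j] - gamma * ki * k[j + (size_t)N * s] / twom[s];
      }
    }
  }
  // ordinal coupling, both directions
  for (int s = 0; s + 1 < T; ++s)
    for (int i = 0; i < N; ++i)
      if (labels(i, s) == labels(i, s + 1)) q += 2.0 * omega;
  return q / twomu;
}

// ---------------------------------------------------------------------------
// Generalized Louvain.  Two alternating greedy phases over the tensor:
//   * tuple sweeps   — move one node-layer tuple at a time (classic phase 1);
//   * community sweeps — move a whole community at a time, the same move
//     class as optimizing over the aggregated super-node graph, evaluated
//     directly against the tensor so the (dense) aggregated null-model
//     matrix is never materialized.
// Rounds alternate until neither phase finds an improving move.

struct Scratch {
  std::vector<double> val;
  std::vector<int> touched;
  explicit Scratch(size_t n) : val(n, 0.0) {}
  inline void add(int c, double w) {
    if (val[c] == 0.0 && w != 0.0) touched.push_back(c);
    val[c] += w;
  }
  inline void reset() {
    for (int c : touched) val[c] = 0.0;
    touched.clear();
  }
};

struct MLState {
  const double *A;
  int N, T;
  double gamma, omega, twomu, tolerance;
  std::vector<double> k, twom;
  std::vector<int> label;        // community of each tuple, size N*T
  std::vector<double> commK;     // commK[s * NT + c]: layer-s strength of c
  std::vector<double> q_trace;
  // sparse intra-layer adjacency per tuple (nonzero weights only)
  std::vector<size_t> nbr_off;
  std::vector<int> nbr_j;
  std::vector<double> nbr_w;

  size_t NT() const { return (size_t)N * T; }

  void build_adjacency() {
    const size_t nt = NT();
    nbr_off.assign(nt + 1, 0);
    size_t nnz = 0;
    for (size_t u = 0; u < nt; ++u) {
      const int i = u % N, s = u / N;
      const double *col = A + (size_t)N * i + (size_t)N * N * s;
      for (int j = 0; j < N; ++j)
        if (col[j] != 0.0 && j != i) ++nnz;
      nbr_off[u + 1] = nnz;
    }
    nbr_j.resize(nnz);
    nbr_w.resize(nnz);
    size_t pos = 0;
    for (size_t u = 0; u < nt; ++u) {
      const int i = u % N, s = u / N;
      const double *col = A + (size_t)N * i + (size_t)N * N * s;
      for (int j = 0; j < N; ++j)
        if (col[j] != 0.0 && j != i) {
          nbr_j[pos] = j;
          nbr_w[pos] = col[j];
          ++pos;
        }
    }
  }

  void rebuild_commK() {
    std::fill(commK.begin(), commK.end(), 0.0);
    for (int s = 0; s < T; ++s)
      for (int i = 0; i < N; ++i)
        commK[(size_t)s * NT() + label[i + (size_t)N * s]] +=
            k[i + (size_t)N * s];
  }
};

// one phase of single-tuple sweeps; returns moves made
static long tuple_phase(MLState &st, int max_sweeps, std::mt19937 &rng,
                        bool &converged) {
  const int N = st.N, T = st.T;
  const size_t NT = st.NT();
  std::vector<int> order(NT);
  for (size_t u = 0; u < NT; ++u) order[u] = (int)u;
  Scratch S(NT), C(NT);

  long total_moves = 0;
  converged = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::shuffle(order.begin(), order.end(), rng);
    long moves = 0;
    for (size_t u0 = 0; u0 < NT; ++u0) {
      const int u = order[u0];
      const int i = u % N, s = u / N;
      const int a = st.label[u];
      const double ki = st.k[i + (size_t)N * s];
      double *cK = st.commK.data() + (size_t)s * NT;

      S.reset();
      C.reset();
      const int *lab_s = st.label.data() + (size_t)N * s;
      for (size_t e = st.nbr_off[u]; e < st.nbr_off[u + 1]; ++e)
        S.add(lab_s[st.nbr_j[e]], st.nbr_w[e]);
      if (s > 0) C.add(st.label[i + (size_t)N * (s - 1)], st.omega);
      if (s + 1 < T) C.add(st.label[i + (size_t)N * (s + 1)], st.omega);

      // membership gain in community c (self terms excluded; the i = j null
      // term is community-independent and cancels)
      auto gain = [&](int c) {
        double Kc = cK[c];
        if (c == a) Kc -= ki;
        return S.val[c] + C.val[c] - st.gamma * ki * Kc / st.twom[s];
      };
      const double stay = gain(a);
      int best = a;
      double best_gain = stay;
      auto consider = [&](int c) {
        if (c == a) return;
        const double g = gain(c);
        if (g > best_gain + st.tolerance ||
            (g >= best_gain - st.tolerance && best != a && c < best)) {
          best = c;
          best_gain = g;
        }
      };
      for (int c : S.touched) consider(c);
      for (int c : C.touched) consider(c);

      if (best != a && best_gain - stay > st.tolerance) {
        cK[a] -= ki;
        cK[best] += ki;
        st.label[u] = best;
        st.q_trace.push_back(2.0 * (best_gain - stay) / st.twomu);
        ++moves;
      }
    }
    total_moves += moves;
    if (moves == 0) {
      converged = true;
      break;
    }
  }
  return total_moves;
}

// one phase of whole-community merge sweeps; returns merges made
static long community_phase(MLState &st, int max_sweeps, std::mt19937 &rng,
                            bool &converged) {
  const int N = st.N, T = st.T;
  const size_t NT = st.NT();
  Scratch S(NT);                    // edge + coupling weight to community d
  std::vector<int> cand;            // distinct candidate communities

  long total_merges = 0;
  converged = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // member lists of live communities
    std::vector<std::vector<int>> members(NT);
    for (size_t u = 0; u < NT; ++u) members[st.label[u]].push_back((int)u);
    std::vector<int> comms;
    for (size_t c = 0; c < NT; ++c)
      if (!members[c].empty()) comms.push_back((int)c);
    std::shuffle(comms.begin(), comms.end(), rng);

    long merges = 0;
    for (int a : comms) {
      if (members[a].empty()) continue;  // absorbed earlier this sweep
      S.reset();
      cand.clear();
      // accumulate edge weight and coupling from members of a to every
      // other community
      for (int u : members[a]) {
        const int i = u % N, s = u / N;
        const int *lab_s = st.label.data() + (size_t)N * s;
        for (size_t e = st.nbr_off[u]; e < st.nbr_off[u + 1]; ++e)
          S.add(lab_s[st.nbr_j[e]], st.nbr_w[e]);
        if (s > 0) S.add(st.label[i + (size_t)N * (s - 1)], st.omega);
        if (s + 1 < T) S.add(st.label[i + (size_t)N * (s + 1)], st.omega);
      }
      // layers occupied by a
      std::vector<int> layers;
      {
        int last = -1;
        std::vector<int> ls;
        for (int u : members[a]) ls.push_back(u / N);
        std::sort(ls.begin(), ls.end());
        for (int s : ls)
          if (s != last) { layers.push_back(s); last = s; }
      }
      // merge gain of a into d (internal terms of a are invariant)
      auto gain = [&](int d) {
        double null_term = 0.0;
        for (int s : layers) {
          const double Ka = st.commK[(size_t)s * NT + a];
          const double Kd = st.commK[(size_t)s * NT + d];
          null_term += Ka * Kd / st.twom[s];
        }
        return S.val[d] - st.gamma * null_term;
      };
      int best = -1;
      double best_gain = st.tolerance;
      for (int c : S.touched) {
        if (c == a) continue;
        const double g = gain(c);
        if (g > best_gain + st.tolerance ||
            (g >= best_gain - st.tolerance && best >= 0 && c < best)) {
          best = c;
          best_gain = g;
        }
      }
      if (best >= 0 && best_gain > st.tolerance) {
        for (int s : layers) {
          st.commK[(size_t)s * NT + best] += st.commK[(size_t)s * NT + a];
          st.commK[(size_t)s * NT + a] = 0.0;
        }
        for (int u : members[a]) st.label[u] = best;
        std::vector<int> &mb = members[best];
        mb.insert(mb.end(), members[a].begin(), members[a].end());
        members[a].clear();
        st.q_trace.push_back(2.0 * best_gain / st.twomu);
        ++merges;
      }
    }
    total_merges += merges;
    if (merges == 0) {
      converged = true;
      break;
    }
  }
  return total_merges;
}

// relabel to dense 0..C-1, preserving order of first appearance
static int compress(std::vector<int> &label) {
  std::vector<int> map(label.size(), -1);
  int next = 0;
  for (size_t u = 0; u < label.size(); ++u) {
    if (map[label[u]] < 0) map[label[u]] = next++;
    label[u] = map[label[u]];
  }
  return next;
}

// [[Rcpp::export]]
List ml_louvain_cpp(NumericVector tensor, double gamma, double omega, int seed,
                    int max_sweeps, double tolerance) {
  IntegerVector dims = tensor.attr("dim");
  MLState st;
  st.N = dims[0];
  st.T = dims[2];
  st.A = REAL(tensor);
  st.gamma = gamma;
  st.omega = omega;
  st.tolerance = tolerance;
  layer_strengths(st.A, st.N, st.T, st.k, st.twom);
  st.twomu = 0.0;
  for (int s = 0; s < st.T; ++s) st.twomu += st.twom[s];
  st.twomu += 2.0 * omega * st.N * (st.T - 1);

  const size_t NT = st.NT();
  st.label.resize(NT);
  for (size_t u = 0; u < NT; ++u) st.label[u] = (int)u;
  st.commK.assign((size_t)st.T * NT, 0.0);
  st.rebuild_commK();
  st.build_adjacency();

  std::mt19937 rng((uint32_t)seed);
  bool all_converged = true;
  int rounds = 0;
  for (int round = 0; round < max_sweeps; ++round) {
    bool conv_t = false, conv_c = false;
    long mt = tuple_phase(st, max_sweeps, rng, conv_t);
    long mc = community_phase(st, max_sweeps, rng, conv_c);
    all_converged = conv_t && conv_c;
    ++rounds;
    if (mt + mc == 0) break;
    if (round == max_sweeps - 1) all_converged = false;
  }

  compress(st.label);
  IntegerMatrix out(st.N, st.T);
  for (int s = 0; s < st.T; ++s)
    for (int i = 0; i < st.N; ++i)
      out(i, s) = st.label[i + (size_t)st.N * s] + 1;  // 1-based for R
  return List::create(
      _["labels"] = out, _["n_levels"] = rounds,
      _["converged"] = all_converged,
      _["q_trace"] = NumericVector(st.q_trace.begin(), st.q_trace.end()));
}
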