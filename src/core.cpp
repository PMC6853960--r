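#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Self-contained deterministic RNG (splitmix64-seeded xorshift128+), so
// corpora and embeddings depend only on the integer seed passed in, never on
// R's global RNG state.
struct XRng {
  uint64_t s[2];
  explicit XRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    if (s[0] == 0 && s[1] == 0) s[0] = 1;
  }
  uint64_t next() {
    uint64_t x = s[0], y = s[1];
    s[0] = y;
    x ^= x << 23;
    s[1] = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s[1] + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int next_int(int n) { return (int)(unif() * n); }
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Meta-path constrained random walks.
// adj: per node, a list of 3 integer vectors (1-based neighbor indices by
// type code). pattern: type codes of meta-path positions 2..L. Every
// attempted walk is returned (stuck walks truncated, completed = false);
// filtering is done in R.
// [[Rcpp::export]]
List cpp_generate_walks(const List& adj, const IntegerVector& starts,
                        const IntegerVector& pattern, int steps,
                        int walks_per_node, double seed) {
  const int n = adj.size();
  const int lm1 = pattern.size();
  const int target_len = steps * lm1 + 1;

  std::vector<std::vector<std::vector<int> > > A(n);
  for (int i = 0; i < n; ++i) {
    List per_type = adj[i];
    A[i].resize(per_type.size());
    for (int t = 0; t < per_type.size(); ++t) {
      IntegerVector nb = per_type[t];
      A[i][t].assign(nb.begin(), nb.end());
    }
  }

  XRng rng((uint64_t)seed);
  const int n_walks = starts.size() * walks_per_node;
  List walks(n_walks);
  LogicalVector completed(n_walks);
  IntegerVector start_of(n_walks);

  int w = 0;
  std::vector<int> buf;
  buf.reserve(target_len);
  for (int si = 0; si < starts.size(); ++si) {
    const int start = starts[si] - 1;
    for (int k = 0; k < walks_per_node; ++k, ++w) {
      buf.clear();
      buf.push_back(start + 1);
      int cur = start;
      bool stuck = false;
      for (int rep = 0; rep < steps && !stuck; ++rep) {
        for (int pos = 0; pos < lm1; ++pos) {
          const std::vector<int>& nb = A[cur][pattern[pos] - 1];
          if (nb.empty()) { stuck = true; break; }
          cur = nb[rng.next_int((int)nb.size())] - 1;
          buf.push_back(cur + 1);
        }
      }
      walks[w] = IntegerVector(buf.begin(), buf.end());
      completed[w] = ((int)buf.size() == target_len);
      start_of[w] = start + 1;
    }
  }
  return List::create(_["walks"] = walks, _["completed"] = completed,
                      _["start"] = start_of);
}

// Typed negative-sampling tables: one cumulative-weight array per node type.
struct NoiseTables {
  int K;
  std::vector<std::vector<int> > ids;      // node index per type
  std::vector<std::vector<double> > cum;   // cumulative weights per type
  NoiseTables(const IntegerVector& node_type, const NumericVector& w, int K_)
      : K(K_), ids(K_), cum(K_) {
    for (int i = 0; i < node_type.size(); ++i) {
      int t = node_type[i] - 1;
      ids[t].push_back(i);
      double prev = cum[t].empty() ? 0.0 : cum[t].back();
      cum[t].push_back(prev + w[i]);
    }
  }
  int draw(int t, XRng& rng) const {
    const std::vector<double>& c = cum[t];
    double x = rng.unif() * c.back();
    int lo = 0, hi = (int)c.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (c[mid] <= x) lo = mid + 1; else hi = mid;
    }
    return ids[t][lo];
  }
};

// One SGD step for a single (center, context) pair plus explicit negatives,
// identical to the update applied inside cpp_train_skipgram. Exposed so the
// analytic gradient can be checked against finite differences of the
// negative-sampling objective. All node arguments are 1-based row indices.
// [[Rcpp::export]]
NumericMatrix cpp_sgd_step(const NumericMatrix& X, int center, int context,
                           const IntegerVector& negatives, double lr,
                           double clamp) {
  NumericMatrix Y = clone(X);
  const int dim = Y.ncol();
  const int v = center - 1;
  std::vector<double> neu(dim, 0.0);
  const int M = negatives.size();
  for (int m = 0; m <= M; ++m) {
    const int u = (m == 0) ? (context - 1) : (negatives[m - 1] - 1);
    const double label = (m == 0) ? 1.0 : 0.0;
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += Y(u, d) * Y(v, d);
    if (dot > clamp) dot = clamp; else if (dot < -clamp) dot = -clamp;
    const double g = lr * (label - sigmoid(dot));
    for (int d = 0; d < dim; ++d) {
      neu[d] += g * Y(u, d);
      Y(u, d) += g * Y(v, d);
    }
  }
  for (int d = 0; d < dim; ++d) Y(v, d) += neu[d];
  return Y;
}

static double eval_objective(const std::vector<double>& X, int dim,
                             const std::vector<int>& ev, int negatives,
                             double clamp) {
  // ev holds triples/blocks: v, c, neg_1..neg_M
  const int block = 2 + negatives;
  const int n_pairs = (int)ev.size() / block;
  if (n_pairs == 0) return NA_REAL;
  double total = 0.0;
  for (int p = 0; p < n_pairs; ++p) {
    const double* xv = &X[(size_t)ev[p * block] * dim];
    double o = 0.0;
    for (int m = 0; m <= negatives; ++m) {
      const int u = ev[p * block + 1 + m];
      const double* xu = &X[(size_t)u * dim];
      double dot = 0.0;
      for (int d = 0; d < dim; ++d) dot += xu[d] * xv[d];
      if (dot > clamp) dot = clamp; else if (dot < -clamp) dot = -clamp;
      o += (m == 0) ? std::log(sigmoid(dot)) : std::log(sigmoid(-dot));
    }
    total += o;
  }
  return total / n_pairs;
}

// Heterogeneous skip-gram with typed negative sampling, trained by SGD over
// sliding-window (center, context) pairs from the walk corpus. Negatives are
// drawn from the context node's type with probability proportional to
// noise_weight (unigram counts already raised to the noise exponent in R).
// Returns the embedding matrix and the mean objective on a fixed held-out
// pair sample at initialization and after each epoch.
// [[Rcpp::export]]
List cpp_train_skipgram(const List& walks, const IntegerVector& node_type,
                        const NumericVector& noise_weight, int dim, int window,
                        int negatives, int epochs, double lr_init,
                        double lr_min, double seed, double clamp) {
  const int n = node_type.size();
  int K = 0;
  for (int i = 0; i < n; ++i) if (node_type[i] > K) K = node_type[i];
  NoiseTables noise(node_type, noise_weight, K);

  std::vector<std::vector<int> > W(walks.size());
  double pairs_per_epoch = 0.0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    W[i].resize(w.size());
    const int T = w.size();
    for (int j = 0; j < T; ++j) W[i][j] = w[j] - 1;
    // self-pairs (a node re-visited inside its own window) are excluded:
    // with a single shared table, log(sigmoid(x.x)) is self-reinforcing
    for (int j = 0; j < T; ++j) {
      const int lo = std::max(0, j - window), hi = std::min(T - 1, j + window);
      for (int k = lo; k <= hi; ++k) {
        if (k != j && W[i][k] != W[i][j]) pairs_per_epoch += 1.0;
      }
    }
  }
  const double total_pairs = pairs_per_epoch * std::max(epochs, 1);

  // init: uniform in [-0.5/dim, 0.5/dim]
  XRng rng_init((uint64_t)seed);
  std::vector<double> X((size_t)n * dim);
  for (size_t i = 0; i < X.size(); ++i) X[i] = (rng_init.unif() - 0.5) / dim;

  // held-out objective sample: a deterministic stride through the corpus
  XRng rng_eval((uint64_t)seed + 0x9e37ULL);
  std::vector<int> ev;
  {
    const int max_eval = 2000;
    long long stride = (long long)std::max(1.0, pairs_per_epoch / max_eval);
    long long pc = 0;
    for (size_t i = 0; i < W.size(); ++i) {
      const int T = (int)W[i].size();
      for (int j = 0; j < T; ++j) {
        int lo = std::max(0, j - window), hi = std::min(T - 1, j + window);
        for (int k = lo; k <= hi; ++k) {
          if (k == j || W[i][k] == W[i][j]) continue;
          if (pc++ % stride == 0) {
            ev.push_back(W[i][j]);
            ev.push_back(W[i][k]);
            int tc = node_type[W[i][k]] - 1;
            for (int m = 0; m < negatives; ++m) ev.push_back(noise.draw(tc, rng_eval));
          }
        }
      }
    }
  }

  NumericVector objective(epochs + 1);
  objective[0] = eval_objective(X, dim, ev, negatives, clamp);

  XRng rng((uint64_t)seed + 0x51f15ULL);
  std::vector<double> neu(dim);
  double processed = 0.0;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (size_t i = 0; i < W.size(); ++i) {
      const std::vector<int>& w = W[i];
      const int T = (int)w.size();
      for (int j = 0; j < T; ++j) {
        const int v = w[j];
        double* xv = &X[(size_t)v * dim];
        const int lo = std::max(0, j - window), hi = std::min(T - 1, j + window);
        for (int k = lo; k <= hi; ++k) {
          if (k == j || w[k] == v) continue;
          const int c = w[k];
          const int tc = node_type[c] - 1;
          double lr = lr_init * (1.0 - processed / total_pairs);
          if (lr < lr_min) lr = lr_min;
          processed += 1.0;
          std::fill(neu.begin(), neu.end(), 0.0);
          for (int m = 0; m <= negatives; ++m) {
            int u;
            double label;
            if (m == 0) {
              u = c; label = 1.0;
            } else {
              u = noise.draw(tc, rng);
              if (u == c) u = noise.draw(tc, rng);  // redraw once, then accept
              label = 0.0;
            }
            double* xu = &X[(size_t)u * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += xu[d] * xv[d];
            if (dot > clamp) dot = clamp; else if (dot < -clamp) dot = -clamp;
            const double g = lr * (label - sigmoid(dot));
            for (int d = 0; d < dim; ++d) {
              neu[d] += g * xu[d];
              xu[d] += g * xv[d];
            }
          }
          for (int d = 0; d < dim; ++d) xv[d] += neu[d];
        }
      }
    }
    objective[epoch + 1] = eval_objective(X, dim, ev, negatives, clamp);
  }

  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = X[(size_t)i * dim + d];
  return List::create(_["embedding"] = out, _["objective"] = objective);
}
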