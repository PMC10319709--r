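#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic single-threaded trainer: all randomness (subsampling,
// dynamic window radii, negative draws) comes from one xorshift64* stream
// seeded from R, so results are reproducible across platforms.
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  inline uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline int randint(int n) {  // uniform on 0..n-1
    return (int)(next() % (uint64_t)n);
  }
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List sgns_train_cpp(List sentences, NumericVector counts, double corpus_n,
                    int dim, int window, int negative, double subsample,
                    int epochs, double alpha0, double alpha_min, int seed) {
  const int V = counts.size();
  if (V < 2) stop("vocabulary must contain at least 2 tokens");
  XorShift64 rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

  // subsampling keep probabilities: min(1, sqrt(t / f)), f = count / N
  std::vector<double> keep(V);
  for (int v = 0; v < V; ++v) {
    double f = counts[v] / corpus_n;
    keep[v] = (subsample > 0 && f > subsample) ? std::sqrt(subsample / f) : 1.0;
  }

  // negative-sampling table on the unigram^(3/4) distribution
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(V);
    for (int v = 0; v < V; ++v) { pw[v] = std::pow(counts[v], 0.75); z += pw[v]; }
    int v = 0;
    double cum = pw[0] / z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1) cum += pw[++v] / z;
    }
  }

  // W ~ U(-0.5/d, 0.5/d); context vectors start at zero
  std::vector<double> W((size_t)V * dim), C((size_t)V * dim, 0.0);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (rng.unif() - 0.5) / dim;

  // pre-decode sentences
  const int S = sentences.size();
  std::vector<std::vector<int>> sents(S);
  double total_tokens = 0.0;
  for (int s = 0; s < S; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    total_tokens += sv.size();
  }
  if (total_tokens < 1) stop("empty corpus");

  NumericVector epoch_loss(epochs);
  std::vector<int> sen;
  std::vector<double> gacc(dim);
  double processed = 0.0;
  const double total_work = total_tokens * (double)epochs;

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    double n_pairs = 0.0;
    for (int s = 0; s < S; ++s) {
      const std::vector<int> &raw = sents[s];
      sen.clear();
      for (int t : raw) {
        ++processed;
        if (keep[t] >= 1.0 || rng.unif() < keep[t]) sen.push_back(t);
      }
      const int L = (int)sen.size();
      if (L < 2) continue;
      double alpha = alpha0 * (1.0 - processed / (total_work + 1.0));
      if (alpha < alpha_min) alpha = alpha_min;
      for (int i = 0; i < L; ++i) {
        const int w = sen[i];
        double *Ww = &W[(size_t)w * dim];
        const int b = 1 + rng.randint(window);  // dynamic radius in 1..window
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= L || j == i) continue;
          const int c = sen[j];
          std::fill(gacc.begin(), gacc.end(), 0.0);
          // positive pair
          {
            double *Cc = &C[(size_t)c * dim];
            double z = 0.0;
            for (int d = 0; d < dim; ++d) z += Ww[d] * Cc[d];
            double sg = sigmoid(z);
            loss_sum += -std::log(sg > 1e-10 ? sg : 1e-10);
            double g = (sg - 1.0) * alpha;  // d(-log sigma(z))/dz * alpha
            for (int d = 0; d < dim; ++d) {
              gacc[d] += g * Cc[d];
              Cc[d] -= g * Ww[d];
            }
          }
          // negatives from the unigram^0.75 table
          for (int k = 0; k < negative; ++k) {
            int n = table[rng.randint(table_size)];
            int tries = 0;
            while (n == c && ++tries < 10) n = table[rng.randint(table_size)];
            if (n == c) continue;
            double *Cn = &C[(size_t)n * dim];
            double z = 0.0;
            for (int d = 0; d < dim; ++d) z += Ww[d] * Cn[d];
            double sg = sigmoid(-z);
            loss_sum += -std::log(sg > 1e-10 ? sg : 1e-10);
            double g = sigmoid(z) * alpha;
            for (int d = 0; d < dim; ++d) {
              gacc[d] += g * Cn[d];
              Cn[d] -= g * Ww[d];
            }
          }
          for (int d = 0; d < dim; ++d) Ww[d] -= gacc[d];
          n_pairs += 1.0;
        }
      }
    }
    epoch_loss[e] = n_pairs > 0 ? loss_sum / n_pairs : NA_REAL;
  }

  NumericMatrix Wout(V, dim), Cout(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d) {
      Wout(v, d) = W[(size_t)v * dim + d];
      Cout(v, d) = C[(size_t)v * dim + d];
    }
  return List::create(_["W"] = Wout, _["C"] = Cout,
                      _["epoch_loss"] = epoch_loss);
}
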