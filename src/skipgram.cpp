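#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Skip-gram with negative sampling over a corpus of node-index walks.
// Single-threaded SGD driven by R's RNG, so results are reproducible
// under set.seed(). Indices in `walks` are 1-based.
// [[Rcpp::export]]
NumericMatrix skipgram_train_cpp(List walks, int vocab_size,
                                 IntegerVector counts, int d, int window,
                                 int negatives, int epochs, double alpha) {
  const int V = vocab_size;
  RNGScope scope;

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> cum(V);
  double total = 0.0;
  for (int i = 0; i < V; ++i) {
    total += std::pow((double)counts[i], 0.75);
    cum[i] = total;
  }

  // input vectors: small uniform init; context vectors: zeros
  std::vector<double> W((size_t)V * d), C((size_t)V * d, 0.0);
  for (size_t i = 0; i < W.size(); ++i)
    W[i] = (unif_rand() - 0.5) / d;

  long long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w)
    total_tokens += Rf_length(VECTOR_ELT(walks, w));
  long long budget = (long long)epochs * total_tokens;
  long long done = 0;

  std::vector<double> grad(d);
  const double min_alpha_frac = 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector walk = walks[w];
      int L = walk.size();
      for (int pos = 0; pos < L; ++pos) {
        double lr = alpha * std::max(min_alpha_frac,
                                     1.0 - (double)done / (double)budget);
        ++done;
        int center = walk[pos] - 1;
        int lo = std::max(0, pos - window);
        int hi = std::min(L - 1, pos + window);
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int ctx = walk[cpos] - 1;
          double *wc = &W[(size_t)center * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = unif_rand() * total;
              int t = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                            cum.begin());
              if (t >= V) t = V - 1;
              if (t == ctx) continue;
              target = t;
              label = 0.0;
            }
            double *ct = &C[(size_t)target * d];
            double dot = 0.0;
            for (int j = 0; j < d; ++j) dot += wc[j] * ct[j];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = lr * (label - pred);
            for (int j = 0; j < d; ++j) {
              grad[j] += g * ct[j];
              ct[j] += g * wc[j];
            }
          }
          for (int j = 0; j < d; ++j) wc[j] += grad[j];
        }
      }
    }
  }

  NumericMatrix out(V, d);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < d; ++j) out(i, j) = W[(size_t)i * d + j];
  return out;
}
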