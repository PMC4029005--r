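#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample a base sequence from an order-k Markov chain.
// cond: (4^k) x 4 matrix, row = context (base-4 encoding of the previous k
// bases, most recent base in the lowest digit), entries = P(next base | ctx).
// init: length-4 marginal used for the first k bases.
// u: n uniforms from R's RNG so that determinism is owned by set.seed().
// Returns 0-based base codes (0=A,1=C,2=G,3=T).
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(NumericMatrix cond, int order, int n,
                                NumericVector init, NumericVector u) {
  if (u.size() < n) stop("need n uniform draws");
  IntegerVector out(n);
  int ctx = 0;
  const int ncontext = cond.nrow();
  for (int i = 0; i < n; ++i) {
    double p = u[i];
    int b = 3;
    if (i < order) {
      double acc = 0.0;
      for (int j = 0; j < 4; ++j) {
        acc += init[j];
        if (p <= acc) { b = j; break; }
      }
    } else {
      double acc = 0.0;
      for (int j = 0; j < 4; ++j) {
        acc += cond(ctx, j);
        if (p <= acc) { b = j; break; }
      }
    }
    out[i] = b;
    if (order > 0) {
      ctx = (ctx * 4 + b) % ncontext;
    }
  }
  return out;
}

static inline int wrapdiff(int a, int b, int n, bool toroidal) {
  int d = a - b;
  if (d < 0) d = -d;
  if (toroidal && n - d < d) d = n - d;
  return d;
}

// Copy an R matrix (n x d, column-major) into a row-contiguous buffer of
// floats: row i occupies out[i*d .. i*d+d-1].  Single precision halves the
// memory traffic of the training loop; distance accumulation stays double.
static std::vector<float> to_rows(const NumericMatrix& m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<float> out((size_t)n * d);
  for (int c = 0; c < d; ++c) {
    const double* col = &m(0, c);
    for (int i = 0; i < n; ++i) out[(size_t)i * d + c] = (float)col[i];
  }
  return out;
}

// Squared distance with early abandonment, checked every 32 dimensions.
static inline double sqdist_bounded(const float* a, const float* b, int d,
                                    double bound) {
  double s = 0.0;
  int c = 0;
  while (c < d) {
    const int stop = (c + 32 < d) ? c + 32 : d;
    float acc = 0.0f;
    for (; c < stop; ++c) {
      const float diff = a[c] - b[c];
      acc += diff * diff;
    }
    s += acc;
    if (s >= bound) return s;
  }
  return s;
}

static int best_unit(const float* x, const std::vector<float>& W,
                     int m, int d, double* dist_out) {
  int best = 0;
  double bestd = R_PosInf;
  for (int j = 0; j < m; ++j) {
    const double s = sqdist_bounded(x, &W[(size_t)j * d], d, bestd);
    if (s < bestd) { bestd = s; best = j; }
  }
  *dist_out = bestd;
  return best;
}

// Online SOM training with Gaussian neighborhood and linear decay of the
// learning rate and radius over all presentation steps.
// X: n x d data; W0: m x d initial weights; pos: m x 2 (row, col) 0-based
// neuron grid coordinates; order: 0-based presentation sequence of length
// epochs * n.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix W0, IntegerMatrix pos,
                   int rows, int cols, IntegerVector order, int epochs,
                   double lr0, double lr1, double r0, double r1,
                   bool toroidal, bool record_qe) {
  const int n = X.nrow(), d = X.ncol(), m = W0.nrow();
  const int total = order.size();
  if (total != epochs * n) stop("presentation order must have epochs * n entries");

  std::vector<float> Xr = to_rows(X);
  std::vector<float> W = to_rows(W0);
  std::vector<int> pr(m), pc(m);
  for (int j = 0; j < m; ++j) { pr[j] = pos(j, 0); pc[j] = pos(j, 1); }

  NumericVector qe(record_qe ? epochs : 0);

  for (int t = 0; t < total; ++t) {
    const double frac = (total > 1) ? (double)t / (double)(total - 1) : 0.0;
    const double lr = lr0 + (lr1 - lr0) * frac;
    double sigma = r0 + (r1 - r0) * frac;
    if (sigma < 1e-9) sigma = 1e-9;

    const float* x = &Xr[(size_t)order[t] * d];
    double bd;
    const int best = best_unit(x, W, m, d, &bd);

    const int br = pr[best], bc = pc[best];
    const double cut2 = 9.0 * sigma * sigma;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    const int R = (int)std::ceil(3.0 * sigma);
    if (2 * R + 1 >= rows || 2 * R + 1 >= cols) {
      // neighborhood spans the grid: scan every neuron
      for (int j = 0; j < m; ++j) {
        const int dr = wrapdiff(pr[j], br, rows, toroidal);
        const int dc = wrapdiff(pc[j], bc, cols, toroidal);
        const double g2 = (double)(dr * dr + dc * dc);
        if (g2 > cut2) continue;
        const float h = (float)(lr * std::exp(-g2 * inv2s2));
        if (h < 1e-8f) continue;
        float* w = &W[(size_t)j * d];
        for (int c = 0; c < d; ++c) w[c] += h * (x[c] - w[c]);
      }
    } else {
      // small neighborhood: visit only the (2R+1)^2 window around the BMU
      for (int dr = -R; dr <= R; ++dr) {
        int rr = br + dr;
        if (toroidal) rr = (rr % rows + rows) % rows;
        else if (rr < 0 || rr >= rows) continue;
        for (int dc = -R; dc <= R; ++dc) {
          int cc = bc + dc;
          if (toroidal) cc = (cc % cols + cols) % cols;
          else if (cc < 0 || cc >= cols) continue;
          const double g2 = (double)(dr * dr + dc * dc);
          if (g2 > cut2) continue;
          const float h = (float)(lr * std::exp(-g2 * inv2s2));
          if (h < 1e-8f) continue;
          float* w = &W[(size_t)(rr * cols + cc) * d];
          for (int c = 0; c < d; ++c) w[c] += h * (x[c] - w[c]);
        }
      }
    }

    if (record_qe && ((t + 1) % n == 0)) {
      double s_all = 0.0;
      for (int q = 0; q < n; ++q) {
        double bq;
        best_unit(&Xr[(size_t)q * d], W, m, d, &bq);
        s_all += std::sqrt(bq);
      }
      qe[(t + 1) / n - 1] = s_all / n;
    }
  }

  NumericMatrix Wout(m, d);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < d; ++c) Wout(j, c) = W[(size_t)j * d + c];
  List out = List::create(_["weights"] = Wout);
  if (record_qe) out["qe_epochs"] = qe;
  return out;
}

// Best-matching unit for each row of X against weight matrix W.
// Returns 1-based neuron indices and the mean Euclidean distance (QE).
// [[Rcpp::export]]
List bmu_cpp(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), d = X.ncol(), m = W.nrow();
  std::vector<float> Xr = to_rows(X);
  std::vector<float> Wr = to_rows(W);
  IntegerVector bmu(n);
  double s_all = 0.0;
  for (int i = 0; i < n; ++i) {
    double bd;
    bmu[i] = best_unit(&Xr[(size_t)i * d], Wr, m, d, &bd) + 1;
    s_all += std::sqrt(bd);
  }
  return List::create(_["bmu"] = bmu, _["qe"] = s_all / n);
}
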