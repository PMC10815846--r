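#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Edge-level operations for a single attention head on a (possibly
// sample-batched) graph. Nodes are rows of Z; `recv`/`send` are 1-based
// directed edge endpoints: edge e carries a message send[e] -> recv[e].
// Every node is assumed to carry a self-loop, so every node occurs at
// least once on both sides and the per-receiver softmax is well defined.
// Internally node features are held in transposed (feature-contiguous)
// scratch buffers: edge traversal is random-access in the node index, and
// keeping a node's d features on one cache line dominates performance.

static std::vector<double> transpose_in(const NumericMatrix& X) {
  const int N = X.nrow(), d = X.ncol();
  std::vector<double> t((size_t)N * d);
  for (int k = 0; k < d; ++k) {
    const double* col = &X(0, k);
    for (int i = 0; i < N; ++i) t[(size_t)i * d + k] = col[i];
  }
  return t;
}

static NumericMatrix transpose_out(const std::vector<double>& t, int N,
                                   int d) {
  NumericMatrix X(N, d);
  for (int k = 0; k < d; ++k) {
    double* col = &X(0, k);
    for (int i = 0; i < N; ++i) col[i] = t[(size_t)i * d + k];
  }
  return X;
}

// [[Rcpp::export]]
List gat_edge_forward(const NumericMatrix& Z,
                      const NumericVector& s,
                      const NumericVector& t,
                      const IntegerVector& recv,
                      const IntegerVector& send,
                      double slope) {
  const int N = Z.nrow(), d = Z.ncol(), E = recv.size();
  std::vector<double> Zt = transpose_in(Z);
  NumericVector pre(E), w(E);
  NumericVector mx(N, R_NegInf), den(N);
  for (int e = 0; e < E; ++e) {
    const int r = recv[e] - 1;
    double v = s[r] + t[send[e] - 1];
    if (v < 0) v *= slope;
    pre[e] = v;
    if (v > mx[r]) mx[r] = v;
  }
  for (int e = 0; e < E; ++e) {
    const int r = recv[e] - 1;
    double x = std::exp(pre[e] - mx[r]);
    w[e] = x;
    den[r] += x;
  }
  NumericVector alpha(E);
  std::vector<double> outt((size_t)N * d, 0.0);
  for (int e = 0; e < E; ++e) {
    const int r = recv[e] - 1, sd = send[e] - 1;
    const double a = w[e] / den[r];
    alpha[e] = a;
    const double* zs = &Zt[(size_t)sd * d];
    double* orow = &outt[(size_t)r * d];
    for (int k = 0; k < d; ++k) orow[k] += a * zs[k];
  }
  return List::create(_["out"] = transpose_out(outt, N, d),
                      _["alpha"] = alpha, _["pre"] = pre);
}

// [[Rcpp::export]]
List gat_edge_backward(const NumericMatrix& Z,
                       const NumericVector& alpha,
                       const NumericVector& pre,
                       const IntegerVector& recv,
                       const IntegerVector& send,
                       double slope,
                       const NumericMatrix& dout) {
  const int N = Z.nrow(), d = Z.ncol(), E = recv.size();
  std::vector<double> Zt = transpose_in(Z), dot = transpose_in(dout);
  std::vector<double> dZt((size_t)N * d, 0.0);
  NumericVector dalpha(E), Sg(N), ds(N), dt(N);
  for (int e = 0; e < E; ++e) {
    const int r = recv[e] - 1, sd = send[e] - 1;
    const double a = alpha[e];
    const double* g = &dot[(size_t)r * d];
    const double* zs = &Zt[(size_t)sd * d];
    double* dzs = &dZt[(size_t)sd * d];
    double acc = 0.0;
    for (int k = 0; k < d; ++k) {
      acc += g[k] * zs[k];
      dzs[k] += a * g[k];  // gradient through the weighted aggregation
    }
    dalpha[e] = acc;
    Sg[r] += a * acc;
  }
  // softmax backward per receiver, then LeakyReLU backward
  for (int e = 0; e < E; ++e) {
    const int r = recv[e] - 1, sd = send[e] - 1;
    double de = alpha[e] * (dalpha[e] - Sg[r]);
    if (pre[e] < 0) de *= slope;
    ds[r] += de;
    dt[sd] += de;
  }
  return List::create(_["dZ"] = transpose_out(dZt, N, d),
                      _["ds"] = ds, _["dt"] = dt);
}
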