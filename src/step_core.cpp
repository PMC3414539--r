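#include <Rcpp.h>
using namespace Rcpp;

// Block integrator for the default interaction kernels.
//
// Runs up to nsteps synchronous explicit-Euler transactions:
//   dx_i = alpha_i * (m_i + x_i |m_i|)  +  sum_{j ~ i} f0(x_i, x_j)
//          +  (h/2)(1 - x_i)
// with f0(x_i, x_j) = sgn(x_i) * (|x_i + x_j| - |x_i - x_j|) / 2, sgn(0) = +1,
// and m = W x for a fixed long-range weight matrix W (rows pre-normalised by
// the caller when the public opinion is an average). Agents whose update
// reaches |x| >= 1 are clamped to the attained extreme and frozen; frozen
// agents never move but stay visible in m and in the pair sums. Stops early
// once every agent is frozen. The network (edges, W) is constant within a
// block; rewiring happens between blocks in R.
//
// [[Rcpp::export]]
List cpp_run_block(NumericVector opinion, LogicalVector frozen,
                   NumericVector attitude, IntegerMatrix edges0,
                   NumericMatrix W, double h, double dt, int nsteps) {
  int n = opinion.size();
  int m_edges = edges0.nrow();
  std::vector<double> x(opinion.begin(), opinion.end());
  std::vector<double> xnew(n);
  std::vector<double> m(n), pair_sum(n);
  std::vector<int> fz(n);
  int n_frozen = 0;
  for (int i = 0; i < n; ++i) {
    fz[i] = frozen[i] ? 1 : 0;
    if (fz[i]) ++n_frozen;
  }

  int steps = 0;
  for (int step = 0; step < nsteps && n_frozen < n; ++step) {
    // long-range public opinion m = W x
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += W(i, j) * x[j];
      m[i] = acc;
      pair_sum[i] = 0.0;
    }
    // pairwise discussion sums over the edge list
    for (int e = 0; e < m_edges; ++e) {
      int u = edges0(e, 0), v = edges0(e, 1);
      double core = (std::fabs(x[u] + x[v]) - std::fabs(x[u] - x[v])) / 2.0;
      pair_sum[u] += (x[u] >= 0 ? core : -core);
      pair_sum[v] += (x[v] >= 0 ? core : -core);
    }
    // synchronous Euler update with clamp-and-freeze
    for (int i = 0; i < n; ++i) {
      if (fz[i]) { xnew[i] = x[i]; continue; }
      double dx = attitude[i] * (m[i] + x[i] * std::fabs(m[i])) +
                  pair_sum[i] + 0.5 * h * (1.0 - x[i]);
      double xi = x[i] + dt * dx;
      if (std::fabs(xi) >= 1.0) {
        xnew[i] = (xi >= 0 ? 1.0 : -1.0);
        fz[i] = 1;
        ++n_frozen;
      } else {
        xnew[i] = xi;
      }
    }
    x.swap(xnew);
    ++steps;
  }

  NumericVector out_x(x.begin(), x.end());
  LogicalVector out_f(n);
  for (int i = 0; i < n; ++i) out_f[i] = fz[i] == 1;
  return List::create(_["opinion"] = out_x, _["frozen"] = out_f,
                      _["steps"] = steps);
}
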