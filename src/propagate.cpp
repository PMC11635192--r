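#include <Rcpp.h>
using namespace Rcpp;

// Time-stepping kernel for the chain simulator.  The state vector
// z = (v_1..v_n, s_1..s_n, 1) holds voltage deviations from rest, the
// per-compartment synaptic currents, and a homogeneous coordinate carrying
// constant inputs.  One step is the precomputed exact propagator P = expm(M dt);
// synaptic events add the kernel amplitude to s[target] at their step.
// [[Rcpp::export]]
NumericMatrix propagate_chain_cpp(const NumericMatrix& P, int n, int n_samples,
                                  const IntegerVector& spike_steps,
                                  const IntegerVector& spike_targets,
                                  double syn_amplitude) {
  const int m = P.nrow();
  if (P.ncol() != m || m != 2 * n + 1)
    stop("propagator must be square of size 2n+1");
  std::vector<double> z(m, 0.0), znew(m, 0.0);
  z[m - 1] = 1.0; // homogeneous coordinate
  NumericMatrix out(n, n_samples);
  const double* p = &P[0];
  int ev = 0;
  const int n_ev = spike_steps.size();
  for (int k = 0; k < n_samples; ++k) {
    while (ev < n_ev && spike_steps[ev] == k) {
      z[n + spike_targets[ev]] += syn_amplitude;
      ++ev;
    }
    for (int i = 0; i < n; ++i) out(i, k) = z[i];
    if (k + 1 == n_samples) break;
    // znew = P %*% z (column-major)
    std::fill(znew.begin(), znew.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      const double zj = z[j];
      if (zj == 0.0) continue;
      const double* col = p + (size_t)j * m;
      for (int i = 0; i < m; ++i) znew[i] += col[i] * zj;
    }
    std::swap(z, znew);
  }
  return out;
}
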