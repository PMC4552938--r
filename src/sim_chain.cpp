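#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the overdamped bead-spring chain
//   R(t+dt) = R(t) - D * grad phi(R) * dt + sqrt(2 D dt) * xi
// with phi = (1/2) R' A R per coordinate plus up to two harmonic wells.
//
// For tridiag = true (Rouse, beta = 2) the chain force is computed from the
// nearest-neighbour springs directly (O(N d) per step); otherwise the dense
// connectivity matrix A is applied (O(N^2 d) per step).
//
// Noise is drawn from R's RNG in coordinate-major order: within each step,
// all monomers of coordinate 1, then all monomers of coordinate 2, ...
// so that seeds set with set.seed() are portable across platforms.
//
// Returns a frames x (length(tagged) * d) matrix, columns grouped by tagged
// monomer (monomer-major: m1x, m1y, m1z, m2x, ...), plus the final chain.

// [[Rcpp::export]]
List sim_chain_cpp(NumericMatrix A, bool tridiag, double kappa,
                   IntegerVector well_n, NumericVector well_k,
                   NumericMatrix well_mu, NumericMatrix R0, double D,
                   double dt, int n_steps, int burn_in, int record_every,
                   IntegerVector tagged) {
  const int N = R0.nrow(), d = R0.ncol(), nw = well_n.size();
  const int nt = tagged.size();
  const double sq = std::sqrt(2.0 * D * dt);
  const long total = (long)burn_in + (long)n_steps * record_every;

  std::vector<double> R(N * d), F(N * d);  // column-major [coord][monomer]
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < N; ++i) R[j * N + i] = R0(i, j);

  NumericMatrix out(n_steps, nt * d);
  int rec = 0;

  for (long s = 0; s < total; ++s) {
    // internal chain force F = -A R (per coordinate)
    if (tridiag) {
      for (int j = 0; j < d; ++j) {
        const double *x = &R[j * N];
        double *f = &F[j * N];
        if (N == 1) { f[0] = 0.0; }
        else {
          f[0] = -kappa * (x[0] - x[1]);
          for (int i = 1; i < N - 1; ++i)
            f[i] = -kappa * (2.0 * x[i] - x[i - 1] - x[i + 1]);
          f[N - 1] = -kappa * (x[N - 1] - x[N - 2]);
        }
      }
    } else {
      for (int j = 0; j < d; ++j) {
        const double *x = &R[j * N];
        double *f = &F[j * N];
        for (int i = 0; i < N; ++i) {
          double acc = 0.0;
          for (int l = 0; l < N; ++l) acc += A(i, l) * x[l];
          f[i] = -acc;
        }
      }
    }
    // external wells: F_n += -k (R_n - mu)
    for (int w = 0; w < nw; ++w) {
      const int n0 = well_n[w] - 1;
      for (int j = 0; j < d; ++j)
        F[j * N + n0] -= well_k[w] * (R[j * N + n0] - well_mu(w, j));
    }
    // Euler step with fresh noise (coordinate-major draw order)
    for (int j = 0; j < d; ++j)
      for (int i = 0; i < N; ++i)
        R[j * N + i] += D * F[j * N + i] * dt + sq * norm_rand();

    long done = s + 1 - burn_in;
    if (done > 0 && done % record_every == 0) {
      for (int t = 0; t < nt; ++t) {
        const int m0 = tagged[t] - 1;
        for (int j = 0; j < d; ++j) {
          double v = R[j * N + m0];
          if (!std::isfinite(v) || std::fabs(v) > 1e6)
            stop("simulation diverged (|coordinate| > 1e6 b): time step too "
                 "large for this stiffness; reduce dt");
          out(rec, t * d + j) = v;
        }
      }
      ++rec;
      if (rec == n_steps) break;
    }
  }

  NumericMatrix Rfin(N, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < N; ++i) Rfin(i, j) = R[j * N + i];
  return List::create(_["positions"] = out, _["final"] = Rfin);
}
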