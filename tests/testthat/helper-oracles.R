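# Shared oracles, independent of the implementation paths they check.

# Nearest-neighbour Rouse spring Laplacian assembled by direct indexing.
oracle_rouse_laplacian <- function(N, kappa) {
  A <- matrix(0, N, N)
  for (j in seq_len(N)) {
    if (j > 1) { A[j, j - 1] <- A[j, j - 1] - kappa; A[j, j] <- A[j, j] + kappa }
    if (j < N) { A[j, j + 1] <- A[j, j + 1] - kappa; A[j, j] <- A[j, j] + kappa }
  }
  A
}

# Exact per-coordinate stationary covariance of the tethered quadratic chain:
# inverse of the precision matrix M = A + sum_w k_w e_n e_n'.
oracle_stationary_cov <- function(spec, wells) {
  M <- connectivity_matrix(spec)
  for (w in wells) M[w$n, w$n] <- M[w$n, w$n] + w$k
  solve(M)
}

# Mode-sum time-averaged MSD of monomer c for the free chain (COM included).
oracle_free_msd <- function(spec, c, times) {
  al <- mode_coefficients(spec)
  kt <- mode_stiffness(spec)
  d <- spec$d; D <- spec$D
  vapply(times, function(tt) {
    2 * d * D * tt / spec$N +
      sum(2 * d * al[-1L, c]^2 * (1 - exp(-D * kt[-1L] * tt)) / kt[-1L])
  }, 0)
}

# Small deterministic pseudo-trajectory for algebraic identity checks.
fixed_toy_track <- function(np = 40L, d = 3L) {
  P <- outer(seq_len(np), seq_len(d), function(i, j) sin(i * j / 3) + j)
  locus_trajectory(P, dt = 0.1)
}
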