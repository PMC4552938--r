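#' Define a bead-spring polymer model
#'
#' A `polymer_spec` collects the static parameters of a Rouse or beta-polymer
#' bead-spring chain. The Rouse chain (nearest-neighbour harmonic springs) is
#' the special case `beta = 2`; for `1 < beta < 2` the chain carries
#' long-range harmonic couplings chosen so that the intermediate-time
#' mean-square displacement of a monomer grows as `t^(1 - 1/beta)`.
#'
#' Natural units are used throughout: lengths in units of the inter-monomer
#' standard deviation `b`, energies in `kBT`, time in `b^2/D`. Stiffnesses
#' (`kappa` and well strengths) are therefore in `kBT/b^2`. Trajectories from
#' experiments may carry their own units (see [locus_trajectory()]); analytic
#' results then hold with `kBT` restored explicitly.
#'
#' @param N integer monomer count, at least 2.
#' @param beta structure exponent in (1, 2]; `2` is the Rouse chain.
#' @param kappa inter-monomer spring constant (kBT/b^2). The harmonic-spring
#'   identification `kappa = d*kBT/b^2` motivates typical values of 2-3, but
#'   `kappa` is a free parameter here, never derived from `d`.
#' @param b inter-monomer distance standard deviation (length unit).
#' @param D monomer diffusion coefficient (b^2 per unit time).
#' @param d spatial dimension, 2 or 3.
#'
#' @return An object of class `polymer_spec`.
#' @examples
#' sp <- polymer_spec(N = 30, kappa = 3)
#' mode_stiffness(sp)[1:4]
#' @export
polymer_spec <- function(N, beta = 2, kappa = 3, b = 1, D = 1, d = 3) {
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 2L)
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 1 && beta <= 2))
    stop("`beta` must lie in (1, 2]", call. = FALSE)
  if (!(is.numeric(kappa) && length(kappa) == 1L && kappa > 0))
    stop("`kappa` must be > 0", call. = FALSE)
  if (!(is.numeric(b) && length(b) == 1L && b > 0))
    stop("`b` must be > 0", call. = FALSE)
  if (!(is.numeric(D) && length(D) == 1L && D > 0))
    stop("`D` must be > 0", call. = FALSE)
  if (!(length(d) == 1L && d %in% c(2, 3)))
    stop("`d` must be 2 or 3", call. = FALSE)
  structure(
    list(N = N, beta = as.numeric(beta), kappa = as.numeric(kappa),
         b = as.numeric(b), D = as.numeric(D), d = as.integer(d)),
    class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  kind <- if (x$beta == 2) "Rouse" else sprintf("beta-polymer (beta = %g)", x$beta)
  cat(sprintf("<polymer_spec> %s chain: N = %d, kappa = %g kBT/b^2, b = %g, D = %g, d = %d\n",
              kind, x$N, x$kappa, x$b, x$D, x$d))
  invisible(x)
}

#' Normal-mode (cosine) basis of the chain
#'
#' Returns the orthogonal matrix of mode coefficients `alpha[p, c]` mapping
#' monomer coordinates onto the cosine normal modes that diagonalise the
#' chain connectivity. Row `p + 1` holds mode `p` (modes are numbered
#' `0..N-1`, monomers `1..N`):
#' `alpha[0, c] = 1/sqrt(N)` and
#' `alpha[p, c] = sqrt(2/N) * cos((c - 1/2) * p * pi / N)` for `p >= 1`.
#'
#' @param spec a [polymer_spec()].
#' @return `N x N` numeric matrix with `t(alpha) %*% alpha = I`. Row `p+1`,
#'   column `c` holds the coefficient of monomer `c` on mode `p`.
#' @seealso [mode_stiffness()], [connectivity_matrix()]
#' @export
mode_coefficients <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  N <- spec$N
  p <- 0:(N - 1L)
  cpos <- 1:N
  alpha <- sqrt(2 / N) * cos(outer(p, cpos - 0.5) * pi / N)
  alpha[1L, ] <- 1 / sqrt(N)
  dimnames(alpha) <- list(mode = p, monomer = cpos)
  alpha
}

#' Mode stiffnesses of the beta-polymer
#'
#' The connectivity quadratic form is diagonal in the cosine mode basis with
#' eigenvalues `kt_p = 4 * kappa * sin(p*pi/(2N))^beta`, `p = 0..N-1`.
#' Mode 0 (centre of mass) has stiffness exactly 0; for `beta = 2` the values
#' are the eigenvalues of the nearest-neighbour Rouse spring Laplacian.
#'
#' @inheritParams mode_coefficients
#' @return Numeric vector of length `N`, element `p + 1` holding `kt_p`.
#' @export
mode_stiffness <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  p <- 0:(spec$N - 1L)
  kt <- 4 * spec$kappa * sin(p * pi / (2 * spec$N))^spec$beta
  kt[1L] <- 0
  names(kt) <- p
  kt
}

#' Monomer-space connectivity matrix
#'
#' Assembles `A[j, k] = sum_p kt_p * alpha[p, j] * alpha[p, k]`, the spring
#' coupling matrix of the chain, so that the internal energy is
#' `(1/2) t(R) %*% A %*% R` per coordinate. For `beta = 2` this is exactly
#' the nearest-neighbour spring Laplacian (tridiagonal, off-diagonal
#' `-kappa`); for `beta < 2` every monomer pair is coupled, with strength
#' decaying along the chain. `A` is symmetric, positive semidefinite, and
#' each row sums to zero (translation invariance).
#'
#' @inheritParams mode_coefficients
#' @return `N x N` numeric matrix.
#' @export
connectivity_matrix <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  alpha <- mode_coefficients(spec)
  kt <- mode_stiffness(spec)
  A <- crossprod(alpha * sqrt(kt), alpha * sqrt(kt))
  # exact symmetry despite floating-point crossprod rounding
  A <- (A + t(A)) / 2
  dimnames(A) <- list(monomer = 1:spec$N, monomer = 1:spec$N)
  A
}

# Rouse nearest-neighbour Laplacian, assembled directly (used as the beta=2
# fast path by the simulator and as a reference form elsewhere).
rouse_laplacian <- function(N, kappa) {
  A <- diag(2 * kappa, N)
  A[1L, 1L] <- kappa
  A[N, N] <- kappa
  idx <- cbind(1:(N - 1L), 2:N)
  A[idx] <- -kappa
  A[idx[, 2:1]] <- -kappa
  A
}
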