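#' Effective spring constant for a single harmonic tether (Rouse chain)
#'
#' When monomer `n` of a Rouse chain is held in a harmonic well of strength
#' `k`, the conditional mean velocity of any monomer `c` is a linear
#' restoring drift `-D * k_cn * (x - mu)` with
#' `k_cn = k * kappa / (kappa + sep * k)`, `sep = |c - n|` counted in chain
#' links. The tether is felt at full strength at the tethered monomer
#' (`sep = 0` gives `k`) and is screened by the intervening chain as
#' `sep` grows; for a pinned monomer (`k >> kappa`) `k_cn ~ kappa / sep`.
#'
#' @param k well strength (kBT/length^2), `>= 0`.
#' @param kappa inter-monomer spring constant (same units), `> 0`.
#' @param sep integer chain separation `|c - n| >= 0` between the observed
#'   and the tethered monomer.
#' @return An object of class `effective_stiffness` with fields `value`,
#'   `model = "single-well"` and the echoed inputs.
#' @examples
#' effective_stiffness_single(k = 2, kappa = 3, sep = 15)$value  # 6/33
#' @export
effective_stiffness_single <- function(k, kappa, sep) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  sep <- as.integer(sep)
  stopifnot(length(sep) == 1L, sep >= 0L)
  value <- if (k == 0) 0 else k * kappa / (kappa + sep * k)
  new_effective_stiffness(value, "single-well",
                          list(k = k, kappa = kappa, sep = sep))
}

new_effective_stiffness <- function(value, model, inputs) {
  structure(list(value = value, model = model, inputs = inputs),
            class = "effective_stiffness")
}

#' @export
print.effective_stiffness <- function(x, ...) {
  cat(sprintf("<effective_stiffness> k_c = %.6g  (model: %s)\n", x$value, x$model))
  invisible(x)
}

#' Stationary variance of a tethered monomer
#'
#' At equilibrium the total positional variance of the observed monomer
#' (summed over the `d` coordinates, about its mean) equals `d / k_c` in
#' natural units, i.e. `d * kBT / k_c` in physical units -- the same
#' relation as for an Ornstein-Uhlenbeck particle in a well of stiffness
#' `k_c`.
#'
#' @param k_c effective spring constant, `> 0`.
#' @param d spatial dimension (2 or 3).
#' @return Total stationary variance (length^2).
#' @export
stationary_variance <- function(k_c, d) {
  kc <- if (inherits(k_c, "effective_stiffness")) k_c$value else k_c
  stopifnot(is.numeric(kc), length(kc) == 1L, length(d) == 1L, d %in% c(2, 3))
  if (kc <= 0) stop("`k_c` must be > 0", call. = FALSE)
  d / kc
}

validate_two_wells <- function(wells) {
  stopifnot(is.list(wells), length(wells) == 2L)
  if (!all(vapply(wells, inherits, TRUE, "well_spec")))
    stop("`wells` must be a list of two well_spec objects", call. = FALSE)
  if (wells[[1L]]$n >= wells[[2L]]$n)
    stop("wells must be ordered n < m with distinct monomers", call. = FALSE)
  wells
}

#' Mean steady-state position between (or beyond) two tethers
#'
#' For a Rouse chain with monomers `n < m` held in wells of strengths
#' `k_n, k_m` centred at `mu_n, mu_m`, the mean position of monomer `c` is
#' the well-centre average weighted by chain-screened stiffnesses:
#' \deqn{\langle R_c\rangle = \frac{\mu_n k_n(\kappa + |m-c| k_m) +
#'   \mu_m k_m(\kappa + |c-n| k_n)}{k_n k_m |m-n| + (k_n+k_m)\kappa}}
#' for `n < c < m`, and
#' \deqn{\langle R_c\rangle = \frac{k_n \mu_n \kappa +
#'   k_m \mu_m(\kappa + |m-n| k_n)}{k_n k_m |m-n| + \kappa(k_n+k_m)}}
#' for `n < m < c` (beyond both wells the mean no longer depends on `c`).
#' The mirror ordering `c < n < m` is obtained by relabelling the chain
#' end-to-end (reflection symmetry) before calling.
#'
#' @param wells list of two [well_spec()] objects, tether monomers `n < m`.
#' @param kappa inter-monomer spring constant.
#' @param c observed monomer index (must not be `c < n`).
#' @return Numeric `d`-vector, the mean position of monomer `c`.
#' @export
mean_position_two_wells <- function(wells, kappa, c) {
  wells <- validate_two_wells(wells)
  w1 <- wells[[1L]]; w2 <- wells[[2L]]
  n <- w1$n; m <- w2$n; kn <- w1$k; km <- w2$k
  stopifnot(length(c) == 1L, c == round(c))
  if (length(w1$mu) != length(w2$mu))
    stop("well centres must have the same dimension", call. = FALSE)
  if (c < n)
    stop("ordering c < n < m is not supported directly; relabel the chain ",
         "end-to-end (reflection symmetry) so that the observed monomer ",
         "lies between or beyond the wells", call. = FALSE)
  den <- kn * km * abs(m - n) + (kn + km) * kappa
  if (c <= m) {
    (w1$mu * kn * (kappa + abs(m - c) * km) +
       w2$mu * km * (kappa + abs(c - n) * kn)) / den
  } else {
    (kn * w1$mu * kappa + km * w2$mu * (kappa + abs(m - n) * kn)) / den
  }
}

#' Effective spring constant with two harmonic tethers
#'
#' For two wells on monomers `n < m` the conditional drift of monomer `c`
#' about its mean ([mean_position_two_wells()]) is again linear,
#' `-D * k_cnm * (x - <R_c>)`, and the stationary variance is `d / k_cnm`.
#' Between the wells (`n < c < m`) the stiffnesses add:
#' `k_cnm = k_cn + k_cm` with each term from
#' [effective_stiffness_single()]. Beyond both wells (`n < m < c`, equal
#' well strengths `k`):
#' \deqn{k_{cnm} = \frac{(2\kappa + |m-n|k) k \kappa}{\kappa^2 +
#'   |2c-m-n| k \kappa + |(m-n)(c-m)| k^2},}
#' which tends to `kappa / |c - m|` (distance to the nearest anchor only)
#' when `m - n >> 1` or `k >> kappa`.
#'
#' @inheritParams mean_position_two_wells
#' @return An `effective_stiffness` with `model = "two-well"`.
#' @export
effective_stiffness_two_wells <- function(wells, kappa, c) {
  wells <- validate_two_wells(wells)
  w1 <- wells[[1L]]; w2 <- wells[[2L]]
  n <- w1$n; m <- w2$n; kn <- w1$k; km <- w2$k
  stopifnot(length(c) == 1L, c == round(c))
  if (c < n)
    stop("ordering c < n < m is not supported directly; relabel the chain ",
         "end-to-end (reflection symmetry) first", call. = FALSE)
  if (c <= m) {
    value <- effective_stiffness_single(kn, kappa, abs(c - n))$value +
      effective_stiffness_single(km, kappa, abs(m - c))$value
  } else {
    if (!isTRUE(all.equal(kn, km)))
      stop("the n < m < c branch requires equal well strengths k_n = k_m",
           call. = FALSE)
    k <- kn
    value <- if (k == 0) 0 else
      (2 * kappa + abs(m - n) * k) * k * kappa /
        (kappa^2 + abs(2 * c - m - n) * k * kappa +
           abs((m - n) * (c - m)) * k^2)
  }
  new_effective_stiffness(value, "two-well",
                          list(n = n, m = m, k_n = kn, k_m = km,
                               kappa = kappa, c = c))
}

#' Generalized effective spring constant for the beta-polymer
#'
#' For a beta-polymer (long-range connectivity matrix `A` from
#' [connectivity_matrix()]) with one harmonic well of strength `k` on
#' monomer `n`, the energy is quadratic per coordinate with precision
#' matrix `M = A + k e_n e_n'`. The conditional drift of monomer `c` given
#' its own position is then governed by the Schur complement of `M` onto
#' index `c`,
#' `k_c = M[c,c] - M[c,-c] %*% solve(M[-c,-c]) %*% M[-c,c]`
#' (equivalently `1 / solve(M)[c,c]`), which for `beta = 2` reduces exactly
#' to [effective_stiffness_single()]. Smaller `beta` (stronger long-range
#' coupling) makes `k_c` decay more slowly with `|c - n|`.
#'
#' @param spec a [polymer_spec()].
#' @param well a [well_spec()] giving the tethered monomer and strength.
#' @param c observed monomer index in `1..N` (`c = n` allowed).
#' @return An `effective_stiffness` with `model = "beta"`.
#' @examples
#' sp <- polymer_spec(N = 100, beta = 2, kappa = 3)
#' effective_stiffness_beta(sp, well_spec(n = 50, k = 2), c = 70)$value # 6/43
#' @export
effective_stiffness_beta <- function(spec, well, c) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(well, "well_spec"))
  c <- as.integer(c)
  stopifnot(length(c) == 1L, c >= 1L, c <= spec$N)
  if (well$n > spec$N) stop("well monomer index exceeds N", call. = FALSE)
  if (well$k == 0)
    return(new_effective_stiffness(0, "beta",
                                   list(beta = spec$beta, N = spec$N,
                                        n = well$n, k = 0, kappa = spec$kappa,
                                        c = c)))
  M <- connectivity_matrix(spec)
  M[well$n, well$n] <- M[well$n, well$n] + well$k
  value <- unname(M[c, c] - drop(M[c, -c, drop = FALSE] %*%
                                 solve(M[-c, -c, drop = FALSE], M[-c, c])))
  new_effective_stiffness(value, "beta",
                          list(beta = spec$beta, N = spec$N, n = well$n,
                               k = well$k, kappa = spec$kappa, c = c))
}

#' Theoretical position autocorrelation of a tethered monomer
#'
#' Weak-coupling (mode-diagonal) approximation of the stationary
#' autocovariance of monomer `c` when monomer `n` sits in a well of
#' strength `k` (valid when `(alpha[p, n]^2 * k << kt_p`, i.e. `k < kappa`
#' and `N` not too small):
#' \deqn{C(t) = \frac{d}{k} e^{-D (\alpha_0^n)^2 k t} + \sum_{p\ge 1}
#'   \frac{d (\alpha_p^c)^2}{(\alpha_p^n)^2 k + \tilde\kappa_p}
#'   e^{-D ((\alpha_p^n)^2 k + \tilde\kappa_p) t}.}
#' The dominant (slowest) rate is `D * k / N`: the well strength is directly
#' readable from the tail decay when `D` is known. `C(0)` approximates the
#' stationary variance `d / k_cn`.
#'
#' @inheritParams effective_stiffness_beta
#' @param times numeric vector of lag times (same time unit as `D`).
#' @return An object of class `autocorr_result` (fields `lags`, `C`) with
#'   attribute `source = "theory"`.
#' @export
autocorrelation_theory <- function(spec, well, c, times) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(well, "well_spec"),
            is.numeric(times), all(times >= 0))
  if (well$k <= 0) stop("autocorrelation_theory requires a well with k > 0",
                        call. = FALSE)
  c <- as.integer(c)
  stopifnot(c >= 1L, c <= spec$N)
  alpha <- mode_coefficients(spec)
  kt <- mode_stiffness(spec)
  d <- spec$d; D <- spec$D; k <- well$k; n <- well$n
  rates <- D * (alpha[, n]^2 * k + kt)
  amps <- d * alpha[, c]^2 / (alpha[, n]^2 * k + kt)
  # p = 0 term: amplitude d/k, rate D k / N
  amps[1L] <- d / k
  C <- as.vector(exp(-outer(times, rates)) %*% amps)
  structure(list(lags = times, C = C), class = "autocorr_result",
            source = "theory")
}

#' Relaxation time of a chain segment
#'
#' Equilibration time of the portion of chain between the tether and the
#' observed monomer, `tau_r = sep^beta / (D * kappa * pi^beta)`. Trajectories
#' much longer than `tau_r` are required for equilibrium-based estimators
#' (variance inversion); drift-based estimators remain usable on shorter
#' records.
#'
#' @param sep chain separation `|c - n| >= 1` (links).
#' @param beta structure exponent in (1, 2].
#' @param kappa inter-monomer spring constant.
#' @param D monomer diffusion coefficient.
#' @return Relaxation time (time units of `D`).
#' @export
relaxation_time <- function(sep, beta = 2, kappa = 3, D = 1) {
  stopifnot(sep >= 1, beta > 1, beta <= 2, kappa > 0, D > 0)
  sep^beta / (D * kappa * pi^beta)
}

#' Anomalous MSD exponent of the beta-polymer
#'
#' A monomer of a free beta-polymer shows subdiffusive mean-square
#' displacement `~ t^alpha` at intermediate times with `alpha = 1 - 1/beta`;
#' the Rouse value is 1/2.
#'
#' @param beta structure exponent in (1, 2].
#' @return The exponent `alpha` in (0, 1/2].
#' @export
anomalous_exponent <- function(beta) {
  if (!(is.numeric(beta) && all(beta > 1 & beta <= 2)))
    stop("`beta` must lie in (1, 2]", call. = FALSE)
  1 - 1 / beta
}
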