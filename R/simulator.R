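#' Define an external harmonic tethering well
#'
#' A tethering well models a stationary local interaction (anchoring at a
#' nuclear pore, spindle pole body, another chromosome, ...) as the quadratic
#' approximation `U = (k/2) * (R_n - mu)^2` of the interaction potential,
#' applied to a single monomer `n`.
#'
#' @param n tethered monomer index (1-based along the chain).
#' @param k well strength (kBT/b^2), `>= 0`.
#' @param mu well centre, numeric vector of length `d` (default the origin
#'   in 3D).
#' @return An object of class `well_spec`.
#' @export
well_spec <- function(n, k, mu = c(0, 0, 0)) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L, is.numeric(k), length(k) == 1L, k >= 0,
            is.numeric(mu), length(mu) %in% c(2L, 3L))
  structure(list(n = n, k = as.numeric(k), mu = as.numeric(mu)),
            class = "well_spec")
}

#' @export
print.well_spec <- function(x, ...) {
  cat(sprintf("<well_spec> monomer %d, k = %g, mu = (%s)\n",
              x$n, x$k, paste(format(x$mu), collapse = ", ")))
  invisible(x)
}

#' Simulation settings
#'
#' @param dt integration time step (b^2/D units); must satisfy
#'   `dt < 0.2 / (D * lambda_max)` where `lambda_max` is the largest
#'   eigenvalue of the connectivity matrix plus the strongest well -- checked
#'   at simulation time.
#' @param n_steps number of recorded frames.
#' @param burn_in discarded equilibration steps; `NULL` (default) chooses
#'   `ceiling(10 * tau_r / dt)` with `tau_r` from [relaxation_time()] using
#'   the chain half-length for a free chain, or the largest chain distance
#'   from the first well to an end for a tethered one.
#' @param seed integer RNG seed (`set.seed()` is called when non-`NULL`);
#'   identical seed and config give bit-identical trajectories.
#' @param record_every record one frame every this many integration steps
#'   (frame interval is `dt * record_every`).
#' @param init initial configuration policy: `"well-centered"` (random-walk
#'   chain with bond sd `b` started at the first well centre, or the origin
#'   for a free chain), `"random-walk"` (started at the origin), or
#'   `"explicit"` (supply `init_positions`).
#' @param init_positions `N x d` matrix of starting positions when
#'   `init = "explicit"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, n_steps = 10000L, burn_in = NULL,
                       seed = NULL, record_every = 1L,
                       init = c("well-centered", "random-walk", "explicit"),
                       init_positions = NULL) {
  init <- match.arg(init)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            length(n_steps) == 1L, n_steps >= 2,
            length(record_every) == 1L, record_every >= 1)
  if (!is.null(burn_in)) stopifnot(length(burn_in) == 1L, burn_in >= 0)
  if (init == "explicit" && is.null(init_positions))
    stop("`init_positions` required when init = \"explicit\"", call. = FALSE)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 burn_in = if (is.null(burn_in)) NULL else as.integer(burn_in),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 record_every = as.integer(record_every),
                 init = init, init_positions = init_positions),
            class = "sim_config")
}

default_burn_in <- function(spec, wells, dt) {
  sep <- if (length(wells) == 0L) {
    max(1L, spec$N %/% 2L)
  } else {
    n1 <- wells[[1L]]$n
    max(1L, n1 - 1L, spec$N - n1)
  }
  tau <- relaxation_time(sep, spec$beta, spec$kappa, spec$D)
  as.integer(ceiling(10 * tau / dt))
}

init_chain <- function(spec, wells, config) {
  N <- spec$N; d <- spec$d
  if (config$init == "explicit") {
    R0 <- as.matrix(config$init_positions)
    if (!all(dim(R0) == c(N, d)))
      stop("`init_positions` must be an N x d matrix", call. = FALSE)
    return(R0)
  }
  origin <- if (config$init == "well-centered" && length(wells) > 0L) {
    mu <- wells[[1L]]$mu
    if (length(mu) != d) stop("well centre dimension != d", call. = FALSE)
    mu
  } else rep(0, d)
  steps <- matrix(stats::rnorm(N * d, sd = spec$b / sqrt(d)), N, d)
  steps[1L, ] <- 0
  sweep(apply(steps, 2L, cumsum), 2L, origin, `+`)
}

check_wells <- function(spec, wells) {
  if (inherits(wells, "well_spec")) wells <- list(wells)
  stopifnot(is.list(wells), length(wells) <= 2L)
  for (w in wells) {
    stopifnot(inherits(w, "well_spec"))
    if (w$n > spec$N) stop("well monomer index exceeds N", call. = FALSE)
    if (length(w$mu) != spec$d)
      stop("well centre dimension does not match spec$d", call. = FALSE)
  }
  wells
}

#' Potential energy of one chain configuration
#'
#' `phi(R) = (kappa/2) * sum_j (R_j - R_{j-1})^2 + sum_wells (k/2)(R_n - mu)^2`
#' for the Rouse chain; for `beta < 2` the chain term is the quadratic form
#' `(1/2) sum_coord t(R) %*% A %*% R` with `A` from [connectivity_matrix()]
#' (the two agree at `beta = 2`).
#'
#' @param positions `N x d` matrix, one chain configuration.
#' @param spec a [polymer_spec()].
#' @param wells list of 0-2 [well_spec()] objects (a bare `well_spec` is
#'   accepted).
#' @return Scalar energy in kBT.
#' @export
potential_energy <- function(positions, spec, wells = list()) {
  stopifnot(inherits(spec, "polymer_spec"))
  positions <- as.matrix(positions)
  if (!all(dim(positions) == c(spec$N, spec$d)))
    stop("`positions` must be an N x d matrix", call. = FALSE)
  wells <- check_wells(spec, wells)
  if (spec$beta == 2) {
    dR <- diff(positions)
    e <- spec$kappa / 2 * sum(dR * dR)
  } else {
    A <- connectivity_matrix(spec)
    e <- sum(vapply(seq_len(spec$d),
                    function(j) drop(positions[, j] %*% A %*% positions[, j]),
                    0)) / 2
  }
  for (w in wells) e <- e + w$k / 2 * sum((positions[w$n, ] - w$mu)^2)
  e
}

#' Total force on every monomer
#'
#' The negative gradient of [potential_energy()]: internal chain forces
#' `-A %*% R` per coordinate plus, on each tethered monomer, the well force
#' `-k * (R_n - mu)`. For an interior Rouse monomer the chain force is
#' `-kappa * (2 R_c - R_{c-1} - R_{c+1})`.
#'
#' @inheritParams potential_energy
#' @return `N x d` matrix of forces (kBT/b).
#' @export
total_force <- function(positions, spec, wells = list()) {
  stopifnot(inherits(spec, "polymer_spec"))
  positions <- as.matrix(positions)
  if (!all(dim(positions) == c(spec$N, spec$d)))
    stop("`positions` must be an N x d matrix", call. = FALSE)
  wells <- check_wells(spec, wells)
  A <- if (spec$beta == 2) rouse_laplacian(spec$N, spec$kappa)
       else connectivity_matrix(spec)
  FF <- -A %*% positions
  for (w in wells)
    FF[w$n, ] <- FF[w$n, ] - w$k * (positions[w$n, ] - w$mu)
  unname(FF)
}

max_rate <- function(spec, wells) {
  # largest eigenvalue of A is 4*kappa*sin((N-1)pi/2N)^beta; add strongest well
  lam <- max(mode_stiffness(spec))
  kmax <- if (length(wells)) max(vapply(wells, `[[`, 0, "k")) else 0
  spec$D * (lam + kmax)
}

#' Brownian (Euler-Maruyama) simulation of the tethered chain
#'
#' Integrates the overdamped Langevin dynamics
#' `R(t + dt) = R(t) - D * grad(phi) * dt + sqrt(2 D dt) * xi`
#' with i.i.d. standard normal `xi` per coordinate, for a chain defined by
#' `spec` with 0-2 external harmonic wells. The first recorded frame follows
#' the burn-in; frames are `dt * record_every` apart. Runs are
#' bit-reproducible for a fixed `config$seed`. The integration aborts if any
#' coordinate exceeds `1e6 * b` (unstable time step).
#'
#' @param spec a [polymer_spec()].
#' @param wells list of 0-2 [well_spec()] objects.
#' @param config a [sim_config()].
#' @param tagged integer vector of monomer indices to record (default all);
#'   recording only the observed loci keeps long runs small.
#' @return A `polymer_trajectory`: list with `positions` (array
#'   `frames x length(tagged) x d`, monomer dimension named by chain index),
#'   `dt` (frame interval), `spec`, `wells`, `config`, `seed`.
#' @examples
#' sp <- polymer_spec(N = 10, kappa = 3, d = 3)
#' tr <- simulate_polymer(sp, list(well_spec(1, k = 2)),
#'                        sim_config(n_steps = 500, seed = 1), tagged = c(1, 5))
#' dim(tr$positions)
#' @export
simulate_polymer <- function(spec, wells = list(), config = sim_config(),
                             tagged = NULL) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(config, "sim_config"))
  wells <- check_wells(spec, wells)
  if (is.null(tagged)) tagged <- seq_len(spec$N)
  tagged <- as.integer(tagged)
  stopifnot(all(tagged >= 1L), all(tagged <= spec$N))

  if (config$dt >= 0.2 / max_rate(spec, wells))
    stop(sprintf(paste0("dt = %g exceeds the stability bound 0.2/(D*lambda_max)",
                        " = %g for this chain"),
         config$dt, 0.2 / max_rate(spec, wells)), call. = FALSE)
  burn_in <- if (is.null(config$burn_in)) default_burn_in(spec, wells, config$dt)
             else config$burn_in
  if (!is.null(config$seed)) set.seed(config$seed)
  R0 <- init_chain(spec, wells, config)

  tri <- spec$beta == 2
  A <- if (tri) matrix(0, 1, 1) else connectivity_matrix(spec)
  nw <- length(wells)
  wn <- if (nw) vapply(wells, `[[`, 0L, "n") else integer(0)
  wk <- if (nw) vapply(wells, `[[`, 0, "k") else numeric(0)
  wmu <- if (nw) do.call(rbind, lapply(wells, `[[`, "mu"))
         else matrix(0, 0, spec$d)

  res <- sim_chain_cpp(A, tri, spec$kappa, wn, wk, wmu, R0, spec$D,
                       config$dt, config$n_steps, burn_in,
                       config$record_every, tagged)
  pos <- array(res$positions,
               dim = c(config$n_steps, spec$d, length(tagged)))
  pos <- aperm(pos, c(1L, 3L, 2L))
  dimnames(pos) <- list(NULL, monomer = tagged,
                        coord = c("x", "y", "z")[seq_len(spec$d)])
  structure(list(positions = pos, dt = config$dt * config$record_every,
                 spec = spec, wells = wells, config = config,
                 burn_in = burn_in, seed = config$seed,
                 tagged = tagged, final = res$final),
            class = "polymer_trajectory")
}

#' @export
print.polymer_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<polymer_trajectory> %d frames x %d monomer(s) x %dD, ",
                     "frame interval %g, %d well(s)\n"),
              dim(x$positions)[1L], dim(x$positions)[2L], dim(x$positions)[3L],
              x$dt, length(x$wells)))
  invisible(x)
}

#' Mode-space simulation of the free beta-polymer
#'
#' Integrates the decoupled normal modes of the free chain,
#' `du_p = -D * kt_p * u_p dt + sqrt(2 D) dW_p`, with the same
#' Euler-Maruyama discretisation and step as [simulate_polymer()] (the
#' recursion is evaluated with [stats::filter()] per mode and coordinate),
#' then maps back to monomer space through [mode_coefficients()]. Mode 0 is
#' the free diffusion of the centre of mass (coefficient `D/N`); modes
#' `p >= 1` are Ornstein-Uhlenbeck with stationary variance `1/kt_p` per
#' coordinate, from which they are initialised. External wells couple the
#' modes and are refused -- use [simulate_polymer()] for tethered chains.
#'
#' Noise is drawn as one block per coordinate (modes varying fastest within
#' a frame), so fixed seeds are portable.
#'
#' @inheritParams simulate_polymer
#' @return A `polymer_trajectory` (same layout as [simulate_polymer()]).
#' @export
simulate_modes <- function(spec, config = sim_config(), tagged = NULL,
                           wells = list()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(config, "sim_config"))
  if (length(wells) > 0L)
    stop("simulate_modes() handles the free chain only: external wells ",
         "couple the modes; use simulate_polymer()", call. = FALSE)
  if (is.null(tagged)) tagged <- seq_len(spec$N)
  tagged <- as.integer(tagged)
  stopifnot(all(tagged >= 1L), all(tagged <= spec$N))
  if (config$dt >= 0.2 / max_rate(spec, list()))
    stop("dt exceeds the stability bound 0.2/(D*lambda_max)", call. = FALSE)

  N <- spec$N; d <- spec$d; D <- spec$D; dt <- config$dt
  kt <- mode_stiffness(spec)
  phi <- 1 - D * kt * dt
  burn_in <- if (is.null(config$burn_in)) default_burn_in(spec, list(), config$dt)
             else config$burn_in
  total <- burn_in + config$n_steps * config$record_every
  if (!is.null(config$seed)) set.seed(config$seed)

  alpha <- mode_coefficients(spec)
  keep <- burn_in + seq(config$record_every, by = config$record_every,
                        length.out = config$n_steps)
  pos <- array(NA_real_, dim = c(config$n_steps, length(tagged), d))
  sd_eps <- sqrt(2 * D * dt)
  for (j in seq_len(d)) {
    # stationary start for internal modes, centre of mass at the origin;
    # modes are integrated one at a time (noise stream: axes outermost,
    # then modes, time fastest) and accumulated at the recorded frames only
    u0 <- c(0, stats::rnorm(N - 1L, sd = sqrt(1 / kt[-1L])))
    acc <- matrix(0, config$n_steps, length(tagged))
    for (p in seq_len(N)) {
      eps <- stats::rnorm(total, sd = sd_eps)
      u <- stats::filter(eps, phi[p], method = "recursive",
                         init = u0[p])  # u[1] = phi*u0 + eps[1]
      acc <- acc + tcrossprod(as.numeric(u)[keep], alpha[p, tagged])
    }
    pos[, , j] <- acc
  }
  dimnames(pos) <- list(NULL, monomer = tagged,
                        coord = c("x", "y", "z")[seq_len(d)])
  structure(list(positions = pos, dt = dt * config$record_every, spec = spec,
                 wells = list(), config = config, burn_in = burn_in,
                 seed = config$seed, tagged = tagged, final = NULL),
            class = "polymer_trajectory")
}

#' Simulate an Ornstein-Uhlenbeck locus
#'
#' Exact sampling of a single particle in a harmonic well,
#' `dR = -D k (R - mu) dt + sqrt(2D) dW`, at frame interval `dt` (the
#' transition kernel is Gaussian, so no discretisation error). This is the
#' effective one-particle model that a tethered locus is often reduced to;
#' its stationary variance is `1/k` per axis and its position
#' autocorrelation decays as a single exponential with rate `D k`. Useful
#' as a ground-truth generator for the estimators.
#'
#' @param k well strength (> 0), `kBT/length^2`.
#' @param D diffusion coefficient.
#' @param d spatial dimension (1-3).
#' @param dt frame interval.
#' @param n_steps number of recorded frames.
#' @param mu well centre (length `d`).
#' @param seed optional RNG seed.
#' @param x0 starting position; default drawn from the stationary law.
#' @return A [locus_trajectory()] labelled `"ou"`.
#' @export
simulate_ou <- function(k, D = 1, d = 3, dt = 0.01, n_steps = 10000L,
                        mu = rep(0, d), seed = NULL, x0 = NULL) {
  stopifnot(k > 0, D > 0, d %in% 1:3, length(mu) == d)
  if (!is.null(seed)) set.seed(seed)
  phi <- exp(-D * k * dt)
  sd_st <- sqrt(1 / k)
  if (is.null(x0)) x0 <- mu + stats::rnorm(d, sd = sd_st)
  eps <- matrix(stats::rnorm(n_steps * d, sd = sd_st * sqrt(1 - phi^2)),
                n_steps, d, byrow = TRUE)
  P <- vapply(seq_len(d), function(j)
    as.numeric(stats::filter(eps[, j], phi, method = "recursive",
                             init = x0[j] - mu[j])),
    numeric(n_steps))
  P <- sweep(matrix(P, n_steps, d), 2L, mu, `+`)
  locus_trajectory(P, dt = dt, units = "b", time_unit = "b^2/D", label = "ou")
}

#' Extract the trajectory of one tagged monomer
#'
#' @param traj a `polymer_trajectory`.
#' @param c monomer index (must be among the recorded monomers).
#' @return A [locus_trajectory()] in natural units (`b`, `b^2/D`).
#' @export
tagged_locus <- function(traj, c) {
  stopifnot(inherits(traj, "polymer_trajectory"))
  idx <- match(as.integer(c), traj$tagged)
  if (is.na(idx))
    stop(sprintf("monomer %d was not recorded (tagged: %s)", c,
                 paste(traj$tagged, collapse = ", ")), call. = FALSE)
  locus_trajectory(traj$positions[, idx, ], dt = traj$dt,
                   units = "b", time_unit = "b^2/D",
                   label = sprintf("monomer%d", c))
}
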