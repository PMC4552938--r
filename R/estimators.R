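#' A single-locus trajectory
#'
#' Time-ordered positions of one tagged locus (e.g. a GFP-labelled
#' chromosomal site) sampled at a fixed frame interval, as produced by
#' particle tracking or by [simulate_polymer()]/[tagged_locus()].
#'
#' @param positions numeric `N_p x d` matrix (columns are coordinates; a
#'   plain vector is treated as 1D); all values must be finite.
#' @param dt frame interval (time units).
#' @param units length unit of the coordinates (`"b"` for natural units or
#'   e.g. `"um"` for microscopy data). Stiffness estimates are reported in
#'   `kBT/units^2`.
#' @param time_unit time unit of `dt` (e.g. `"s"`, or `"b^2/D"`).
#' @param label optional identifier (e.g. a cell id).
#' @return An object of class `locus_trajectory`.
#' @export
locus_trajectory <- function(positions, dt, units = "b", time_unit = "b^2/D",
                             label = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    stop("trajectory contains non-finite coordinates", call. = FALSE)
  stopifnot(nrow(positions) >= 2L, ncol(positions) >= 1L, ncol(positions) <= 3L,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  structure(list(positions = positions, dt = as.numeric(dt),
                 units = units, time_unit = time_unit, label = label),
            class = "locus_trajectory")
}

#' @export
print.locus_trajectory <- function(x, ...) {
  cat(sprintf("<locus_trajectory>%s %d frames x %dD, dt = %g %s, units %s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$positions), ncol(x$positions), x$dt, x$time_unit, x$units))
  invisible(x)
}

#' Select coordinate axes of a trajectory
#'
#' Microscopy localisation is typically less precise axially than laterally;
#' experimental analyses therefore often use only the x-y projection. For an
#' isotropic tether the projection changes `d` but not the expected
#' stiffness.
#'
#' @param traj a [locus_trajectory()].
#' @param axes character subset of `c("x", "y", "z")` or column indices.
#' @return A [locus_trajectory()] restricted to the chosen axes.
#' @export
project_axes <- function(traj, axes = c("x", "y")) {
  stopifnot(inherits(traj, "locus_trajectory"))
  locus_trajectory(traj$positions[, axes, drop = FALSE], dt = traj$dt,
                   units = traj$units, time_unit = traj$time_unit,
                   label = traj$label)
}

check_length <- function(traj, n_min, what) {
  stopifnot(inherits(traj, "locus_trajectory"))
  if (nrow(traj$positions) < n_min)
    stop(sprintf("%s needs at least %d frames (got %d)", what, n_min,
                 nrow(traj$positions)), call. = FALSE)
  invisible(traj)
}

#' Time-averaged locus position
#'
#' For a locus tethered through a single well this estimates the location
#' where the force is applied (the well centre); its standard error shrinks
#' as `sigma/sqrt(N_p)` per axis.
#'
#' @param traj a [locus_trajectory()].
#' @return Named numeric vector, the mean position per axis.
#' @export
mean_position <- function(traj) {
  check_length(traj, 10L, "mean_position")
  colMeans(traj$positions)
}

new_stiffness_estimate <- function(k_c, se, method, D_used, traj, variance) {
  structure(list(k_c = k_c, se = se, method = method, D_used = D_used,
                 units = sprintf("kBT/%s^2", traj$units),
                 n_frames = nrow(traj$positions), variance = variance,
                 label = traj$label),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("<stiffness_estimate> k_c = %.4g +/- %.3g %s  (%s, %d frames)\n",
              x$k_c, x$se, x$units, x$method, x$n_frames))
  invisible(x)
}

# Per-axis step-vs-position statistics shared by the moment and regression
# estimators: slope of (R(h+1) - R(h)) on (R(h) - mean R(h)), h = 1..Np-1.
step_position_stats <- function(traj) {
  P <- traj$positions
  n <- nrow(P) - 1L
  X <- P[1:n, , drop = FALSE]
  dX <- P[-1L, , drop = FALSE] - X
  X <- sweep(X, 2L, colMeans(X))
  sxy <- colSums(dX * X)
  sxx <- colSums(X * X)
  if (any(sxx == 0))
    stop("degenerate trajectory: zero position variance on an axis",
         call. = FALSE)
  # residual variance per axis for slope standard errors
  slope <- sxy / sxx
  res2 <- colSums((dX - sweep(X, 2L, slope, `*`))^2)
  se <- sqrt(res2 / pmax(n - 2L, 1L) / sxx)
  list(n = n, sxy = sxy, sxx = sxx, slope = slope, slope_se = se,
       res2 = res2)
}

#' Moment (step-times-position) stiffness estimator
#'
#' Estimates the effective spring constant from the first moment of the
#' steps: a restoring drift `-D k_c (R - <R>)` makes the average product of
#' the step with the centred position negative and proportional to `k_c`.
#' Implemented per axis as the step-vs-position slope normalised by that
#' axis' position variance, averaged over axes, and divided by `-D dt`:
#' equivalent to the raw step-position moment divided by the per-axis
#' variance, which is required for the estimator to converge to `k_c` of
#' the single-well inversion formula regardless of units. It differs from
#' [estimate_stiffness_regression()] only in how axes are pooled (average of
#' per-axis slopes vs variance-weighted pooled slope); for isotropic data
#' the two agree.
#'
#' Unlike the variance inversion ([estimate_stiffness_variance()]) this
#' drift-based estimator does not require the trajectory to be longer than
#' the relaxation time.
#'
#' @param traj a [locus_trajectory()].
#' @param D diffusion coefficient of the locus, in `units^2` per
#'   `time_unit` (see [estimate_diffusion()]).
#' @return A `stiffness_estimate` (fields `k_c`, `se`, `method`, `D_used`,
#'   `units`, `n_frames`, `variance`).
#' @export
estimate_stiffness_moment <- function(traj, D) {
  check_length(traj, 10L, "estimate_stiffness_moment")
  stopifnot(is.numeric(D), length(D) == 1L)
  if (D <= 0) stop("`D` must be > 0", call. = FALSE)
  st <- step_position_stats(traj)
  d <- length(st$slope)
  k_c <- -mean(st$slope) / (D * traj$dt)
  se <- sqrt(sum(st$slope_se^2)) / d / (D * traj$dt)
  new_stiffness_estimate(k_c, se, "moment", D, traj,
                         variance = sum(st$sxx) / st$n)
}

#' Linear-regression (step-vs-position) stiffness estimator
#'
#' Least-squares slope `s` of the step `R(h+1) - R(h)` against the centred
#' position `R(h) - <R>`, pooled over axes; `k_c = -s / (D dt)`. This is the
#' scatter-plot fit of step against position and the default estimator for
#' tethered-locus data: in expectation `s = -D k_cn dt` by the single-well
#' inversion formula.
#'
#' @inheritParams estimate_stiffness_moment
#' @return A `stiffness_estimate`.
#' @export
estimate_stiffness_regression <- function(traj, D) {
  check_length(traj, 10L, "estimate_stiffness_regression")
  stopifnot(is.numeric(D), length(D) == 1L)
  if (D <= 0) stop("`D` must be > 0", call. = FALSE)
  st <- step_position_stats(traj)
  slope <- sum(st$sxy) / sum(st$sxx)
  n_tot <- st$n * length(st$slope)
  res2 <- sum(st$res2) + sum((st$slope - slope)^2 * st$sxx)
  se <- sqrt(res2 / (n_tot - 2L) / sum(st$sxx)) / (D * traj$dt)
  new_stiffness_estimate(-slope / (D * traj$dt), se, "regression", D, traj,
                         variance = sum(st$sxx) / st$n)
}

#' Variance-inversion stiffness estimator
#'
#' At equilibrium the total centred variance of a tethered locus is
#' `d / k_c`; hence `k_c = d / var`. The variance is the mean squared
#' deviation from the time-averaged position (normalisation `1/N_p`,
#' matching lag 0 of [empirical_autocorrelation()]). Its standard error
#' (`sigma^2 * sqrt(2/(N_p - 1))` per axis, treating frames as independent)
#' is propagated to `k_c`; serial correlation makes this a lower bound.
#'
#' This estimator requires the trajectory to be much longer than the
#' relaxation time of the chain segment involved; pass `tau_r` (from
#' [relaxation_time()]) to have the coverage checked, otherwise it is the
#' caller's responsibility.
#'
#' @param traj a [locus_trajectory()].
#' @param tau_r optional relaxation time in the trajectory's time unit; a
#'   warning is emitted when the record is shorter than `20 * tau_r`.
#' @return A `stiffness_estimate`.
#' @export
estimate_stiffness_variance <- function(traj, tau_r = NULL) {
  check_length(traj, 10L, "estimate_stiffness_variance")
  P <- traj$positions
  np <- nrow(P); d <- ncol(P)
  if (!is.null(tau_r) && np * traj$dt < 20 * tau_r)
    warning(sprintf(paste0("trajectory (%.3g time units) shorter than 20 ",
                           "relaxation times (tau_r = %.3g): variance ",
                           "inversion assumes equilibrium; prefer the drift ",
                           "estimators"), np * traj$dt, tau_r), call. = FALSE)
  v <- sum(sweep(P, 2L, colMeans(P))^2) / np
  if (v == 0) stop("zero-variance trajectory", call. = FALSE)
  k_c <- d / v
  rel_se <- sqrt(2 / (np - 1L))  # relative SE of the variance, per axis
  new_stiffness_estimate(k_c, k_c * rel_se / sqrt(d), "variance", NA_real_,
                         traj, variance = v)
}

#' Binned conditional drift field
#'
#' Estimates `E[(R(t+dt) - R(t))/dt | R(t) = x]` per axis by binning the
#' steps by starting position. For a locus tethered through harmonic wells
#' the profile is linear with slope `-D k_c`, the empirical face of the
#' inversion formulas; [fit_drift_stiffness()] extracts `k_c` from it.
#'
#' Bins are equal-width over the central 99% of positions per axis
#' (outliers are dropped); bins holding fewer than `min_count` steps are
#' flagged (`ok = FALSE`) and excluded from fits. An error is raised when
#' fewer than 80% of bins are adequately occupied.
#'
#' @param traj a [locus_trajectory()].
#' @param n_bins bins per axis; default `ceiling(N_p^(1/3))`.
#' @param min_count minimum steps per usable bin (default 20).
#' @return A `drift_profile`: data frame with columns `axis`, `center`,
#'   `drift` (mean step/dt), `count`, `ok`; attributes `dt`, `d`.
#' @export
conditional_drift <- function(traj, n_bins = NULL, min_count = 20L) {
  check_length(traj, 100L, "conditional_drift")
  P <- traj$positions
  n <- nrow(P) - 1L
  if (is.null(n_bins)) n_bins <- ceiling(n^(1 / 3))
  out <- do.call(rbind, lapply(seq_len(ncol(P)), function(j) {
    x <- P[1:n, j]
    v <- (P[-1L, j] - x) / traj$dt
    qs <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
    inside <- x >= qs[1L] & x <= qs[2L]
    br <- seq(qs[1L], qs[2L], length.out = n_bins + 1L)
    bin <- findInterval(x[inside], br, rightmost.closed = TRUE)
    data.frame(axis = colnames(P)[j],
               center = (br[-1L] + br[-(n_bins + 1L)]) / 2,
               drift = vapply(seq_len(n_bins), function(b) {
                 s <- bin == b
                 if (any(s)) mean(v[inside][s]) else NA_real_
               }, 0),
               count = tabulate(bin, n_bins))
  }))
  out$ok <- out$count >= min_count
  if (mean(out$ok) < 0.8)
    stop(sprintf(paste0("insufficient occupancy: only %.0f%% of bins hold at ",
                        "least %d steps; use fewer bins or a longer ",
                        "trajectory"), 100 * mean(out$ok), min_count),
         call. = FALSE)
  structure(out, class = c("drift_profile", "data.frame"),
            dt = traj$dt, d = ncol(P))
}

#' Stiffness from a conditional drift profile
#'
#' Weighted least-squares slope of drift against position over the usable
#' bins of a [conditional_drift()] profile (per axis, pooled with bin-count
#' weights); `k_c = -slope / D`.
#'
#' @param profile a `drift_profile`.
#' @param D diffusion coefficient.
#' @return A list with `k_c`, `se`, and the fitted `slope`.
#' @export
fit_drift_stiffness <- function(profile, D) {
  stopifnot(inherits(profile, "drift_profile"), D > 0)
  use <- profile$ok & is.finite(profile$drift)
  df <- profile[use, , drop = FALSE]
  # centre positions within each axis so axes share one slope
  ctr <- stats::ave(df$center * df$count, df$axis) /
    stats::ave(df$count, df$axis)
  fit <- stats::lm(drift ~ 0 + I(center - ctr), data = df,
                   weights = df$count)
  slope <- unname(stats::coef(fit)[1L])
  se <- summary(fit)$coefficients[1L, 2L]
  list(k_c = -slope / D, se = se / D, slope = slope)
}

#' Empirical position autocorrelation
#'
#' Lagged, mean-subtracted autocovariance of the locus position, summed
#' over axes:
#' `C(h dt) = 1/(N_p - h) * sum_axes sum_k (R(k) - <R>) (R(k+h) - <R>)`.
#' Lag 0 equals the total centred variance. For an Ornstein-Uhlenbeck locus
#' the curve decays as a single exponential with rate `D k`; for a tethered
#' polymer it is a sum of exponentials whose slowest rate is `D k / N`
#' (see [autocorrelation_theory()]), motivating the double-exponential fit
#' of [fit_double_exponential()].
#'
#' @param traj a [locus_trajectory()].
#' @param max_lag largest lag in frames; at most `N_p/5` (default) so that
#'   every lag is averaged over enough frame pairs.
#' @return An `autocorr_result` (fields `lags` in time units, `C`), with
#'   attribute `source = "empirical"`.
#' @export
empirical_autocorrelation <- function(traj, max_lag = NULL) {
  check_length(traj, 10L, "empirical_autocorrelation")
  P <- traj$positions
  np <- nrow(P)
  if (is.null(max_lag)) max_lag <- floor(np / 5)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag > np / 5)
    stop(sprintf("max_lag too large: must be in 1..N_p/5 = %d", np %/% 5L),
         call. = FALSE)
  X <- sweep(P, 2L, colMeans(P))
  # lagged products via FFT (exact up to rounding, O(n log n))
  m <- stats::nextn(2L * np, 2L)
  raw <- rowSums(vapply(seq_len(ncol(X)), function(j) {
    f <- stats::fft(c(X[, j], rep(0, m - np)))
    Re(stats::fft(Mod(f)^2, inverse = TRUE))[1:(max_lag + 1L)] / m
  }, numeric(max_lag + 1L)))
  C <- raw / (np - 0:max_lag)
  structure(list(lags = (0:max_lag) * traj$dt, C = C),
            class = "autocorr_result", source = "empirical")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("<autocorr_result> %d lags (0..%g), C(0) = %.4g [%s]\n",
              length(x$lags), max(x$lags), x$C[1L],
              attr(x, "source") %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Data-driven candidate starting points for the two-exponential fit: pair
# time constants around the 1/e crossing and the lag span, solve the two
# amplitudes linearly for each pair, and order candidates by residual sum
# of squares.
dexp_candidate_starts <- function(t, C) {
  c0 <- C[1L]
  span <- max(t)
  below <- which(C <= c0 / exp(1) & t > 0)
  t_e <- if (length(below)) t[below[1L]] else span / 3
  tau2s <- unique(pmax(c(t_e / 3, t_e), min(t[t > 0]) / 2))
  tau1s <- unique(c(3 * t_e, 10 * t_e, span / 2))
  cands <- list()
  for (tau2 in tau2s) for (tau1 in tau1s) {
    if (tau1 <= tau2 * 1.5) next
    e1 <- exp(-t / tau1); e2 <- exp(-t / tau2)
    amp <- tryCatch(stats::coef(stats::lm(C ~ 0 + e1 + e2)),
                    error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(amp))) next
    # keep both starting amplitudes away from zero: a vanishing component
    # makes the Jacobian singular at the starting point
    amp <- pmax(amp, 0.05 * c0)
    rss <- sum((C - amp[1L] * e1 - amp[2L] * e2)^2)
    cands[[length(cands) + 1L]] <-
      list(rss = rss, start = list(a1 = unname(amp[1L]), tau1 = tau1,
                                   a2 = unname(amp[2L]), tau2 = tau2))
  }
  if (length(cands) == 0L)
    stop("could not build initial values for the double-exponential fit",
         call. = FALSE)
  lapply(cands[order(vapply(cands, `[[`, 0, "rss"))], `[[`, "start")
}

#' Double-exponential fit of an autocorrelation curve
#'
#' Nonlinear least squares of `C(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)`
#' with the convention `tau1 > tau2` (slow component first). Initial values
#' are derived from the data, never from fixed defaults: candidate time
#' constants are built around the observed `1/e` crossing of the curve and
#' its lag span, the amplitudes for each candidate pair are solved linearly,
#' and the lowest-residual candidate seeds the nonlinear fit (remaining
#' candidates are fallbacks). Parameter standard errors come from the fit
#' covariance. Non-convergence raises an error carrying the optimizer
#' diagnostics.
#'
#' @param acf an `autocorr_result` ([empirical_autocorrelation()] or
#'   [autocorrelation_theory()]) with at least 8 lags and `C(0) > 0`.
#' @param start optional named list (`a1`, `tau1`, `a2`, `tau2`) overriding
#'   the automatic initial values.
#' @return An `autocorr_fit`: list with `a1`, `tau1`, `a2`, `tau2`,
#'   `se` (named vector), `fitted`, and the underlying `fit` object.
#' @export
fit_double_exponential <- function(acf, start = NULL) {
  stopifnot(inherits(acf, "autocorr_result"))
  t <- acf$lags; C <- acf$C
  if (length(t) < 8L) stop("need at least 8 lag points", call. = FALSE)
  if (C[1L] <= 0) stop("C(0) must be > 0", call. = FALSE)

  starts <- if (is.null(start)) dexp_candidate_starts(t, C) else list(start)

  model <- function(p) p[1L] * exp(-t / p[2L]) + p[3L] * exp(-t / p[4L])
  fit <- NULL
  fails <- character(0)
  for (s in starts) {
    p0 <- unlist(s[c("a1", "tau1", "a2", "tau2")])
    o <- tryCatch(
      minpack.lm::nls.lm(p0, fn = function(p) C - model(p),
                         lower = c(0, 1e-12, 0, 1e-12),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(o) && o$info %in% 1:4) { fit <- o; break }
    fails <- c(fails, sprintf("[a1=%.3g tau1=%.3g a2=%.3g tau2=%.3g: %s]",
                              p0[1L], p0[2L], p0[3L], p0[4L],
                              if (is.null(o)) "evaluation error" else o$message))
  }
  if (is.null(fit))
    stop("double-exponential fit failed to converge from every candidate ",
         "start: ", paste(fails, collapse = " "), call. = FALSE)

  cf <- stats::setNames(fit$par, c("a1", "tau1", "a2", "tau2"))
  # standard errors from the Levenberg-Marquardt curvature; a component that
  # collapsed to zero amplitude leaves its parameters without curvature, in
  # which case their errors are reported as NA rather than invented
  dof <- length(C) - 4L
  se <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance / dof
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 4L))
  se <- stats::setNames(se, names(cf))
  if (cf["tau1"] < cf["tau2"]) {  # enforce slow-first convention
    cf <- cf[c("a2", "tau2", "a1", "tau1")]
    se <- se[c("a2", "tau2", "a1", "tau1")]
    names(cf) <- names(se) <- c("a1", "tau1", "a2", "tau2")
  }
  structure(list(a1 = unname(cf["a1"]), tau1 = unname(cf["tau1"]),
                 a2 = unname(cf["a2"]), tau2 = unname(cf["tau2"]),
                 se = se, fitted = model(fit$par), fit = fit),
            class = "autocorr_fit")
}

#' @export
print.autocorr_fit <- function(x, ...) {
  cat(sprintf(paste0("<autocorr_fit> a1 = %.4g (tau1 = %.4g), ",
                     "a2 = %.4g (tau2 = %.4g)\n"),
              x$a1, x$tau1, x$a2, x$tau2))
  invisible(x)
}

#' Short-lag diffusion coefficient estimate
#'
#' `D = (<|dR|^2> - |<dR>|^2) / (2 d dt)`: the drift-corrected second moment
#' of single-frame steps. Exact for free Brownian motion; for a tethered
#' locus it is a short-lag approximation, accurate when `D k_c dt << 1`.
#'
#' @param traj a [locus_trajectory()] with at least 100 frames.
#' @return Estimated diffusion coefficient (`units^2` per `time_unit`).
#' @export
estimate_diffusion <- function(traj) {
  check_length(traj, 100L, "estimate_diffusion")
  P <- traj$positions
  dX <- diff(P)
  (mean(rowSums(dX^2)) - sum(colMeans(dX)^2)) / (2 * ncol(P) * traj$dt)
}

#' Time-averaged MSD and anomalous exponent
#'
#' Computes the time-averaged mean-square displacement
#' `MSD(h dt) = <|R(t + h dt) - R(t)|^2>_t` and the log-log regression
#' slope `alpha` over a caller-chosen intermediate-time window (free
#' Brownian motion gives 1; a free Rouse monomer 1/2; a beta-polymer
#' monomer `1 - 1/beta`). The window must avoid both the short-time
#' single-monomer regime and the long-time centre-of-mass regime; it is the
#' caller's to choose.
#'
#' @param traj a [locus_trajectory()].
#' @param lag_window numeric `c(t_min, t_max)` in time units, the fitting
#'   window; must lie within the available lags.
#' @param n_lags number of (log-spaced) lags at which the MSD is evaluated.
#' @return A list: `msd` (data frame `lag`, `time`, `msd`), `alpha`,
#'   `alpha_se`, `window`.
#' @export
msd_and_exponent <- function(traj, lag_window, n_lags = 40L) {
  check_length(traj, 100L, "msd_and_exponent")
  P <- traj$positions
  np <- nrow(P)
  stopifnot(length(lag_window) == 2L, lag_window[1L] > 0,
            lag_window[2L] > lag_window[1L])
  hmax <- min(np - 1L, ceiling(lag_window[2L] / traj$dt))
  if (lag_window[2L] > (np - 1L) * traj$dt)
    stop("lag window extends beyond the trajectory", call. = FALSE)
  hs <- unique(round(exp(seq(log(1), log(hmax), length.out = n_lags))))
  msd <- vapply(hs, function(h) {
    dX <- P[(1 + h):np, , drop = FALSE] - P[1:(np - h), , drop = FALSE]
    mean(rowSums(dX^2))
  }, 0)
  tt <- hs * traj$dt
  in_win <- tt >= lag_window[1L] & tt <= lag_window[2L]
  if (sum(in_win) < 3L)
    stop("fewer than 3 MSD points inside the lag window", call. = FALSE)
  fit <- stats::lm(log(msd[in_win]) ~ log(tt[in_win]))
  list(msd = data.frame(lag = hs, time = tt, msd = msd),
       alpha = unname(stats::coef(fit)[2L]),
       alpha_se = summary(fit)$coefficients[2L, 2L],
       window = lag_window)
}

#' Power-law fit of stiffness against variance
#'
#' Fits `k_c = a * v^b` by least squares in log-log space across loci or
#' cells, where `v` is each locus' positional variance. The equilibrium
#' inversion `k_c = d / v` predicts `b = -1` with `a = d` when `v` is the
#' centred variance; an empirical exponent near -1 across a population
#' indicates that confinement is force-generated rather than crowding.
#'
#' @param k_c numeric vector of stiffness estimates (all `> 0`).
#' @param variance numeric vector of matching positional variances
#'   (all `> 0`), same length as `k_c` (at least 3 points).
#' @return A `powerlaw_fit`: list with `a`, `b`, `se` (named, delta-method
#'   error on `a`), and the underlying `fit`.
#' @export
powerlaw_fit <- function(k_c, variance) {
  stopifnot(is.numeric(k_c), is.numeric(variance),
            length(k_c) == length(variance))
  if (length(k_c) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(k_c <= 0) || any(variance <= 0))
    stop("all k_c and variance values must be > 0", call. = FALSE)
  fit <- stats::lm(log(k_c) ~ log(variance))
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  a <- exp(unname(cf[1L]))
  structure(list(a = a, b = unname(cf[2L]),
                 se = c(a = a * sm[1L, 2L], b = sm[2L, 2L]), fit = fit),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> k_c = %.4g * variance^%.4g (se: a %.3g, b %.3g)\n",
              x$a, x$b, x$se["a"], x$se["b"]))
  invisible(x)
}
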