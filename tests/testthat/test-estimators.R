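test_that("locus trajectories validate and project", {
  expect_error(locus_trajectory(matrix(c(1, NA, 2, 3), 2), dt = 1),
               "non-finite")
  expect_error(locus_trajectory(matrix(1, 2, 2), dt = 0))
  tr <- locus_trajectory(matrix(rnorm(30), 10, 3), dt = 0.5, units = "um",
                         time_unit = "s", label = "cell1")
  p <- project_axes(tr, c("x", "y"))
  expect_equal(ncol(p$positions), 2L)
  expect_equal(p$units, "um")
  expect_equal(p$positions, tr$positions[, 1:2], ignore_attr = TRUE)
})

test_that("mean position estimates the well centre", {
  const <- locus_trajectory(matrix(rep(c(1, 2, 3), each = 12), 12, 3), dt = 1)
  expect_equal(unname(mean_position(const)), c(1, 2, 3))
  tr <- simulate_ou(k = 2, d = 3, dt = 0.2, n_steps = 5000, seed = 21,
                    mu = c(5, 0, 0))
  # SE per axis ~ sigma/sqrt(N_eff); allow for serial correlation
  expect_lt(max(abs(mean_position(tr) - c(5, 0, 0))), 0.2)
  expect_error(mean_position(locus_trajectory(matrix(1:8, 4, 2), dt = 1)),
               "at least 10")
})

test_that("moment and regression estimators agree with their algebra", {
  # fixed deterministic data: compare against plain-arithmetic oracles
  tr <- fixed_toy_track()
  P <- tr$positions
  n <- nrow(P) - 1L
  X <- sweep(P[1:n, ], 2, colMeans(P[1:n, ]))
  dX <- P[-1, ] - P[1:n, ]
  slopes <- colSums(dX * X) / colSums(X * X)
  D <- 1
  mom <- estimate_stiffness_moment(tr, D)
  reg <- estimate_stiffness_regression(tr, D)
  expect_equal(mom$k_c, -mean(slopes) / (D * tr$dt))
  expect_equal(reg$k_c, -sum(colSums(dX * X)) / sum(colSums(X * X)) / (D * tr$dt))
  expect_equal(mom$method, "moment")
  expect_equal(reg$method, "regression")
  expect_error(estimate_stiffness_moment(tr, 0), "D")
})

test_that("stiffness estimators recover a known OU spring constant", {
  k <- 1.5
  tr <- simulate_ou(k = k, D = 1, d = 3, dt = 0.02, n_steps = 1e5, seed = 31)
  mom <- estimate_stiffness_moment(tr, 1)
  reg <- estimate_stiffness_regression(tr, 1)
  va <- estimate_stiffness_variance(tr)
  # finite-lag attenuation of the exact OU kernel: slope = -(1 - e^{-Dk dt})
  k_eff <- (1 - exp(-k * 0.02)) / 0.02
  expect_lt(abs(mom$k_c - k_eff), 3 * mom$se)
  expect_lt(abs(reg$k_c - k_eff), 3 * reg$se)
  expect_equal(va$k_c, k, tolerance = 0.05)
  # isotropic data: the two poolings agree closely
  expect_equal(mom$k_c, reg$k_c, tolerance = 0.02)
  # drift-profile route gives the same stiffness
  prof <- conditional_drift(tr, n_bins = 25)
  dr <- fit_drift_stiffness(prof, 1)
  expect_equal(dr$k_c, k_eff, tolerance = 0.1)
})

test_that("a free Brownian locus shows no restoring drift", {
  set.seed(41)
  P <- apply(matrix(rnorm(3 * 5000, sd = sqrt(2 * 0.01)), 5000, 3), 2, cumsum)
  tr <- locus_trajectory(P, dt = 0.01)
  reg <- estimate_stiffness_regression(tr, 1)
  expect_lt(abs(reg$k_c), 3 * reg$se + 0.05)
})

test_that("variance inversion flags non-equilibrated records", {
  tr <- simulate_ou(k = 2, d = 3, dt = 0.01, n_steps = 200, seed = 5)
  expect_warning(estimate_stiffness_variance(tr, tau_r = 10), "equilibrium")
  expect_silent(estimate_stiffness_variance(tr))
  flat <- locus_trajectory(matrix(1, 50, 2), dt = 1)
  expect_error(estimate_stiffness_variance(flat), "zero-variance")
})

test_that("variance estimator inverts d/variance", {
  # scale a centred track to known variance 1.5 in d = 3: k_c must be 2
  set.seed(51)
  P <- matrix(rnorm(600), 200, 3)
  P <- sweep(P, 2, colMeans(P))
  P <- P * sqrt(1.5 / (sum(P^2) / 200))
  est <- estimate_stiffness_variance(locus_trajectory(P, dt = 1))
  expect_equal(est$k_c, 3 / 1.5)
})

test_that("conditional drift is linear for a tethered locus", {
  tr <- simulate_ou(k = 2, D = 1, d = 2, dt = 0.02, n_steps = 4e4, seed = 61)
  prof <- conditional_drift(tr, n_bins = 21)
  expect_s3_class(prof, "drift_profile")
  expect_true(all(prof$count[prof$ok] >= 20))
  # restoring field: positive drift left of the centre, negative right
  lo <- prof$ok & prof$center < -0.5
  hi <- prof$ok & prof$center > 0.5
  expect_true(mean(prof$drift[lo]) > 0)
  expect_true(mean(prof$drift[hi]) < 0)
  k_eff <- (1 - exp(-2 * 0.02)) / 0.02
  dr <- fit_drift_stiffness(prof, 1)
  expect_lt(abs(dr$k_c - k_eff), 3 * dr$se + 0.1)
  # occupancy guard
  short <- simulate_ou(k = 2, d = 2, dt = 0.02, n_steps = 150, seed = 62)
  expect_error(conditional_drift(short, n_bins = 60), "occupancy")
})

test_that("empirical autocorrelation matches variance at lag zero", {
  tr <- simulate_ou(k = 1, d = 3, dt = 0.05, n_steps = 2000, seed = 71)
  acf1 <- empirical_autocorrelation(tr, 100)
  expect_equal(acf1$lags[1L], 0)
  expect_equal(acf1$C[1L], estimate_stiffness_variance(tr)$variance,
               tolerance = 1e-12)
  expect_error(empirical_autocorrelation(tr, 500), "max_lag")
})

test_that("white-noise positions decorrelate after one frame", {
  set.seed(81)
  tr <- locus_trajectory(matrix(rnorm(6000), 2000, 3), dt = 1)
  acf1 <- empirical_autocorrelation(tr, 20)
  expect_lt(max(abs(acf1$C[-1L])), 4 * 3 / sqrt(2000))
})

test_that("OU autocorrelation decays with rate D*k", {
  tr <- simulate_ou(k = 2, D = 1, d = 2, dt = 0.05, n_steps = 5e4, seed = 91)
  acf1 <- empirical_autocorrelation(tr, 60)
  i <- 1:30
  rate <- -unname(coef(lm(log(acf1$C[i]) ~ acf1$lags[i]))[2L])
  expect_equal(rate, 2, tolerance = 0.1)
})

test_that("double-exponential fit recovers generating parameters", {
  # parameters of the two-component decay used for chromatin-locus records
  a1 <- 0.109; tau1 <- 45.7; a2 <- 8.38e-3; tau2 <- 2.4
  t <- seq(0, 60, by = 0.33)
  clean <- structure(list(lags = t, C = a1 * exp(-t / tau1) +
                            a2 * exp(-t / tau2)),
                     class = "autocorr_result", source = "synthetic")
  fit <- fit_double_exponential(clean)
  expect_equal(fit$a1, a1, tolerance = 0.01)
  expect_equal(fit$tau1, tau1, tolerance = 0.01)
  expect_equal(fit$a2, a2, tolerance = 0.01)
  expect_equal(fit$tau2, tau2, tolerance = 0.01)
  expect_true(fit$tau1 > fit$tau2)
  expect_true(all(is.finite(fit$se)))
  # with 1% multiplicative noise: recovery within 5%
  set.seed(101)
  noisy <- clean
  noisy$C <- noisy$C * (1 + 0.01 * rnorm(length(t)))
  fitn <- fit_double_exponential(noisy)
  expect_equal(fitn$a1, a1, tolerance = 0.05)
  expect_equal(fitn$tau1, tau1, tolerance = 0.05)
  expect_equal(fitn$a2, a2, tolerance = 0.05)
  expect_equal(fitn$tau2, tau2, tolerance = 0.05)
})

test_that("double-exponential fit degrades gracefully to one component", {
  t <- seq(0, 30, by = 0.5)
  single <- structure(list(lags = t, C = 2 * exp(-t / 5)),
                      class = "autocorr_result", source = "synthetic")
  fit <- fit_double_exponential(single)
  # one amplitude vanishes or both time constants collapse onto 5
  expect_true(min(fit$a1, fit$a2) < 0.02 * max(fit$a1, fit$a2) ||
                (abs(fit$tau1 - 5) / 5 < 0.05 && abs(fit$tau2 - 5) / 5 < 0.2))
  expect_error(fit_double_exponential(
    structure(list(lags = 0:5, C = rep(1, 6)), class = "autocorr_result")),
    "at least 8")
})

test_that("theory autocorrelation of a tether fits with dominant rate Dk/N", {
  sp <- polymer_spec(30, kappa = 3)
  th <- autocorrelation_theory(sp, well_spec(1, 1), 16,
                               seq(0, 150, by = 0.5))
  fit <- fit_double_exponential(th)
  expect_equal(1 / fit$tau1, 1 / 30, tolerance = 0.1)
})

test_that("diffusion estimator recovers D at short lags", {
  set.seed(111)
  P <- apply(matrix(rnorm(3 * 2e4, sd = sqrt(2 * 1 * 0.01)), 2e4, 3), 2, cumsum)
  expect_equal(estimate_diffusion(locus_trajectory(P, dt = 0.01)), 1,
               tolerance = 0.05)
  # tethered locus, Dk dt << 1
  tr <- simulate_ou(k = 2, D = 1, d = 3, dt = 0.005, n_steps = 4e4, seed = 112)
  expect_equal(estimate_diffusion(tr), 1, tolerance = 0.05)
  # immobile locus
  expect_equal(estimate_diffusion(locus_trajectory(matrix(1, 200, 2), dt = 1)),
               0)
})

test_that("MSD exponent is 1 for free Brownian motion", {
  set.seed(121)
  P <- apply(matrix(rnorm(2 * 2e4, sd = sqrt(2 * 0.05)), 2e4, 2), 2, cumsum)
  tr <- locus_trajectory(P, dt = 0.05)
  m <- msd_and_exponent(tr, c(0.25, 20))
  expect_equal(m$alpha, 1, tolerance = 0.05)
  expect_error(msd_and_exponent(tr, c(10, 1e5)), "beyond")
})

test_that("power-law fit inverts the variance-stiffness relation", {
  ks <- 1:10
  # exact d = 2 family (suppress the perfect-fit note from the summary)
  pl <- suppressWarnings(powerlaw_fit(ks, 2 / ks))
  expect_equal(pl$b, -1, tolerance = 1e-10)
  expect_equal(pl$a, 2, tolerance = 1e-10)
  expect_error(powerlaw_fit(1:2, 1:2), "at least 3")
  expect_error(powerlaw_fit(c(1, -1, 2), c(1, 1, 1)), "> 0")
  # 21-cell cloud with 30% lognormal scatter
  set.seed(131)
  ks <- exp(runif(21, log(0.5), log(8)))
  v <- 2 / ks * exp(rnorm(21, sd = 0.3))
  pl2 <- powerlaw_fit(ks, v)
  expect_lt(abs(pl2$b - (-1)), 0.15)
})

test_that("estimators are equivariant under 2D projection of isotropic data", {
  tr <- simulate_ou(k = 2, D = 1, d = 3, dt = 0.02, n_steps = 6e4, seed = 141)
  full <- estimate_stiffness_regression(tr, 1)
  proj <- estimate_stiffness_regression(project_axes(tr, c("x", "y")), 1)
  expect_lt(abs(full$k_c - proj$k_c), 3 * sqrt(full$se^2 + proj$se^2))
  vfull <- estimate_stiffness_variance(tr)
  vproj <- estimate_stiffness_variance(project_axes(tr, c("x", "y")))
  expect_equal(vproj$k_c, vfull$k_c, tolerance = 0.1)
})

test_that("standard errors shrink as sigma/sqrt(N_p) on replicates", {
  # frames sampled 5/(Dk) apart are nearly independent, so the iid formulas
  # for the mean and variance standard errors apply
  k <- 2; np <- 1500
  reps <- t(vapply(1:20, function(s) {
    tr <- simulate_ou(k = k, d = 3, dt = 5 / k, n_steps = np, seed = 200 + s)
    c(mean_position(tr)[1L], estimate_stiffness_variance(tr)$variance)
  }, numeric(2)))
  sigma <- sqrt(1 / k)
  expect_equal(sd(reps[, 1L]), sigma / sqrt(np), tolerance = 0.45)
  expect_equal(sd(reps[, 2L]), (3 / k) * sqrt(2 / (np - 1)) / sqrt(3),
               tolerance = 0.45)
})

test_that("estimator family converges to one k_c on tethered-chain data", {
  sp <- polymer_spec(10, kappa = 3)
  tr <- simulate_polymer(sp, list(well_spec(1, 2, c(0, 0, 0))),
                         sim_config(dt = 0.01, n_steps = 2e5, seed = 151,
                                    burn_in = 2e4), tagged = 5L)
  lt <- tagged_locus(tr, 5)
  truth <- effective_stiffness_single(2, 3, 4)$value
  reg <- estimate_stiffness_regression(lt, 1)
  mom <- estimate_stiffness_moment(lt, 1)
  va <- estimate_stiffness_variance(lt)
  dr <- fit_drift_stiffness(conditional_drift(lt, n_bins = 15), 1)
  ests <- c(reg$k_c, mom$k_c, va$k_c, dr$k_c)
  expect_equal(ests, rep(truth, 4), tolerance = 0.2)
  # pairwise agreement among the drift-based estimators is much tighter
  expect_equal(reg$k_c, mom$k_c, tolerance = 0.02)
})
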