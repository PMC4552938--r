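test_that("well and config constructors validate their inputs", {
  expect_error(well_spec(0, 1), "n >= 1")
  expect_error(well_spec(1, -1), "k >= 0")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(n_steps = 1), "n_steps")
  expect_error(sim_config(init = "explicit"), "init_positions")
})

test_that("potential energy matches its direct pairwise oracle", {
  sp <- polymer_spec(3, kappa = 1)
  straight <- cbind(0:2, 0, 0)
  expect_equal(potential_energy(straight, sp), 1.0)  # two unit bonds
  # everything at the well centre: zero chain and well energy
  mu <- c(2, -1, 0.5)
  allmu <- matrix(mu, 3, 3, byrow = TRUE)
  expect_equal(potential_energy(allmu, polymer_spec(3, kappa = 2),
                                well_spec(2, 5, mu)), 0)
  # random configuration: pairwise sum vs quadratic form, both beta
  set.seed(4)
  for (beta in c(2, 1.5)) {
    spb <- polymer_spec(8, beta = beta, kappa = 3)
    R <- matrix(rnorm(24), 8, 3)
    w <- list(well_spec(3, 1.5, c(1, 0, 0)), well_spec(7, 0.5, c(0, 2, 0)))
    A <- connectivity_matrix(spb)
    direct <- sum(vapply(1:3, function(j) R[, j] %*% A %*% R[, j], 0)) / 2 +
      1.5 / 2 * sum((R[3, ] - c(1, 0, 0))^2) +
      0.5 / 2 * sum((R[7, ] - c(0, 2, 0))^2)
    expect_equal(potential_energy(R, spb, w), drop(direct), tolerance = 1e-10)
  }
  expect_error(potential_energy(straight, sp, well_spec(1, 1, c(0, 0))),
               "dimension")
})

test_that("total force is the negative potential gradient", {
  set.seed(5)
  for (beta in c(2, 1.4)) {
    sp <- polymer_spec(6, beta = beta, kappa = 2)
    R <- matrix(rnorm(18), 6, 3)
    wells <- list(well_spec(1, 2, c(0, 0, 0)))
    FF <- total_force(R, sp, wells)
    # central-difference oracle
    h <- 1e-6
    num <- matrix(0, 6, 3)
    for (i in 1:6) for (j in 1:3) {
      Rp <- R; Rp[i, j] <- R[i, j] + h
      Rm <- R; Rm[i, j] <- R[i, j] - h
      num[i, j] <- -(potential_energy(Rp, sp, wells) -
                       potential_energy(Rm, sp, wells)) / (2 * h)
    }
    expect_equal(FF, num, tolerance = 1e-5)
  }
  # interior Rouse monomer: -kappa(2Rc - Rc-1 - Rc+1)
  sp <- polymer_spec(5, kappa = 3)
  R <- matrix(rnorm(15), 5, 3)
  FF <- total_force(R, sp)
  expect_equal(FF[3, ], -3 * (2 * R[3, ] - R[2, ] - R[4, ]))
  # equilibrium: all monomers at the well centre
  mu <- c(1, 1, 1)
  expect_equal(total_force(matrix(1, 5, 3), sp, well_spec(2, 4, mu)),
               matrix(0, 5, 3))
})

test_that("simulation is bit-reproducible and respects the stability bound", {
  sp <- polymer_spec(5, kappa = 3)
  cfg <- sim_config(n_steps = 200, seed = 99)
  t1 <- simulate_polymer(sp, list(well_spec(1, 2, c(0, 0, 0))), cfg)
  t2 <- simulate_polymer(sp, list(well_spec(1, 2, c(0, 0, 0))), cfg)
  expect_identical(t1$positions, t2$positions)
  expect_equal(dim(t1$positions), c(200L, 5L, 3L))
  expect_error(
    simulate_polymer(sp, list(), sim_config(dt = 0.1, n_steps = 100)),
    "stability")
  # diverged chains are reported, not silently propagated
  far <- matrix(5e6, 5, 3)
  expect_error(
    simulate_polymer(sp, list(), sim_config(n_steps = 10, burn_in = 0,
                                            init = "explicit",
                                            init_positions = far)),
    "diverged")
})

test_that("frame interval accounts for record_every", {
  sp <- polymer_spec(4, kappa = 3)
  tr <- simulate_polymer(sp, list(), sim_config(dt = 0.01, n_steps = 50,
                                                record_every = 10, seed = 1))
  expect_equal(tr$dt, 0.1)
  expect_equal(dim(tr$positions)[1L], 50L)
})

test_that("tethered chain matches its exact Gaussian covariance", {
  # N = 2 with one well: stationary covariance is solve(A + k e1 e1')
  sp <- polymer_spec(2, kappa = 3)
  wells <- list(well_spec(1, 2, c(0, 0, 0)))
  tr <- simulate_polymer(sp, wells,
                         sim_config(dt = 0.01, n_steps = 2e5, seed = 2,
                                    burn_in = 5000))
  S <- oracle_stationary_cov(sp, wells)
  v1 <- mean(apply(tr$positions[, 1, ], 2, var))
  v2 <- mean(apply(tr$positions[, 2, ], 2, var))
  expect_equal(v1, S[1, 1], tolerance = 0.06)
  expect_equal(v2, S[2, 2], tolerance = 0.06)
})

test_that("centre of mass of a free chain diffuses with coefficient D/N", {
  sp <- polymer_spec(10, kappa = 3)
  tr <- simulate_polymer(sp, list(), sim_config(dt = 0.01, n_steps = 1e5,
                                                burn_in = 0, seed = 3,
                                                init = "random-walk"))
  com <- apply(tr$positions, c(1, 3), mean)
  h <- 100L
  msd <- mean(rowSums((com[-(1:h), ] - com[1:(nrow(com) - h), ])^2))
  expect_equal(msd / (2 * 3 * h * 0.01), 1 / 10, tolerance = 0.1)
})

test_that("mode-space simulator refuses wells and matches real space", {
  sp <- polymer_spec(10, kappa = 3)
  expect_error(simulate_modes(sp, sim_config(n_steps = 10),
                              wells = list(well_spec(1, 1, rep(0, 3)))),
               "free chain")
  # middle-monomer MSD: two-sample comparison over replicate seeds
  lags <- c(10L, 40L, 160L)
  msd_of <- function(sim, seeds) {
    t(vapply(seeds, function(s) {
      tr <- sim(sp, sim_config(dt = 0.01, n_steps = 4000, burn_in = 500,
                               seed = s, init = "random-walk"), tagged = 5L)
      P <- tr$positions[, 1, ]
      vapply(lags, function(h)
        mean(rowSums((P[-(1:h), ] - P[1:(nrow(P) - h), ])^2)), 0)
    }, numeric(length(lags))))
  }
  m_real <- msd_of(function(sp, cfg, tagged)
    simulate_polymer(sp, list(), cfg, tagged), 1:20)
  m_mode <- msd_of(simulate_modes, 101:120)
  for (i in seq_along(lags)) {
    se <- sqrt(var(m_real[, i]) / 20 + var(m_mode[, i]) / 20)
    expect_lt(abs(mean(m_real[, i]) - mean(m_mode[, i])), 3 * se)
  }
})

test_that("mode-0 free diffusion and stationary mode variances are correct", {
  # the centre of mass from the mode simulator also diffuses at D/N
  sp <- polymer_spec(10, kappa = 3)
  tr <- simulate_modes(sp, sim_config(dt = 0.01, n_steps = 1e5, burn_in = 2000,
                                      seed = 8))
  com <- apply(tr$positions, c(1, 3), mean)
  h <- 50L
  msd <- mean(rowSums((com[-(1:h), ] - com[1:(nrow(com) - h), ])^2))
  expect_equal(msd / (2 * 3 * h * 0.01), 1 / 10, tolerance = 0.1)
  # relative coordinate of two monomers has the mode-sum stationary variance
  al <- mode_coefficients(sp); kt <- mode_stiffness(sp)
  rel_var_th <- sum((al[-1, 2] - al[-1, 9])^2 / kt[-1])
  rel <- tr$positions[, 2, ] - tr$positions[, 9, ]
  expect_equal(mean(apply(rel, 2, var)), rel_var_th, tolerance = 0.15)
})

test_that("OU simulator reproduces the exact stationary law", {
  tr <- simulate_ou(k = 2, D = 1, d = 3, dt = 0.05, n_steps = 4e4, seed = 6,
                    mu = c(5, 0, 0))
  expect_equal(unname(colMeans(tr$positions)), c(5, 0, 0), tolerance = 0.1)
  expect_equal(mean(apply(tr$positions, 2, var)), 0.5, tolerance = 0.05)
  # exact sampling: autocorrelation rate D*k even at coarse dt
  acf1 <- empirical_autocorrelation(tr, 40)
  rate <- -unname(coef(lm(log(acf1$C[1:20]) ~ acf1$lags[1:20]))[2L])
  expect_equal(rate, 2, tolerance = 0.1)
})

test_that("tagged_locus extracts recorded monomers only", {
  sp <- polymer_spec(6, kappa = 3)
  tr <- simulate_polymer(sp, list(), sim_config(n_steps = 100, seed = 1),
                         tagged = c(2L, 5L))
  lt <- tagged_locus(tr, 5)
  expect_s3_class(lt, "locus_trajectory")
  expect_equal(nrow(lt$positions), 100L)
  expect_equal(lt$positions, tr$positions[, 2, ], ignore_attr = TRUE)
  expect_error(tagged_locus(tr, 3), "not recorded")
})
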