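---
title: "Inferring chromatin tethering forces from single-locus trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromatin tethering forces from single-locus trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A chromosomal locus tagged with a fluorescent marker and followed through
time explores only a small region of the nucleus. Such confinement can arise
from passive crowding or from genuine forces — anchoring at a nuclear pore,
at the spindle pole body, or interactions with other chromosomes. The two are
distinguishable because a force applied *anywhere* on the chromatin fiber
leaves a specific statistical fingerprint on the motion of a locus observed
*elsewhere* on the fiber. `tetherscope` implements the polymer-model
machinery that turns single-particle-tracking statistics into estimates of
the strength of such a tether and of its distance (along the chain) from the
observed locus.

## The model

The fiber is a bead-spring chain of `N` monomers. In the Rouse model the
energy is

$$\phi(R) = \frac{\kappa}{2}\sum_{j=2}^{N}(R_j - R_{j-1})^2 + U_\text{ext}(R),$$

and each monomer follows overdamped Langevin dynamics

$$\dot R_j = -D\,\nabla_{R_j}\phi(R) + \sqrt{2D}\,\dot w_j,$$

with diffusion coefficient `D` and independent white noises `w_j`. All
quantities default to natural units: lengths in the bond scale `b`, energies
in `kBT`, time in `b^2/D`; stiffnesses are `kBT/b^2`. The inter-monomer
constant `kappa` is a free input — the harmonic identification
`kappa = d*kBT/b^2` motivates values around 2–3, but nothing in the package
derives it from the dimension.

The *beta-polymer* generalises this: long-range harmonic couplings are
chosen so that a monomer's intermediate-time MSD grows as `t^alpha` with
`alpha = 1 - 1/beta` (Rouse: `beta = 2`, `alpha = 1/2`). Its construction is
spectral: in the cosine mode basis (`mode_coefficients()`) the mode
stiffnesses are `kt_p = 4*kappa*sin(p*pi/(2N))^beta`
(`mode_stiffness()`), and `connectivity_matrix()` maps them back to the
monomer-space coupling matrix `A`. At `beta = 2` this reproduces the
nearest-neighbour spring Laplacian exactly, which the tests verify against a
directly assembled oracle.

A tether is an external harmonic well `U = (k/2)(R_n - \mu)^2` acting on a
single monomer `n` (`well_spec()`) — the quadratic approximation of any
smooth stationary interaction. Up to two wells are supported.

## The inversion formulas

The central objects are closed forms for the *effective spring constant*
`k_c`: the coefficient of the linear restoring drift seen at the observed
monomer `c`,
$$\lim_{\Delta t \to 0} E\left\{\tfrac{R_c(t+\Delta t)-R_c(t)}{\Delta t}
\,\middle|\, R_c = x\right\} = -D\,k_c\,(x - \langle R_c\rangle).$$

* **Single well, Rouse** (`effective_stiffness_single()`):
  `k_cn = k*kappa/(kappa + |c-n|*k)`. The tether is felt undiminished at the
  tethered monomer and is screened by the intervening chain; in the pinned
  limit `k >> kappa` it reduces to `kappa/|c-n|`, so the measured stiffness
  reads out the *distance to the anchor*.
* **Stationary variance** (`stationary_variance()`): at equilibrium the total
  centred variance of the locus is `d/k_c` (natural units; `d*kBT/k_c`
  otherwise) — the same law as an Ornstein–Uhlenbeck particle in a well of
  stiffness `k_c`.
* **Two wells** (`effective_stiffness_two_wells()`,
  `mean_position_two_wells()`): between the anchors the effective
  stiffnesses add, `k_cnm = k_cn + k_cm`; beyond both anchors a rational
  expression applies that tends to `kappa/|c-m|` — only the nearest anchor
  is visible from outside. The beyond-anchors closed form is only available
  for equal well strengths, and the package refuses to guess a
  generalisation. The mirror ordering (observed monomer before both wells)
  is obtained by relabelling the chain end-to-end, which is exact by
  reflection symmetry.
* **Beta-polymer, one well** (`effective_stiffness_beta()`): the energy is
  quadratic per coordinate with precision matrix `M = A + k e_n e_n'`, and
  the conditional drift of coordinate `c` given only `R_c` is governed by
  the Schur complement of `M` onto `c` (equivalently `1/(M^{-1})_{cc}`).
  This is the unique quantity consistent with the conditional-Gaussian drift,
  and it reduces to the single-well formula at `beta = 2` to `1e-10` over a
  broad parameter grid (tested). Long-range coupling (`beta < 2`) makes `k_c`
  decay *more slowly* with chain distance.

### Theory autocorrelation and its validity

`autocorrelation_theory()` evaluates the mode-diagonal approximation of the
stationary autocovariance of a tethered monomer: a sum of exponentials whose
slowest rate is `D*k/N`, so the well strength can be read off the tail decay
when `D` is known. Two properties matter in practice:

* the *rate* structure is accurate in the weak-coupling regime
  `(alpha_p^n)^2 k << kt_p`;
* the *amplitude* at lag zero **underestimates** the exact variance
  `d/k_cn` whenever the separation term `|c-n|/kappa` contributes, because
  dropping the well-induced mode coupling discards exactly the
  cross-covariances that build that term. The approximation converges to the
  exact variance as `k -> 0`; the tests assert the direction, monotonicity,
  and weak-coupling convergence of this error rather than a blanket
  agreement that does not hold.

`relaxation_time()` returns `tau_r = sep^beta/(D*kappa*pi^beta)` for a chain
segment. Note that for a *strongly* tethered chain the slowest relaxation —
the pendulum mode of the chain about the pin — is roughly four times longer
than this segment estimate (wavelength `4L` rather than `2L`). The package's
default burn-in (10 `tau_r`) is therefore adequate for drift-based
estimation, but experiments targeting equilibrium variances should use runs
of hundreds of `tau_r`, as the bundled acceptance experiments do.

## Simulation

`simulate_polymer()` integrates the dynamics by Euler–Maruyama,
`R(t+dt) = R(t) - D*grad(phi)*dt + sqrt(2*D*dt)*xi`, in compiled code
(nearest-neighbour fast path at `beta = 2`, dense coupling otherwise).
Choices worth knowing:

* **Stability.** The step must satisfy `dt < 0.2/(D*lambda_max)` with
  `lambda_max` the largest connectivity eigenvalue plus the strongest well;
  violating it is an error, and any coordinate exceeding `1e6*b` aborts the
  run rather than returning garbage. The default `dt = 0.01 b^2/D` sits
  comfortably below the bound for the chains studied here.
* **Discretisation bias.** Euler dynamics at `dt = 0.01` inflate stationary
  variances and drift-slope estimates by a few percent (order `D*lambda*dt/2`
  per mode). This is a property of the discretised chain itself, shared by
  any analysis run at that step.
* **Initialisation and burn-in.** Default start is a random-walk chain with
  bond sd `b` placed at the first well centre (fast approach to the tethered
  state); default burn-in is `10*tau_r` rounded up, with `tau_r` taken over
  the half-chain (free) or the longest tether-to-end segment (tethered).
* **Reproducibility.** One RNG stream (R's, seeded by `sim_config(seed=)`),
  drawn in coordinate-major order within each step; identical config and
  seed give bit-identical trajectories, which the tests assert.
* **Geometry.** Free space only; no reflecting confinement, hydrodynamics,
  self-avoidance, or active forcing.

`simulate_modes()` integrates the free chain in normal-mode space (the same
Euler recursion, evaluated as a vectorised AR(1) filter per mode, modes
initialised from their stationary law, centre of mass at the origin) and is
the cheap route to long free-chain runs; it refuses wells, which couple the
modes. Real-space and mode-space simulators agree in distribution, which the
tests check on replicate middle-monomer MSDs. `simulate_ou()` provides the
exact one-particle reduction (no discretisation error) and serves as ground
truth for estimator tests.

## Estimators

Given a `locus_trajectory` (from tracking exports via `read_locus_csv()` or
from `tagged_locus()`):

* `mean_position()` — estimates the well centre for single-tether data;
  SE `sigma/sqrt(N_p)` per axis for effectively independent frames.
* `estimate_stiffness_regression()` (default) — pooled least-squares slope
  of the step `R(h+1)-R(h)` against the centred position; `k_c = -s/(D dt)`.
  In expectation this equals the inversion-formula `k_c` (up to the Euler
  attenuation `(1-e^{-lambda dt})/(lambda dt)` at finite lag).
* `estimate_stiffness_moment()` — the first-moment form of the same
  statistic with per-axis variance normalisation, averaged over axes. The
  raw step-times-position moment *without* a variance divisor is
  dimensionally a pure number (its expectation is `-k_c sigma^2_axis`,
  i.e. `-1` at equilibrium in natural units), so a variance normalisation is
  required for the estimator to converge to `k_c`; the moment and regression
  forms then differ only in how axes are pooled and agree on isotropic data.
* `estimate_stiffness_variance()` — `k_c = d/variance`; valid only at
  equilibrium (records much longer than `tau_r`; pass `tau_r` to get a
  warning otherwise). Drift-based estimators remain valid on short records.
* `conditional_drift()` / `fit_drift_stiffness()` — the binned empirical
  drift field `E[dR/dt | R = x]`, the most direct face of the inversion
  formula: linear with slope `-D*k_c` for harmonic tethers. Bins are
  equal-width over the central 99% of positions; bins with fewer than 20
  steps are flagged and excluded, and the call errors when fewer than 80% of
  bins are usable.
* `empirical_autocorrelation()` — lagged, mean-subtracted autocovariance
  summed over axes, normalisation `1/(N_p - h)`; lag 0 equals the total
  centred variance exactly. Lags are capped at `N_p/5` so every point
  averages enough pairs.
* `fit_double_exponential()` — `a1 e^{-t/tau1} + a2 e^{-t/tau2}`
  (`tau1 > tau2`) by Levenberg–Marquardt with non-negativity bounds.
  Starting values are always derived from the curve (candidate time
  constants around the 1/e crossing and the lag span; amplitudes solved
  linearly; candidates tried in order of residual). Genuinely
  single-exponential input converges to a boundary solution with one
  amplitude at zero — reported as such, with `NA` standard errors for the
  collapsed component rather than invented ones. Non-convergence from every
  candidate raises an error carrying the diagnostics.
* `estimate_diffusion()` — drift-corrected second moment of single-frame
  steps over `2 d dt`; a short-lag approximation, accurate when
  `D k_c dt << 1`.
* `msd_and_exponent()` — time-averaged MSD and the log-log slope over a
  caller-chosen window. The window matters: it must sit above the
  single-monomer crossover and below the centre-of-mass regime, and for
  `beta < 2` the asymptotic exponent is approached slowly, so long chains
  and late windows are needed (see below).
* `powerlaw_fit()` — `k_c = a * v^b` across loci in log-log space. The
  equilibrium law predicts `b = -1`, `a = d` with the centred variance on
  the x-axis. (Reported population fits in the experimental literature
  sometimes quote a positive exponent; that convention corresponds to the
  reciprocal axis, and this function simply fits the cloud it is given.)

For 3D microscopy data with poor axial precision, `project_axes()` restricts
the analysis to the x–y plane; for an isotropic tether this changes `d` but
not the expected `k_c`, which the tests verify.

## The synthetic-data generator

`generate_fixture()` produces trajectory CSVs with a JSON ground-truth
sidecar (all generating parameters plus the analytic `k_c` for each
recorded locus). Scenarios: `ou` (single particle in a well, exact sampler),
`tethered-rouse` (the reference experiment: `N = 30`, first monomer tethered
with `k = 2`, `kappa = 3`, `dt = 0.01`, loci at the tethered, middle and end
monomers — analytic stiffnesses 2, 6/33, 6/61), `tethered-beta`
(`beta = 1.5` variant), `two-well` (`N = 21`, both ends anchored 5 `b`
apart), and `free-chain`. Everything is deterministic given the seed, and
every output file carries the package version, seed and a config
fingerprint.

What the generator emulates: equilibrium tethered-polymer and OU motion at a
uniform frame interval, with heterogeneous stiffness across cells. What it
does **not** emulate: localisation noise, motion blur, tracking failures,
photobleaching-limited record lengths, nuclear confinement, or
ATP-driven activity. Passing tests therefore demonstrate correctness of the
method under its own model assumptions, not robustness to those
experimental artefacts — which is the appropriate scope for validating the
inversion machinery itself.

## Study conditions used in the tests

Problem sizes were chosen once as realistic for the method and kept fixed:

* Tethered-chain recovery: `N = 30`, `k = 2`, `kappa = 3`, `dt = 0.01`,
  2×10⁶ frames after a 10⁵-step burn-in (run length ≈ 170 slowest
  relaxation times); the acceptance script uses 5×10⁶ frames.
* Variance–stiffness: `N = 5` (single well, separation 2) and `N = 9`
  (both ends anchored), 10⁶ frames each.
* MSD exponents: free chains via the mode simulator — Rouse `N = 100`,
  fit window 0.5–8 `b²/D`; `beta = 1.5` `N = 300`, window 4–40 `b²/D`
  (the `beta = 1.5` exponent approaches 1/3 slowly, so shorter chains or
  earlier windows read high).
* Population pipeline: 21 synthetic cells, `d = 2`, stiffness log-uniform
  in [0.5, 8], 6000 frames at `dt = 0.05`.

## Known limitations

* Equilibrium Boltzmann statistics are assumed by the variance and
  mean-position inversions; only the drift-based estimators are valid on
  non-equilibrated records.
* The two-well beyond-anchor formula requires equal well strengths.
* The theory autocorrelation is a weak-coupling approximation (see above);
  use the exact variance relation, not its lag-zero value, for stiffness.
* Estimator standard errors treat steps as independent; serial correlation
  on times comparable to the slowest chain mode makes them optimistic for
  long-separation loci.
* Active (non-thermal) forces, time-varying tethers and confinement are out
  of scope.
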