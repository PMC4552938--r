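# tetherscope

Extracting tethering interactions acting on chromatin (or any bead-spring
polymer) from the trajectory of a single tracked locus.

A chromosomal locus followed by live-cell imaging often explores only a small
region of the nucleus. `tetherscope` implements the polymer-model analysis
that decides whether such confinement reflects a genuine force — anchoring at
a nuclear pore, the spindle pole body, another chromosome — and, if so, how
strong that force is and how far along the fiber it acts, even though the
interacting site itself is invisible.

## The model in one paragraph

The fiber is a Rouse chain (N monomers, spring constant κ, monomer diffusion
coefficient D) or its β-polymer generalisation with long-range couplings and
anomalous MSD exponent α = 1 − 1/β. A stationary interaction is a harmonic
well U = (k/2)(R_n − μ)² on monomer n. The observed monomer c then feels a
linear restoring drift −D·k_c·(x − ⟨R_c⟩) with an *effective spring
constant* given in closed form:

- one well, Rouse: `k_cn = kκ / (κ + |c−n|·k)` — screened by the chain, and
  `k_cn ≈ κ/|c−n|` for strong anchors, so the stiffness reads out the
  distance to the anchor;
- stationary variance: `⟨(R_c − ⟨R_c⟩)²⟩ = d/k_c` (d = dimension; natural
  units with kBT = 1);
- two wells: stiffnesses add between the anchors, only the nearest anchor is
  felt beyond them;
- β-polymer: k_c is the Schur complement of the tethered coupling matrix
  onto the observed monomer, reducing exactly to the Rouse formula at β = 2.

On the data side, the package estimates k_c from trajectories by
step-vs-position regression (valid even before equilibration), by variance
inversion, and from the binned conditional drift field; plus the diffusion
coefficient, the time-averaged MSD exponent, the position autocorrelation
with a double-exponential fit, and the population-level power law between
stiffness and variance across cells.

A compiled Euler–Maruyama simulator (full chain, up to two wells), a
normal-mode simulator for free chains, an exact Ornstein–Uhlenbeck reference
sampler, and a synthetic-fixture generator with JSON ground truth round out
the toolbox.

## Worked example

Tether the first monomer of an N = 30 Rouse chain (k = 2, κ = 3 kBT/b²) and
recover the force felt by the middle monomer, 15 links away:

```r
library(tetherscope)

sp   <- polymer_spec(N = 30, kappa = 3)          # Rouse chain, natural units
well <- well_spec(n = 1, k = 2)                  # tether at the origin

effective_stiffness_single(k = 2, kappa = 3, sep = 15)
#> <effective_stiffness> k_c = 0.181818  (model: single-well)

tr <- simulate_polymer(sp, list(well),
                       sim_config(dt = 0.01, n_steps = 1e6, seed = 1),
                       tagged = c(1, 16))
locus <- tagged_locus(tr, 16)
locus
#> <locus_trajectory> [monomer16] 1000000 frames x 3D, dt = 0.01 b^2/D, units b

estimate_stiffness_regression(locus, D = 1)
#> <stiffness_estimate> k_c = 0.186 +/- 0.00352 kBT/b^2  (regression, 1000000 frames)
estimate_stiffness_variance(locus)
#> <stiffness_estimate> k_c = 0.1807 +/- 0.000148 kBT/b^2  (variance, 1000000 frames)

round(mean_position(locus), 3)       # estimates the well centre (0,0,0)
#>      x      y      z
#>  0.429 -0.634  0.281
estimate_diffusion(locus)            # short-lag estimate of D (true value 1)
#> [1] 1.03
```

Both estimators recover the analytic k_c = 0.182 from the trajectory alone:
a locus 15 monomers from the anchor still carries a measurable imprint of
the force. The small excess of the regression value is the Euler
discretisation bias at dt = 0.01 plus finite-record noise (see the
vignette). The autocorrelation view of the same data:

```r
acf1 <- empirical_autocorrelation(locus, max_lag = 3e4)
fit_double_exponential(acf1)
#> <autocorr_fit> a1 = 9.362 (tau1 = 245.1), a2 = 6.035 (tau2 = 40.56)
```

a two-exponential decay whose amplitudes sum to the stationary variance
d/k_c ≈ 16.5 b², as the theory predicts for a tethered polymer (a confined
*free* locus would not show this structure).

Batch analysis of tracked loci (CSV files `time,x,y[,z]`, one row per
frame) runs through `run_pipeline("dir/")` or the thin CLI in
`exec/tetherscope` (`analytic`, `simulate`, `fixture`, `estimate`, `acf`,
`pipeline` subcommands).

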