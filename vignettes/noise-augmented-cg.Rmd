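---
title: "Methods: noise-augmented training of coarse-grained force fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise-augmented training of coarse-grained force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `cgnoise`, the closed-form
identities the implementation is tested against, the defaults and why they
have the values they do, the design of the synthetic reference systems, and
the limitations of the approach. Code chunks are illustrative and not
evaluated at build time.

## 1. Model

### 1.1 Force matching

A coarse-grained (CG) configuration is `R = M r`, with `M` an `N x n` linear
map from `n` fine particles to `N` CG sites. Bottom-up training of a CG
potential `u_theta(R)` by **force matching** minimizes

```
L_FM(theta) = < | F_theta(M r) - T f(r) |^2 >,
```

the mean squared difference between the model force `F_theta = -grad u_theta`
and a mapped fine-grained force `T f(r)`. The force map `T` must satisfy the
consistency constraint `T M' = I` for the minimizer of `L_FM` to be the
many-body potential of mean force (PMF); any such `T` gives an unbiased
estimator, and the freedom in `T` can be used to reduce its variance
(Section 2).

### 1.2 Denoising score matching

The second ingredient needs only *configurations*, not forces. Replace the
deterministic map by a Gaussian kernel

```
kappa(R | r) ∝ exp( -|M r - R|^2 / (2 sigma^2) ),
```

i.e. `R = M r + sigma * eps` with `eps ~ N(0, I)`. Single-noise-level
**denoising score matching** (DSM) trains the model force to predict the
score of this kernel:

```
L_DSM(theta) = < | F_theta(M r + sigma eps) - ( -eps / sigma ) |^2 >.
```

Its exact minimizer is the gradient of the log *noised* marginal
`p_sigma(R) = ∫ p(r) kappa(R|r) dr`, so DSM on its own learns the PMF of the
noised ensemble — for a Gaussian fine system with coupling matrix `K` this is
explicit: the noised CG precision is `(M K^-1 M' + sigma^2 I)^-1`. Crucially,
DSM learns the PMF of the *data distribution*: if the data are biased, so is
the learned surface (this is tested directly; see Section 4.3).

### 1.3 The combined objective

Writing the kernel score in closed form,

```
grad_R log kappa = (M r - R) / sigma^2 = -eps / sigma,
grad_r log kappa = -M' grad_R log kappa,
```

both losses become instances of one regression with per-frame targets

```
target = -eps/sigma + V ( T f(r) + eps/sigma ),
```

where `V` is an `N x N` *noise-stage* map acting after the atomistic stage
`T`. Conditionally on the noised input `R`, the mean of
`T f + eps/sigma` is zero whenever `T M' = I`, so the regression target has
the same conditional mean — the noised mean force — **for every finite
`V`**. `V` trades variance, never bias. Two limits are exact and are
enforced by tests to machine precision:

* `V = 0` recovers pure DSM (`loss_combined` equals `loss_denoising`
  batch-for-batch when the same draws are used);
* `sigma^2 = 0` (degenerate kernel) recovers plain force matching on
  `(M r, T f)`.

The practical appeal: frames without force labels still contribute through
the `-eps/sigma` part, so the combined loss extracts more information per
frame on scarce data.

## 2. Two-stage optimal force maps

### 2.1 Atomistic stage

`optimize_atomistic_map()` minimizes the mapped-force second moment
`< |T f|^2 >` subject to `T M' = I`, with an optional ridge
`l2_atom |T - T_ref|^2` toward a reference map (the slice map when the CG
map is a slice). The KKT system is solved for the deviation `D = T - T_ref`
by Schur-complement elimination against `A = C + l2_atom I` (with `C` the
force second-moment matrix), which stays well conditioned for any ridge
strength — a direct bordered-KKT solve loses the constraint to roundoff when
`l2_atom` is many orders of magnitude larger than `C`.

A fully worked example used throughout the tests: two particles with
coupling `K = [[2,-1],[-1,2]]` and the slice map `M = [1, 0]`. The
constrained optimum is `T = [1, 1/2]`, with residual `<|T f|^2> = 3/2`
versus `2` for the slice map `T = [1, 0]` — about a 25% variance reduction
at zero bias.

### 2.2 Noise stage

With blocks `g = -eps/sigma` and `h = T f + eps/sigma`,
`optimize_noise_stage()` solves the ridge regression

```
V = argmin < | g + V h |^2 >  =  -<g h'> ( <h h'> + l2_noise I )^-1,
```

with moments accumulated over frames, seeded noise draws and spatial
dimensions. Any `V` keeps the target conditionally unbiased (tested by
regressing targets on `R` for zero, optimized and arbitrary `V` and checking
the slope against the analytic score slope `-1/(2/3 + sigma^2)` of the
worked example).

### 2.3 Ridge defaults

The default ridge strengths are `l2_atom = 1e3` for the atomistic stage and
`l2_noise = 5` for the noise stage. These are study conditions, appropriate
when atomistic forces are in physical units (kcal/mol/Å) where force second
moments are numerically large; for the unit-free synthetic systems the
tests frequently pass `l2 = 0` to compare against closed-form optima.

## 3. Noise level and training defaults

* **Noise variance.** Useful values of `sigma^2` are small: around
  `5e-4`–`5e-3` Å² in the regime the defaults target (the package default is
  `3e-3`). `noise_kernel()` warns above `1e-2` because large noise blurs the
  landscape faster than it regularizes: the learned surface converges to the
  noised PMF, whose barriers are provably lower (tested on the double-well
  oracle), so the error with respect to the true PMF grows monotonically
  with `sigma^2` (tested as a strict drift on the Gaussian network).
* **Optimization.** `fit_sgd()` is ADAM with a frozen validation noise set,
  early stopping on patience, and best-validation parameter selection; all
  randomness (split, validation noise, per-epoch draws) is derived from one
  seed via `derive_seed()`. For linear-in-parameters bases,
  `fit_linear_closed_form()` solves the same objective exactly by
  SVD-pseudoinverse, and SGD is tested to converge to it.
* **Simulation.** CG dynamics use BAOAB Langevin with friction `1 ps^-1` and
  a `2 fs` timestep in physical-unit presets (the unit-free tests use larger
  dimensionless steps). Parallel tempering uses a geometric temperature
  ladder — the preset spans `284.1`–`362` K over 10 rungs — with
  alternating-parity Metropolis exchanges and velocity rescaling; exchange
  acceptance is reported per adjacent pair and should be monitored to stay
  above ~0.3 (tests require all rates inside `(0.05, 0.95)` on a 6 kT
  tilted double well).

## 4. Synthetic reference systems and why they look the way they do

The generators are deliberately *exactly solvable*, so every statistical
test has a closed-form or quadrature ground truth rather than a golden file.

### 4.1 Gaussian network

`make_gaussian_network(n)` builds `u(r) = r' K r / 2` with a
nearest-neighbour spring + tether precision `K` (positive definite by
construction, rejected otherwise). Everything is analytic: the exact sampler
is a Cholesky draw, the CG marginal precision is `(M K^-1 M')^-1`, and the
noised marginal adds `sigma^2 I` inside the inverse. This is the oracle for
loss reductions, map optimality, unbiasedness slopes and precision-recovery
tests.

### 4.2 Double-well chain

`make_double_well_chain()` couples a 1-D double well in the bond
displacement `d`, `a (d^2 - d0^2)^2`, to `n_bath` harmonic bath coordinates
whose rest positions depend on `d`:

```
u = a (d^2 - d0^2)^2 + (k_bath / 2) * sum_i ( y_i - c_couple * d^2 )^2.
```

The bath integrates out exactly — the PMF over `d` is the bare double well,
computable by quadrature — but the `d`-dependent rest offset makes the
*mapped force* on `d` depend on the instantaneous bath state, creating a
large irreducible variance (~400 in squared thermal-force units with the
defaults `a = 6, d0 = 1, k_bath = 100, c_couple = 0.5, n_bath = 4`). That
variance is the point: it makes forces-only training data-hungry, so the
benefit of adding the noise term is measurable at realistic sample sizes
(`n = 2000` frames) instead of being washed out. Biased datasets seed the
two basins 80/20 to emulate unconverged sampling.

### 4.3 What the oracles check

`quadrature_pmf()` integrates the Boltzmann weight on a grid and convolves
with the Gaussian kernel on a padded grid when `sigma^2 > 0`;
`basin_probability()` integrates basin weights (splitting a grid point that
falls exactly on the divide). These back three headline comparisons: noise
lowers barriers; combined training beats forces-only on scarce biased data
(median FES error over seeds); and noise-only training reproduces the
*biased empirical* histogram rather than the equilibrium PMF — the
signature that DSM learns the data distribution.

## 5. Analysis choices

* `histogram_fes()` returns `-log p`, min-shifted, with empty bins masked;
  `fes_error()` is a mean-aligned mean absolute error over jointly populated
  bins with reference free energy below 9 kT, so the metric is invariant to
  the arbitrary FES offset and not dominated by never-visited bins.
* `tica()` symmetrizes the lagged covariance, whitens with a ridge-guarded
  inverse square root, clips eigenvalues to `[-1, 1]` and fixes the sign by
  the largest loading; the slow eigenvalue equals the lag-autocorrelation of
  the slow latent mode of an AR(1) mixture, which the tests recover to 0.02.
* `run_pipeline()` hashes the configuration *excluding* the output
  directory, so bit-identical artifacts are produced for the same scientific
  configuration regardless of where they are written.

## 6. Limitations

* Maps are **linear** (`M`, `T`, `V`); nonlinear CG maps and
  configuration-dependent force maps are out of scope.
* The kernel is **single-noise-level** and isotropic; no noise schedules,
  annealing or diffusion-style multi-level training.
* The synthetic systems are low-dimensional stand-ins: they reproduce the
  *statistical structure* of the problem (mapped-force variance, metastable
  basins, biased sampling) but none of the chemistry — no excluded volume,
  no solvent, no transferability questions.
* DSM inherits the bias of the data distribution by construction; the
  combined loss mitigates but does not remove this when force labels are
  scarce.
* Quadrature oracles are 1-D in the coarse coordinate; multidimensional
  reference PMFs are only available for Gaussian systems.

## 7. Minimal end-to-end example

```{r example}
library(cgnoise)
cfg <- preset_config("double_well")
cfg$outdir <- "run1"
res <- run_pipeline(cfg)
res$summary
```
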