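---
title: "Null-model normalisation of partial information decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model normalisation of partial information decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numit)
```

## The problem

Partial information decomposition (PID) splits the mutual information
that two sources $X$, $Y$ carry about a target $T$ into four atoms,

$$I(X,Y;T) = \mathrm{Red} + \mathrm{Un}_X + \mathrm{Un}_Y + \mathrm{Syn},$$

interpreted as redundant, unique, and synergistic information. Under the
minimal-mutual-information (MMI) definition used throughout this package,
$\mathrm{Red} = \min(I(X;T), I(Y;T))$ and the other atoms follow from the
identity above; for jointly Gaussian systems this coincides with several
otherwise distinct redundancy proposals.

Raw atoms are not comparable across systems: their values depend strongly
on the total mutual information (TMI) of the system, which in turn tracks
the signal-to-noise ratio. On the package's reference bivariate system
(`gaussian_system` with couplings $(0.5, 0.5)$, source covariance
$[[20,10],[10,20]]$, unit noise) the decomposition is synergy-dominated
at low noise and redundancy-dominated at high noise, even though the
coupling structure never changes. Dividing each atom by the TMI (the
"NMI" baseline, `nmi_normalise()`) does not fix this, because the atoms
do not grow linearly with TMI: ensembles of random systems are
unique-information-dominated at low TMI and synergy-dominated at high
TMI.

## The NuMIT procedure

NuMIT scores a system against *all systems that carry the same total
mutual information*:

1. compute the system's TMI and PID atoms;
2. sample a random system constrained to the same TMI;
3. repeat $N$ times, obtaining a null distribution per atom;
4. report each observed atom's quantile within its null distribution.

A quantile near 1 means the system is more redundant (or unique, or
synergistic) than almost any random system with the same TMI; 0.5 means
typical. The construction removes the mechanical dependence of the atoms
on TMI, so the normalised values are comparable across systems, datasets,
and noise levels.

### Gaussian nulls

For a linear-Gaussian system $T = AS + \sqrt{g}\,\varepsilon$ with
$S \sim \mathcal N(0, \Sigma_S)$, $\varepsilon \sim \mathcal N(0,
\Sigma_\varepsilon)$, the target covariance is
$A\Sigma_S A^\top + g\,\Sigma_\varepsilon$ and

$$\mathrm{TMI}(g) = \tfrac12 \log
\frac{|A\Sigma_S A^\top + g\Sigma_\varepsilon|}{|g\Sigma_\varepsilon|},$$

a strictly decreasing function of the noise strength $g$. Null systems
draw $A_{ij} \sim \mathcal N(0,1)$ and $\Sigma_S, \Sigma_\varepsilon$
from Wishart distributions with identity scale and degrees of freedom
equal to the dimension (the smallest value giving almost-surely
positive-definite draws), then solve $\mathrm{TMI}(g) = \text{target}$
for $g$. Note the convention: $g$ enters on the covariance scale, so the
effective noise covariance is $g\,\Sigma_\varepsilon$ and samplers use
$\sqrt g$ on the noise draw; this is the reading under which the
closed-form TMI above is exact.

`solve_noise_parameter()` reduces the TMI to
$\tfrac12\sum_i \log(1 + \lambda_i/g)$, where $\lambda_i$ are the
eigenvalues of $L^{-\top} A\Sigma_S A^\top L^{-1}$ with
$\Sigma_\varepsilon = L^\top L$. Rank-one signals admit the closed form
$g = \lambda / (e^{2\,\mathrm{TMI}} - 1)$; otherwise the root is found on
the $\log g$ scale (bracketing plus Newton polish), which avoids
determinant overflow at extreme $g$ and achieves the TMI constraint to
well below $10^{-8}$ nats. All log-determinants go through Cholesky
factors, never raw determinants; positive definiteness requires the
smallest eigenvalue to exceed $10^{-10}$ times the largest.

### VAR nulls

A stationary VAR(p) process
$X_t = \sum_l A_l X_{t-l} + \eta_t$, $\eta_t \sim \mathcal N(0, V)$, has
autocovariances $\Gamma_k = E[X_t X_{t-k}^\top]$ obtained from the
discrete Lyapunov equation of the companion form,
$\Gamma = \mathbf A \Gamma \mathbf A^\top + W$ (solved here by Kronecker
vectorisation, which is exact and fast at the state dimensions used).
Treating the past state as the sources and the one-step future as the
target,

$$\mathrm{TMI} = \tfrac12 \log|\Gamma_0| - \tfrac12 \log|V|,$$

because $V$ is exactly the conditional covariance of the future given the
past. Rescaling $V$ rescales every $\Gamma_k$ identically and leaves the
TMI — and every PID atom — unchanged, so the noise scale cannot play the
role of the tuning parameter. Instead the spectral radius of the
companion matrix does: decaying the lag-$k$ coefficients by $f^k$ with
$f = \rho'/\rho$ sets the radius to $\rho'$ exactly
(`rescale_to_radius()`; plain rescaling of $A$ for VAR(1)), and the TMI
is strictly increasing in $\rho'$ on $(0, 1)$. VAR nulls therefore draw
$A_{ij} \sim \mathcal N(0,1)$ (or, in data-driven mode, an empirical
coefficient matrix from the supplied pool) and $V \sim$ Wishart, then
solve for the radius that reproduces the observed TMI
(`solve_radius_for_tmi()`, bisection plus secant polish to $10^{-10}$
nats). Targets that remain unreachable at the stability margin
($\rho' \le 1 - 10^{-6}$) cause that draw to be discarded and resampled —
keeping the ensemble exactly on the TMI constraint at the cost of a mild
selection effect, whose count is reported with each ensemble.

## Tunable parameters

* `n_samples` (default 500): null-ensemble size; quantile resolution is
  $1/N$ (0.002 at the default), and the Monte-Carlo error of a quantile
  is about $\sqrt{q(1-q)/N}$ ($\approx 0.022$ at $q = 0.5$).
* `coeff_std` (default 1) and the Wishart degrees of freedom (default =
  dimension): the shape of the null family. Normalised results are
  reported to be robust to these choices; they are exposed as knobs, not
  swept here.
* `tmi_tol` in `numit_quantile()` ($10^{-6}$ nats): guard against scoring
  a system on an ensemble built for a different TMI.
* Degeneracy floor ($10^{-6}$ nats): systems carrying essentially no
  information are refused by the normalisers — quantiles within a
  no-information null family are meaningless.
* `tmi_floor` in `region_subset_pipeline()`: same role, but worth raising
  for fitted models, since OLS estimation bias alone produces a TMI of
  roughly $n^2 / (2 \cdot \text{rows})$ nats on pure noise — far above
  $10^{-6}$ at realistic sample sizes.

## Quantile and tie conventions

Quantiles use the mid-rank convention,
$(\#\{\text{null} < x\} + \tfrac12 \#\{\text{null} = x\})/N$, so an
observation below every null scores 0 and ties split the difference.
Under MMI the smaller unique information is identically zero, which has
two consequences worth knowing: when $I(X;T) = I(Y;T)$ both uniques are
zero, and the null distribution of each individual unique atom carries a
point mass at zero. The probability-integral-transform property (null
draws scored on independent same-TMI ensembles are uniform) therefore
holds for redundancy and synergy, and for the continuous
$\max(\mathrm{Un}_X, \mathrm{Un}_Y)$ summary, but cannot hold for an
individual unique atom — a property of the MMI measure itself, not of the
implementation. Summaries labelled "unique information" in the
distribution study report the per-draw maximum for the same reason.

## Fitting VAR models from data

`fit_var()` pools time-lagged regression rows across epochs (epochs are
treated as independent stationary realisations), de-means each channel
within each epoch, and fits each equation by least squares without
intercept; the innovation covariance uses the degrees-of-freedom
corrected denominator (rows $- np$). This is a plain OLS estimator
rather than the locally-weighted variant found in some toolboxes; at the
sample sizes used here (tens of thousands of rows) the estimators agree
to well within the tolerances of every downstream property, and OLS
keeps the implementation transparent. The fitted model is not forced to
be stationary; operations that require stability re-validate the
spectral radius (margin $1 - 10^{-6}$) and fail loudly.

The region-subset pipeline mirrors a standard multichannel analysis:
repeatedly draw 10 of the available channels, split 5/5 at random into
sources, fit a VAR(1), and compute raw, NMI, and NuMIT atoms,
averaging across subsets at the end. All random choices (subsets,
splits, per-subset ensemble seeds) are frozen up-front from one master
seed, so runs are exactly reproducible.

## What the synthetic generator does and does not emulate

`surrogate_meg()` draws a random stable VAR(1) at a chosen spectral
radius (default 0.8, a typical value for band-limited neural recordings)
with a Wishart innovation covariance, and simulates 50 epochs of 1200
timepoints — the epoch geometry of a 2-second, 600 Hz epoching. It gives
the pipeline a ground truth with known coefficients and known TMI. It
does **not** emulate non-linearity, non-stationarity across epochs,
volume conduction / field spread, 1/f spectra, or artefact structure of
real recordings; passing tests on surrogates demonstrates correctness of
the estimators and the normalisation machinery, not robustness to those
real-data features.

## Numerical choices and degenerate inputs

* Log-determinants via Cholesky; failures name the offending marginal.
* Positive-definiteness tolerance: $\lambda_{\min} > 10^{-10}
  \lambda_{\max}$; near-singular Wishart draws in null sampling are
  discarded and redrawn (bounded by `max_resample`).
* Closed-form marginal informations are clamped at the TMI before the
  decomposition (rounding can push them above by $\sim 10^{-14}$);
  violations beyond $10^{-9}$ abort, since they signal a genuine
  upstream inconsistency.
* Zero coupling ($A = 0$): TMI is identically zero; solvers and
  normalisers refuse with explicit errors rather than returning
  meaningless quantiles.
* The radius solver brackets strictly inside the stability margin and
  polishes to $10^{-10}$ nats; the g-solver reaches machine precision.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately modest scale: noise
sweeps use 20 grid points with 500-draw ensembles; distribution studies
2000 draws per TMI; parameter sweeps 6-point grids × 20 noise values
with 200-draw ensembles; the PIT audit 200 repetitions against 200-draw
ensembles; the simulation oracle $10^6$ steps; fitting checks 50 × 1200
× 10 channels. These sizes put Monte-Carlo noise comfortably below the
effect sizes being asserted while keeping the whole suite in a few
minutes; every runner accepts larger values for full-scale replication.

## Worked example

```{r example, eval = FALSE}
sys <- gaussian_system(sigma_s = matrix(c(20, 10, 10, 20), 2),
                       a = c(0.5, 0.5), sigma_eps = 1, g = 1, d_x = 1)
pid_from_system(sys)          # raw atoms, synergy-dominated
numit_normalise_gaussian(sys, null_config(n_samples = 500, seed = 1))

# the same structure at 100x the noise: raw atoms collapse and flip,
# NuMIT quantiles barely move
sys100 <- gaussian_system(matrix(c(20, 10, 10, 20), 2), c(0.5, 0.5),
                          1, 100, d_x = 1)
pid_from_system(sys100)
numit_normalise_gaussian(sys100, null_config(n_samples = 500, seed = 1))
```

## Known limitations

* Only the MMI redundancy ships; `mmi_atoms()` accepts any redundancy
  function with signature `(i_x, i_y, tmi)` as a plug-in point, but no
  alternative definition is provided.
* The past→future decomposition is implemented for VAR(1); the companion
  and Lyapunov machinery handles general order (and the $f^k$ rescaling
  law honours it), but the stacked-past PID assembly for $p > 1$ is out
  of scope.
* Gaussian and VAR families only; no discrete-system nulls.
* Group-level statistics across recordings (mixed models, regressions
  between PID definitions) are downstream analyses, not part of this
  package.
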