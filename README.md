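# numit

Null-model normalisation of partial information decomposition (PID) for
Gaussian and vector-autoregressive systems.

## The problem

PID splits the mutual information two sources X, Y carry about a target
T into four atoms:

    I(X,Y;T) = Red + Un_X + Un_Y + Syn

(redundant, unique-to-X, unique-to-Y, synergistic). Under the
minimal-mutual-information (MMI) definition used here,
`Red = min(I(X;T), I(Y;T))` and the rest follow from the identity.

Raw atoms are not comparable across systems or conditions: they depend
strongly on the total mutual information (TMI), which tracks the
signal-to-noise ratio rather than the coupling structure. A system can
read as synergy-dominated at low noise and redundancy-dominated at high
noise without its structure changing at all, and dividing atoms by the
TMI ("NMI") does not fix this because the atoms grow non-linearly with
TMI.

**NuMIT** (null models for information theory) fixes the comparison by
scoring each atom as its quantile within an ensemble of N random systems
constrained to the *same TMI*: random couplings `A_ij ~ N(0,1)`, Wishart
covariances, and one scalar knob solved so every null lands exactly on
the observed TMI — the noise strength g for Gaussian systems (where
`TMI(g) = ½ log |AΣ_SAᵀ + gΣ_ε| / |gΣ_ε|` is strictly decreasing in g),
the spectral radius of the coefficient matrix for VAR models (where
`TMI = ½ log |Γ_0| − ½ log |V|` is strictly increasing in the radius and
invariant to rescaling V). A quantile near 1 means "more of this atom
than almost any random system with this much information"; 0.5 means
typical.

The package provides, for both model families: the closed-form MMI-PID
calculus, the NMI baseline, null-ensemble construction (random and
data-driven variants), VAR(1) fitting from epoched multivariate time
series with a random-subset analysis pipeline, seeded synthetic
validation studies, and a command-line interface.

## Worked example

```r
library(numit)

# correlated sources, symmetric couplings, unit noise
sys <- gaussian_system(sigma_s = matrix(c(20, 10, 10, 20), 2),
                       a = c(0.5, 0.5), sigma_eps = 1, g = 1, d_x = 1)
pid_from_system(sys)
#> PID atoms (nats):
#>       red      un_x      un_y       syn       tmi
#> 0.6072221 0.0000000 0.0000000 0.7790723 1.3862944

numit_normalise_gaussian(sys, null_config(n_samples = 500, seed = 1))
#> NuMIT-normalised PID atoms (raw TMI = 1.38629 nats):
#>   red  un_x  un_y   syn
#> 0.654 0.243 0.257 0.812
```

The raw decomposition is synergy-dominated (0.78 vs 0.61 nats). Now the
same structure at 100× the noise:

```r
sys100 <- gaussian_system(matrix(c(20, 10, 10, 20), 2), c(0.5, 0.5),
                          1, 100, d_x = 1)
pid_from_system(sys100)
#> PID atoms (nats):
#>        red       un_x       un_y        syn        tmi
#> 0.05147398 0.00000000 0.00000000 0.01840699 0.06988097

numit_normalise_gaussian(sys100, null_config(n_samples = 500, seed = 1))
#> NuMIT-normalised PID atoms (raw TMI = 0.069881 nats):
#>   red  un_x  un_y   syn
#> 0.654 0.243 0.257 0.812
```

The raw atoms have collapsed by an order of magnitude and the dominance
has flipped (redundancy 0.051 now exceeds synergy 0.018) — yet the NuMIT
quantiles are unchanged: relative to what any system with that TMI could
do, this one is still moderately redundant (0.65) and strongly
synergistic (0.81). That stability under noise is the point of the
method.

For time series, fit and normalise in one pipeline:

```r
ts <- surrogate_meg(n_channels = 12, seed = 1)   # 50 epochs x 1200 x 12
res <- region_subset_pipeline(ts, n_subsets = 10, subset_size = 10,
                              split = 5,
                              config = var_null_config(n_samples = 500),
                              seed = 1)
res$means   # mean raw / NMI / NuMIT atoms across subsets
```

## Command line

```sh
Rscript inst/cli/numit.R decompose-gaussian --system system.json --n-null 500 --seed 1
Rscript inst/cli/numit.R decompose-var --data epochs_dir/ --n-subsets 10 --seed 1
Rscript inst/cli/numit.R experiment --name noise_sweep --out results/fig1
```

Exit codes: 0 success, 2 usage error, 3 data/validation error, 4
numerical failure. Outputs are tidy CSV plus a JSON sidecar recording
the seed.

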