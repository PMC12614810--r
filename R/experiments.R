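# Seeded synthetic studies: the noise sweep on a fixed bivariate system,
# the null-atom distribution study across TMI values, the three
# parameter-sweep validation scenarios, and a surrogate generator for an
# epoched multichannel recording. These double as the package's fixture
# generators: every experiment is a pure function of (config, seed).

# The fixed bivariate reference system used by the noise sweep:
# strongly and symmetrically coupled correlated sources, unit noise.
.example_system <- function(g) {
  gaussian_system(sigma_s = matrix(c(20, 10, 10, 20), 2),
                  a = c(0.5, 0.5), sigma_eps = 1, g = g, d_x = 1)
}

# Derive per-point sub-seeds from one master seed without coupling the
# consumer's RNG stream to the number of points.
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Noise sweep on a fixed bivariate Gaussian system
#'
#' Sweeps the noise strength `g` over a logarithmic grid for a fixed
#' symmetric two-source system (equal couplings 0.5, source covariance
#' `[[20, 10], [10, 20]]`, unit noise) and records raw, NMI- and
#' NuMIT-normalised atoms at each point. The raw and NMI atoms flip from
#' synergy- to redundancy-dominated along the sweep, while the NuMIT
#' quantiles stay nearly flat: the structure of the system does not
#' change with its signal-to-noise ratio.
#'
#' @param g_grid Noise-strength grid (default 20 log-spaced points on
#'   `[1, 100]`).
#' @param n_null Null-ensemble size per grid point (default 500).
#' @param seed Integer master seed.
#' @return A `sweep_result`: tidy data frame with columns `g`, `scheme`
#'   (`raw` / `NMI` / `NuMIT`), `red`, `un_x`, `un_y`, `syn`, `tmi`;
#'   metadata (seed, n_null) in attributes.
#' @export
noise_sweep <- function(g_grid = exp(seq(log(1), log(100), length.out = 20)),
                        n_null = 500, seed = 1) {
  seeds <- .derive_seeds(seed, length(g_grid))
  rows <- vector("list", length(g_grid))
  for (i in seq_along(g_grid)) {
    sys <- .example_system(g_grid[i])
    raw <- pid_from_system(sys)
    nmi <- nmi_normalise(raw)
    num <- numit_normalise_gaussian(
      sys, null_config(n_samples = n_null, seed = seeds[i]))
    rows[[i]] <- rbind(
      cbind(g = g_grid[i], scheme = "raw", as.data.frame(raw)),
      cbind(g = g_grid[i],
            as.data.frame(nmi)[c("scheme", "red", "un_x", "un_y", "syn", "tmi")]),
      cbind(g = g_grid[i],
            as.data.frame(num)[c("scheme", "red", "un_x", "un_y", "syn", "tmi")])
    )[, c("g", "scheme", "red", "un_x", "un_y", "syn", "tmi")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", class(out)),
            seed = seed, n_null = n_null)
}

#' Distribution of PID atoms across random systems at fixed TMI
#'
#' For each target TMI, draws `n_draws` random Gaussian null systems with
#' univariate sources and target constrained to that TMI and summarises
#' the atom distributions. "Unique information" is reported as
#' `max(un_x, un_y)` per draw (under MMI the smaller unique information
#' is identically zero). Low-TMI ensembles are dominated by unique
#' information; high-TMI ensembles by synergy, with mean synergy growing
#' monotonically in TMI.
#'
#' @param tmi_grid Target TMI values in nats.
#' @param n_draws Draws per TMI value (default 2000).
#' @param seed Integer master seed.
#' @param keep_draws If `TRUE`, attach the per-draw atom tables as the
#'   `"draws"` attribute.
#' @return A `sweep_result` data frame with columns `tmi_target`,
#'   `mean_red`, `mean_un`, `mean_syn` (and `sd_` analogues).
#' @export
atom_distribution_study <- function(tmi_grid = c(0.25, 1, 1.75, 2.5, 3.25, 4),
                                    n_draws = 2000, seed = 1,
                                    keep_draws = FALSE) {
  part <- source_partition(1, 1, 1)
  cfg <- null_config(n_samples = max(2, n_draws))
  seeds <- .derive_seeds(seed, length(tmi_grid))
  rows <- vector("list", length(tmi_grid))
  draws <- if (keep_draws) vector("list", length(tmi_grid)) else NULL
  for (i in seq_along(tmi_grid)) {
    cfg$seed <- seeds[i]
    ens <- build_null_ensemble(tmi_grid[i], part, cfg)
    at <- ens$atoms
    un <- pmax(at$un_x, at$un_y)
    rows[[i]] <- data.frame(
      tmi_target = tmi_grid[i],
      mean_red = mean(at$red), sd_red = stats::sd(at$red),
      mean_un = mean(un), sd_un = stats::sd(un),
      mean_syn = mean(at$syn), sd_syn = stats::sd(at$syn))
    if (keep_draws) draws[[i]] <- at
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- structure(out, class = c("sweep_result", class(out)),
                   seed = seed, n_draws = n_draws)
  if (keep_draws) attr(out, "draws") <- draws
  out
}

# Scenario definitions for the validation sweeps: each returns the system
# for one (parameter, g) pair.
.validation_system <- function(scenario, param, g) {
  switch(scenario,
    redundancy_rho = gaussian_system(
      sigma_s = matrix(c(1, param, param, 1), 2),
      a = c(0.01, 0.99), sigma_eps = 1, g = g, d_x = 1),
    unique_a = ,
    synergy_a = gaussian_system(
      sigma_s = diag(2), a = c(param, 0.49),
      sigma_eps = 1e-4, g = g, d_x = 1),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' Parameter-sweep validation of normalised PID atoms
#'
#' Three scenarios on small Gaussian systems whose informational
#' structure is known by construction, each swept over a parameter grid
#' and, at every parameter value, averaged over a grid of noise strengths
#' `g` (mean and standard deviation across the g-grid):
#'
#' * `redundancy_rho`: asymmetric couplings `(0.01, 0.99)` with source
#'   correlation `rho`; redundancy comes only from the source
#'   correlation, so normalised redundancy should track `rho`.
#' * `unique_a`: uncorrelated unit sources, couplings `(a, 0.49)`, small
#'   noise floor `1e-4`; source `Y` carries large unique information at
#'   small `a`, vanishing as `a` approaches 0.5.
#' * `synergy_a`: same family; as the couplings become comparable the
#'   information becomes synergistic.
#'
#' @param scenario One of `"redundancy_rho"`, `"unique_a"`, `"synergy_a"`.
#' @param param_grid Parameter grid; defaults: 6 points on `[0, 1]` for
#'   `redundancy_rho` (upper end pulled just inside positive definiteness
#'   of the source covariance) and `[0, 0.5]` for the coupling scenarios.
#' @param g_grid Noise grid; defaults to 20 log-spaced points on
#'   `[1e-2, 1e2]` (`[1e-2, 10]` for `synergy_a`).
#' @param n_null Null-ensemble size per (parameter, g) point.
#' @param seed Integer master seed.
#' @return A `sweep_result` data frame in long form: `scenario`, `param`,
#'   `scheme`, `atom`, `mean`, `sd`.
#' @export
validation_sweep <- function(scenario = c("redundancy_rho", "unique_a",
                                          "synergy_a"),
                             param_grid = NULL, g_grid = NULL,
                             n_null = 200, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(param_grid)) {
    param_grid <- if (scenario == "redundancy_rho") {
      c(0, 0.2, 0.4, 0.6, 0.8, 0.999)
    } else {
      seq(0, 0.5, length.out = 6)
    }
  }
  if (is.null(g_grid)) {
    hi <- if (scenario == "synergy_a") 10 else 100
    g_grid <- exp(seq(log(1e-2), log(hi), length.out = 20))
  }
  seeds <- .derive_seeds(seed, length(param_grid) * length(g_grid))
  atoms <- c("red", "un_x", "un_y", "syn")
  rows <- list()
  k <- 0
  for (ip in seq_along(param_grid)) {
    acc <- list(NMI = list(), NuMIT = list())
    for (g in g_grid) {
      k <- k + 1
      sys <- .validation_system(scenario, param_grid[ip], g)
      raw <- pid_from_system(sys)
      acc$NMI[[length(acc$NMI) + 1]] <- unlist(nmi_normalise(raw)[atoms])
      num <- numit_normalise_gaussian(
        sys, null_config(n_samples = n_null, seed = seeds[k]))
      acc$NuMIT[[length(acc$NuMIT) + 1]] <- unlist(num[atoms])
    }
    for (scheme in names(acc)) {
      m <- do.call(rbind, acc[[scheme]])
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenario, param = param_grid[ip], scheme = scheme,
        atom = atoms, mean = colMeans(m), sd = apply(m, 2, stats::sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", class(out)),
            seed = seed, n_null = n_null)
}

#' Surrogate epoched multichannel recording
#'
#' Stand-in for a source-reconstructed resting-state recording: draws a
#' random stable VAR(1) model (standard-normal coefficients rescaled to
#' the requested spectral radius, Wishart innovation covariance scaled to
#' unit mean variance) and simulates independent epochs from it. The
#' default geometry (50 epochs of 1200 timepoints) matches a 2-second
#' epoching of a 600 Hz recording.
#'
#' @param n_channels Number of channels (default 12).
#' @param epochs,timepoints Epoch geometry (default 50 x 1200).
#' @param radius Spectral radius of the generating model, in (0, 1).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An [epoched_ts()] with the generating [var_model()] attached
#'   as the `"model"` attribute.
#' @export
surrogate_meg <- function(n_channels = 12, epochs = 50, timepoints = 1200,
                          radius = 0.8, seed = 1) {
  if (radius <= 0 || radius >= 1 - .stability_margin) {
    stop("radius must lie in (0, 1) within the stability margin",
         call. = FALSE)
  }
  set.seed(seed)
  a <- matrix(stats::rnorm(n_channels^2), n_channels, n_channels)
  v <- .draw_wishart(n_channels, n_channels) / n_channels
  model <- rescale_to_radius(var_model(a, v), radius)
  ts <- simulate_var(model, epochs, timepoints)
  ts$note <- sprintf("surrogate recording: VAR(1), n = %d, radius = %g, seed = %d",
                     n_channels, radius, seed)
  attr(ts, "model") <- model
  ts
}
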