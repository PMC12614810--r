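# NuMIT null construction for VAR(1) systems. The tunable parameter of
# the Gaussian case (the noise strength g) is repurposed as the spectral
# radius of the coefficient matrix: rescaling V leaves all autocovariance
# ratios -- and hence the TMI and every PID atom -- unchanged, so the
# radius is the one knob that moves the TMI without changing the
# coefficient "direction".

#' Configuration for a VAR null ensemble
#'
#' @param n_samples Ensemble size `N` (default 500).
#' @param seed Optional integer seed.
#' @param mode `"random"` samples coefficient matrices entrywise from
#'   `N(0, 1)`; `"data_driven"` draws them uniformly from `coeff_pool`
#'   (empirical estimates from one subject/condition context), anchoring
#'   the null space to the observed system. Innovation covariances are
#'   Wishart draws in both modes.
#' @param coeff_pool List of empirical `n x n` coefficient matrices;
#'   required iff `mode = "data_driven"`.
#' @param max_resample Maximum number of re-draws per null member when the
#'   target TMI is unreachable for a draw.
#' @return An object of class `var_null_config`.
#' @export
var_null_config <- function(n_samples = 500, seed = NULL,
                            mode = c("random", "data_driven"),
                            coeff_pool = NULL, max_resample = 25) {
  mode <- match.arg(mode)
  n_samples <- .check_count(n_samples, "n_samples")
  if (n_samples < 2) stop("n_samples must be at least 2", call. = FALSE)
  if (mode == "data_driven") {
    if (is.null(coeff_pool) || length(coeff_pool) == 0) {
      stop("data_driven mode requires a non-empty coeff_pool", call. = FALSE)
    }
    n <- nrow(coeff_pool[[1]])
    for (a in coeff_pool) {
      if (!is.matrix(a) || nrow(a) != n || ncol(a) != n) {
        stop("all coeff_pool matrices must be square with matching size",
             call. = FALSE)
      }
    }
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_samples = n_samples, seed = seed, mode = mode,
                 coeff_pool = coeff_pool,
                 max_resample = .check_count(max_resample, "max_resample")),
            class = "var_null_config")
}

#' Solve for the spectral radius that yields a target TMI
#'
#' For a fixed coefficient direction and innovation covariance, the TMI of
#' a stable VAR is strictly increasing in the spectral radius, so the
#' constraint has at most one root on `(0, 1)`. The solver brackets the
#' radius on `(1e-9, 1 - 1e-6)` (the stability margin), bisects with
#' [stats::uniroot()], and polishes by secant steps to within 1e-10 nats.
#'
#' @param model A [var_model()] with nonzero coefficients; only its
#'   coefficient direction and `V` matter.
#' @param target_tmi Desired TMI in nats (> 0). Targets above the TMI
#'   achievable at the stability margin raise an error (`"TMI
#'   unreachable"`), which null samplers handle by resampling.
#' @return The radius `rho` in `(0, 1 - 1e-6)`.
#' @export
solve_radius_for_tmi <- function(model, target_tmi) {
  stopifnot(inherits(model, "var_model"))
  if (!is.numeric(target_tmi) || target_tmi <= 0) {
    stop("target_tmi must be positive", call. = FALSE)
  }
  if (spectral_radius(model) == 0) {
    stop("coefficients are all zero: TMI is identically zero", call. = FALSE)
  }
  lo <- 1e-9
  hi <- 1 - 1.5 * .stability_margin   # strictly inside the stability margin
  phi <- function(r) var_tmi(rescale_to_radius(model, r)) - target_tmi
  if (phi(hi) < 0) {
    stop("TMI unreachable within the stability margin", call. = FALSE)
  }
  if (phi(lo) > 0) {
    stop("target_tmi below the TMI at vanishing radius", call. = FALSE)
  }
  r <- stats::uniroot(phi, c(lo, hi), tol = 1e-13)$root
  err <- phi(r)
  iter <- 0
  while (abs(err) > 1e-10 && iter < 25) {      # secant polish in rho
    r2 <- min(max(r + 1e-7, lo), hi - 1e-9)
    slope <- (phi(r2) - err) / (r2 - r)
    if (!is.finite(slope) || slope <= 0) break
    r <- min(max(r - err / slope, lo), hi)
    err <- phi(r)
    iter <- iter + 1
  }
  r
}

#' Sample one VAR(1) null model with a prescribed TMI
#'
#' Draws a coefficient matrix (standard-normal entries, or an empirical
#' matrix from the pool in data-driven mode) and an innovation covariance
#' `V ~ Wishart(I_n, n)`, then rescales the coefficients to the spectral
#' radius that yields `target_tmi`. Draws for which the target is
#' unreachable are discarded and resampled, up to
#' `config$max_resample` times; the number of discarded draws is recorded
#' in the `"resamples"` attribute.
#'
#' @param target_tmi Target TMI in nats (> 0).
#' @param n Channel count.
#' @param config A [var_null_config()].
#' @param seed Optional integer seed applied before the draw.
#' @return A stable VAR(1) [var_model()] whose TMI matches the target to
#'   solver tolerance.
#' @export
sample_null_var <- function(target_tmi, n, config = var_null_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- .check_count(n, "n")
  resamples <- 0
  for (attempt in seq_len(config$max_resample)) {
    a <- if (config$mode == "random") {
      matrix(stats::rnorm(n * n), n, n)
    } else {
      pool <- config$coeff_pool
      if (nrow(pool[[1]]) != n) {
        stop("coeff_pool matrices do not match the requested channel count",
             call. = FALSE)
      }
      pool[[sample.int(length(pool), 1)]]
    }
    v <- .draw_wishart(n, n)
    model <- tryCatch(var_model(a, v), error = function(e) NULL)
    if (!is.null(model) && spectral_radius(model) > 0) {
      rho <- tryCatch(solve_radius_for_tmi(model, target_tmi),
                      error = function(e) NULL)
      if (!is.null(rho)) {
        out <- rescale_to_radius(model, rho)
        attr(out, "resamples") <- resamples
        return(out)
      }
    }
    resamples <- resamples + 1
  }
  stop("failed to sample a null VAR model within max_resample attempts",
       call. = FALSE)
}

# Build a null_ensemble of VAR atom records at a fixed TMI.
.build_var_null_ensemble <- function(target_tmi, n, x_channels, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nn <- config$n_samples
  red <- un_x <- un_y <- syn <- tmi <- numeric(nn)
  resamples <- 0
  for (i in seq_len(nn)) {
    m <- sample_null_var(target_tmi, n, config)
    resamples <- resamples + attr(m, "resamples")
    bl <- var_pid_blocks(m, x_channels)
    at <- mmi_atoms(bl$i_x, bl$i_y, bl$tmi)
    red[i] <- at$red; un_x[i] <- at$un_x; un_y[i] <- at$un_y
    syn[i] <- at$syn; tmi[i] <- at$tmi
  }
  structure(
    list(target_tmi = target_tmi,
         atoms = data.frame(red = red, un_x = un_x, un_y = un_y,
                            syn = syn, tmi = tmi),
         config = config,
         achieved_tmi_error = max(abs(tmi - target_tmi)),
         resamples = resamples),
    class = "null_ensemble"
  )
}

#' End-to-end NuMIT normalisation of a VAR(1) model
#'
#' Computes the observed past->future PID atoms, builds a VAR null
#' ensemble constrained to the observed TMI, and returns the atom
#' quantiles (mid-rank convention, see [numit_quantile()]).
#'
#' @param model A stable VAR(1) [var_model()].
#' @param x_channels Channel indices forming source `X` (rest are `Y`).
#' @param config A [var_null_config()].
#' @return A `normalised_atoms` object with `scheme = "NuMIT"`. The
#'   number of discarded (unreachable-TMI) null draws is attached as the
#'   `"resamples"` attribute.
#' @export
numit_normalise_var <- function(model, x_channels,
                                config = var_null_config()) {
  bl <- var_pid_blocks(model, x_channels)
  if (bl$tmi <= 1e-6) {
    stop("target TMI too small to normalise (<= 1e-6 nats)", call. = FALSE)
  }
  observed <- mmi_atoms(bl$i_x, bl$i_y, bl$tmi)
  ens <- .build_var_null_ensemble(bl$tmi, model$n, x_channels, config)
  out <- numit_quantile(observed, ens)
  attr(out, "resamples") <- ens$resamples
  out
}

#' Random-subset PID pipeline over an epoched recording
#'
#' Emulates a region-subset analysis of a multichannel recording: for each
#' of `n_subsets` repetitions, draws `subset_size` channels without
#' replacement, splits them at random into an `X` group of `split`
#' channels and a `Y` group of the rest, fits a VAR(1) to the subset by
#' pooled OLS, and computes raw, NMI- and NuMIT-normalised PID atoms for
#' the past->future decomposition. Subsets whose fitted TMI is degenerate
#' (<= 1e-6 nats) get `NA` normalised atoms and a warning.
#'
#' @param ts An [epoched_ts()] with at least `subset_size` channels.
#' @param n_subsets Number of random channel subsets.
#' @param subset_size Channels per subset (default 10).
#' @param split Size of the `X` group (default 5, i.e. a 5/5 split).
#' @param config A [var_null_config()] for the per-subset null ensembles;
#'   its `seed` field is ignored (per-subset seeds are derived from
#'   `seed`).
#' @param seed Integer seed controlling subset selection, splits and null
#'   ensembles; identical inputs give identical tables.
#' @param tmi_floor Smallest fitted TMI (nats) considered normalisable;
#'   subsets at or below it are reported raw-only. The default matches
#'   the degeneracy threshold of the normalisers; raise it to screen out
#'   subsets whose TMI is indistinguishable from estimation noise.
#' @return An object of class `pid_subset_result`: a list with
#'   `per_subset` (tidy data frame: `subset_id`, `scheme`, `red`, `un_x`,
#'   `un_y`, `syn`, `tmi`), `means` (across-subset mean per atom per
#'   scheme), `n_degenerate`, and `resamples` (total discarded null
#'   draws).
#' @export
region_subset_pipeline <- function(ts, n_subsets, subset_size = 10,
                                   split = 5, config = var_null_config(),
                                   seed = NULL, tmi_floor = 1e-6) {
  stopifnot(inherits(ts, "epoched_ts"))
  n_subsets <- .check_count(n_subsets, "n_subsets")
  n_ch <- dim(ts$data)[3]
  if (subset_size > n_ch) {
    stop("subset_size exceeds the number of channels", call. = FALSE)
  }
  if (split < 1 || split >= subset_size) {
    stop("split must leave both groups non-empty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # Freeze all random choices up-front so per-subset ensemble seeding
  # cannot perturb the subset draws.
  channel_sets <- replicate(n_subsets, sample.int(n_ch, subset_size),
                            simplify = FALSE)
  x_sets <- replicate(n_subsets, sample.int(subset_size, split),
                      simplify = FALSE)
  sub_seeds <- sample.int(.Machine$integer.max, n_subsets)
  rows <- vector("list", n_subsets)
  n_degenerate <- 0
  resamples <- 0
  for (i in seq_len(n_subsets)) {
    chs <- channel_sets[[i]]
    sub <- epoched_ts(ts$data[, , chs, drop = FALSE])
    model <- fit_var(sub, p = 1)
    bl <- var_pid_blocks(model, x_sets[[i]])
    raw <- mmi_atoms(bl$i_x, bl$i_y, bl$tmi)
    recs <- list(cbind(subset_id = i, scheme = "raw", as.data.frame(raw)))
    if (raw$tmi > tmi_floor) {
      nmi <- nmi_normalise(raw)
      cfg <- config
      cfg$seed <- sub_seeds[i]
      num <- numit_normalise_var(model, x_sets[[i]], cfg)
      resamples <- resamples + attr(num, "resamples")
      recs <- c(recs, list(
        cbind(subset_id = i, as.data.frame(nmi)[c("red", "un_x", "un_y",
                                                  "syn", "tmi", "scheme")]),
        cbind(subset_id = i, as.data.frame(num)[c("red", "un_x", "un_y",
                                                  "syn", "tmi", "scheme")])
      ))
    } else {
      n_degenerate <- n_degenerate + 1
      warning(sprintf("subset %d: TMI degenerate, normalisation skipped", i),
              call. = FALSE)
      na_row <- data.frame(red = NA_real_, un_x = NA_real_, un_y = NA_real_,
                           syn = NA_real_, tmi = raw$tmi)
      recs <- c(recs, list(cbind(subset_id = i, scheme = "NMI", na_row),
                           cbind(subset_id = i, scheme = "NuMIT", na_row)))
    }
    recs <- lapply(recs, function(r) {
      r[c("subset_id", "scheme", "red", "un_x", "un_y", "syn", "tmi")]
    })
    rows[[i]] <- do.call(rbind, recs)
  }
  per_subset <- do.call(rbind, rows)
  rownames(per_subset) <- NULL
  means <- do.call(rbind, lapply(split(per_subset, per_subset$scheme),
    function(df) {
      data.frame(scheme = df$scheme[1],
                 red = mean(df$red, na.rm = TRUE),
                 un_x = mean(df$un_x, na.rm = TRUE),
                 un_y = mean(df$un_y, na.rm = TRUE),
                 syn = mean(df$syn, na.rm = TRUE),
                 tmi = mean(df$tmi, na.rm = TRUE))
    }))
  rownames(means) <- NULL
  structure(list(per_subset = per_subset, means = means,
                 n_degenerate = n_degenerate, resamples = resamples),
            class = "pid_subset_result")
}

#' @export
print.pid_subset_result <- function(x, ...) {
  cat(sprintf("Region-subset PID pipeline: %d subsets (%d degenerate)\n",
              length(unique(x$per_subset$subset_id)), x$n_degenerate))
  cat("Across-subset means:\n")
  print(x$means)
  invisible(x)
}
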