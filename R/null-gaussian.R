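# NuMIT null-model construction for Gaussian systems: sample random
# (A, Sigma_S, Sigma_eps), tune the noise strength g so every null hits
# the observed TMI, and score observed atoms as quantiles of the null
# atom distributions.

#' Configuration for a Gaussian null ensemble
#'
#' @param n_samples Ensemble size `N` (number of null systems). Default
#'   500, giving quantile resolution 1/500 = 0.002.
#' @param seed Optional integer seed; when set, ensemble construction is
#'   fully reproducible.
#' @param coeff_std Standard deviation of the i.i.d. Gaussian draws for
#'   the coefficient matrix entries (default 1).
#' @param wishart_dof_s,wishart_dof_t Degrees of freedom of the Wishart
#'   draws for the source and noise covariances; default equals the
#'   corresponding dimension (the smallest value for which draws are
#'   almost surely positive definite).
#' @param max_resample Maximum number of re-draws when a sampled system is
#'   degenerate before giving up.
#' @return An object of class `null_config`.
#' @export
null_config <- function(n_samples = 500, seed = NULL, coeff_std = 1,
                        wishart_dof_s = NULL, wishart_dof_t = NULL,
                        max_resample = 25) {
  n_samples <- .check_count(n_samples, "n_samples")
  if (n_samples < 2) stop("n_samples must be at least 2", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  if (coeff_std <= 0) stop("coeff_std must be positive", call. = FALSE)
  structure(list(n_samples = n_samples, seed = seed, coeff_std = coeff_std,
                 wishart_dof_s = wishart_dof_s, wishart_dof_t = wishart_dof_t,
                 max_resample = .check_count(max_resample, "max_resample")),
            class = "null_config")
}

#' Solve for the noise strength that yields a target TMI
#'
#' For fixed `(A, sigma_s, sigma_eps)` the total mutual information
#' `0.5 * logdet(I + (1/g) sigma_eps^{-1} A sigma_s A')` is strictly
#' decreasing in `g`, so the constraint `TMI(g) = target` has a unique
#' root. Writing `L'L = sigma_eps` and taking the eigenvalues `lambda_i`
#' of `L^{-T} (A sigma_s A') L^{-1}` reduces the TMI to
#' `0.5 * sum(log(1 + lambda_i / g))`; the root is found on the log-g
#' scale (avoids determinant under/overflow for extreme `g`) and polished
#' by Newton steps to solver tolerance well below 1e-8 nats.
#'
#' @param a Coefficient matrix (`d_t x d_s`; a vector is taken as one row).
#' @param sigma_s,sigma_eps Source and noise covariances.
#' @param target_tmi Desired total mutual information in nats (> 0).
#' @return The positive noise strength `g`.
#' @export
solve_noise_parameter <- function(a, sigma_s, sigma_eps, target_tmi) {
  if (is.vector(a) && is.numeric(a)) a <- matrix(a, nrow = 1)
  if (length(sigma_eps) == 1 && !is.matrix(sigma_eps)) {
    sigma_eps <- matrix(sigma_eps, 1, 1)
  }
  if (!is.numeric(target_tmi) || target_tmi <= 0) {
    stop("target_tmi must be positive", call. = FALSE)
  }
  signal <- .sym(a %*% sigma_s %*% t(a))
  u_chol <- chol(sigma_eps)
  u_inv <- backsolve(u_chol, diag(nrow(u_chol)))
  k <- .sym(t(u_inv) %*% signal %*% u_inv)
  lam <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (max(lam) <= 0) {
    stop("coefficient matrix carries no signal: TMI is identically zero",
         call. = FALSE)
  }
  lam <- lam[lam > max(lam) * 1e-15]
  if (length(lam) == 1) {
    # Rank-one signal: closed form g = lambda / (exp(2 TMI) - 1).
    return(lam / expm1(2 * target_tmi))
  }
  h <- function(u) 0.5 * sum(log1p(lam * exp(-u))) - target_tmi
  lo <- -30; hi <- 30
  while (h(lo) < 0 && lo > -700) lo <- lo - 30
  while (h(hi) > 0 && hi < 700) hi <- hi + 30
  if (h(lo) < 0 || h(hi) > 0) {
    stop("TMI out of bracket for the noise-strength solver", call. = FALSE)
  }
  u <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
  for (i in 1:4) {                 # Newton polish on the log scale
    e <- lam * exp(-u)
    hp <- -0.5 * sum(e / (1 + e))
    step <- h(u) / hp
    if (!is.finite(step)) break
    u <- u - step
  }
  exp(u)
}

# Draw one Wishart(diag(d), dof) matrix using the current RNG stream.
.draw_wishart <- function(d, dof) {
  stats::rWishart(1, df = max(dof, d), Sigma = diag(d))[, , 1]
}

#' Sample one Gaussian null system with a prescribed TMI
#'
#' Draws coefficients `A_ij ~ N(0, coeff_std^2)`, a source covariance
#' `sigma_s ~ Wishart(I_{d_s}, d_s)` and a noise covariance
#' `sigma_eps ~ Wishart(I_{d_t}, d_t)`, then solves for the noise strength
#' `g` that makes the system's TMI equal to `target_tmi`. Consumes the
#' current RNG stream unless `seed` is given, so that ensemble builders
#' can seed once and draw repeatedly.
#'
#' @param target_tmi Target total mutual information in nats (> 0).
#' @param partition A [source_partition()].
#' @param config A [null_config()].
#' @param seed Optional integer seed applied before the draw.
#' @return A [gaussian_system()] whose TMI matches `target_tmi` to
#'   solver tolerance (about 1e-10 nats).
#' @export
sample_null_system <- function(target_tmi, partition, config = null_config(),
                               seed = NULL) {
  stopifnot(inherits(partition, "source_partition"))
  if (!is.null(seed)) set.seed(seed)
  dof_s <- if (is.null(config$wishart_dof_s)) partition$d_s else config$wishart_dof_s
  dof_t <- if (is.null(config$wishart_dof_t)) partition$d_t else config$wishart_dof_t
  for (attempt in seq_len(config$max_resample)) {
    a <- matrix(stats::rnorm(partition$d_t * partition$d_s, sd = config$coeff_std),
                partition$d_t, partition$d_s)
    sigma_s <- .draw_wishart(partition$d_s, dof_s)
    sigma_eps <- .draw_wishart(partition$d_t, dof_t)
    # Near-singular Wishart draws (or degenerate coefficients) fail the
    # PD checks or the solver; discard and redraw.
    sys <- tryCatch({
      g <- solve_noise_parameter(a, sigma_s, sigma_eps, target_tmi)
      if (!is.finite(g) || g <= 0) stop("invalid g")
      gaussian_system(sigma_s, a, sigma_eps, g, d_x = partition$d_x)
    }, error = function(e) NULL)
    if (!is.null(sys)) return(sys)
  }
  stop("failed to sample a valid null system within max_resample attempts",
       call. = FALSE)
}

#' Build a NuMIT null ensemble for Gaussian systems
#'
#' Draws `n_samples` independent null systems constrained to share the
#' target TMI and records their PID atoms; this is the reference
#' distribution against which observed atoms are scored by
#' [numit_quantile()].
#'
#' @param target_tmi Target total mutual information in nats. Values at or
#'   below `1e-6` are refused: quantiles within a null family that carries
#'   essentially no information are meaningless.
#' @param partition A [source_partition()].
#' @param config A [null_config()]; `config$seed`, when set, makes the
#'   ensemble reproducible.
#' @return An object of class `null_ensemble` with fields `target_tmi`,
#'   `atoms` (a data frame with one row per null member), `config`, and
#'   `achieved_tmi_error` (the largest deviation of any member's TMI from
#'   the target).
#' @export
build_null_ensemble <- function(target_tmi, partition, config = null_config()) {
  if (!is.numeric(target_tmi) || target_tmi <= 1e-6) {
    stop("target TMI too small to normalise (<= 1e-6 nats)", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  red <- un_x <- un_y <- syn <- tmi <- numeric(n)
  for (i in seq_len(n)) {
    sys <- sample_null_system(target_tmi, partition, config)
    at <- pid_from_system(sys)
    red[i] <- at$red; un_x[i] <- at$un_x; un_y[i] <- at$un_y
    syn[i] <- at$syn; tmi[i] <- at$tmi
  }
  structure(
    list(target_tmi = target_tmi,
         atoms = data.frame(red = red, un_x = un_x, un_y = un_y,
                            syn = syn, tmi = tmi),
         config = config,
         achieved_tmi_error = max(abs(tmi - target_tmi))),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("NuMIT null ensemble: N = %d, target TMI = %.6g nats (max dev %.2g)\n",
              nrow(x$atoms), x$target_tmi, x$achieved_tmi_error))
  invisible(x)
}

# Mid-rank quantile of `x` within the sample `ref`: ties count half.
.mid_rank_quantile <- function(x, ref) {
  (sum(ref < x) + 0.5 * sum(ref == x)) / length(ref)
}

#' NuMIT normalisation: quantile of observed atoms in a null ensemble
#'
#' Scores each observed PID atom as its mid-rank quantile within the
#' matching null distribution: `(#null strictly below + 0.5 #ties) / N`.
#' A value near 1 means the system carries more of that atom than almost
#' any random system with the same TMI; near 0, less.
#'
#' @param observed A `pid_atoms` object (e.g. from [pid_from_system()]).
#' @param ensemble A [build_null_ensemble()] result whose `target_tmi`
#'   matches `observed$tmi` within `tmi_tol` (guards against scoring a
#'   system on an ensemble built for a different TMI).
#' @param tmi_tol Allowed mismatch between observed TMI and the ensemble
#'   target, in nats.
#' @return A `normalised_atoms` object with `scheme = "NuMIT"`, all
#'   components in `[0, 1]`.
#' @export
numit_quantile <- function(observed, ensemble, tmi_tol = 1e-6) {
  stopifnot(inherits(observed, "pid_atoms"), inherits(ensemble, "null_ensemble"))
  if (abs(observed$tmi - ensemble$target_tmi) >= tmi_tol) {
    stop("ensemble built for different TMI", call. = FALSE)
  }
  at <- ensemble$atoms
  .new_normalised_atoms(
    red = .mid_rank_quantile(observed$red, at$red),
    un_x = .mid_rank_quantile(observed$un_x, at$un_x),
    un_y = .mid_rank_quantile(observed$un_y, at$un_y),
    syn = .mid_rank_quantile(observed$syn, at$syn),
    scheme = "NuMIT", tmi = observed$tmi
  )
}

#' End-to-end NuMIT normalisation of a Gaussian system
#'
#' Computes the system's TMI and PID atoms, builds a null ensemble at that
#' TMI, and returns the atom quantiles.
#'
#' @param system A [gaussian_system()].
#' @param config A [null_config()].
#' @return A `normalised_atoms` object with `scheme = "NuMIT"`.
#' @export
numit_normalise_gaussian <- function(system, config = null_config()) {
  observed <- pid_from_system(system)
  if (observed$tmi <= 1e-6) {
    stop("target TMI too small to normalise (<= 1e-6 nats)", call. = FALSE)
  }
  ensemble <- build_null_ensemble(observed$tmi, system$partition, config)
  numit_quantile(observed, ensemble)
}
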