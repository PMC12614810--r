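# Fixture generators shared across the suite. All randomness flows from
# the caller's seed so tests are deterministic.

# Random symmetric positive-definite matrix with eigenvalues bounded
# away from zero.
random_spd <- function(d) {
  m <- matrix(rnorm(d * d), d)
  crossprod(m) + diag(d)
}

# Random linear-Gaussian system with small multivariate dimensions.
random_gaussian_system <- function(d_x = NULL, d_y = NULL, d_t = NULL) {
  if (is.null(d_x)) d_x <- sample(1:2, 1)
  if (is.null(d_y)) d_y <- sample(1:2, 1)
  if (is.null(d_t)) d_t <- sample(1:2, 1)
  d_s <- d_x + d_y
  gaussian_system(sigma_s = random_spd(d_s),
                  a = matrix(rnorm(d_t * d_s), d_t, d_s),
                  sigma_eps = random_spd(d_t),
                  g = exp(runif(1, -1, 1)), d_x = d_x)
}

# Random stationary VAR(p) model with the requested spectral radius.
random_stable_var <- function(n, p = 1, radius = 0.7) {
  coeffs <- replicate(p, matrix(rnorm(n * n), n), simplify = FALSE)
  rescale_to_radius(var_model(coeffs, random_spd(n)), radius)
}

# The fixed bivariate system used in the noise-sweep study.
example_bivariate_system <- function(g) {
  gaussian_system(sigma_s = matrix(c(20, 10, 10, 20), 2),
                  a = c(0.5, 0.5), sigma_eps = 1, g = g, d_x = 1)
}

# Assemble a null_ensemble object from explicit atom draws (for exact
# quantile arithmetic checks).
manual_ensemble <- function(atoms, target_tmi) {
  structure(list(target_tmi = target_tmi, atoms = atoms,
                 config = null_config(n_samples = max(2, nrow(atoms))),
                 achieved_tmi_error = 0),
            class = "null_ensemble")
}
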