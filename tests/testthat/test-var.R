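# VAR machinery: companion form, Lyapunov autocovariances, past->future
# information, fitting, simulation, and radius rescaling.

test_that("companion matrix has the block structure and right spectrum", {
  a1 <- matrix(c(0.3, 0.1, 0, 0.2), 2)
  expect_equal(companion_matrix(var_model(a1, diag(2))), a1)
  m2 <- var_model(list(matrix(0.5), matrix(0.2)), matrix(1))
  expect_equal(companion_matrix(m2), matrix(c(0.5, 1, 0.2, 0), 2))
  # companion eigenvalues are reciprocal roots of det(I - sum A_l z^l)
  set.seed(1)
  m <- random_stable_var(2, p = 2, radius = 0.8)
  ev <- eigen(companion_matrix(m), only.values = TRUE)$values
  for (lam in ev) {
    z <- 1 / lam
    charpoly <- diag(2) - m$coeffs[[1]] * z - m$coeffs[[2]] * z^2
    det_mod <- prod(Mod(eigen(charpoly, only.values = TRUE)$values))
    expect_lt(det_mod, 1e-8)
  }
})

test_that("autocovariances solve the Yule-Walker equations", {
  # white noise
  v <- matrix(c(2, 0.5, 0.5, 1), 2)
  wn <- var_model(matrix(0, 2, 2), v)
  expect_equal(solve_autocovariance(wn)$gammas[[1]], v)
  # univariate AR(1) closed form
  ar <- solve_autocovariance(var_model(matrix(0.5), matrix(1)))
  expect_equal(ar$gammas[[1]][1, 1], 4 / 3, tolerance = 1e-10)
  expect_equal(ar$gammas[[2]][1, 1], 2 / 3, tolerance = 1e-10)
  # Yule-Walker residuals vanish for random stable models of orders 1..3
  set.seed(2)
  for (i in 1:30) {
    p <- sample(1:3, 1)
    m <- random_stable_var(sample(2:4, 1), p = p, radius = runif(1, 0.3, 0.9))
    ac <- solve_autocovariance(m)
    for (k in 0:p) {
      pred <- matrix(0, m$n, m$n)
      for (l in seq_len(p)) {
        idx <- k - l
        gk <- if (idx >= 0) ac$gammas[[idx + 1]] else t(ac$gammas[[-idx + 1]])
        pred <- pred + m$coeffs[[l]] %*% gk
      }
      if (k == 0) pred <- pred + m$resid_cov
      expect_lt(max(abs(ac$gammas[[k + 1]] - pred)), 1e-8)
    }
  }
})

test_that("unstable models are rejected by the Lyapunov solver", {
  m <- var_model(matrix(1.01), matrix(1))
  expect_error(solve_autocovariance(m), "spectral radius")
  expect_error(simulate_var(m, 1, 100), "spectral radius")
})

test_that("autocovariances match a long simulation", {
  set.seed(3)
  m <- random_stable_var(3, p = 1, radius = 0.6)
  ac <- solve_autocovariance(m)
  ts <- simulate_var(m, epochs = 1, timepoints = 2e5, seed = 4)
  x <- ts$data[1, , ]
  tt <- nrow(x)
  emp0 <- crossprod(x) / tt
  emp1 <- crossprod(x[-1, , drop = FALSE], x[-tt, , drop = FALSE]) / (tt - 1)
  g0 <- ac$gammas[[1]]
  # effective sample size shrinks with autocorrelation
  n_eff <- tt * (1 - 0.6) / (1 + 0.6)
  se <- sqrt((outer(diag(g0), diag(g0)) + g0^2) / n_eff)
  expect_true(all(abs(emp0 - g0) < 3 * se))
  expect_true(all(abs(emp1 - ac$gammas[[2]]) < 3 * se))
})

test_that("VAR TMI matches closed forms and is invariant to V-rescaling", {
  expect_equal(var_tmi(var_model(matrix(0, 2, 2), diag(2))), 0)
  a <- 0.5
  expect_equal(var_tmi(var_model(matrix(a), matrix(1))),
               -0.5 * log(1 - a^2), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    m <- random_stable_var(3, p = 1, radius = runif(1, 0.2, 0.9))
    m7 <- var_model(m$coeffs, 7 * m$resid_cov)
    expect_equal(var_tmi(m7), var_tmi(m), tolerance = 1e-12)
  }
})

test_that("TMI increases with the spectral radius at fixed direction", {
  set.seed(6)
  m <- random_stable_var(4, p = 1, radius = 0.5)
  tmis <- sapply(seq(0.1, 0.95, by = 0.1), function(r) {
    var_tmi(rescale_to_radius(m, r))
  })
  expect_true(all(diff(tmis) > 0))
})

test_that("past->future blocks are consistent and respect decoupling", {
  # two decoupled 2-channel blocks: the joint past carries exactly the sum
  # of the marginal informations (zero co-information), so under MMI the
  # synergy equals the redundancy (= the smaller marginal) exactly
  set.seed(7)
  a <- matrix(0, 4, 4)
  a[1:2, 1:2] <- matrix(rnorm(4), 2)
  a[3:4, 3:4] <- matrix(rnorm(4), 2)
  v <- matrix(0, 4, 4)
  v[1:2, 1:2] <- random_spd(2)
  v[3:4, 3:4] <- random_spd(2)
  m <- rescale_to_radius(var_model(a, v), 0.6)
  bl <- var_pid_blocks(m, 1:2)
  at <- mmi_atoms(bl$i_x, bl$i_y, bl$tmi)
  expect_equal(bl$i_x + bl$i_y, bl$tmi, tolerance = 1e-8)
  expect_equal(at$syn, at$red, tolerance = 1e-8)
  # random stable model: marginals bounded by the total; matches the
  # assembled joint covariance fed to the generic MI
  m2 <- random_stable_var(4, p = 1, radius = 0.7)
  bl2 <- var_pid_blocks(m2, c(1, 3))
  expect_lte(bl2$i_x, bl2$tmi)
  expect_lte(bl2$i_y, bl2$tmi)
  ac <- solve_autocovariance(m2)
  joint <- rbind(cbind(ac$gammas[[1]], t(ac$gammas[[2]])),
                 cbind(ac$gammas[[2]], ac$gammas[[1]]))
  expect_equal(bl2$tmi, mutual_information(joint, 1:4, 5:8),
               tolerance = 1e-10)
  expect_error(var_pid_blocks(random_stable_var(2, p = 2), 1),
               "VAR\\(1\\) only")
})

test_that("OLS fitting recovers a known generating model", {
  set.seed(8)
  gen <- random_stable_var(4, p = 1, radius = 0.6)
  ts <- simulate_var(gen, epochs = 50, timepoints = 500, seed = 9)
  fit <- fit_var(ts, p = 1)
  expect_lt(max(abs(fit$coeffs[[1]] - gen$coeffs[[1]])), 0.05)
  expect_lt(max(abs(fit$resid_cov - gen$resid_cov)), 0.2)
  # refit on data resimulated from the fit: TMI agreement within 5%
  ts2 <- simulate_var(fit, epochs = 50, timepoints = 500, seed = 10)
  refit <- fit_var(ts2, p = 1)
  expect_equal(var_tmi(refit), var_tmi(fit), tolerance = 0.05)
})

test_that("fitting white noise returns near-zero coefficients", {
  set.seed(11)
  wn <- epoched_ts(array(rnorm(20 * 300 * 3), c(20, 300, 3)))
  fit <- fit_var(wn, p = 1)
  # OLS standard error ~ 1/sqrt(rows)
  expect_lt(max(abs(fit$coeffs[[1]])), 3 / sqrt(20 * 299))
})

test_that("fitting rejects short or degenerate inputs", {
  expect_error(fit_var(epoched_ts(array(rnorm(8), c(1, 4, 2))), p = 2),
               "too short")
  # a duplicated channel makes the regressors rank-deficient
  x <- array(rnorm(2 * 100 * 2), c(2, 100, 3))
  x[, , 3] <- x[, , 2]
  expect_error(fit_var(epoched_ts(x), p = 1), "rank-deficient")
})

test_that("simulation is seeded and matches known moments", {
  m <- var_model(matrix(0.9), matrix(1))
  t1 <- simulate_var(m, 2, 500, seed = 12)
  t2 <- simulate_var(m, 2, 500, seed = 12)
  expect_identical(t1$data, t2$data)
  long <- simulate_var(m, 1, 5e4, seed = 13)
  x <- long$data[1, , 1]
  expect_equal(stats::cor(x[-1], x[-length(x)]), 0.9, tolerance = 0.02)
  wn <- simulate_var(var_model(matrix(0, 2, 2), diag(2)), 1, 2e4, seed = 14)
  expect_equal(stats::cov(wn$data[1, , ]), diag(2), tolerance = 0.05)
})

test_that("radius rescaling is exact, homogeneous, and idempotent", {
  set.seed(15)
  m1 <- random_stable_var(3, p = 1, radius = 0.4)
  expect_equal(spectral_radius(rescale_to_radius(m1, 0.9)), 0.9,
               tolerance = 1e-10)
  m2 <- random_stable_var(2, p = 2, radius = 0.8)
  expect_equal(spectral_radius(rescale_to_radius(m2, 0.5)), 0.5,
               tolerance = 1e-10)
  same <- rescale_to_radius(m2, spectral_radius(m2))
  expect_equal(same$coeffs, m2$coeffs, tolerance = 1e-12)
  expect_error(rescale_to_radius(var_model(matrix(0, 2, 2), diag(2)), 0.5),
               "radius undefined")
})

test_that("epoched time series round-trip through a CSV directory", {
  set.seed(16)
  ts <- epoched_ts(array(rnorm(3 * 40 * 2), c(3, 40, 2)))
  dir <- withr::local_tempdir()
  write_epochs_csv(ts, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 3)
  back <- read_epochs_csv(dir)
  expect_equal(back$data, ts$data, tolerance = 1e-12)
})
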