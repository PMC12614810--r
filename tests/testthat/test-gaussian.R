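# Gaussian core: joint covariance assembly and closed-form mutual
# information.

test_that("joint covariance has the prescribed block structure", {
  sys <- example_bivariate_system(1)
  jc <- joint_covariance(sys)
  expect_equal(jc$matrix[1:2, 1:2], matrix(c(20, 10, 10, 20), 2))
  # target variance 0.25 * (20 + 10 + 10 + 20) + 1 = 16
  expect_equal(jc$matrix[3, 3], 16)
  expect_equal(jc$matrix[1:2, 3], c(15, 15))  # sigma_s %*% t(a)
  expect_equal(jc$matrix, t(jc$matrix))

  # independence: zero coupling wipes the cross block
  set.seed(1)
  sys0 <- gaussian_system(random_spd(3), matrix(0, 2, 3), diag(2), 1, d_x = 1)
  jc0 <- joint_covariance(sys0)
  expect_equal(jc0$matrix[1:3, 4:5], matrix(0, 3, 2))
  expect_equal(jc0$matrix[4:5, 4:5], diag(2))
})

test_that("joint covariance matches Monte-Carlo sampling of T = AS + sqrt(g) eps", {
  set.seed(42)
  sys <- random_gaussian_system(d_x = 1, d_y = 2, d_t = 2)
  jc <- joint_covariance(sys)$matrix
  n <- 2e5
  ls <- chol(sys$sigma_s)
  le <- chol(sys$sigma_eps)
  s <- matrix(rnorm(n * 3), n, 3) %*% ls
  eps <- matrix(rnorm(n * 2), n, 2) %*% le
  draws <- cbind(s, s %*% t(sys$a) + sqrt(sys$g) * eps)
  emp <- crossprod(draws) / n
  se <- sqrt((outer(diag(jc), diag(jc)) + jc^2) / n)
  expect_true(all(abs(emp - jc) < 3 * se))
})

test_that("system validation rejects bad inputs by name", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # indefinite
  expect_error(gaussian_system(bad, c(1, 1), 1, 1, d_x = 1), "sigma_s")
  expect_error(gaussian_system(diag(2), c(1, 1), -1, 1, d_x = 1), "sigma_eps")
  expect_error(gaussian_system(diag(2), c(1, 1), 1, 0, d_x = 1), "g")
  expect_error(gaussian_system(diag(2), c(1, 1), 1, 1, d_x = 2), "d_x")
})

test_that("mutual information: independence, bivariate closed form, symmetry", {
  expect_equal(mutual_information(diag(4), 1:2, 3:4), 0)
  r <- 0.5
  biv <- matrix(c(1, r, r, 1), 2)
  expect_equal(mutual_information(biv, 1, 2), -0.5 * log(1 - r^2),
               tolerance = 1e-12)
  set.seed(2)
  m <- random_spd(5)
  expect_equal(mutual_information(m, c(1, 3), c(2, 5)),
               mutual_information(m, c(2, 5), c(1, 3)))
})

test_that("mutual information equals the entropy difference H(a)+H(b)-H(a,b)", {
  set.seed(3)
  gauss_entropy <- function(cov) {
    d <- nrow(cov)
    0.5 * (d * log(2 * pi * exp(1)) + determinant(cov)$modulus[1])
  }
  for (i in 1:20) {
    m <- random_spd(4)
    ia <- 1:2; ib <- 3:4
    h <- gauss_entropy(m[ia, ia]) + gauss_entropy(m[ib, ib]) - gauss_entropy(m)
    expect_equal(mutual_information(m, ia, ib), h, tolerance = 1e-10)
  }
})

test_that("mutual information rejects overlapping, empty, or out-of-range indices", {
  m <- diag(3)
  expect_error(mutual_information(m, 1:2, 2:3), "disjoint")
  expect_error(mutual_information(m, integer(0), 2), "non-empty")
  expect_error(mutual_information(m, 1, 5), "bounds")
  sing <- matrix(1, 3, 3)
  expect_error(mutual_information(sing, 1:2, 3), "idx_a")
})

test_that("total mutual information matches the determinant form and the generic MI", {
  expect_equal(total_mutual_information(example_bivariate_system(1)),
               0.5 * log(16), tolerance = 1e-12)
  set.seed(4)
  a0 <- gaussian_system(random_spd(2), matrix(0, 1, 2), 1, 1, d_x = 1)
  expect_equal(total_mutual_information(a0), 0)
  for (i in 1:100) {
    sys <- random_gaussian_system()
    jc <- joint_covariance(sys)
    p <- sys$partition
    expect_equal(total_mutual_information(sys),
                 mutual_information(jc, seq_len(p$d_s), p$d_s + seq_len(p$d_t)),
                 tolerance = 1e-10)
  }
})

test_that("TMI is non-increasing in g and non-negative", {
  set.seed(5)
  for (i in 1:10) {
    sys <- random_gaussian_system()
    tmis <- sapply(10^seq(-2, 2, length.out = 15), function(g) {
      sys$g <- g
      total_mutual_information(sys)
    })
    expect_true(all(diff(tmis) <= 1e-12))
    expect_true(all(tmis >= -1e-12))
  }
})

test_that("rescaling sigma_eps by c is equivalent to replacing g by c*g", {
  set.seed(6)
  sys <- random_gaussian_system(d_x = 2, d_y = 1, d_t = 2)
  cc <- 3.7
  scaled <- gaussian_system(sys$sigma_s, sys$a, cc * sys$sigma_eps, sys$g,
                            d_x = 2)
  bumped <- gaussian_system(sys$sigma_s, sys$a, sys$sigma_eps, cc * sys$g,
                            d_x = 2)
  expect_equal(total_mutual_information(scaled),
               total_mutual_information(bumped), tolerance = 1e-12)
  expect_equal(marginal_informations(scaled), marginal_informations(bumped),
               tolerance = 1e-12)
})

test_that("marginal informations respect symmetry, disconnection, and samples", {
  # exchangeable sources with equal couplings: I(X;T) = I(Y;T)
  mi <- marginal_informations(example_bivariate_system(2))
  expect_equal(mi[["i_x"]], mi[["i_y"]])
  # X disconnected and uncorrelated: I(X;T) = 0
  disc <- gaussian_system(diag(2), c(0, 0.99), 1, 1, d_x = 1)
  expect_equal(marginal_informations(disc)[["i_x"]], 0)
  # sample-based oracle: plug-in Gaussian MI from the empirical covariance
  set.seed(7)
  sys <- random_gaussian_system(d_x = 1, d_y = 1, d_t = 1)
  n <- 1e5
  s <- matrix(rnorm(n * 2), n, 2) %*% chol(sys$sigma_s)
  tt <- s %*% t(sys$a) + sqrt(sys$g) * matrix(rnorm(n), n, 1) %*% chol(sys$sigma_eps)
  emp <- stats::cov(cbind(s, tt))
  mi_hat <- c(mutual_information(emp, 1, 3), mutual_information(emp, 2, 3))
  expect_equal(unname(marginal_informations(sys)), mi_hat, tolerance = 0.02)
})

test_that("systems round-trip exactly through JSON", {
  set.seed(8)
  sys <- random_gaussian_system(d_x = 2, d_y = 2, d_t = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_gaussian_system(sys, f)
  back <- read_gaussian_system(f)
  expect_identical(back$sigma_s, sys$sigma_s)
  expect_identical(back$a, sys$a)
  expect_identical(back$sigma_eps, sys$sigma_eps)
  expect_identical(back$g, sys$g)
  expect_identical(back$partition, sys$partition)
})

test_that("reading a malformed system file names the missing key", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(sigma_s = diag(2), g = 1), f)
  expect_error(read_gaussian_system(f), "a, sigma_eps")
})
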