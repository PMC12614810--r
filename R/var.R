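# VAR(p) modelling: companion form, autocovariances via the discrete
# Lyapunov equation, past->future mutual information blocks, OLS fitting
# from epoched multivariate time series, and stable simulation.

#' Vector autoregression model
#'
#' `X_t = A_1 X_{t-1} + ... + A_p X_{t-p} + eta_t` with white Gaussian
#' innovations `eta_t ~ N(0, V)`.
#'
#' @param coeffs A single `n x n` matrix (order 1) or a list of `p`
#'   `n x n` coefficient matrices `A_1 ... A_p`.
#' @param resid_cov Symmetric positive-definite innovation covariance `V`.
#' @return An object of class `var_model` with fields `p`, `n`, `coeffs`
#'   (list of matrices) and `resid_cov`.
#' @export
var_model <- function(coeffs, resid_cov) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || length(coeffs) == 0) {
    stop("coeffs must be a matrix or a non-empty list of matrices", call. = FALSE)
  }
  n <- nrow(coeffs[[1]])
  for (a in coeffs) {
    if (!is.matrix(a) || nrow(a) != n || ncol(a) != n) {
      stop("all coefficient matrices must be square with matching size",
           call. = FALSE)
    }
  }
  if (length(resid_cov) == 1 && !is.matrix(resid_cov)) {
    resid_cov <- matrix(resid_cov, 1, 1)
  }
  .check_spd(resid_cov, "resid_cov")
  if (nrow(resid_cov) != n) stop("resid_cov must be n x n", call. = FALSE)
  structure(list(p = length(coeffs), n = n, coeffs = coeffs,
                 resid_cov = .sym(resid_cov)),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model on %d channels, spectral radius %.4f\n",
              x$p, x$n, spectral_radius(x)))
  invisible(x)
}

#' Companion matrix of a VAR(p) model
#'
#' The `np x np` block matrix with `[A_1 ... A_p]` on the top block row,
#' identity blocks on the sub-diagonal and zeros elsewhere; it rewrites
#' the VAR(p) as a VAR(1) on the stacked state
#' `(X_t, X_{t-1}, ..., X_{t-p+1})`.
#'
#' @param model A [var_model()].
#' @return An `np x np` matrix.
#' @export
companion_matrix <- function(model) {
  stopifnot(inherits(model, "var_model"))
  n <- model$n; p <- model$p
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) {
    comp[seq_len(n), (l - 1) * n + seq_len(n)] <- model$coeffs[[l]]
  }
  if (p > 1) {
    sub <- seq_len(n * (p - 1))
    comp[cbind(n + sub, sub)] <- 1
  }
  comp
}

#' Spectral radius of the companion matrix
#'
#' Largest eigenvalue magnitude; strictly below 1 means the VAR is
#' stationary.
#'
#' @param model A [var_model()] or a plain square matrix.
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(model) {
  m <- if (inherits(model, "var_model")) companion_matrix(model) else model
  max(Mod(eigen(m, only.values = TRUE)$values))
}

# Margin below 1 required for simulation and Lyapunov solving.
.stability_margin <- 1e-6

.check_stable <- function(model) {
  rho <- spectral_radius(model)
  if (rho >= 1 - .stability_margin) {
    stop(sprintf("spectral radius >= 1 (%.6f): model is not stationary", rho),
         call. = FALSE)
  }
  rho
}

# Solve X = A X A' + W for the stationary covariance of a stable linear
# system (discrete Lyapunov equation) by Kronecker vectorisation:
# (I - A (x) A) vec(X) = vec(W). Dense direct solve; intended for the
# moderate state dimensions (tens) used here.
.dlyap <- function(a, w) {
  m <- nrow(a)
  x <- solve(diag(m * m) - kronecker(a, a), as.vector(w))
  .sym(matrix(x, m, m))
}

#' Autocovariance sequence of a stable VAR(p) model
#'
#' Solves the discrete Lyapunov equation `Gamma = A Gamma A' + W` for the
#' stacked-state covariance (with `W` holding the innovation covariance
#' `V` in its leading block and zeros elsewhere), then reads
#' `Gamma_0 ... Gamma_{p-1}` off the first block row and extends to
#' `Gamma_p` through the Yule-Walker recursion
#' `Gamma_k = sum_l A_l Gamma_{k-l}`.
#'
#' @param model A stable [var_model()].
#' @return An object of class `autocovariance_set`: a list with `gammas`
#'   (list of `p + 1` matrices `Gamma_0 ... Gamma_p`, where
#'   `Gamma_k = E[X_t X_{t-k}']`).
#' @export
solve_autocovariance <- function(model) {
  .check_stable(model)
  n <- model$n; p <- model$p
  comp <- companion_matrix(model)
  w <- matrix(0, n * p, n * p)
  w[seq_len(n), seq_len(n)] <- model$resid_cov
  big <- .dlyap(comp, w)
  gammas <- vector("list", p + 1)
  gammas[[1]] <- .sym(big[seq_len(n), seq_len(n), drop = FALSE])
  if (p > 1) {
    for (k in seq_len(p - 1)) {
      # Block (1, k+1) of the stacked-state covariance is
      # E[X_t X_{t-k}'] = Gamma_k.
      gammas[[k + 1]] <- big[seq_len(n), k * n + seq_len(n), drop = FALSE]
    }
  }
  gp <- matrix(0, n, n)
  for (l in seq_len(p)) {
    gp <- gp + model$coeffs[[l]] %*% gammas[[p - l + 1]]
  }
  gammas[[p + 1]] <- gp
  structure(list(gammas = gammas, n = n, p = p), class = "autocovariance_set")
}

#' Total mutual information of a VAR model (past vs one-step future)
#'
#' `I(past; X_t) = 0.5 * (logdet Gamma_0 - logdet V)`, in nats: the
#' conditional covariance of the next state given the full `p`-lag past is
#' the innovation covariance `V`, while its marginal covariance is
#' `Gamma_0`. Invariant to rescaling `V` by any positive constant (the
#' autocovariances scale by the same factor).
#'
#' @param model A stable [var_model()].
#' @param acov Optional precomputed [solve_autocovariance()] result.
#' @return TMI in nats (non-negative).
#' @export
var_tmi <- function(model, acov = NULL) {
  if (is.null(acov)) acov <- solve_autocovariance(model)
  0.5 * (.logdet(acov$gammas[[1]], "Gamma_0") -
         .logdet(model$resid_cov, "resid_cov"))
}

#' Mutual-information triple for a VAR(1) past->future decomposition
#'
#' Treats the past states of two channel groups as sources `X`, `Y` and
#' the joint one-step future of all channels as the target `T`. Assembles
#' the `2n x 2n` covariance of `(state_{t-1}, state_t)` from the blocks
#' `[[Gamma_0, Gamma_1'], [Gamma_1, Gamma_0]]` and computes
#' `i_x = I(X_past; future)`, `i_y = I(Y_past; future)` and the TMI.
#'
#' @param model A stable VAR(1) [var_model()]. Orders above 1 are not
#'   supported by this decomposition (the stacked-past assembly is out of
#'   scope).
#' @param x_channels Indices (1-based) of the channels forming source `X`;
#'   the remaining channels form `Y`.
#' @return A list with `i_x`, `i_y`, `tmi` (nats).
#' @export
var_pid_blocks <- function(model, x_channels) {
  stopifnot(inherits(model, "var_model"))
  if (model$p != 1) {
    stop("past->future PID blocks are implemented for VAR(1) only", call. = FALSE)
  }
  n <- model$n
  x_channels <- as.integer(x_channels)
  if (length(x_channels) == 0 || any(x_channels < 1) || any(x_channels > n) ||
      anyDuplicated(x_channels) || length(x_channels) >= n) {
    stop("x_channels must be a proper non-empty subset of 1..n", call. = FALSE)
  }
  acov <- solve_autocovariance(model)
  g0 <- acov$gammas[[1]]
  g1 <- acov$gammas[[2]]
  joint <- rbind(cbind(g0, t(g1)), cbind(g1, g0))
  fut <- n + seq_len(n)
  tmi <- var_tmi(model, acov)
  i_x <- mutual_information(joint, x_channels, fut)
  i_y <- mutual_information(joint, setdiff(seq_len(n), x_channels), fut)
  list(i_x = min(i_x, tmi), i_y = min(i_y, tmi), tmi = tmi)
}

#' Epoched multivariate time series
#'
#' A 3-dimensional array of shape `epochs x timepoints x channels`,
#' treated as independent stationary realisations of one process.
#'
#' @param data Numeric 3-d array (`epochs x timepoints x channels`).
#' @param note Free-text provenance note.
#' @return An object of class `epoched_ts`.
#' @export
epoched_ts <- function(data, note = "") {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("data must be a 3-d array: epochs x timepoints x channels",
         call. = FALSE)
  }
  if (dim(data)[1] < 1) stop("need at least one epoch", call. = FALSE)
  structure(list(data = data, note = note), class = "epoched_ts")
}

#' @export
print.epoched_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched time series: %d epochs x %d timepoints x %d channels\n",
              d[1], d[2], d[3]))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Fit a VAR(p) model by pooled ordinary least squares
#'
#' De-means each channel within each epoch, builds time-lagged regressors,
#' pools the regression rows across epochs, and fits each equation by OLS
#' without intercept (zero-mean convention). The innovation covariance is
#' the residual cross-product divided by `(rows - n * p)`.
#'
#' The fitted model is returned as-is (it need not be stationary);
#' downstream operations that require stability re-validate it.
#'
#' @param ts An [epoched_ts()].
#' @param p Model order (default 1).
#' @return A [var_model()].
#' @export
fit_var <- function(ts, p = 1) {
  stopifnot(inherits(ts, "epoched_ts"))
  p <- .check_count(p, "p")
  d <- dim(ts$data)
  n_epochs <- d[1]; n_time <- d[2]; n <- d[3]
  if (n_time <= n * p + p) {
    stop("epochs too short for the requested model order", call. = FALSE)
  }
  rows_per_epoch <- n_time - p
  y <- matrix(0, n_epochs * rows_per_epoch, n)
  z <- matrix(0, n_epochs * rows_per_epoch, n * p)
  for (e in seq_len(n_epochs)) {
    x <- ts$data[e, , ]
    if (!is.matrix(x)) x <- matrix(x, n_time, n)
    x <- sweep(x, 2, colMeans(x))          # de-mean per channel per epoch
    rows <- (e - 1) * rows_per_epoch + seq_len(rows_per_epoch)
    y[rows, ] <- x[(p + 1):n_time, , drop = FALSE]
    for (l in seq_len(p)) {
      z[rows, (l - 1) * n + seq_len(n)] <- x[(p + 1 - l):(n_time - l), ,
                                             drop = FALSE]
    }
  }
  qz <- qr(z)
  if (qz$rank < n * p) {
    stop("rank-deficient regressor matrix: cannot identify VAR coefficients",
         call. = FALSE)
  }
  coef <- qr.coef(qz, y)                   # (n*p) x n, block l = t(A_l)
  resid <- y - z %*% coef
  v <- crossprod(resid) / (nrow(z) - n * p)
  coeffs <- lapply(seq_len(p), function(l) {
    t(coef[(l - 1) * n + seq_len(n), , drop = FALSE])
  })
  var_model(coeffs, v)
}

#' Simulate epoched data from a stable VAR model
#'
#' Each epoch is an independent realisation: Gaussian innovations with
#' covariance `V`, a discarded burn-in, then `timepoints` recorded steps.
#'
#' @param model A stable [var_model()].
#' @param epochs,timepoints Output dimensions.
#' @param burn_in Number of initial steps discarded per epoch (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return An [epoched_ts()].
#' @export
simulate_var <- function(model, epochs, timepoints, burn_in = 200,
                         seed = NULL) {
  .check_stable(model)
  epochs <- .check_count(epochs, "epochs")
  timepoints <- .check_count(timepoints, "timepoints")
  if (burn_in < 100) stop("burn_in must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n; p <- model$p
  u_chol <- chol(model$resid_cov)
  total <- burn_in + timepoints
  out <- array(0, dim = c(epochs, timepoints, n))
  for (e in seq_len(epochs)) {
    innov <- matrix(stats::rnorm(total * n), total, n) %*% u_chol
    x <- matrix(0, total, n)
    for (t in seq_len(total)) {
      xt <- innov[t, ]
      for (l in seq_len(p)) {
        if (t - l >= 1) xt <- xt + model$coeffs[[l]] %*% x[t - l, ]
      }
      x[t, ] <- xt
    }
    out[e, , ] <- x[(burn_in + 1):total, , drop = FALSE]
  }
  epoched_ts(out, note = sprintf("simulated VAR(%d), n = %d", p, n))
}

#' Rescale a VAR model to a prescribed spectral radius
#'
#' Exponentially decays the lag-`k` coefficients by `f^k` with
#' `f = target_radius / current_radius`, which sets the companion-matrix
#' spectral radius exactly to `target_radius`. For VAR(1) this is plain
#' rescaling of `A`.
#'
#' @param model A [var_model()] with nonzero coefficients.
#' @param target_radius Desired spectral radius (> 0).
#' @return A rescaled [var_model()] sharing `V`.
#' @export
rescale_to_radius <- function(model, target_radius) {
  stopifnot(inherits(model, "var_model"))
  if (!is.numeric(target_radius) || target_radius <= 0) {
    stop("target_radius must be positive", call. = FALSE)
  }
  rho <- spectral_radius(model)
  if (rho == 0) {
    stop("spectral radius is zero (all coefficients vanish): radius undefined",
         call. = FALSE)
  }
  f <- target_radius / rho
  coeffs <- lapply(seq_along(model$coeffs), function(k) f^k * model$coeffs[[k]])
  var_model(coeffs, model$resid_cov)
}

#' Read or write epoched time series as a directory of CSV files
#'
#' One CSV per epoch (`epoch_001.csv`, ...), each `timepoints x channels`
#' with a header row of channel names; the channel order defines partition
#' indices. The writer mirrors the reader so round-trips are exact to
#' printed precision.
#'
#' @param dir Directory holding (or to hold) the per-epoch CSV files.
#' @param ts An [epoched_ts()] (for writing).
#' @return `read_epochs_csv` returns an [epoched_ts()];
#'   `write_epochs_csv` returns `dir` invisibly.
#' @export
read_epochs_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no CSV files found in ", dir, call. = FALSE)
  mats <- lapply(files, function(f) as.matrix(utils::read.csv(f)))
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!all(dim(m) == d)) {
      stop("all epoch files must share timepoints x channels shape",
           call. = FALSE)
    }
  }
  out <- array(0, dim = c(length(mats), d[1], d[2]))
  for (e in seq_along(mats)) out[e, , ] <- mats[[e]]
  epoched_ts(out, note = sprintf("read from %s", dir))
}

#' @rdname read_epochs_csv
#' @export
write_epochs_csv <- function(ts, dir) {
  stopifnot(inherits(ts, "epoched_ts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(ts$data)
  for (e in seq_len(d[1])) {
    m <- ts$data[e, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, d[2], d[3])
    colnames(m) <- sprintf("ch%02d", seq_len(d[3]))
    utils::write.csv(m, file.path(dir, sprintf("epoch_%03d.csv", e)),
                     row.names = FALSE)
  }
  invisible(dir)
}
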