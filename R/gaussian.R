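# Linear-Gaussian source->target systems and closed-form Gaussian
# mutual information from covariance blocks.

# Symmetrise a nearly-symmetric matrix (guards accumulated fp asymmetry).
.sym <- function(m) (m + t(m)) / 2

# Log-determinant of a symmetric positive-definite matrix via Cholesky.
# Never uses det(): raw determinants overflow for moderate dimension/scale.
.logdet <- function(m, what = "matrix") {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf("%s is singular or not positive definite", what), call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

# Positive-definite check: symmetric and min eigenvalue > rel_tol * max.
.check_spd <- function(m, what = "matrix", rel_tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  ev <- eigen(.sym(m), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= rel_tol * max(ev) || max(ev) <= 0) {
    stop(sprintf("%s is not positive definite", what), call. = FALSE)
  }
  invisible(TRUE)
}

.check_count <- function(x, what) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("%s must be a positive integer", what), call. = FALSE)
  }
  as.integer(x)
}

#' Partition of a stacked Gaussian source into two sources and a target
#'
#' Fixes the dimensions of the two (possibly multivariate) sources `X`, `Y`
#' and the target `T`. By convention `X` occupies the first `d_x`
#' coordinates of the stacked source vector `S = (X, Y)` and `Y` the
#' remaining `d_y`; the target occupies the trailing `d_t` coordinates of
#' the joint `(S, T)` vector.
#'
#' @param d_x,d_y,d_t Positive integers: dimensions of source `X`, source
#'   `Y`, and target `T`.
#' @return An object of class `source_partition` with fields `d_x`, `d_y`,
#'   `d_t` and the derived source dimension `d_s = d_x + d_y`.
#' @examples
#' source_partition(1, 1, 1)
#' @export
source_partition <- function(d_x, d_y, d_t) {
  d_x <- .check_count(d_x, "d_x")
  d_y <- .check_count(d_y, "d_y")
  d_t <- .check_count(d_t, "d_t")
  structure(list(d_x = d_x, d_y = d_y, d_t = d_t, d_s = d_x + d_y),
            class = "source_partition")
}

# Index helpers (1-based, R convention): X first, then Y, then T.
.idx_x <- function(p) seq_len(p$d_x)
.idx_y <- function(p) p$d_x + seq_len(p$d_y)
.idx_s <- function(p) seq_len(p$d_s)
.idx_t <- function(p) p$d_s + seq_len(p$d_t)

#' Linear-Gaussian source-target system
#'
#' Represents the model `T = A S + sqrt(g) * eps` with zero-mean Gaussian
#' source `S ~ N(0, sigma_s)` and white noise `eps ~ N(0, sigma_eps)`.
#' The noise-strength parameter `g` enters on the covariance scale: the
#' effective noise covariance of the target is `g * sigma_eps`, so that
#' `Cov(T) = A sigma_s A' + g sigma_eps`.
#'
#' @param sigma_s Symmetric positive-definite source covariance
#'   (`d_s x d_s`).
#' @param a Coefficient (connectivity) matrix, `d_t x d_s`. A numeric
#'   vector is interpreted as a single-row matrix.
#' @param sigma_eps Symmetric positive-definite noise covariance
#'   (`d_t x d_t`). A scalar is promoted to a `1 x 1` matrix.
#' @param g Positive noise-strength scalar.
#' @param d_x Dimension of source `X` (first `d_x` rows/columns of
#'   `sigma_s`); the remaining `d_s - d_x` coordinates form `Y`.
#' @return An object of class `gaussian_system`.
#' @examples
#' sys <- gaussian_system(
#'   sigma_s = matrix(c(20, 10, 10, 20), 2),
#'   a = c(0.5, 0.5), sigma_eps = 1, g = 1, d_x = 1
#' )
#' total_mutual_information(sys) # 0.5 * log(16)
#' @export
gaussian_system <- function(sigma_s, a, sigma_eps, g, d_x) {
  if (is.vector(a) && is.numeric(a)) a <- matrix(a, nrow = 1)
  if (length(sigma_eps) == 1 && !is.matrix(sigma_eps)) {
    sigma_eps <- matrix(sigma_eps, 1, 1)
  }
  if (!is.matrix(sigma_s)) stop("sigma_s must be a matrix", call. = FALSE)
  d_s <- ncol(sigma_s)
  if (ncol(a) != d_s) {
    stop("a must have as many columns as sigma_s has rows", call. = FALSE)
  }
  d_t <- nrow(a)
  d_x <- .check_count(d_x, "d_x")
  if (d_x >= d_s) stop("d_x must be smaller than the source dimension", call. = FALSE)
  .check_spd(sigma_s, "sigma_s")
  .check_spd(sigma_eps, "sigma_eps")
  if (nrow(sigma_eps) != d_t) {
    stop("sigma_eps must be d_t x d_t", call. = FALSE)
  }
  if (!is.numeric(g) || length(g) != 1 || is.na(g) || g <= 0) {
    stop("g must be a positive scalar", call. = FALSE)
  }
  structure(
    list(sigma_s = .sym(sigma_s), a = a, sigma_eps = .sym(sigma_eps),
         g = as.numeric(g),
         partition = source_partition(d_x, d_s - d_x, d_t)),
    class = "gaussian_system"
  )
}

#' @export
print.gaussian_system <- function(x, ...) {
  p <- x$partition
  cat(sprintf("Linear-Gaussian system: d_x = %d, d_y = %d, d_t = %d, g = %g\n",
              p$d_x, p$d_y, p$d_t, x$g))
  cat(sprintf("  TMI = %.6g nats\n", total_mutual_information(x)))
  invisible(x)
}

#' Joint covariance of sources and target
#'
#' Assembles the full `(d_s + d_t) x (d_s + d_t)` covariance of the stacked
#' vector `(S, T)`: the source block is `sigma_s`, the target block is
#' `A sigma_s A' + g sigma_eps`, and the cross block is `sigma_s A'`.
#'
#' @param system A [gaussian_system()].
#' @return An object of class `joint_covariance` with fields `matrix` and
#'   `partition`.
#' @export
joint_covariance <- function(system) {
  stopifnot(inherits(system, "gaussian_system"))
  a <- system$a
  cross <- system$sigma_s %*% t(a)          # Cov(S, T)
  target <- .sym(a %*% cross + system$g * system$sigma_eps)
  m <- rbind(cbind(system$sigma_s, cross),
             cbind(t(cross), target))
  dimnames(m) <- NULL
  structure(list(matrix = m, partition = system$partition),
            class = "joint_covariance")
}

#' Gaussian mutual information between two index sets
#'
#' Closed-form mutual information `I(a; b) = (H(a) + H(b) - H(a,b))`
#' between two disjoint coordinate subsets of a joint Gaussian vector,
#' computed from log-determinants of covariance sub-blocks:
#' `0.5 * (logdet C_aa + logdet C_bb - logdet C_ab,ab)`, in nats.
#'
#' @param joint A [joint_covariance()] object or a plain symmetric
#'   covariance matrix.
#' @param idx_a,idx_b Disjoint, non-empty 1-based index vectors.
#' @return Mutual information in nats (non-negative up to rounding).
#' @export
mutual_information <- function(joint, idx_a, idx_b) {
  m <- if (inherits(joint, "joint_covariance")) joint$matrix else joint
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("joint must be a square covariance matrix", call. = FALSE)
  }
  idx_a <- as.integer(idx_a); idx_b <- as.integer(idx_b)
  if (length(idx_a) == 0 || length(idx_b) == 0) {
    stop("index sets must be non-empty", call. = FALSE)
  }
  if (any(idx_a < 1) || any(idx_b < 1) ||
      any(idx_a > nrow(m)) || any(idx_b > nrow(m))) {
    stop("index out of bounds", call. = FALSE)
  }
  if (length(intersect(idx_a, idx_b)) > 0) {
    stop("index sets must be disjoint", call. = FALSE)
  }
  ab <- c(idx_a, idx_b)
  0.5 * (.logdet(m[idx_a, idx_a, drop = FALSE], "marginal covariance of idx_a") +
         .logdet(m[idx_b, idx_b, drop = FALSE], "marginal covariance of idx_b") -
         .logdet(m[ab, ab, drop = FALSE], "joint covariance of idx_a + idx_b"))
}

#' Total mutual information of a Gaussian system
#'
#' The joint mutual information `I(S; T)` between the stacked sources and
#' the target, in nats:
#' `0.5 * (logdet(A sigma_s A' + g sigma_eps) - logdet(g sigma_eps))`.
#' Monotonically decreasing in `g` whenever the signal term is nonzero.
#'
#' @param system A [gaussian_system()].
#' @return TMI in nats.
#' @export
total_mutual_information <- function(system) {
  stopifnot(inherits(system, "gaussian_system"))
  signal <- .sym(system$a %*% system$sigma_s %*% t(system$a))
  noise <- system$g * system$sigma_eps
  0.5 * (.logdet(signal + noise, "target covariance") -
         .logdet(noise, "noise covariance"))
}

#' Marginal source-target mutual informations
#'
#' Returns `I(X; T)` and `I(Y; T)` by index selection on the joint
#' covariance. Each is bounded above by the total mutual information
#' (Gaussian MI monotonicity under inclusion of sources).
#'
#' @param system A [gaussian_system()].
#' @return Named numeric vector `c(i_x =, i_y =)`, in nats.
#' @export
marginal_informations <- function(system) {
  jc <- joint_covariance(system)
  p <- jc$partition
  c(i_x = mutual_information(jc, .idx_x(p), .idx_t(p)),
    i_y = mutual_information(jc, .idx_y(p), .idx_t(p)))
}

#' Read or write a Gaussian system as JSON
#'
#' The JSON document has keys `sigma_s`, `a`, `sigma_eps` (row-major nested
#' arrays), `g`, `d_x`, and `d_y`; values round-trip at full double
#' precision.
#'
#' @param path File path.
#' @param system A [gaussian_system()] (for writing).
#' @return `read_gaussian_system` returns a [gaussian_system()];
#'   `write_gaussian_system` returns `path` invisibly.
#' @export
read_gaussian_system <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sigma_s", "a", "sigma_eps", "g", "d_x", "d_y")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0) {
    stop(sprintf("system file is missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  gaussian_system(sigma_s = as_mat(doc$sigma_s), a = as_mat(doc$a),
                  sigma_eps = as_mat(doc$sigma_eps), g = doc$g,
                  d_x = doc$d_x)
}

#' @rdname read_gaussian_system
#' @export
write_gaussian_system <- function(system, path) {
  stopifnot(inherits(system, "gaussian_system"))
  p <- system$partition
  doc <- list(sigma_s = system$sigma_s, a = system$a,
              sigma_eps = system$sigma_eps, g = system$g,
              d_x = p$d_x, d_y = p$d_y)
  # 17 significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}
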