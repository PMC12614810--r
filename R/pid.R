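# Partial information decomposition (two sources, one target) under the
# minimal-mutual-information (MMI) redundancy, plus the NMI baseline
# normalisation.

.new_pid_atoms <- function(red, un_x, un_y, syn, tmi) {
  structure(list(red = red, un_x = un_x, un_y = un_y, syn = syn, tmi = tmi),
            class = "pid_atoms")
}

#' PID atoms from the mutual-information triple
#'
#' Given the two marginal mutual informations `I(X;T)`, `I(Y;T)` and the
#' total mutual information `I(X,Y;T)`, returns the four PID atoms.
#' Redundancy defaults to the MMI definition
#' `Red = min(I(X;T), I(Y;T))`; the remaining atoms then follow from the
#' defining identities `Un_X = I(X;T) - Red`, `Un_Y = I(Y;T) - Red`,
#' `Syn = TMI - Red - Un_X - Un_Y`, so the decomposition sums to TMI
#' exactly by construction. Under MMI at least one unique information is
#' identically zero, and all atoms are non-negative for Gaussian inputs.
#'
#' @param i_x,i_y Marginal mutual informations in nats.
#' @param tmi Total mutual information in nats.
#' @param redundancy Optional redundancy function with signature
#'   `function(i_x, i_y, tmi)`; defaults to `min(i_x, i_y)` (MMI). Hook
#'   for alternative two-source PID definitions.
#' @param tol Tolerance on the Gaussian monotonicity constraints
#'   `0 <= i_x, i_y <= tmi`; violations beyond `tol` signal an upstream
#'   error and abort.
#' @return An object of class `pid_atoms` with fields `red`, `un_x`,
#'   `un_y`, `syn`, `tmi` (all in nats).
#' @examples
#' mmi_atoms(0.3, 0.5, 0.9) # red 0.3, un_x 0, un_y 0.2, syn 0.4
#' @export
mmi_atoms <- function(i_x, i_y, tmi, redundancy = NULL, tol = 1e-9) {
  stopifnot(is.numeric(i_x), is.numeric(i_y), is.numeric(tmi))
  if (i_x < -tol || i_y < -tol || tmi < -tol) {
    stop("mutual informations must be non-negative", call. = FALSE)
  }
  if (i_x > tmi + tol || i_y > tmi + tol) {
    stop("marginal mutual information exceeds the total: inconsistent inputs",
         call. = FALSE)
  }
  red <- if (is.null(redundancy)) min(i_x, i_y) else redundancy(i_x, i_y, tmi)
  un_x <- i_x - red
  un_y <- i_y - red
  syn <- tmi - red - un_x - un_y
  .new_pid_atoms(red, un_x, un_y, syn, tmi)
}

#' @export
print.pid_atoms <- function(x, ...) {
  cat("PID atoms (nats):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.data.frame.pid_atoms <- function(x, ...) {
  data.frame(red = x$red, un_x = x$un_x, un_y = x$un_y, syn = x$syn,
             tmi = x$tmi)
}

.new_normalised_atoms <- function(red, un_x, un_y, syn, scheme, tmi) {
  structure(list(red = red, un_x = un_x, un_y = un_y, syn = syn,
                 scheme = scheme, tmi = tmi),
            class = "normalised_atoms")
}

#' @export
print.normalised_atoms <- function(x, ...) {
  cat(sprintf("%s-normalised PID atoms (raw TMI = %.6g nats):\n",
              x$scheme, x$tmi))
  print(unlist(x[c("red", "un_x", "un_y", "syn")]))
  invisible(x)
}

#' @export
as.data.frame.normalised_atoms <- function(x, ...) {
  data.frame(red = x$red, un_x = x$un_x, un_y = x$un_y, syn = x$syn,
             tmi = x$tmi, scheme = x$scheme)
}

#' Naive normalisation by total mutual information (NMI)
#'
#' Divides each atom by the TMI, so the normalised atoms sum to one and
#' can be read as the fraction of the total mutual information carried by
#' each atom. This baseline implicitly assumes every atom grows linearly
#' with TMI, which random-system ensembles show is false; it is provided
#' for comparison with [numit_quantile()].
#'
#' @param atoms A [mmi_atoms()] result.
#' @param tol Smallest TMI (nats) considered normalisable.
#' @return An object of class `normalised_atoms` with `scheme = "NMI"`.
#' @export
nmi_normalise <- function(atoms, tol = 1e-9) {
  stopifnot(inherits(atoms, "pid_atoms"))
  if (atoms$tmi <= tol) {
    stop("TMI too small to normalise", call. = FALSE)
  }
  .new_normalised_atoms(atoms$red / atoms$tmi, atoms$un_x / atoms$tmi,
                        atoms$un_y / atoms$tmi, atoms$syn / atoms$tmi,
                        scheme = "NMI", tmi = atoms$tmi)
}

#' PID atoms of a linear-Gaussian system
#'
#' Convenience composition: computes the marginal and total mutual
#' informations of the system in closed form and applies [mmi_atoms()].
#'
#' @param system A [gaussian_system()].
#' @param redundancy Optional redundancy function, see [mmi_atoms()].
#' @return A `pid_atoms` object.
#' @export
pid_from_system <- function(system, redundancy = NULL) {
  mi <- marginal_informations(system)
  tmi <- total_mutual_information(system)
  # Closed-form MI can exceed TMI by ~1e-14 through rounding; clamp within
  # a strict tolerance so downstream atoms stay consistent.
  mmi_atoms(min(mi[["i_x"]], tmi), min(mi[["i_y"]], tmi), tmi)
}
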