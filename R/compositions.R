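#' Close a non-negative vector to a composition
#'
#' Normalises a non-negative vector (or the rows of a matrix) to sum to one,
#' the closure operation \eqn{C} of compositional data analysis.  A fatty-acid
#' profile or a vector of diet proportions is a composition: a vector of
#' non-negative parts carrying only relative information.
#'
#' @param x numeric vector with at least two entries, all non-negative and not
#'   all zero, or a matrix whose rows are such vectors.
#' @return a vector (or matrix of rows) proportional to `x` summing to one.
#'   Names/dimnames are preserved.
#' @examples
#' closure(c(1, 1, 2))
#' @export
closure <- function(x) {
  if (is.matrix(x)) {
    .check_parts(x)
    s <- rowSums(x)
    if (any(s <= 0)) stop("invalid composition: a row sums to zero", call. = FALSE)
    return(x / s)
  }
  .check_parts(x)
  s <- sum(x)
  if (s <= 0) stop("invalid composition: all parts are zero", call. = FALSE)
  x / s
}

.check_parts <- function(x) {
  if (!is.numeric(x)) stop("composition parts must be numeric", call. = FALSE)
  p <- if (is.matrix(x)) ncol(x) else length(x)
  if (p < 2) stop("a composition needs at least two parts", call. = FALSE)
  if (any(!is.finite(x))) stop("composition parts must be finite", call. = FALSE)
  if (any(x < 0)) stop("invalid composition: negative part", call. = FALSE)
  invisible(TRUE)
}

.check_positive_comp <- function(x, caller) {
  if (any(x == 0))
    stop(caller, ": composition has zero parts; apply replace_zeros() first",
         call. = FALSE)
  invisible(TRUE)
}

#' Additive log-ratio transform
#'
#' Maps a strictly positive composition of `p` parts to an unconstrained
#' vector of `p - 1` log ratios against a reference part,
#' \eqn{alr(\phi)_k = \log(\phi_k / \phi_{ref})}.  The reference part is
#' dropped from the output, which keeps the remaining part names.
#'
#' @param x a composition (or matrix of row compositions) with strictly
#'   positive parts.
#' @param ref index of the reference part; defaults to the last part.
#' @return numeric vector of length `p - 1` (or a matrix with `p - 1`
#'   columns).
#' @seealso [alr_inv()], [clr()], [replace_zeros()]
#' @export
alr <- function(x, ref = NULL) {
  if (is.matrix(x)) {
    p <- ncol(x)
    if (is.null(ref)) ref <- p
    .check_parts(x); .check_positive_comp(x, "alr")
    return(log(x[, -ref, drop = FALSE] / x[, ref]))
  }
  p <- length(x)
  if (is.null(ref)) ref <- p
  .check_parts(x); .check_positive_comp(x, "alr")
  log(x[-ref] / x[ref])
}

#' Inverse additive log-ratio transform
#'
#' Recovers a composition from alr coordinates by exponentiating, inserting a
#' unit entry at the reference position, and closing.  The largest coordinate
#' is subtracted before exponentiation so very large log ratios do not
#' overflow.
#'
#' @param y numeric vector of `p - 1` finite alr coordinates, or a matrix of
#'   row coordinate vectors.
#' @param ref index at which the reference part is re-inserted; defaults to
#'   the final position.
#' @return a composition of `p` parts (or matrix of row compositions).
#' @export
alr_inv <- function(y, ref = NULL) {
  if (is.matrix(y)) {
    return(t(apply(y, 1L, alr_inv, ref = ref)))
  }
  if (any(!is.finite(y))) stop("alr_inv: coordinates must be finite", call. = FALSE)
  p <- length(y) + 1L
  if (is.null(ref)) ref <- p
  full <- append(y, 0, after = ref - 1L)
  full <- full - max(full)   # overflow guard; closure removes the shift
  closure(exp(full))
}

#' Centred log-ratio transform and its inverse
#'
#' `clr()` maps a strictly positive composition to
#' \eqn{\log(\phi) - \overline{\log(\phi)}}, a vector of the same length
#' summing to zero.  `clr_inv()` closes the exponentiated vector; it is
#' invariant to adding a constant to its argument, so any real vector is a
#' valid input.
#'
#' @param x a strictly positive composition, or a matrix of row compositions.
#' @param z a finite real vector (or matrix of rows).
#' @return `clr()`: zero-sum coordinates of the same length; `clr_inv()`: a
#'   composition.
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    .check_parts(x); .check_positive_comp(x, "clr")
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  .check_parts(x); .check_positive_comp(x, "clr")
  lx <- log(x)
  lx - mean(lx)
}

#' @rdname clr
#' @export
clr_inv <- function(z) {
  if (is.matrix(z)) return(t(apply(z, 1L, clr_inv)))
  if (any(!is.finite(z))) stop("clr_inv: coordinates must be finite", call. = FALSE)
  closure(exp(z - max(z)))
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts by a small proportion `delta` and rescales the
#' non-zero parts so the composition still sums to one, preserving the ratios
#' among the non-zero parts.  Log-ratio transforms require strictly positive
#' parts, and trace fatty acids are routinely reported as exact zeros, so
#' some replacement rule is unavoidable; the multiplicative rule is the
#' standard one because it perturbs the covariance structure least.
#'
#' @param x a composition, or matrix of row compositions.
#' @param delta replacement value for each zero part; must be positive and
#'   smaller than the smallest positive part.  Default: half the smallest
#'   positive part observed in `x`.
#' @return a strictly positive composition; input without zeros is returned
#'   unchanged.
#' @export
replace_zeros <- function(x, delta = NULL) {
  if (is.matrix(x)) {
    if (is.null(delta)) delta <- 0.5 * min(x[x > 0])
    return(t(apply(x, 1L, replace_zeros, delta = delta)))
  }
  .check_parts(x)
  if (is.null(delta)) delta <- 0.5 * min(x[x > 0])
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("replace_zeros: delta must be a positive scalar", call. = FALSE)
  z <- x == 0
  if (!any(z)) return(x)
  if (delta >= min(x[!z]))
    stop("replace_zeros: delta must be smaller than the smallest positive part",
         call. = FALSE)
  out <- x
  out[z] <- delta * sum(x)
  out[!z] <- x[!z] * (1 - delta * sum(z))
  out
}

#' Geometric mean profile of a set of compositions
#'
#' Column-wise geometric mean of strictly positive row compositions, closed
#' to sum to one.  Useful for condensing many predator profiles into a single
#' representative signature before a first, cheap model fit.
#'
#' @param x matrix whose rows are strictly positive compositions.
#' @return a single composition.
#' @export
geometric_mean_profile <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L) stop("geometric_mean_profile: need at least one row", call. = FALSE)
  .check_parts(x); .check_positive_comp(x, "geometric_mean_profile")
  closure(exp(colMeans(log(x))))
}

# Orthonormal ilr contrast matrix (p x (p-1)): columns are an orthonormal
# basis of the zero-sum subspace (Helmert-type).  Used internally to give
# diet-proportion vectors a non-degenerate density; users see clr /
# proportions on output.
.ilr_basis <- function(p) {
  H <- stats::contr.helmert(p)        # p x (p-1), columns orthogonal, zero-sum
  sweep(H, 2L, sqrt(colSums(H^2)), "/")
}

.ilr <- function(x, V = .ilr_basis(length(x))) as.vector(crossprod(V, clr(x)))

.ilr_inv <- function(z, V = .ilr_basis(length(z) + 1L)) clr_inv(as.vector(V %*% z))
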