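# Internal numerical helpers.  All multivariate-normal work goes through a
# single Cholesky-based density so that an upper-triangular factor can be
# cached alongside each covariance block in the sampler.

# Upper Cholesky factor, or NULL when the matrix is not positive definite.
.chol_or_null <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  out
}

# Sum of log N(x_i; mu, Sigma) over the rows of X, given U = chol(Sigma).
# mu may be a single vector or a matrix of row means matching X.
.ldmvnorm_rows <- function(X, mu, U) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  d <- ncol(X)
  n <- nrow(X)
  Rt <- if (is.matrix(mu)) t.default(X - mu) else t.default(X) - mu
  Q <- backsolve(U, Rt, transpose = TRUE)       # d x n
  -0.5 * n * d * 1.837877066409345 - n * sum(log(diag(U))) - 0.5 * sum(Q * Q)
}

# Per-row log N(x_i; mu, Sigma) for the rows of X, given U = chol(Sigma).
.ldmvnorm_each <- function(X, mu, U) {
  d <- ncol(X)
  Rt <- if (is.matrix(mu)) t.default(X - mu) else t.default(X) - mu
  Q <- backsolve(U, Rt, transpose = TRUE)
  -0.5 * d * 1.837877066409345 - sum(log(diag(U))) - 0.5 * colSums(Q * Q)
}

# One draw from N(mu, Sigma) given U = chol(Sigma); n draws as rows.
.rmvnorm <- function(n, mu, U) {
  d <- length(mu)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% U
  sweep(Z, 2L, mu, "+")
}

# Row-wise inverse alr for a matrix of coordinate rows (fast path; falls
# back to the guarded scalar version on overflow).
.alr_inv_rows <- function(Y, ref) {
  E <- exp(Y)
  p <- ncol(Y) + 1L
  out <- matrix(NA_real_, nrow(Y), p)
  out[, -ref] <- E
  out[, ref] <- 1
  s <- rowSums(out)
  bad <- !is.finite(s)
  out <- out / s
  if (any(bad))
    for (i in which(bad)) out[i, ] <- alr_inv(Y[i, ], ref)
  out
}

# Inverse-Wishart draw: S ~ IW(nu, Psi) <=> S^{-1} ~ Wishart(nu, Psi^{-1}).
.rinvwish <- function(nu, Psi) {
  W <- stats::rWishart(1L, df = nu, Sigma = solve(Psi))[, , 1L]
  S <- solve(W)
  (S + t(S)) / 2
}

# log IW(S; nu, Psi) density (constant terms included; multivariate gamma).
.ldinvwish <- function(S, nu, Psi) {
  d <- nrow(S)
  US <- .chol_or_null(S)
  if (is.null(US)) return(-Inf)
  ldS <- 2 * sum(log(diag(US)))
  ldPsi <- 2 * sum(log(diag(chol(Psi))))
  lmgamma <- d * (d - 1) / 4 * log(pi) +
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
  0.5 * nu * ldPsi - 0.5 * nu * d * log(2) - lmgamma -
    0.5 * (nu + d + 1) * ldS - 0.5 * sum(diag(solve(S, Psi)))
}

# Moment-matched prior parametrisations (means/variances from feeding trials).
.gamma_pars <- function(mean, var) list(shape = mean^2 / var, rate = mean / var)

.lnorm_pars <- function(mean, var) {
  s2 <- log(1 + var / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Dirichlet log density (symmetric or general alpha) on a simplex vector.
.lddirichlet <- function(x, alpha) {
  if (length(alpha) == 1L) alpha <- rep(alpha, length(x))
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  g / rowSums(g)
}

# Log-Jacobian of z -> pi = clr_inv(V z) with orthonormal V: log|J| =
# sum(log pi) up to a constant.  Needed when a Dirichlet prior on pi is
# expressed over unconstrained ilr coordinates.
.ilr_logjac <- function(pi) sum(log(pi))
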