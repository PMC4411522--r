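# Convergence diagnostics: split-chain potential scale reduction factor and
# effective sample size via paired autocorrelation summation.

.split_chains <- function(x) {
  # x: iterations x chains matrix -> halves as separate chains
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1L, n), , drop = FALSE])
}

.rhat_one <- function(x) {
  x <- .split_chains(x)
  n <- nrow(x); mchains <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) return(1)   # constant parameter
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(Inf)                       # chains stuck at distinct values
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_one <- function(x) {
  n <- nrow(x); mchains <- ncol(x)
  N <- n * mchains
  if (stats::sd(as.vector(x)) == 0) return(N)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 1L, 1000L)
  # mean within-chain autocovariance per lag
  acov <- vapply(seq_len(mchains), function(ch) {
    a <- stats::acf(x[, ch], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1L]) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  if (npair == 0L) return(N)
  psums <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  keep <- 0L
  running_min <- Inf
  for (k in seq_len(npair)) {
    if (psums[k] <= 0) break
    running_min <- min(running_min, psums[k])
    psums[k] <- running_min
    keep <- k
  }
  tau <- 1 + 2 * sum(psums[seq_len(keep)])
  max(1, min(N, N / tau))
}

#' Convergence diagnostics for posterior draws
#'
#' `rhat()` computes the split-chain potential scale reduction factor per
#' parameter; values near 1 indicate that the chains agree.  `ess()` computes
#' the effective sample size per parameter by summing autocorrelations
#' (initial monotone positive sequence).  A parameter that is constant across
#' all draws is reported as `rhat = 1` and `ess = ` total number of draws.
#'
#' @param draws a [diet_draws] object with at least 2 chains and 10
#'   post-warmup iterations.
#' @return named numeric vector over parameters.
#' @export
rhat <- function(draws) {
  x <- .draws_array(draws)
  if (dim(x)[2L] < 2L) stop("rhat: need at least 2 chains", call. = FALSE)
  if (dim(x)[1L] < 10L) stop("rhat: need at least 10 iterations", call. = FALSE)
  vapply(seq_len(dim(x)[3L]), function(k) .rhat_one(x[, , k]),
         0, USE.NAMES = FALSE) |> stats::setNames(dimnames(x)[[3L]])
}

#' @rdname rhat
#' @export
ess <- function(draws) {
  x <- .draws_array(draws)
  if (dim(x)[2L] < 2L) stop("ess: need at least 2 chains", call. = FALSE)
  if (dim(x)[1L] < 10L) stop("ess: need at least 10 iterations", call. = FALSE)
  vapply(seq_len(dim(x)[3L]), function(k) .ess_one(x[, , k]),
         0, USE.NAMES = FALSE) |> stats::setNames(dimnames(x)[[3L]])
}
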