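# Flat unconstrained parameterisation of a diet_model state, and state
# initialisation.  Positive scalars are sampled on the log scale, simplex
# vectors via an orthonormal ilr basis, covariance matrices via the upper
# Cholesky factor with log diagonal; the Jacobians of these maps are part of
# the flat-vector density so that the sampler targets the intended posterior.

# theta (upper-triangle, column-major, log diagonal) -> chol factor
.theta_to_chol <- function(th, d) {
  U <- matrix(0, d, d)
  U[upper.tri(U, diag = TRUE)] <- th
  diag(U) <- exp(diag(U))
  U
}

.chol_to_theta <- function(S) {
  U <- chol(S)
  diag(U) <- log(diag(U))
  U[upper.tri(U, diag = TRUE)]
}

# log |d Sigma / d theta| for the above map
.chol_logjac <- function(th, d) {
  ld <- th[cumsum(seq_len(d))]      # diagonal positions in column-major order
  d * log(2) + sum((d - seq_len(d) + 2L) * ld)
}

.cov_from_theta <- function(th, d) {
  U <- .theta_to_chol(th, d)
  crossprod(U)
}

# Unflatten a theta vector into a natural-space state; returns the state and
# the accumulated log Jacobian.
.unflatten <- function(m, theta) {
  if (length(theta) != m$dim) stop("theta has wrong length", call. = FALSE)
  if (any(!is.finite(theta))) return(list(state = NULL, ljac = -Inf))
  idx <- m$index; fx <- m$fixed; n <- m$n
  st <- list(); ljac <- 0
  gv <- function(nm) theta[idx[[nm]]]

  if (!is.null(fx$pi)) st$pi <- fx$pi
  else if (m$spec$grouping == "population") {
    st$pi <- .ilr_inv(gv("z"), m$V)
    ljac <- ljac + .ilr_logjac(st$pi)
  } else {
    st$pi <- t(vapply(seq_len(m$J), function(j) .ilr_inv(gv(paste0("z.", j)), m$V),
                      numeric(n)))
    if (m$spec$grouping == "individual") st$Pi <- gv("Pi")
    else st$B <- matrix(gv("B"), m$q, n - 1L)
    st$Sigma_Pi <- .cov_from_theta(gv("Sigma_Pi"), n - 1L)
    ljac <- ljac + .chol_logjac(gv("Sigma_Pi"), n - 1L)
  }
  if (m$use_fa) {
    dfa <- m$dfa; dd <- m$data
    st$mu <- if (!is.null(fx$mu)) fx$mu else
      lapply(seq_len(n), function(s) gv(paste0("mu.", s)))
    if (!is.null(fx$Sigma)) st$Sigma <- fx$Sigma
    else {
      st$Sigma <- lapply(seq_len(n), function(s) {
        th <- gv(paste0("Sigma.", s)); .cov_from_theta(th, dfa) })
      for (s in seq_len(n)) ljac <- ljac + .chol_logjac(gv(paste0("Sigma.", s)), dfa)
    }
    if (!is.null(fx$Sigma_tau)) st$Sigma_tau <- fx$Sigma_tau
    else {
      st$Sigma_tau <- .cov_from_theta(gv("Sigma_tau"), dfa)
      ljac <- ljac + .chol_logjac(gv("Sigma_tau"), dfa)
    }
    st$kappa <- if (!is.null(fx$kappa)) fx$kappa else dd$kappa_mean
    st$Phi <- if (!is.null(fx$Phi)) fx$Phi else dd$fat_mean
    if (is.null(fx$kappa)) for (s in seq_len(n)) if (any(m$kap_mask[s, ])) {
      lk <- gv(paste0("kappa.", s))
      st$kappa[s, m$kap_mask[s, ]] <- exp(lk)
      ljac <- ljac + sum(lk)
    }
    if (is.null(fx$Phi) && any(m$phi_mask)) {
      lph <- gv("Phi")
      st$Phi[m$phi_mask] <- exp(lph)
      ljac <- ljac + sum(lph)
    }
    if (m$spec$latent_prey) {
      Jl <- if (m$spec$grouping == "population") m$Jfa else m$J
      st$phi_lat <- lapply(seq_len(n), function(s)
        t(vapply(seq_len(Jl), function(j) gv(paste0("phi_lat.", j, ".", s)),
                 numeric(dfa))))
    }
  }
  if (m$use_si) {
    K <- m$K; dd <- m$data
    st$mu_si <- if (!is.null(fx$mu_si)) fx$mu_si else
      t(vapply(seq_len(n), function(s) gv(paste0("mu_si.", s)), numeric(K)))
    if (!is.null(fx$Sigma_si)) st$Sigma_si <- fx$Sigma_si
    else {
      st$Sigma_si <- lapply(seq_len(n), function(s)
        .cov_from_theta(gv(paste0("Sigma_si.", s)), K))
      for (s in seq_len(n)) ljac <- ljac + .chol_logjac(gv(paste0("Sigma_si.", s)), K)
    }
    if (!is.null(fx$Sigma_tau_si)) st$Sigma_tau_si <- fx$Sigma_tau_si
    else {
      st$Sigma_tau_si <- .cov_from_theta(gv("Sigma_tau_si"), K)
      ljac <- ljac + .chol_logjac(gv("Sigma_tau_si"), K)
    }
    st$gamma <- if (!is.null(fx$gamma)) fx$gamma else dd$frac_mean
    if (is.null(fx$gamma) && any(m$gam_mask))
      st$gamma[m$gam_mask] <- gv("gamma")
    if (m$spec$latent_prey) {
      Jl <- if (m$spec$grouping == "population") m$Jsi else m$J
      st$si_lat <- lapply(seq_len(n), function(s)
        t(vapply(seq_len(Jl), function(j) gv(paste0("si_lat.", j, ".", s)),
                 numeric(K))))
    }
  }
  list(state = st, ljac = ljac)
}

.flat_logpost <- function(m, theta) {
  u <- .unflatten(m, theta)
  if (!is.finite(u$ljac)) return(-Inf)
  st <- .refresh_caches(m, u$state)
  lp <- .state_logpost(m, st)
  if (!is.finite(lp)) return(-Inf)
  lp + u$ljac
}

# Regularised sample covariance: guaranteed positive definite.
.reg_cov <- function(X) {
  S <- stats::cov(X)
  d <- ncol(X)
  ridge <- 0.1 * mean(diag(S)) + 1e-6
  S <- S + diag(ridge, d)
  if (is.null(.chol_or_null(S))) S <- diag(diag(S), d)
  S
}

# Initial state; `overdisp` scales the diet-vector jitter so chains start
# from dispersed points.
.init_state <- function(m, overdisp = 1) {
  fx <- m$fixed; n <- m$n; st <- list()
  jit <- 0.25 * overdisp
  if (!is.null(fx$pi)) st$pi <- fx$pi
  else if (m$spec$grouping == "population") {
    st$pi <- .ilr_inv(stats::rnorm(n - 1L, 0, jit), m$V)
  } else {
    Z <- matrix(stats::rnorm(m$J * (n - 1L), 0, jit), m$J)
    st$pi <- t(apply(Z, 1L, .ilr_inv, V = m$V))
    if (m$spec$grouping == "individual") st$Pi <- colMeans(Z)
    else st$B <- matrix(0, m$q, n - 1L)
    st$Sigma_Pi <- diag(0.5, n - 1L)
  }
  if (m$use_fa) {
    dd <- m$data
    st$mu <- fx$mu %||% lapply(seq_len(n), function(s)
      m$ybar[[s]] + stats::rnorm(m$dfa, 0, 0.02))
    st$Sigma <- fx$Sigma %||% lapply(m$Y, .reg_cov)
    st$Sigma_tau <- fx$Sigma_tau %||% diag(0.05, m$dfa)
    st$kappa <- fx$kappa %||% dd$kappa_mean
    st$Phi <- fx$Phi %||% dd$fat_mean
    if (m$spec$latent_prey) {
      Jl <- if (m$spec$grouping == "population") m$Jfa else m$J
      st$phi_lat <- lapply(seq_len(n), function(s)
        matrix(st$mu[[s]], Jl, m$dfa, byrow = TRUE) +
          matrix(stats::rnorm(Jl * m$dfa, 0, 0.02), Jl))
    }
  }
  if (m$use_si) {
    dd <- m$data
    st$mu_si <- fx$mu_si %||%
      (t(vapply(m$ysibar, identity, numeric(m$K))) +
         matrix(stats::rnorm(n * m$K, 0, 0.02), n))
    st$Sigma_si <- fx$Sigma_si %||% lapply(m$Ysi, .reg_cov)
    st$Sigma_tau_si <- fx$Sigma_tau_si %||% diag(0.5, m$K)
    st$gamma <- fx$gamma %||% dd$frac_mean
    if (m$spec$latent_prey) {
      Jl <- if (m$spec$grouping == "population") m$Jsi else m$J
      st$si_lat <- lapply(seq_len(n), function(s)
        matrix(st$mu_si[s, ], Jl, m$K, byrow = TRUE) +
          matrix(stats::rnorm(Jl * m$K, 0, 0.02), Jl))
    }
  }
  .refresh_caches(m, st)
}

# Flatten a state for the LogPosterior contract (used for tests and for a
# finite-density check at initialisation).
.flatten_state <- function(m, st) {
  idx <- m$index; theta <- numeric(m$dim)
  sv <- function(nm, v) theta[idx[[nm]]] <<- v
  if (is.null(m$fixed$pi)) {
    if (m$spec$grouping == "population") sv("z", .ilr(st$pi, m$V))
    else {
      for (j in seq_len(m$J)) sv(paste0("z.", j), .ilr(st$pi[j, ], m$V))
      if (m$spec$grouping == "individual") sv("Pi", st$Pi)
      else sv("B", as.vector(st$B))
      sv("Sigma_Pi", .chol_to_theta(st$Sigma_Pi))
    }
  }
  if (m$use_fa) {
    for (s in seq_len(m$n)) {
      if (is.null(m$fixed$mu)) sv(paste0("mu.", s), st$mu[[s]])
      if (is.null(m$fixed$Sigma)) sv(paste0("Sigma.", s), .chol_to_theta(st$Sigma[[s]]))
      if (is.null(m$fixed$kappa) && any(m$kap_mask[s, ]))
        sv(paste0("kappa.", s), log(st$kappa[s, m$kap_mask[s, ]]))
    }
    if (is.null(m$fixed$Sigma_tau)) sv("Sigma_tau", .chol_to_theta(st$Sigma_tau))
    if (is.null(m$fixed$Phi) && any(m$phi_mask)) sv("Phi", log(st$Phi[m$phi_mask]))
    if (m$spec$latent_prey)
      for (s in seq_len(m$n)) for (j in seq_len(nrow(st$phi_lat[[s]])))
        sv(paste0("phi_lat.", j, ".", s), st$phi_lat[[s]][j, ])
  }
  if (m$use_si) {
    for (s in seq_len(m$n)) {
      if (is.null(m$fixed$mu_si)) sv(paste0("mu_si.", s), st$mu_si[s, ])
      if (is.null(m$fixed$Sigma_si))
        sv(paste0("Sigma_si.", s), .chol_to_theta(st$Sigma_si[[s]]))
    }
    if (is.null(m$fixed$Sigma_tau_si)) sv("Sigma_tau_si", .chol_to_theta(st$Sigma_tau_si))
    if (is.null(m$fixed$gamma) && any(m$gam_mask)) sv("gamma", st$gamma[m$gam_mask])
    if (m$spec$latent_prey)
      for (s in seq_len(m$n)) for (j in seq_len(nrow(st$si_lat[[s]])))
        sv(paste0("si_lat.", j, ".", s), st$si_lat[[s]][j, ])
  }
  theta
}
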