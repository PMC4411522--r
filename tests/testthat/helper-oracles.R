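# Independent brute-force oracles for the mixing-model densities.  These are
# deliberately written with explicit loops, solve()/det() multivariate-normal
# densities and no shared code with the package internals, so that agreement
# is a genuine cross-check.

naive_ldmvnorm <- function(x, mu, S) {
  d <- length(x)
  r <- as.numeric(x - mu)
  as.numeric(-0.5 * d * log(2 * pi) - 0.5 * log(det(S)) -
               0.5 * t(r) %*% solve(S) %*% r)
}

naive_alr <- function(x, ref = length(x)) log(x[-ref] / x[ref])

# Direct-summation FA log likelihood. `d` is a diet_data, `st` a state list,
# latent flags which consumed-prey mode is in force.
oracle_fa_loglik <- function(d, st, latent = FALSE) {
  n <- d$n_species
  p <- length(d$fa_names)
  total <- 0
  for (s in seq_len(n)) {
    rows <- which(d$prey_fa_species == d$species[s])
    for (i in rows)
      total <- total + naive_ldmvnorm(naive_alr(d$prey_fa[i, ], d$alr_ref),
                                      st$mu[[s]], st$Sigma[[s]])
  }
  J <- nrow(d$pred_fa)
  if (latent)
    for (s in seq_len(n))
      for (j in seq_len(J))
        total <- total + naive_ldmvnorm(st$phi_lat[[s]][j, ], st$mu[[s]],
                                        st$Sigma[[s]])
  for (j in seq_len(J)) {
    pij <- if (is.matrix(st$pi)) st$pi[j, ] else st$pi
    pre <- numeric(p)
    for (s in seq_len(n)) {
      phi_s <- if (latent) {
        a <- st$phi_lat[[s]][j, ]
        full <- append(exp(a), 1, after = d$alr_ref - 1L)
        full / sum(full)
      } else {
        full <- append(exp(st$mu[[s]]), 1, after = d$alr_ref - 1L)
        full / sum(full)
      }
      for (f in seq_len(p))
        pre[f] <- pre[f] + pij[s] * st$Phi[s] * st$kappa[s, f] * phi_s[f]
    }
    tau <- pre / sum(pre)
    total <- total + naive_ldmvnorm(naive_alr(d$pred_fa[j, ], d$alr_ref),
                                    naive_alr(tau, d$alr_ref), st$Sigma_tau)
  }
  total
}

oracle_si_loglik <- function(d, st, latent = FALSE) {
  n <- d$n_species
  K <- length(d$iso_names)
  total <- 0
  for (s in seq_len(n)) {
    rows <- which(d$prey_si_species == d$species[s])
    for (i in rows)
      total <- total + naive_ldmvnorm(d$prey_si[i, ], st$mu_si[s, ],
                                      st$Sigma_si[[s]])
  }
  J <- nrow(d$pred_si)
  if (latent)
    for (s in seq_len(n))
      for (j in seq_len(J))
        total <- total + naive_ldmvnorm(st$si_lat[[s]][j, ], st$mu_si[s, ],
                                        st$Sigma_si[[s]])
  for (j in seq_len(J)) {
    pij <- if (is.matrix(st$pi)) st$pi[j, ] else st$pi
    mu <- numeric(K)
    for (s in seq_len(n)) {
      ys <- if (latent) st$si_lat[[s]][j, ] else st$mu_si[s, ]
      for (k in seq_len(K))
        mu[k] <- mu[k] + pij[s] * (ys[k] + st$gamma[s, k])
    }
    total <- total + naive_ldmvnorm(d$pred_si[j, ], mu, st$Sigma_tau_si)
  }
  total
}

# Random positive-definite matrix
rand_pd <- function(d, scale = 0.3) {
  A <- matrix(rnorm(d * d, 0, scale), d)
  crossprod(A) + diag(0.05, d)
}

rand_simplex <- function(n) {
  g <- rgamma(n, 1.5)
  g / sum(g)
}

# Small random diet dataset + compatible random state for oracle checks.
random_instance <- function(seed, markers = "both", latent = FALSE,
                            individual = FALSE) {
  set.seed(seed)
  n <- sample(2:3, 1)
  p <- sample(3:4, 1)
  K <- sample(2:3, 1)
  J <- sample(1:3, 1)
  species <- paste0("sp", seq_len(n))
  fa <- paste0("FA", seq_len(p))
  iso <- paste0("iso", seq_len(K))
  prey_fa <- pred_fa <- prey_si <- pred_si <- NULL
  if (markers %in% c("fa", "both")) {
    prey_fa <- data.frame(species = rep(species, each = 3),
                          matrix(rdiri(3 * n, p), 3 * n,
                                 dimnames = list(NULL, fa)),
                          check.names = FALSE)
    pred_fa <- data.frame(matrix(rdiri(J, p), J, dimnames = list(NULL, fa)),
                          check.names = FALSE)
  }
  if (markers %in% c("si", "both")) {
    prey_si <- data.frame(species = rep(species, each = 3),
                          matrix(rnorm(3 * n * K, -10, 4), 3 * n,
                                 dimnames = list(NULL, iso)),
                          check.names = FALSE)
    pred_si <- data.frame(matrix(rnorm(J * K, -10, 4), J,
                                 dimnames = list(NULL, iso)),
                          check.names = FALSE)
  }
  fm <- fs <- NULL
  if (!is.null(prey_si)) {
    fm <- data.frame(species = species,
                     matrix(runif(n * K, 0, 3), n, dimnames = list(NULL, iso)),
                     check.names = FALSE)
    fs <- data.frame(species = species,
                     matrix(runif(n * K, .1, 1), n, dimnames = list(NULL, iso)),
                     check.names = FALSE)
  }
  d <- diet_data(prey_fa = prey_fa, predator_fa = pred_fa,
                 prey_si = prey_si, predator_si = pred_si,
                 frac_mean = fm, frac_sd = fs)
  st <- list(pi = if (individual) t(replicate(J, rand_simplex(n))) else
               rand_simplex(n))
  if (!is.null(prey_fa)) {
    st$mu <- lapply(seq_len(n), function(s) rnorm(p - 1, 0, 1))
    st$Sigma <- lapply(seq_len(n), function(s) rand_pd(p - 1))
    st$Sigma_tau <- rand_pd(p - 1, 0.15)
    st$kappa <- matrix(runif(n * p, 0.5, 2), n, p)
    st$Phi <- runif(n, 0.5, 2)
    if (latent)
      st$phi_lat <- lapply(seq_len(n), function(s)
        matrix(rnorm(J * (p - 1), 0, 1), J))
  }
  if (!is.null(prey_si)) {
    st$mu_si <- matrix(rnorm(n * K, -10, 3), n)
    st$Sigma_si <- lapply(seq_len(n), function(s) rand_pd(K, 0.5))
    st$Sigma_tau_si <- rand_pd(K, 0.4)
    st$gamma <- matrix(runif(n * K, 0, 3), n)
    if (latent)
      st$si_lat <- lapply(seq_len(n), function(s)
        matrix(rnorm(J * K, -10, 3), J))
  }
  list(data = d, state = st, n = n, p = p, K = K, J = J)
}

rdiri <- function(n, k) {
  g <- matrix(rgamma(n * k, 2), n, k)
  g / rowSums(g)
}
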