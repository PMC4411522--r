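# Posterior sampling: adaptive random-walk Metropolis within Gibbs.
# Parameter blocks with conditionally conjugate full conditionals (all
# covariance matrices; prey means and the diet hyper-parameters where the
# predator likelihood does not involve them) are updated by exact Gibbs
# draws; every other block by a Gaussian random walk in unconstrained space
# whose scale is adapted towards a target acceptance rate during warmup and
# frozen afterwards.

.ACC_TARGET <- function(d) if (d == 1L) 0.44 else if (d <= 4L) 0.35 else 0.234

# -- conjugate updates ------------------------------------------------------

.gibbs_Sigma_s <- function(m, st, s) {
  pr <- m$spec$prior
  Rt <- t.default(m$Y[[s]]) - st$mu[[s]]
  SSE <- tcrossprod(Rt); N <- m$Nfa[s]
  if (m$spec$latent_prey) {
    R2t <- t.default(st$phi_lat[[s]]) - st$mu[[s]]
    SSE <- SSE + tcrossprod(R2t); N <- N + ncol(R2t)
  }
  S <- .rinvwish(m$dfa + 2 + N, diag(pr$sigma_prey_scale, m$dfa) + SSE)
  st$Sigma[[s]] <- S
  st$Sigma_chol[[s]] <- chol(S)
  st
}

.gibbs_mu_s <- function(m, st, s) {     # latent mode only
  pr <- m$spec$prior
  Sinv <- chol2inv(st$Sigma_chol[[s]])
  N <- m$Nfa[s] + nrow(st$phi_lat[[s]])
  b <- Sinv %*% (m$Nfa[s] * m$ybar[[s]] + colSums(st$phi_lat[[s]]))
  prec <- N * Sinv + diag(1 / pr$mu_sd^2, m$dfa)
  Up <- chol(prec)
  mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
  st$mu[[s]] <- as.vector(mu + backsolve(Up, stats::rnorm(m$dfa)))
  st
}

.gibbs_Sigma_tau <- function(m, st) {
  pr <- m$spec$prior
  tau <- .tau_alr(m, st)
  R <- if (is.matrix(tau)) m$T - tau else sweep(m$T, 2L, tau)
  S <- .rinvwish(m$dfa + 2 + nrow(R),
                 diag(pr$sigma_pred_scale, m$dfa) + crossprod(R))
  st$Sigma_tau <- S
  st$Sigma_tau_chol <- chol(S)
  st
}

# Marginal-mode residual covariance updates: the latent mixture deviation
# eta_j is re-drawn from its exact conditional (prior N(0, C), observation
# residual eta + noise), the covariance is updated conjugately given eta,
# and eta is discarded (partially collapsed Gibbs).
.gibbs_Sigma_tau_marg <- function(m, st) {
  pr <- m$spec$prior
  mp <- .marginal_parts(m, st)
  tau <- .tau_alr(m, st)
  R <- if (is.matrix(tau)) sweep(m$T - tau, 2L, mp$corr) else
    sweep(m$T, 2L, tau + mp$corr)
  C <- mp$C + diag(1e-10, m$dfa)
  Cinv <- chol2inv(chol(C))
  Stinv <- chol2inv(st$Sigma_tau_chol)
  Up <- chol(Cinv + Stinv)
  pcov <- chol2inv(Up)
  Meta <- R %*% Stinv %*% pcov
  Z <- matrix(stats::rnorm(nrow(R) * m$dfa), nrow(R))
  eta <- Meta + t(backsolve(Up, t(Z)))
  S <- .rinvwish(m$dfa + 2 + nrow(R),
                 diag(pr$sigma_pred_scale, m$dfa) + crossprod(R - eta))
  st$Sigma_tau <- S
  st$Sigma_tau_chol <- chol(S)
  st
}

.gibbs_Sigma_tau_si_marg <- function(m, st) {
  pr <- m$spec$prior
  mu <- .si_mean(m, st)
  R <- if (is.matrix(mu)) m$Tsi - mu else sweep(m$Tsi, 2L, mu)
  C <- .si_mix_cov(m, st) + diag(1e-10, m$K)
  Cinv <- chol2inv(chol(C))
  Stinv <- st$Sigma_tau_si_inv
  Up <- chol(Cinv + Stinv)
  pcov <- chol2inv(Up)
  Meta <- R %*% Stinv %*% pcov
  Z <- matrix(stats::rnorm(nrow(R) * m$K), nrow(R))
  eta <- Meta + t(backsolve(Up, t(Z)))
  S <- .rinvwish(m$K + 2 + nrow(R),
                 diag(pr$sigma_si_pred_scale, m$K) + crossprod(R - eta))
  st$Sigma_tau_si <- S
  st$Sigma_tau_si_chol <- chol(S)
  st$Sigma_tau_si_inv <- chol2inv(st$Sigma_tau_si_chol)
  st
}

.gibbs_Sigma_si_s <- function(m, st, s) {
  pr <- m$spec$prior
  Rt <- t.default(m$Ysi[[s]]) - st$mu_si[s, ]
  SSE <- tcrossprod(Rt); N <- m$Nsi[s]
  if (m$spec$latent_prey) {
    R2t <- t.default(st$si_lat[[s]]) - st$mu_si[s, ]
    SSE <- SSE + tcrossprod(R2t); N <- N + ncol(R2t)
  }
  S <- .rinvwish(m$K + 2 + N, diag(pr$sigma_si_prey_scale, m$K) + SSE)
  st$Sigma_si[[s]] <- S
  st$Sigma_si_chol[[s]] <- chol(S)
  st$Sigma_si_inv[[s]] <- chol2inv(st$Sigma_si_chol[[s]])
  st
}

.gibbs_mu_si_s <- function(m, st, s) {  # latent mode only
  pr <- m$spec$prior
  Sinv <- chol2inv(st$Sigma_si_chol[[s]])
  N <- m$Nsi[s] + nrow(st$si_lat[[s]])
  b <- Sinv %*% (m$Nsi[s] * m$ysibar[[s]] + colSums(st$si_lat[[s]]))
  prec <- N * Sinv + diag(1 / pr$mu_si_sd^2, m$K)
  Up <- chol(prec)
  mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
  st$mu_si[s, ] <- as.vector(mu + backsolve(Up, stats::rnorm(m$K)))
  st
}

.gibbs_Sigma_tau_si <- function(m, st) {
  pr <- m$spec$prior
  mu <- .si_mean(m, st)
  R <- if (is.matrix(mu)) m$Tsi - mu else sweep(m$Tsi, 2L, mu)
  S <- .rinvwish(m$K + 2 + nrow(R),
                 diag(pr$sigma_si_pred_scale, m$K) + crossprod(R))
  st$Sigma_tau_si <- S
  st$Sigma_tau_si_chol <- chol(S)
  st$Sigma_tau_si_inv <- chol2inv(st$Sigma_tau_si_chol)
  st
}

# Conjugate update of the latent consumed-isotope values for one species.
# The predator SI mean is linear in the consumed values and the per-predator
# blocks are conditionally independent, so all predators are drawn at once.
.gibbs_si_lat_s <- function(m, st, s) {
  J <- nrow(st$si_lat[[s]])
  Pi <- .pi_matrix(m, st, J)
  Ssinv <- st$Sigma_si_inv[[s]]
  Tinv <- st$Sigma_tau_si_inv
  o <- matrix(st$gamma[s, ], J, m$K, byrow = TRUE) * Pi[, s]
  for (s2 in seq_len(m$n)) if (s2 != s)
    o <- o + Pi[, s2] * sweep(st$si_lat[[s2]], 2L, st$gamma[s2, ], "+")
  R <- m$Tsi - o
  if (!is.matrix(st$pi)) {           # common weight: one factorisation
    ps <- st$pi[s]
    prec <- Ssinv + ps^2 * Tinv
    Up <- chol(prec)
    B <- matrix(as.vector(Ssinv %*% st$mu_si[s, ]), J, m$K, byrow = TRUE) +
      ps * R %*% Tinv
    M <- B %*% chol2inv(Up)
    Z <- matrix(stats::rnorm(J * m$K), J)
    st$si_lat[[s]] <- M + t(backsolve(Up, t(Z)))
  } else {
    for (j in seq_len(J)) {
      ps <- Pi[j, s]
      prec <- Ssinv + ps^2 * Tinv
      Up <- chol(prec)
      b <- Ssinv %*% st$mu_si[s, ] + ps * (Tinv %*% R[j, ])
      mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
      st$si_lat[[s]][j, ] <- as.vector(mu + backsolve(Up, stats::rnorm(m$K)))
    }
  }
  st
}

# Vectorised Metropolis update of the latent consumed prey profiles of one
# species: per-predator blocks are conditionally independent given the rest,
# so proposals and accept/reject decisions are made row-wise in one pass.
.step_phi_lat <- function(m, st, s, scale) {
  cur <- st$phi_lat[[s]]
  J <- nrow(cur)
  prop <- cur + scale * matrix(stats::rnorm(J * m$dfa), J)
  cmp1 <- .alr_inv_rows(prop, m$ref)
  A1 <- sweep(cmp1, 2L, st$kappa[s, ], "*")
  w <- (if (is.matrix(st$pi)) st$pi[, s] else st$pi[s]) * st$Phi[s]
  pre1 <- st$pre + w * (A1 - st$Acons[[s]])
  lg0 <- log(st$pre); lg1 <- log(pre1)
  t0 <- lg0[, -m$ref, drop = FALSE] - lg0[, m$ref]
  t1 <- lg1[, -m$ref, drop = FALSE] - lg1[, m$ref]
  U <- st$Sigma_chol[[s]]; Ut <- st$Sigma_tau_chol
  lp0 <- .ldmvnorm_each(cur, st$mu[[s]], U) + .ldmvnorm_each(m$T, t0, Ut)
  lp1 <- .ldmvnorm_each(prop, st$mu[[s]], U) + .ldmvnorm_each(m$T, t1, Ut)
  ok <- log(stats::runif(J)) < (lp1 - lp0)
  ok[!is.finite(lp1)] <- FALSE
  if (any(ok)) {
    st$phi_lat[[s]][ok, ] <- prop[ok, ]
    st$philat_comp[[s]][ok, ] <- cmp1[ok, ]
    st$Acons[[s]][ok, ] <- A1[ok, ]
    st$pre[ok, ] <- pre1[ok, ]
  }
  list(state = st, acc = mean(ok))
}

# Independence Metropolis-Hastings for prey means in mean-prey mode: the
# proposal is the exact conditional given the prey samples and the prior
# (both Gaussian), so those terms cancel and the acceptance ratio reduces to
# the predator-likelihood ratio.  Mixing is then governed by how much the
# predators inform the prey mean, which is weak next to the prey samples.
.mh_mu_s <- function(m, st, s) {
  pr <- m$spec$prior
  Sinv <- chol2inv(st$Sigma_chol[[s]])
  prec <- m$Nfa[s] * Sinv + diag(1 / pr$mu_sd^2, m$dfa)
  Up <- chol(prec)
  mq <- backsolve(Up, backsolve(Up, Sinv %*% (m$Nfa[s] * m$ybar[[s]]),
                                transpose = TRUE))
  prop <- as.vector(mq + backsolve(Up, stats::rnorm(m$dfa)))
  st1 <- st
  st1$mu[[s]] <- prop
  st1$A[s, ] <- st1$kappa[s, ] * alr_inv(prop, m$ref)
  la <- .ll_pred_fa(m, st1) - .ll_pred_fa(m, st)
  if (is.finite(la) && (la >= 0 || log(stats::runif(1)) < la)) st1 else st
}

.mh_mu_si_s <- function(m, st, s) {
  pr <- m$spec$prior
  Sinv <- chol2inv(st$Sigma_si_chol[[s]])
  prec <- m$Nsi[s] * Sinv + diag(1 / pr$mu_si_sd^2, m$K)
  Up <- chol(prec)
  mq <- backsolve(Up, backsolve(Up, Sinv %*% (m$Nsi[s] * m$ysibar[[s]]),
                                transpose = TRUE))
  prop <- as.vector(mq + backsolve(Up, stats::rnorm(m$K)))
  st1 <- st
  st1$mu_si[s, ] <- prop
  la <- .ll_pred_si(m, st1) - .ll_pred_si(m, st)
  if (is.finite(la) && (la >= 0 || log(stats::runif(1)) < la)) st1 else st
}

# Conjugate update for the fractionation coefficients: the predator SI mean
# is linear in gamma, so given everything else the full conditional is
# multivariate normal.
.gibbs_gamma <- function(m, st) {
  msk <- m$gam_mask
  J <- if (m$spec$grouping == "population") m$Jsi else m$J
  Pi <- .pi_matrix(m, st, J)
  offset <- if (!m$spec$latent_prey) Pi %*% st$mu_si else {
    o <- matrix(0, J, m$K)
    for (s in seq_len(m$n)) o <- o + Pi[, s] * st$si_lat[[s]]
    o
  }
  Gfix <- st$gamma
  Gfix[msk] <- 0
  offset <- offset + Pi %*% Gfix
  Einv <- if (m$spec$consumed == "marginal")
    chol2inv(chol(st$Sigma_tau_si + .si_mix_cov(m, st))) else
      chol2inv(st$Sigma_tau_si_chol)
  R <- m$Tsi - offset
  prec_full <- kronecker(Einv, crossprod(Pi))
  b_full <- as.vector(crossprod(Pi, R %*% Einv))
  ix <- which(as.vector(msk))
  prec <- prec_full[ix, ix, drop = FALSE] +
    diag(1 / m$data$frac_sd[msk]^2, length(ix))
  b <- b_full[ix] + m$data$frac_mean[msk] / m$data$frac_sd[msk]^2
  Up <- chol(prec)
  mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
  st$gamma[msk] <- as.vector(mu + backsolve(Up, stats::rnorm(length(ix))))
  st
}

.gibbs_Pi <- function(m, st) {
  pr <- m$spec$prior
  Sinv <- chol2inv(st$Sigma_Pi_chol)
  prec <- m$J * Sinv + diag(1 / pr$mu_sd^2, m$n - 1L)
  Up <- chol(prec)
  b <- Sinv %*% colSums(st$Z)
  mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
  st$Pi <- as.vector(mu + backsolve(Up, stats::rnorm(m$n - 1L)))
  st
}

.gibbs_B <- function(m, st) {
  pr <- m$spec$prior
  Einv <- chol2inv(st$Sigma_Pi_chol)
  prec <- kronecker(Einv, crossprod(m$X)) +
    diag(1 / pr$mu_sd^2, m$q * (m$n - 1L))
  Up <- chol(prec)
  b <- as.vector(crossprod(m$X, st$Z %*% Einv))
  mu <- backsolve(Up, backsolve(Up, b, transpose = TRUE))
  st$B <- matrix(as.vector(mu + backsolve(Up, stats::rnorm(length(b)))),
                 m$q, m$n - 1L)
  st
}

.gibbs_Sigma_Pi <- function(m, st) {
  pr <- m$spec$prior
  mean_z <- if (m$spec$grouping == "individual")
    matrix(st$Pi, m$J, m$n - 1L, byrow = TRUE) else m$X %*% st$B
  R <- st$Z - mean_z
  S <- .rinvwish((m$n - 1L) + 2 + m$J,
                 diag(pr$sigma_diet_scale, m$n - 1L) + crossprod(R))
  st$Sigma_Pi <- S
  st$Sigma_Pi_chol <- chol(S)
  st
}

# -- block table ------------------------------------------------------------

.diet_blocks <- function(m) {
  spec <- m$spec; fx <- m$fixed; n <- m$n
  blocks <- list()
  push <- function(b) blocks[[length(blocks) + 1L]] <<- b
  rwm <- function(name, d, get, set, cond, iso = FALSE)
    list(name = name, kind = "rwm", d = d, get = get, set = set, cond = cond,
         iso = iso)
  gibbs <- function(name, draw) list(name = name, kind = "gibbs", draw = draw)
  vec <- function(name, d, step) list(name = name, kind = "vec", d = d,
                                      step = step)
  pred_terms <- function(st, j = NULL) {
    out <- 0
    if (m$use_fa) out <- out + .ll_pred_fa(m, st, j)
    if (m$use_si) out <- out + .ll_pred_si(m, st, j)
    out
  }

  ## diet proportions
  if (is.null(fx$pi)) {
    latent_fa <- m$use_fa && spec$latent_prey
    if (spec$grouping == "population") {
      push(rwm("z", n - 1L,
        get = function(st) st$z,
        set = function(st, v) {
          st$z <- v; st$pi <- .ilr_inv(v, m$V)
          if (latent_fa) st <- .recompute_pre(m, st)
          st },
        cond = function(st) .lddirichlet(st$pi, spec$prior$alpha) +
          .ilr_logjac(st$pi) + pred_terms(st)))
    } else {
      for (j in seq_len(m$J)) local({
        jj <- j
        push(rwm(paste0("z.", jj), n - 1L,
          get = function(st) st$Z[jj, ],
          set = function(st, v) {
            st$Z[jj, ] <- v; st$pi[jj, ] <- .ilr_inv(v, m$V)
            if (latent_fa) {
              row <- numeric(m$p)
              for (s in seq_len(n))
                row <- row + st$pi[jj, s] * st$Phi[s] * st$Acons[[s]][jj, ]
              st$pre[jj, ] <- row
            }
            st },
          cond = function(st) {
            mz <- if (spec$grouping == "individual") st$Pi else
              as.vector(m$X[jj, ] %*% st$B)
            .ldmvnorm_rows(st$Z[jj, , drop = FALSE], mz, st$Sigma_Pi_chol) +
              pred_terms(st, jj)
          }))
      })
      if (spec$grouping == "individual") push(gibbs("Pi", .gibbs_Pi))
      else push(gibbs("B", .gibbs_B))
      push(gibbs("Sigma_Pi", .gibbs_Sigma_Pi))
    }
  }

  ## FA blocks
  if (m$use_fa) {
    for (s in seq_len(n)) local({
      ss <- s
      if (is.null(fx$mu)) {
        if (spec$latent_prey)
          push(gibbs(paste0("mu.", ss), function(m, st) .gibbs_mu_s(m, st, ss)))
        else
          push(gibbs(paste0("mu.", ss), function(m, st) .mh_mu_s(m, st, ss)))
      }
      if (is.null(fx$Sigma)) {
        bS <- gibbs(paste0("Sigma.", ss), function(m, st) .gibbs_Sigma_s(m, st, ss))
        # in marginal mode the prey covariance is informed by prey samples
        # only; its conditional is static within an iteration, so it is
        # refreshed every other sweep
        if (spec$consumed == "marginal") bS$every <- 2L
        push(bS)
      }
      if (is.null(fx$kappa) && any(m$kap_mask[ss, ])) {
        msk <- m$kap_mask[ss, ]
        push(rwm(paste0("kappa.", ss), sum(msk),
          get = function(st) log(st$kappa[ss, msk]),
          set = function(st, v) {
            st$kappa[ss, msk] <- exp(v)
            if (spec$latent_prey) {
              st$Acons[[ss]] <- sweep(st$philat_comp[[ss]], 2L, st$kappa[ss, ], "*")
              st <- .recompute_pre(m, st)
            } else
              st$A[ss, ] <- st$kappa[ss, ] * alr_inv(st$mu[[ss]], m$ref)
            st },
          cond = function(st) {
            k <- st$kappa[ss, msk]
            sum(stats::dgamma(k, m$kap_shape[ss, msk], m$kap_rate[ss, msk],
                              log = TRUE)) + sum(log(k)) + .ll_pred_fa(m, st)
          }))
      }
      if (spec$latent_prey)
        push(vec(paste0("phi_lat.", ss), m$dfa,
                 step = function(st, scale) .step_phi_lat(m, st, ss, scale)))
    })
    if (is.null(fx$Sigma_tau))
      push(gibbs("Sigma_tau", if (spec$consumed == "marginal")
        .gibbs_Sigma_tau_marg else .gibbs_Sigma_tau))
    if (is.null(fx$Phi) && any(m$phi_mask)) {
      msk <- m$phi_mask
      push(rwm("Phi", sum(msk),
        get = function(st) log(st$Phi[msk]),
        set = function(st, v) {
          st$Phi[msk] <- exp(v)
          if (spec$latent_prey) st <- .recompute_pre(m, st)
          st },
        cond = function(st) {
          ph <- st$Phi[msk]
          sum(stats::dlnorm(ph, m$fat_meanlog[msk], m$fat_sdlog[msk],
                            log = TRUE)) + sum(log(ph)) + .ll_pred_fa(m, st)
        }))
    }
  }

  ## SI blocks
  if (m$use_si) {
    for (s in seq_len(n)) local({
      ss <- s
      if (is.null(fx$mu_si)) {
        if (spec$latent_prey)
          push(gibbs(paste0("mu_si.", ss),
                     function(m, st) .gibbs_mu_si_s(m, st, ss)))
        else
          push(gibbs(paste0("mu_si.", ss),
                     function(m, st) .mh_mu_si_s(m, st, ss)))
      }
      if (is.null(fx$Sigma_si)) {
        bS <- gibbs(paste0("Sigma_si.", ss),
                    function(m, st) .gibbs_Sigma_si_s(m, st, ss))
        if (spec$consumed == "marginal") bS$every <- 2L
        push(bS)
      }
      if (spec$latent_prey)
        push(gibbs(paste0("si_lat.", ss),
                   function(m, st) .gibbs_si_lat_s(m, st, ss)))
    })
    if (is.null(fx$Sigma_tau_si))
      push(gibbs("Sigma_tau_si", if (spec$consumed == "marginal")
        .gibbs_Sigma_tau_si_marg else .gibbs_Sigma_tau_si))
    if (is.null(fx$gamma) && any(m$gam_mask))
      push(gibbs("gamma", .gibbs_gamma))
  }
  # Joint move along the diet / consumed-prey ridge.  The predator term
  # pins the mixture, so the diet vector and the per-species consumed (or
  # prey) means can only move together; a joint block with an adapted
  # proposal covariance learns that direction, which neither block reaches
  # alone.
  if (spec$grouping == "population" && is.null(fx$pi) &&
      spec$consumed != "marginal") {
    dz <- n - 1L
    lat <- spec$latent_prey
    base_cond <- function(st) .lddirichlet(st$pi, spec$prior$alpha) +
      .ilr_logjac(st$pi) + pred_terms(st)
    if (m$use_fa) for (s in seq_len(n)) local({
      ss <- s
      push(rwm(paste0("zphi.", ss), dz + m$dfa,
        get = function(st) c(st$z, if (lat) colMeans(st$phi_lat[[ss]]) else
          st$mu[[ss]]),
        set = function(st, v) {
          st$z <- v[seq_len(dz)]
          st$pi <- .ilr_inv(st$z, m$V)
          tgt <- v[dz + seq_len(m$dfa)]
          if (lat) {
            delta <- tgt - colMeans(st$phi_lat[[ss]])
            st$phi_lat[[ss]] <- sweep(st$phi_lat[[ss]], 2L, delta, "+")
            st$philat_comp[[ss]] <- .alr_inv_rows(st$phi_lat[[ss]], m$ref)
            st$Acons[[ss]] <- sweep(st$philat_comp[[ss]], 2L,
                                    st$kappa[ss, ], "*")
            st <- .recompute_pre(m, st)
          } else {
            st$mu[[ss]] <- tgt
            st$A[ss, ] <- st$kappa[ss, ] * alr_inv(tgt, m$ref)
          }
          st },
        cond = function(st) base_cond(st) +
          (if (lat) .ll_lat_fa(m, st, ss) else
            .ll_prey_fa(m, st, ss) +
              sum(stats::dnorm(st$mu[[ss]], 0, spec$prior$mu_sd,
                               log = TRUE)))))
    })
    if (m$use_si) for (s in seq_len(n)) local({
      ss <- s
      push(rwm(paste0("zsi.", ss), dz + m$K,
        get = function(st) c(st$z, if (lat) colMeans(st$si_lat[[ss]]) else
          st$mu_si[ss, ]),
        set = function(st, v) {
          st$z <- v[seq_len(dz)]
          st$pi <- .ilr_inv(st$z, m$V)
          if (m$use_fa && lat) st <- .recompute_pre(m, st)
          tgt <- v[dz + seq_len(m$K)]
          if (lat) {
            delta <- tgt - colMeans(st$si_lat[[ss]])
            st$si_lat[[ss]] <- sweep(st$si_lat[[ss]], 2L, delta, "+")
          } else st$mu_si[ss, ] <- tgt
          st },
        cond = function(st) base_cond(st) +
          (if (lat) .ll_lat_si(m, st, ss) else
            .ll_prey_si(m, st, ss) +
              sum(stats::dnorm(st$mu_si[ss, ], 0, spec$prior$mu_si_sd,
                               log = TRUE)))))
    })
  }
  # extra sweeps of the plain diet blocks: cheap relative to the rest of an
  # iteration, and the diet vector is the quantity of interest
  zb <- blocks[vapply(blocks, function(b)
    b$kind == "rwm" && (b$name == "z" || startsWith(b$name, "z.")), TRUE)]
  blocks <- c(blocks, zb, if (spec$grouping == "population") zb)
  blocks
}

# -- monitored parameters ---------------------------------------------------

.monitor_names <- function(m) {
  sp <- m$species; out <- character(0)
  if (!is.null(m$fixed$pi)) {
    # diet fixed (feeding-trial estimation): nothing to monitor for pi
  } else if (m$spec$grouping == "population") {
    out <- c(out, paste0("pi[", sp, "]"))
  } else {
    if (m$spec$grouping == "individual")
      out <- c(out, paste0("pi_pop[", sp, "]"))
    else
      out <- c(out, paste0("B[", rep(colnames(m$X), m$n - 1L), ",",
                           rep(seq_len(m$n - 1L), each = m$q), "]"))
    out <- c(out, paste0("pi[", rep(m$ids, m$n), ",", rep(sp, each = m$J), "]"))
  }
  if (m$use_fa && is.null(m$fixed$kappa))
    for (s in seq_len(m$n)) if (any(m$kap_mask[s, ]))
      out <- c(out, paste0("kappa[", sp[s], ",", m$data$fa_names, "]"))
  if (m$use_fa && is.null(m$fixed$Phi) && any(m$phi_mask))
    out <- c(out, paste0("Phi[", sp[m$phi_mask], "]"))
  if (m$use_si && is.null(m$fixed$gamma) && any(m$gam_mask)) {
    ij <- which(m$gam_mask, arr.ind = TRUE)
    out <- c(out, paste0("gamma[", sp[ij[, 1L]], ",",
                         m$data$iso_names[ij[, 2L]], "]"))
  }
  out
}

.monitor_values <- function(m, st) {
  out <- numeric(0)
  if (!is.null(m$fixed$pi)) {
  } else if (m$spec$grouping == "population") {
    out <- c(out, st$pi)
  } else {
    if (m$spec$grouping == "individual") out <- c(out, .ilr_inv(st$Pi, m$V))
    else out <- c(out, as.vector(st$B))
    out <- c(out, as.vector(st$pi))
  }
  if (m$use_fa && is.null(m$fixed$kappa))
    for (s in seq_len(m$n)) if (any(m$kap_mask[s, ]))
      out <- c(out, st$kappa[s, ] / sum(st$kappa[s, ]))
  if (m$use_fa && is.null(m$fixed$Phi) && any(m$phi_mask))
    out <- c(out, st$Phi[m$phi_mask])
  if (m$use_si && is.null(m$fixed$gamma) && any(m$gam_mask))
    out <- c(out, st$gamma[m$gam_mask])
  out
}

# -- main loops -------------------------------------------------------------

#' Run MCMC chains for a model
#'
#' For a `diet_model` this runs the blocked adaptive
#' Metropolis-within-Gibbs sampler; for a plain log-posterior object (a list
#' with elements `fn` (log density over a flat vector), `dim`, and optionally
#' `names`, `init` (function of the chain index returning a start vector) and
#' `blocks` (list of index vectors updated jointly)) it runs adaptive
#' random-walk Metropolis.  Chains are initialised from overdispersed start
#' points, proposal scales are adapted only during warmup, and the draws are
#' reproducible: the same seed gives identical output.
#'
#' @param lp a `diet_model` from [build_model()], or a plain log-posterior
#'   list as described above.
#' @param n_chains number of chains (at least 2 for diagnostics).
#' @param n_iter iterations per chain, including warmup.
#' @param n_warmup warmup iterations discarded from the output.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed controlling all randomness.
#' @return a [diet_draws] object.
#' @export
run_chains <- function(lp, n_chains = 3, n_iter = 20000,
                       n_warmup = floor(n_iter / 2), thin = 1, seed = 1) {
  stopifnot(n_chains >= 1, n_iter > n_warmup, n_warmup >= 0)
  if (inherits(lp, "diet_model"))
    .run_diet_chains(lp, n_chains, n_iter, n_warmup, thin, seed)
  else .run_generic_chains(lp, n_chains, n_iter, n_warmup, thin, seed)
}

.run_diet_chains <- function(m, n_chains, n_iter, n_warmup, thin, seed) {
  blocks <- .diet_blocks(m)
  mon_names <- .monitor_names(m)
  n_keep <- length(seq.int(n_warmup + 1L, n_iter, by = thin))
  draws <- array(NA_real_, c(n_keep, n_chains, length(mon_names)),
                 dimnames = list(NULL, NULL, mon_names))
  rwm_idx <- which(vapply(blocks, function(b) b$kind %in% c("rwm", "vec"), TRUE))
  acc_tot <- stats::setNames(numeric(length(rwm_idx)),
                             vapply(blocks[rwm_idx], `[[`, "", "name"))
  plugin <- NULL; n_plug <- 0L

  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    st <- NULL
    for (try in 1:20) {
      cand <- .init_state(m, overdisp = 0.5 + 0.5 * ch)
      if (is.finite(.state_logpost(m, cand))) { st <- cand; break }
    }
    if (is.null(st))
      stop("run_chains: could not initialise a finite posterior state after ",
           "20 attempts; check the data and priors", call. = FALSE)
    if (m$spec$grouping == "population") {
      if (is.null(m$fixed$pi)) st$z <- .ilr(st$pi, m$V)
    } else if (is.null(m$fixed$pi)) {
      st$Z <- t(apply(st$pi, 1L, .ilr, V = m$V))
      if (m$n == 2L) st$Z <- matrix(st$Z, ncol = 1L)
    }
    lsc <- vapply(blocks[rwm_idx], function(b) log(0.3 / sqrt(b$d)), 0)
    acc <- numeric(length(rwm_idx))
    # per-block proposal-covariance adaptation (Haario-style): running
    # mean/scatter collected during warmup, proposal switched to the
    # empirical covariance once enough draws exist, frozen after warmup
    ad <- lapply(blocks[rwm_idx], function(b)
      list(t = 0L, mean = numeric(b$d), M2 = matrix(0, b$d, b$d), U = NULL))
    keep_row <- 0L
    for (it in seq_len(n_iter)) {
      ib <- 0L
      for (b in blocks) {
        if (b$kind == "gibbs") {
          if (is.null(b$every) || it %% b$every == 0L) st <- b$draw(m, st)
          next
        }
        ib <- ib + 1L
        if (b$kind == "vec") {
          out <- b$step(st, exp(lsc[ib]))
          st <- out$state
          if (it <= n_warmup) {
            g <- min(0.05, 3 / sqrt(it))
            lsc[ib] <- lsc[ib] + g * (out$acc - .ACC_TARGET(b$d))
          } else acc[ib] <- acc[ib] + out$acc
          next
        }
        cur <- b$get(st)
        l0 <- b$cond(st)
        U <- ad[[ib]]$U
        step <- if (is.null(U))
          exp(lsc[ib]) * stats::rnorm(b$d)
        else
          exp(lsc[ib]) * (2.38 / sqrt(b$d)) *
            drop(crossprod(U, stats::rnorm(b$d)))
        st1 <- b$set(st, cur + step)
        l1 <- b$cond(st1)
        a <- l1 - l0
        ok <- is.finite(a) && (a >= 0 || log(stats::runif(1)) < a)
        if (ok) st <- st1
        if (it <= n_warmup) {
          g <- min(0.05, 3 / sqrt(it))
          lsc[ib] <- lsc[ib] + g * ((if (ok) 1 else 0) - .ACC_TARGET(b$d))
          if (!isTRUE(b$iso)) {
            x <- if (ok) cur + step else cur
            aa <- ad[[ib]]
            aa$t <- aa$t + 1L
            dlt <- x - aa$mean
            aa$mean <- aa$mean + dlt / aa$t
            aa$M2 <- aa$M2 + tcrossprod(dlt, x - aa$mean)
            if (aa$t >= 150L && aa$t %% 25L == 0L) {
              Unew <- .chol_or_null(aa$M2 / (aa$t - 1L) + diag(1e-10, b$d))
              if (!is.null(Unew)) {
                if (is.null(aa$U)) lsc[ib] <- 0   # rescale for new proposal
                aa$U <- Unew
              }
            }
            ad[[ib]] <- aa
          }
        } else acc[ib] <- acc[ib] + (if (ok) 1 else 0)
      }
      if (it > n_warmup) {
        if ((it - n_warmup - 1L) %% thin == 0L) {
          keep_row <- keep_row + 1L
          draws[keep_row, ch, ] <- .monitor_values(m, st)
        }
        if (is.null(plugin)) { plugin <- .plugin_init(st) }
        plugin <- .plugin_add(plugin, st)
        n_plug <- n_plug + 1L
      }
    }
    acc_tot <- acc_tot + acc / (n_iter - n_warmup)
  }
  plugin <- .plugin_scale(plugin, 1 / n_plug)
  diet_draws(draws, seed = seed, n_warmup = n_warmup, thin = thin,
             accept = acc_tot / n_chains, species = m$species,
             model_info = list(markers = m$spec$markers,
                               grouping = m$spec$grouping,
                               latent_prey = m$spec$latent_prey,
                               consumed = m$spec$consumed),
             plugin = plugin)
}

.plugin_fields <- c("pi", "mu", "Sigma", "Sigma_tau", "kappa", "Phi",
                    "mu_si", "Sigma_si", "Sigma_tau_si", "gamma",
                    "Pi", "Sigma_Pi", "B")

.plugin_init <- function(st) {
  out <- st[intersect(.plugin_fields, names(st))]
  rapply(out, function(x) 0 * x, how = "replace")
}

.plugin_add <- function(acc, st) {
  for (nm in names(acc)) {
    if (is.list(acc[[nm]]))
      for (i in seq_along(acc[[nm]]))
        acc[[nm]][[i]] <- acc[[nm]][[i]] + st[[nm]][[i]]
    else acc[[nm]] <- acc[[nm]] + st[[nm]]
  }
  acc
}

.plugin_scale <- function(acc, f) rapply(acc, function(x) x * f, how = "replace")

.run_generic_chains <- function(lp, n_chains, n_iter, n_warmup, thin, seed) {
  stopifnot(is.function(lp$fn), is.numeric(lp$dim))
  d <- as.integer(lp$dim)
  nms <- lp$names %||% paste0("theta[", seq_len(d), "]")
  blocks <- lp$blocks %||% list(seq_len(d))
  n_keep <- length(seq.int(n_warmup + 1L, n_iter, by = thin))
  draws <- array(NA_real_, c(n_keep, n_chains, d),
                 dimnames = list(NULL, NULL, nms))
  acc_tot <- numeric(length(blocks))

  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    theta <- NULL
    for (try in 1:20) {
      cand <- if (is.function(lp$init)) lp$init(ch) else
        stats::rnorm(d, 0, 0.5 + 0.5 * ch)
      if (is.finite(lp$fn(cand))) { theta <- cand; break }
    }
    if (is.null(theta))
      stop("run_chains: could not find a finite starting point after 20 ",
           "attempts", call. = FALSE)
    l0 <- lp$fn(theta)
    lsc <- vapply(blocks, function(ix) log(0.5 / sqrt(length(ix))), 0)
    acc <- numeric(length(blocks))
    keep_row <- 0L
    for (it in seq_len(n_iter)) {
      for (ib in seq_along(blocks)) {
        ix <- blocks[[ib]]
        prop <- theta
        prop[ix] <- prop[ix] + exp(lsc[ib]) * stats::rnorm(length(ix))
        l1 <- lp$fn(prop)
        a <- l1 - l0
        ok <- is.finite(a) && (a >= 0 || log(stats::runif(1)) < a)
        if (ok) { theta <- prop; l0 <- l1 }
        if (it <= n_warmup) {
          g <- min(0.05, 3 / sqrt(it))
          lsc[ib] <- lsc[ib] + g * ((if (ok) 1 else 0) - .ACC_TARGET(length(ix)))
        } else acc[ib] <- acc[ib] + (if (ok) 1 else 0)
      }
      if (it > n_warmup && (it - n_warmup - 1L) %% thin == 0L) {
        keep_row <- keep_row + 1L
        draws[keep_row, ch, ] <- theta
      }
    }
    acc_tot <- acc_tot + acc / (n_iter - n_warmup)
  }
  diet_draws(draws, seed = seed, n_warmup = n_warmup, thin = thin,
             accept = acc_tot / n_chains)
}
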