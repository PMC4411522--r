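test_that("compute_tau implements the closure-normalised mixing rule", {
  phi <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  k1 <- matrix(1, 2, 2)
  expect_equal(compute_tau(c(1, 0), k1, phi), c(0.5, 0.5))
  expect_equal(compute_tau(c(0.5, 0.5), k1, phi), c(0.7, 0.3))
  expect_equal(compute_tau(c(0.5, 0.5), k1, phi, fat = c(2, 1)),
               closure(c(1.9, 1.1)))
  # closure absorbs any common scaling of fat content or kappa
  p <- c(0.3, 0.7)
  expect_equal(compute_tau(p, k1, phi, fat = c(1.3, 0.4)),
               compute_tau(p, k1, phi, fat = 2 * c(1.3, 0.4)))
  k2 <- matrix(runif(4, 0.5, 2), 2)
  expect_equal(compute_tau(p, k2, phi), compute_tau(p, 3 * k2, phi))
  # no-conversion, equal-fat limit: plain compositional mixture
  expect_equal(compute_tau(p, k1, phi), closure(drop(p %*% phi)))
})

test_that("si_expected is the fractionation-shifted linear mixture", {
  expect_equal(si_expected(c(0.5, 0.5), c(-20, -10), matrix(1, 2, 1)), -14)
  y <- matrix(c(-20, -10, 8, 12), 2)
  g <- matrix(c(1, 1.5, 3, 2.5), 2)
  expect_equal(si_expected(c(1, 0), y, g), y[1, ] + g[1, ])
  expect_equal(si_expected(c(0.4, 0.6), y, 0 * g),
               drop(c(0.4, 0.6) %*% y))
})

test_that("likelihoods match the direct-summation oracle on small instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed, markers = "both",
                            latent = seed %% 2 == 0,
                            individual = seed %% 3 == 0)
    latent <- seed %% 2 == 0
    grouping <- if (seed %% 3 == 0) "individual" else "population"
    spec_fa <- model_spec("fa", grouping, latent_prey = latent)
    spec_si <- model_spec("si", grouping, latent_prey = latent)
    fa <- fa_loglik(inst$data, inst$state, spec_fa)
    si <- si_loglik(inst$data, inst$state, spec_si)
    expect_equal(fa, oracle_fa_loglik(inst$data, inst$state, latent),
                 tolerance = 1e-10)
    expect_equal(si, oracle_si_loglik(inst$data, inst$state, latent),
                 tolerance = 1e-10)
  }
})

test_that("predator term peaks at the expected signature and falls off monotonically", {
  inst <- random_instance(42, markers = "fa")
  d <- inst$data
  st <- inst$state
  spec <- model_spec("fa", latent_prey = FALSE)
  m <- build_model(d, spec)
  # place the single predator exactly at its expected signature
  phi <- t(vapply(st$mu, function(mm) alr_inv(mm), numeric(inst$p)))
  tau <- compute_tau(st$pi, st$kappa, phi, st$Phi)
  d1 <- d
  d1$pred_fa <- matrix(tau, inst$J, inst$p, byrow = TRUE,
                       dimnames = dimnames(d$pred_fa))
  at_mode <- fa_loglik(d1, st, spec)
  eig <- eigen(st$Sigma_tau, symmetric = TRUE)
  for (k in seq_len(inst$p - 1)) {
    v <- eig$vectors[, k]
    lls <- vapply(c(0.5, 1, 2), function(cc) {
      d2 <- d1
      shifted <- alr(tau) + cc * v
      d2$pred_fa <- matrix(alr_inv(shifted), inst$J, inst$p, byrow = TRUE,
                           dimnames = dimnames(d$pred_fa))
      fa_loglik(d2, st, spec)
    }, 0)
    expect_true(all(diff(c(at_mode, lls)) < 0))
  }
})

test_that("log_prior moment-matches kappa and fat priors and fixes zero-variance blocks", {
  tb <- random_instance(7, markers = "fa")
  d <- tb$data
  d$kappa_var[] <- 0.25   # mean 1, var 0.25 -> Gamma(shape 4, rate 4)
  m <- build_model(d, model_spec("fa", latent_prey = FALSE))
  expect_equal(unique(as.vector(m$kap_shape)), 4)
  expect_equal(unique(as.vector(m$kap_rate)), 4)
  expect_true(all(m$kap_mask))
  expect_false(any(m$phi_mask))           # fat variance 0: fixed, no prior term
  # Dirichlet(1) prior is the constant log Gamma(n) over the whole simplex
  st <- tb$state
  st$kappa <- matrix(1, tb$n, tb$p)
  base <- log_prior(st, data = m)
  st2 <- st
  st2$pi <- rand_simplex(tb$n)
  expect_equal(log_prior(st2, data = m), base, tolerance = 1e-10)
  # invalid diet proportions give -Inf exactly
  st3 <- st
  st3$pi <- c(-0.1, st3$pi[-1] / sum(st3$pi[-1]) * 1.1)
  expect_identical(log_prior(st3, data = m), -Inf)
})

test_that("build_model dimension bookkeeping is consistent", {
  sim <- simulate_diet_data(scenario_spec(n_species = 2, n_fa = 4,
                                          n_isotopes = 2, n_samples = 5,
                                          n_predators = 3, seed = 9))
  d <- sim$data
  n <- 2; p <- 4; dfa <- p - 1; K <- 2
  m_fa <- build_model(d, model_spec("fa", latent_prey = FALSE))
  expect_equal(m_fa$dim,
               (n - 1) + n * dfa + n * dfa * (dfa + 1) / 2 + dfa * (dfa + 1) / 2)
  m_si <- build_model(d, model_spec("si", latent_prey = FALSE))
  expect_equal(m_si$dim,
               (n - 1) + n * K + n * K * (K + 1) / 2 + K * (K + 1) / 2 + n * K)
  m_both <- build_model(d, model_spec("both", latent_prey = FALSE))
  expect_equal(m_both$dim, m_fa$dim + m_si$dim - (n - 1))  # shared diet block
  expect_length(m_both$param_map, m_both$dim)
  # flat density is finite at a valid state, -Inf on non-finite input
  set.seed(1)
  st <- dietmix:::.init_state(m_both)
  th <- dietmix:::.flatten_state(m_both, st)
  expect_true(is.finite(m_both$fn(th)))
  th[1] <- NA
  expect_identical(m_both$fn(th), -Inf)
})

test_that("SI models refuse to build without fractionation priors", {
  sim <- simulate_diet_data(scenario_spec(n_species = 2, n_fa = 4,
                                          n_isotopes = 2, n_samples = 5,
                                          n_predators = 3, seed = 10))
  d <- sim$data
  d$frac_mean <- NULL
  d$frac_sd <- NULL
  expect_error(build_model(d, model_spec("si")), "fractionation")
  expect_error(build_model(d, model_spec("both")), "fractionation")
})

test_that("non-positive-definite covariances yield -Inf likelihoods", {
  inst <- random_instance(11, markers = "fa")
  st <- inst$state
  st$Sigma_tau <- matrix(1, inst$p - 1, inst$p - 1)  # singular
  expect_identical(fa_loglik(inst$data, st, model_spec("fa", latent_prey = FALSE)),
                   -Inf)
})

test_that("the marginal predator covariance matches finite-difference propagation", {
  inst <- random_instance(77, markers = "fa")
  d <- inst$data
  m <- build_model(d, model_spec("fa", consumed = "marginal"))
  st <- dietmix:::.refresh_caches(m, inst$state)
  C <- dietmix:::.latent_mix_cov(m, st)
  # numerical Jacobian of alr(mixture) wrt each species' alr coordinates
  p <- inst$p; n <- inst$n
  mix_alr <- function(mu_list) {
    phi <- t(vapply(mu_list, function(v) alr_inv(v, p), numeric(p)))
    alr(compute_tau(as.vector(st$pi), st$kappa, phi, st$Phi), p)
  }
  h <- 1e-6
  Cnum <- matrix(0, p - 1, p - 1)
  for (s in seq_len(n)) {
    J <- matrix(0, p - 1, p - 1)
    for (g in seq_len(p - 1)) {
      up <- st$mu; up[[s]][g] <- up[[s]][g] + h
      dn <- st$mu; dn[[s]][g] <- dn[[s]][g] - h
      J[, g] <- (mix_alr(up) - mix_alr(dn)) / (2 * h)
    }
    Cnum <- Cnum + J %*% st$Sigma[[s]] %*% t(J)
  }
  expect_equal(C, Cnum, tolerance = 1e-5)
})

test_that("the forward simulator is consistent with the likelihood mixing rule", {
  # zero residual + mean-prey consumed items: predator alr = alr(compute_tau)
  sp <- scenario_spec(n_species = 3, n_fa = 5, n_isotopes = 0, n_samples = 5,
                      n_predators = 2, pred_fa_noise = 1e-12, mean_prey = TRUE,
                      pi_true = c(0.2, 0.3, 0.5), seed = 12)
  prey <- simulate_prey(sp)
  pred <- simulate_predators(prey, sp)
  tau <- compute_tau(c(0.2, 0.3, 0.5), pred$kappa_true, prey$mean_profiles,
                     sp$fat_true)
  expect_equal(unname(as.matrix(pred$predator_fa[1, -1])[1, ]), tau,
               tolerance = 1e-6)
  # scaling the true kappa matrix leaves simulated predators unchanged
  sp2 <- sp; sp2$kappa_true <- matrix(2, 3, 5)
  pred2 <- simulate_predators(prey, sp2)
  expect_equal(pred2$predator_fa, pred$predator_fa, tolerance = 1e-9)
})
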