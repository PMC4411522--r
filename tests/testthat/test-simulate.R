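test_that("separation controls among-species structure in the prey library", {
  base <- function(sep, seed) scenario_spec(n_species = 3, n_fa = 8,
                                            n_isotopes = 0, n_samples = 15,
                                            n_predators = 2,
                                            separation = sep, seed = seed)
  # zero separation: species indistinguishable
  prey0 <- simulate_prey(base(0, 1))
  ord0 <- cap_ordination(prey0$prey_fa)
  expect_lt(ord0$among_variance, 0.25)
  # large separation: near-perfect leave-one-out nearest-mean classification
  prey1 <- simulate_prey(base(4, 1))
  X <- alr(as.matrix(prey1$prey_fa[, -1]))
  lab <- prey1$prey_fa$species
  hits <- vapply(seq_len(nrow(X)), function(i) {
    mus <- rowsum(X[-i, ], lab[-i]) / as.vector(table(lab[-i]))
    names(which.min(apply(mus, 1, function(mu) sum((X[i, ] - mu)^2)))) ==
      lab[i]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the prey library is reproducible from the seed", {
  sp <- scenario_spec(n_species = 3, n_fa = 6, n_samples = 5,
                      n_predators = 2, seed = 77)
  expect_identical(simulate_prey(sp), simulate_prey(sp))
  sp2 <- sp; sp2$seed <- 78
  expect_false(identical(simulate_prey(sp)$prey_fa,
                         simulate_prey(sp2)$prey_fa))
})

test_that("a single-prey diet with no noise reproduces that species' profile", {
  sp <- scenario_spec(n_species = 2, n_fa = 5, n_isotopes = 0, n_samples = 5,
                      n_predators = 3, pi_true = c(1, 0),
                      pred_fa_noise = 1e-12, mean_prey = TRUE, seed = 13)
  prey <- simulate_prey(sp)
  pred <- simulate_predators(prey, sp)
  for (j in 1:3)
    expect_equal(unname(as.matrix(pred$predator_fa[j, -1])[1, ]),
                 unname(prey$mean_profiles[1, ]), tolerance = 1e-6)
})

test_that("simulated datasets validate and carry a complete truth record", {
  sim <- simulate_diet_data(scenario_spec(n_species = 3, n_fa = 6,
                                          n_isotopes = 2, n_samples = 8,
                                          n_predators = 4,
                                          pi_true = c(0.2, 0.3, 0.5),
                                          kappa_noise = 0.1, seed = 19))
  expect_s3_class(sim$data, "diet_data")
  expect_equal(unname(sim$truth$pi_pop), c(0.2, 0.3, 0.5))
  expect_equal(dim(sim$truth$pi_true), c(4, 3))
  expect_equal(dim(sim$truth$kappa_true), c(3, 6))
  expect_true(all(sim$data$kappa_var == 0.1))
  expect_equal(unname(sim$data$frac_mean), unname(sim$truth$gamma_true))
  # evenness draws per-predator diets from a symmetric Dirichlet
  sim2 <- simulate_diet_data(scenario_spec(n_species = 3, n_fa = 6,
                                           n_isotopes = 0, n_samples = 8,
                                           n_predators = 50, evenness = 0.5,
                                           seed = 20))
  expect_gt(max(apply(sim2$truth$pi_true, 1, max)), 0.9)  # specialists exist
  expect_equal(unname(rowSums(sim2$truth$pi_true)), rep(1, 50),
               tolerance = 1e-12)
})

test_that("a one-cell scenario grid returns finite scores", {
  base <- scenario_spec(n_species = 2, n_fa = 4, n_isotopes = 0,
                        n_samples = 8, n_predators = 4, seed = 3)
  out <- run_scenario_grid(base, axis = "separation", levels = 2,
                           replicates = 1,
                           mcmc = mcmc_control(n_chains = 2, n_iter = 500))
  expect_equal(nrow(out), 1)
  expect_true(is.finite(out$mae) && out$mae >= 0 && out$mae <= 1)
  expect_true(out$coverage90 >= 0 && out$coverage90 <= 1)
})
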