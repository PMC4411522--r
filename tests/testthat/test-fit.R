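# Small end-to-end fits exercising the user-facing surface.  Sampler sizes
# here are deliberately modest: these check the interface and invariants,
# not posterior accuracy (covered by the acceptance suite).

sim_small <- simulate_diet_data(scenario_spec(n_species = 3, n_fa = 5,
                                              n_isotopes = 2, n_samples = 10,
                                              n_predators = 4,
                                              pi_true = c(0.2, 0.3, 0.5),
                                              seed = 101))

fit_small <- suppressWarnings(
  fit_diet(sim_small$data, markers = "fa", grouping = "population",
           latent_prey = FALSE,
           mcmc = mcmc_control(n_chains = 2, n_iter = 800), seed = 2))

test_that("a population fit exposes the standard modelling methods", {
  expect_s3_class(fit_small, "diet_fit")
  cf <- coef(fit_small)
  expect_named(cf, sim_small$data$species)
  expect_equal(sum(cf), 1, tolerance = 1e-9)
  expect_output(print(fit_small), "diet proportions")
  sm <- summary(fit_small)
  expect_true(all(c("mean", "sd", "rhat", "ess") %in% names(sm)))
  f <- fitted(fit_small)
  expect_equal(dim(f$fa), c(4, 4))          # predators x alr coordinates
  r <- residuals(fit_small)
  expect_true(all(is.finite(r$fa)))
  ssim <- simulate(fit_small, nsim = 1, seed = 1)
  expect_equal(unname(rowSums(ssim$fa)), rep(1, 4), tolerance = 1e-9)
  pdf(NULL); on.exit(dev.off())
  plot(fit_small)
  rep_lines <- report(fit_small, truth = sim_small$truth)
  expect_true(any(grepl("Recovery against truth", rep_lines)))
  expect_true(any(grepl("Mean absolute error", rep_lines)))
})

test_that("marginal consumed-prey mode fits and widens over mean-prey appropriately", {
  fit_m <- suppressWarnings(
    fit_diet(sim_small$data, markers = "both", grouping = "population",
             consumed = "marginal",
             mcmc = mcmc_control(n_chains = 2, n_iter = 700), seed = 9))
  expect_equal(sum(coef(fit_m)), 1, tolerance = 1e-9)
  expect_identical(fit_m$spec$consumed, "marginal")
  expect_error(fit_diet(sim_small$data, markers = "fa",
                        grouping = "individual", consumed = "marginal",
                        mcmc = mcmc_control(n_chains = 2, n_iter = 200)),
               "population")
})

test_that("latent-prey mode fits and carries latent consumed profiles", {
  fit_lat <- suppressWarnings(
    fit_diet(sim_small$data, markers = "fa", grouping = "population",
             latent_prey = TRUE,
             mcmc = mcmc_control(n_chains = 2, n_iter = 500), seed = 3))
  cf <- coef(fit_lat)
  expect_equal(sum(cf), 1, tolerance = 1e-9)
  expect_true(fit_lat$spec$latent_prey)
})

test_that("individual grouping yields per-predator and population diets", {
  fit_ind <- suppressWarnings(
    fit_diet(sim_small$data, markers = "fa", grouping = "individual",
             latent_prey = FALSE,
             mcmc = mcmc_control(n_chains = 2, n_iter = 700), seed = 4))
  cf <- coef(fit_ind)
  expect_equal(dim(cf), c(4, 3))
  expect_equal(unname(rowSums(cf)), rep(1, 4), tolerance = 1e-9)
  expect_true(any(grepl("^pi_pop\\[", fit_ind$summary$parameter)))
  grp <- combine_sources(fit_ind$draws,
                         c(prey1 = "a", prey2 = "a", prey3 = "b"))
  tot <- grp$draws[, , "pi_pop[a]"] + grp$draws[, , "pi_pop[b]"]
  expect_equal(as.vector(tot), rep(1, length(tot)), tolerance = 1e-9)
})

test_that("linear grouping estimates covariate effects and predicts diets", {
  covs <- data.frame(id = sim_small$data$pred_fa_ids,
                     treatment = rep(c("A", "B"), 2))
  d <- sim_small$data
  d$covariates <- covs
  fit_lin <- suppressWarnings(
    fit_diet(d, markers = "fa", grouping = "linear", formula = ~ treatment,
             latent_prey = FALSE,
             mcmc = mcmc_control(n_chains = 2, n_iter = 700), seed = 5))
  expect_true(any(grepl("^B\\[", fit_lin$summary$parameter)))
  pr <- predict(fit_lin, newdata = data.frame(treatment = c("A", "B")))
  expect_equal(dim(pr), c(2, 3))
  expect_equal(unname(rowSums(pr)), rep(1, 2), tolerance = 1e-9)
})

test_that("joint models reuse one diet vector across both markers", {
  fit_joint <- suppressWarnings(
    fit_diet(sim_small$data, markers = "both", grouping = "population",
             latent_prey = FALSE,
             mcmc = mcmc_control(n_chains = 2, n_iter = 600), seed = 6))
  expect_true(any(grepl("^gamma\\[", fit_joint$summary$parameter)))
  expect_equal(sum(coef(fit_joint)), 1, tolerance = 1e-9)
  f <- fitted(fit_joint)
  expect_named(f, c("fa", "si"))
})

test_that("feeding-trial conversion-coefficient estimation is wired through", {
  k_true <- rbind(c(1.6, 0.6, 1.0, 1.1, 0.7), c(1, 1, 1, 1, 1))
  sp <- scenario_spec(n_species = 2, n_fa = 5, n_isotopes = 0,
                      n_samples = 12, n_predators = 6, pi_true = c(1, 0),
                      kappa_true = k_true, pred_fa_noise = 0.05,
                      mean_prey = TRUE, seed = 55)
  sim <- simulate_diet_data(sp)
  known <- matrix(c(1, 0), 6, 2, byrow = TRUE)
  fit_k <- suppressWarnings(
    estimate_conversion_coefficients(sim$data, known, latent_prey = FALSE,
                                     mcmc = mcmc_control(n_chains = 2,
                                                         n_iter = 1200),
                                     seed = 7))
  sm <- fit_k$summary
  k1 <- sm$mean[match(paste0("kappa[prey1,FA", 1:5, "]"), sm$parameter)]
  expect_equal(sum(k1), 1, tolerance = 1e-9)  # closure-normalised draws
  expect_lt(max(abs(k1 - k_true[1, ] / sum(k_true[1, ]))), 0.08)
  pri <- as_kappa_priors(fit_k)
  expect_equal(dim(pri$kappa_mean), c(2, 6))
  one_pred <- local({
    d <- sim$data
    d$pred_fa <- d$pred_fa[1, , drop = FALSE]
    d$pred_fa_ids <- d$pred_fa_ids[1]
    d
  })
  w <- capture_warnings(
    estimate_conversion_coefficients(one_pred, matrix(c(1, 0), 1),
                                     latent_prey = FALSE,
                                     mcmc = mcmc_control(n_chains = 2,
                                                         n_iter = 200),
                                     seed = 8))
  expect_true(any(grepl("fewer than 2", w)))
})
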