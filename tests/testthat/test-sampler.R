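test_that("the generic sampler recovers a known 2-d Gaussian target", {
  lp <- list(fn = function(th) -0.5 * sum(th^2), dim = 2,
             names = c("x", "y"))
  dr <- run_chains(lp, n_chains = 2, n_iter = 10000, n_warmup = 2000,
                   seed = 4)
  X <- dietmix:::.draws_matrix(dr)
  expect_equal(unname(colMeans(X)), c(0, 0), tolerance = 0.1)
  expect_equal(unname(cov(X)), diag(2), tolerance = 0.12)
})

test_that("a Dirichlet(1,1,1) prior-only model has uniform marginal means", {
  V <- dietmix:::.ilr_basis(3)
  lp <- list(fn = function(z) {
    pi <- dietmix:::.ilr_inv(z, V)
    dietmix:::.lddirichlet(pi, 1) + sum(log(pi))
  }, dim = 2)
  dr <- run_chains(lp, n_chains = 2, n_iter = 8000, n_warmup = 2000, seed = 8)
  Z <- dietmix:::.draws_matrix(dr)
  P <- t(apply(Z, 1, function(z) dietmix:::.ilr_inv(z, V)))
  expect_equal(unname(colMeans(P)), rep(1 / 3, 3), tolerance = 0.03)
})

test_that("draws are reproducible from the seed alone", {
  sim <- simulate_diet_data(scenario_spec(n_species = 2, n_fa = 4,
                                          n_isotopes = 0, n_samples = 5,
                                          n_predators = 3, seed = 5))
  m <- build_model(sim$data, model_spec("fa", latent_prey = FALSE))
  d1 <- run_chains(m, n_chains = 2, n_iter = 300, n_warmup = 150, seed = 7)
  d2 <- run_chains(m, n_chains = 2, n_iter = 300, n_warmup = 150, seed = 7)
  d3 <- run_chains(m, n_chains = 2, n_iter = 300, n_warmup = 150, seed = 8)
  expect_identical(d1$draws, d2$draws)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("rhat is near 1 for well-mixed draws and large for disjoint chains", {
  set.seed(31)
  good <- array(rnorm(5000 * 2), c(2500, 2, 1), dimnames = list(NULL, NULL, "a"))
  expect_lt(rhat(diet_draws(good))["a"], 1.01)
  bad <- array(c(rep(0, 500), rep(5, 500)), c(500, 2, 1),
               dimnames = list(NULL, NULL, "a"))
  expect_gt(rhat(diet_draws(bad))["a"], 2)
  const <- array(1, c(100, 2, 1), dimnames = list(NULL, NULL, "a"))
  expect_identical(unname(rhat(diet_draws(const))["a"]), 1)
  expect_identical(unname(ess(diet_draws(const))["a"]), 200)
})

test_that("ess matches the AR(1) closed form within 25%", {
  set.seed(17)
  rho <- 0.9
  n <- 4000; chains <- 4
  x <- array(NA_real_, c(n, chains, 1), dimnames = list(NULL, NULL, "a"))
  for (ch in 1:chains) {
    v <- numeric(n); v[1] <- rnorm(1)
    for (t in 2:n) v[t] <- rho * v[t - 1] + sqrt(1 - rho^2) * rnorm(1)
    x[, ch, 1] <- v
  }
  est <- ess(diet_draws(x))["a"]
  expected <- n * chains * (1 - rho) / (1 + rho)
  expect_lt(abs(est - expected) / expected, 0.25)
})

test_that("summaries report means, quantile-nested intervals and diagnostics", {
  set.seed(23)
  a <- array(rnorm(2000 * 2 * 2, mean = c(1, 2)), c(2000, 2, 2),
             dimnames = list(NULL, NULL, c("a", "b")))
  a[, , 1] <- 1 + a[, , 1] * 0    # constant parameter flagged gracefully
  a[, , 2] <- rnorm(4000, 2, 0.5)
  sm <- summarize_draws(diet_draws(a), levels = c(0.5, 0.9))
  expect_identical(sm$parameter, c("a", "b"))
  expect_equal(sm$mean[1], 1)
  expect_equal(sm$mean[2], 2, tolerance = 0.05)
  # wider level nests the narrower one
  expect_lte(sm$lower_0.9[2], sm$lower_0.5[2])
  expect_gte(sm$upper_0.9[2], sm$upper_0.5[2])
  expect_true(all(c("rhat", "ess") %in% names(sm)))
})

test_that("combine_sources partitions and conserves total diet per draw", {
  set.seed(29)
  P <- rdiri(600, 3)
  a <- array(P, c(300, 2, 3),
             dimnames = list(NULL, NULL, paste0("pi[sp", 1:3, "]")))
  dr <- diet_draws(a, species = paste0("sp", 1:3))
  # trivial partition: unchanged values
  triv <- combine_sources(dr, c(sp1 = "sp1", sp2 = "sp2", sp3 = "sp3"))
  expect_equal(sort(triv$params), sort(dr$params))
  for (pp in dr$params) expect_equal(triv$draws[, , pp], dr$draws[, , pp])
  # everything in one group: exactly 1
  one <- combine_sources(dr, c(sp1 = "all", sp2 = "all", sp3 = "all"))
  expect_equal(as.vector(one$draws), rep(1, 600), tolerance = 1e-12)
  # fish/crustacean style grouping sums to 1 per draw
  g <- combine_sources(dr, c(sp1 = "fish", sp2 = "fish", sp3 = "crust"))
  tot <- g$draws[, , "pi[fish]"] + g$draws[, , "pi[crust]"]
  expect_equal(as.vector(tot), rep(1, 600), tolerance = 1e-12)
  expect_error(combine_sources(dr, c(sp1 = "a", sp2 = "b")), "exactly once")
})

test_that("compare_spread returns SD ratios relative to the second run", {
  set.seed(37)
  a <- array(rnorm(1000), c(500, 2, 1), dimnames = list(NULL, NULL, "a"))
  da <- diet_draws(a)
  expect_equal(compare_spread(da, da)$sd_ratio, 1)
  b <- a
  b[] <- mean(a) + 2 * (a - mean(a))
  expect_equal(compare_spread(da, diet_draws(b))$sd_ratio, 0.5,
               tolerance = 1e-12)
})
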