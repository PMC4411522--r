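two_species_one_signal <- function(seed = 1, p = 6, samples = 12, delta = 1.5) {
  # species differ (in log space) only through FA1
  set.seed(seed)
  base <- rep(1 / p, p)
  lbase <- log(base)
  mk <- function(shift) t(replicate(samples, {
    l <- lbase + rnorm(p, 0, 0.05)
    l[1] <- l[1] + shift
    closure(exp(l))
  }))
  X <- rbind(mk(0), mk(delta))
  colnames(X) <- paste0("FA", seq_len(p))
  data.frame(species = rep(c("a", "b"), each = samples), X,
             check.names = FALSE)
}

test_that("the FA carrying the species signal dominates the contributions", {
  df <- two_species_one_signal()
  ord <- cap_ordination(df)
  expect_equal(sum(ord$contribution), 1, tolerance = 1e-10)
  expect_identical(names(which.max(ord$contribution)), "FA1")
  expect_gt(ord$contribution["FA1"], 3 * max(ord$contribution[-1]))
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(length(ord$eigenvalues), 1)   # n_species - 1 constrained axes
})

test_that("permuting species labels collapses among-species variance", {
  df <- two_species_one_signal(2)
  ord <- cap_ordination(df)
  set.seed(99)
  perm <- replicate(20, {
    df2 <- df
    df2$species <- sample(df2$species)
    cap_ordination(df2)$among_variance
  })
  expect_gt(ord$among_variance, 0.5)
  expect_lt(mean(perm), 0.3 * ord$among_variance)
})

test_that("duplicating every sample leaves contributions unchanged", {
  df <- two_species_one_signal(3)
  c1 <- cap_ordination(df)$contribution
  c2 <- cap_ordination(rbind(df, df))$contribution
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("condition number is 1 for orthonormal species means and grows with collinearity", {
  # two species concentrated on distinct FAs: identity species-mean matrix
  df <- data.frame(species = rep(c("a", "b"), each = 2),
                   FA1 = c(1, 1, 0, 0), FA2 = c(0, 0, 1, 1))
  expect_identical(prey_condition_number(df), 1)
  # identical mean subcompositions on the subset -> rank deficient
  df2 <- data.frame(species = rep(c("a", "b"), each = 2),
                    FA1 = rep(0.3, 4), FA2 = rep(0.7, 4))
  expect_warning(cn <- prey_condition_number(df2), "rank-deficient")
  expect_gt(cn, 1e6)
  # collinear sources: moving one species' mean into the convex hull of the
  # others drives the condition number up
  mk <- function(coll, seed) {
    prey <- simulate_prey(scenario_spec(n_species = 3, n_fa = 6,
                                        n_isotopes = 0, n_samples = 2,
                                        n_predators = 2, collinearity = coll,
                                        seed = seed))
    M <- prey$mean_profiles
    data.frame(species = rep(rownames(M), each = 2),
               M[rep(1:3, each = 2), ], check.names = FALSE)
  }
  for (seed in 1:5)
    expect_gt(prey_condition_number(mk(0.9, seed)),
              prey_condition_number(mk(0, seed)))
})

test_that("greedy selection honours the variance target and condition cap", {
  sim <- simulate_diet_data(scenario_spec(n_species = 3, n_fa = 8,
                                          n_isotopes = 0, n_samples = 15,
                                          n_predators = 3, seed = 21))
  d <- sim$data
  # target 1, no cap: everything selected in contribution order
  sel <- select_fas(d, cum_var_target = 1, cond_cap = Inf)
  expect_identical(sel$selected, sel$ranking)
  expect_equal(unname(sel$contribution), sort(unname(sel$contribution),
                                              decreasing = TRUE))
  expect_true(all(diff(sel$cum_variance) >= -1e-12))
  expect_equal(max(sel$cum_variance), 1, tolerance = 1e-10)
  # a cap below the best-2 condition number forces the fallback
  expect_warning(fb <- select_fas(d, cum_var_target = 1, cond_cap = 1 + 1e-9),
                 "best 2")
  expect_length(fb$selected, 2)
  expect_true(fb$fallback)
})

test_that("discriminative fatty acids are recovered from simulated data", {
  sim <- simulate_diet_data(scenario_spec(n_species = 4, n_fa = 10,
                                          n_isotopes = 0, n_samples = 15,
                                          n_predators = 3,
                                          n_discriminative = 3, seed = 33))
  sel <- select_fas(sim$data, cum_var_target = 0.95, cond_cap = Inf)
  expect_setequal(sel$ranking[1:3], sim$truth$discriminative)
})

test_that("selection trajectory is deterministic and printable", {
  df <- two_species_one_signal(5)
  s1 <- select_fas(df)
  s2 <- select_fas(df)
  expect_identical(s1$selected, s2$selected)
  expect_output(print(s1), "Selected")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(s1))
})
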