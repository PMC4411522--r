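test_that("closure normalises and is idempotent, preserving zeros", {
  expect_equal(closure(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(closure(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(closure(c(3, 0, 1)), c(0.75, 0, 0.25))
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(3:10, 1), 0, 5)
    expect_equal(closure(closure(v)), closure(v), tolerance = 1e-12)
  }
  expect_error(closure(c(0, 0, 0)), "zero")
  expect_error(closure(c(-1, 2, 3)), "negative")
  expect_error(closure(5), "at least two")
})

test_that("alr and its inverse match the log-ratio formula and round-trip", {
  expect_equal(alr(c(0.2, 0.3, 0.5)), log(c(0.4, 0.6)))
  expect_equal(alr(rep(1 / 3, 3)), c(0, 0))
  expect_equal(alr_inv(c(0, 0)), rep(1 / 3, 3))
  expect_equal(alr_inv(c(log(0.4), log(0.6))), c(0.2, 0.3, 0.5))
  # reference in another position
  x <- c(0.1, 0.6, 0.3)
  expect_equal(alr(x, ref = 1), log(c(6, 3)))
  expect_equal(alr_inv(alr(x, ref = 1), ref = 1), x)
  # numerical stability for extreme log ratios
  y <- alr_inv(c(700, 0))
  expect_true(all(is.finite(y)))
  expect_equal(y[1], 1, tolerance = 1e-12)
  expect_error(alr(c(0.5, 0, 0.5)), "zero parts")
})

test_that("clr is centred, shift-invariant under inversion, and round-trips", {
  expect_equal(clr(rep(0.25, 4)), rep(0, 4))
  set.seed(2)
  for (i in 1:20) {
    x <- closure(rgamma(sample(3:8, 1), 2))
    expect_equal(sum(clr(x)), 0, tolerance = 1e-12)
    expect_equal(clr_inv(clr(x)), x, tolerance = 1e-12)
    z <- rnorm(4)
    expect_equal(clr_inv(z + 5), clr_inv(z), tolerance = 1e-12)
  }
  expect_error(clr(c(1, 0, 1) / 2), "zero parts")
})

test_that("multiplicative zero replacement follows the rule and keeps ratios", {
  expect_equal(replace_zeros(c(0.75, 0, 0.25), 0.01), c(0.7425, 0.01, 0.2475))
  expect_equal(replace_zeros(c(1, 0, 0), 0.01), c(0.98, 0.01, 0.01))
  x <- c(0.2, 0.3, 0.5)
  expect_identical(replace_zeros(x, 0.01), x)
  y <- replace_zeros(c(0.6, 0, 0.1, 0.3), 0.005)
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_equal(y[1] / y[3], 6, tolerance = 1e-12)   # nonzero ratios preserved
  expect_error(replace_zeros(c(0.5, 0, 0.5), -1), "positive")
  expect_error(replace_zeros(c(0.9, 0, 0.1), 0.2), "smaller")
})

test_that("geometric mean profile is symmetric and permutation-invariant", {
  expect_equal(geometric_mean_profile(matrix(c(0.2, 0.8), 1)), c(0.2, 0.8))
  M <- rbind(c(0.2, 0.8), c(0.8, 0.2))
  expect_equal(geometric_mean_profile(M), c(0.5, 0.5))
  set.seed(3)
  X <- t(replicate(5, closure(rgamma(4, 2))))
  expect_equal(geometric_mean_profile(X),
               geometric_mean_profile(X[sample(5), ]))
  expect_error(geometric_mean_profile(rbind(c(1, 0), c(0.5, 0.5))), "zero")
})

test_that("ilr basis is orthonormal and consistent with clr", {
  for (p in c(2, 3, 7)) {
    V <- dietmix:::.ilr_basis(p)
    expect_equal(crossprod(V), diag(p - 1), tolerance = 1e-12)
    expect_equal(colSums(V), rep(0, p - 1), tolerance = 1e-12)
    x <- closure(rgamma(p, 2) + 0.1)
    expect_equal(dietmix:::.ilr_inv(dietmix:::.ilr(x)), x, tolerance = 1e-12)
  }
})
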