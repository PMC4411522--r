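make_tables <- function(seed = 1, n = 2, p = 4, samples = 3, J = 2) {
  set.seed(seed)
  fa <- paste0("FA", seq_len(p))
  prey <- data.frame(species = rep(paste0("sp", 1:n), each = samples),
                     matrix(rdiri(n * samples, p), n * samples,
                            dimnames = list(NULL, fa)), check.names = FALSE)
  pred <- data.frame(id = paste0("P", 1:J),
                     matrix(rdiri(J, p), J, dimnames = list(NULL, fa)),
                     check.names = FALSE)
  list(prey = prey, pred = pred, fa = fa)
}

test_that("diet_data validates, canonicalises column order and reports errors", {
  tb <- make_tables()
  d <- diet_data(prey_fa = tb$prey, predator_fa = tb$pred)
  expect_s3_class(d, "diet_data")
  expect_identical(d$fa_names, tb$fa)
  expect_null(d$prey_si)

  # predator columns shuffled -> loaded in canonical (prey) order
  shuffled <- tb$pred[, c("id", rev(tb$fa))]
  d2 <- diet_data(prey_fa = tb$prey, predator_fa = shuffled)
  expect_identical(colnames(d2$pred_fa), tb$fa)
  expect_equal(d2$pred_fa, d$pred_fa)

  # one species with a single sample
  bad <- tb$prey[-(1:2), ]
  expect_error(diet_data(prey_fa = bad, predator_fa = tb$pred),
               "at least 2")
  # negative proportion names row and column
  neg <- tb$prey; neg$FA2[3] <- -neg$FA2[3]
  expect_error(diet_data(prey_fa = neg, predator_fa = tb$pred),
               "negative proportion.*row 3.*FA2")
  # mismatched FA sets
  ren <- tb$pred; names(ren)[2] <- "FAx"
  expect_error(diet_data(prey_fa = tb$prey, predator_fa = ren), "differ")
})

test_that("percentage tables are detected and rescaled", {
  tb <- make_tables(2)
  pct <- tb$prey
  pct[, tb$fa] <- pct[, tb$fa] * 100
  expect_message(d <- diet_data(prey_fa = pct, predator_fa = tb$pred),
                 "percent")
  expect_equal(unname(rowSums(d$prey_fa)), rep(1, nrow(d$prey_fa)))
})

test_that("zeros are replaced multiplicatively at load", {
  tb <- make_tables(3)
  tb$prey$FA1[1] <- tb$prey$FA1[1] + tb$prey$FA3[1]
  tb$prey$FA3[1] <- 0
  d <- diet_data(prey_fa = tb$prey, predator_fa = tb$pred)
  expect_true(all(d$prey_fa > 0))
  expect_equal(unname(rowSums(d$prey_fa)), rep(1, nrow(d$prey_fa)),
               tolerance = 1e-9)
})

test_that("subset_fas re-closes rows and keeps provenance", {
  tb <- make_tables(4)
  tb$prey[1, tb$fa] <- c(0.1, 0.2, 0.3, 0.4)
  d <- diet_data(prey_fa = tb$prey, predator_fa = tb$pred)
  d2 <- subset_fas(d, c("FA1", "FA2"))
  expect_equal(unname(d2$prey_fa[1, ]), c(1 / 3, 2 / 3))
  expect_identical(d2$provenance$fa_subset, c("FA1", "FA2"))
  # subset to everything = unchanged up to re-closure
  d3 <- subset_fas(d, tb$fa)
  expect_equal(d3$prey_fa, d$prey_fa, tolerance = 1e-12)
  # subsetting twice equals one subset to the intersection
  a <- subset_fas(subset_fas(d, c("FA1", "FA2", "FA3")), c("FA1", "FA2"))
  expect_equal(a$prey_fa, d2$prey_fa, tolerance = 1e-12)
  expect_error(subset_fas(d, c("FA1", "nope")), "unknown")
})

test_that("a run-config file loads a dataset deterministically", {
  tb <- make_tables(5)
  dir <- withr::local_tempdir()
  write.csv(tb$prey, file.path(dir, "prey.csv"), row.names = FALSE)
  write.csv(tb$pred, file.path(dir, "pred.csv"), row.names = FALSE)
  cfg <- file.path(dir, "run.yml")
  writeLines(c("prey_fa: prey.csv", "predator_fa: pred.csv",
               "fa_subset: [FA1, FA2, FA3]"), cfg)
  d1 <- read_diet_data(cfg)
  d2 <- read_diet_data(cfg)
  expect_identical(d1$prey_fa, d2$prey_fa)
  expect_identical(d1$fa_names, c("FA1", "FA2", "FA3"))
  expect_error(read_diet_data({
    bad <- file.path(dir, "bad.yml")
    writeLines(c("prey_fa: missing.csv", "predator_fa: pred.csv"), bad)
    bad
  }), "missing.csv")
})

test_that("posterior draws round-trip through delimited files", {
  set.seed(6)
  a <- array(rnorm(40 * 2 * 3), c(40, 2, 3),
             dimnames = list(NULL, NULL, c("pi[sp1]", "pi[sp2]", "pi[sp3]")))
  dr <- diet_draws(a, species = paste0("sp", 1:3))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "draws.csv")
  paths <- write_posterior(dr, path)
  expect_true(all(file.exists(paths)))
  back <- read_posterior(path)
  expect_equal(back$draws, a)
  sm <- read.csv(paths[2])
  expect_equal(nrow(sm), 3)                # one summary row per parameter
  expect_error(diet_draws(array(numeric(0), c(0, 2, 3))), "empty")
})
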