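#' Specify a simulation scenario
#'
#' Defines the generative conditions for a synthetic diet study: prey
#' species separated in log-ratio space, predators mixing them with known
#' diet proportions through the same forward model the estimator assumes.
#' Defaults emulate a feasibility setting of three well-separated prey
#' species sampled 30 times each, 12 fatty acids and 2 isotopes; the
#' sensitivity axes (separation, evenness, conversion-coefficient noise,
#' collinearity) are single interpretable knobs.
#'
#' @param n_species,n_fa,n_isotopes,n_samples,n_predators problem sizes
#'   (`n_isotopes = 0` drops the SI tables).
#' @param separation pairwise distance between species mean log-profiles
#'   (alr/clr units); species means sit at the vertices of a regular simplex
#'   in the zero-sum log-abundance subspace.
#' @param within_sd within-species SD per alr coordinate.
#' @param n_discriminative if set, species differences are confined to this
#'   many fatty acids (the first `n_discriminative` in the table); the
#'   remaining FAs carry no among-species signal.  Requires at least 2.
#' @param collinearity in `[0, 1)`: mixes the last species' mean towards the
#'   midpoint of the first two, making sources progressively collinear.
#' @param pi_true population diet proportions (default: proportional to
#'   `1:n_species`).
#' @param evenness if set, per-predator diets are drawn from a symmetric
#'   Dirichlet with this concentration instead of being fixed at `pi_true`
#'   (small = specialist predators, large = generalists).
#' @param kappa_noise variance of the true conversion coefficients around 1
#'   (gamma-distributed per species and FA); the generated dataset carries
#'   matching prior tables (mean 1, variance `kappa_noise`).
#' @param kappa_true optional explicit species-by-FA matrix of true
#'   conversion coefficients (overrides `kappa_noise` draws; useful for
#'   feeding-trial simulations).
#' @param fat_true per-species relative fat content (default 1).
#' @param gamma_true species-by-isotope additive fractionation truth
#'   (default 1.0 per-mil for the first isotope, 3.4 for the second,
#'   carbon/nitrogen-like).
#' @param gamma_prior_sd SD of the fractionation priors handed to the
#'   dataset (per-mil).
#' @param si_separation,si_within_sd,si_center isotope-space geometry
#'   (per-mil).
#' @param pred_fa_noise,pred_si_noise predator residual SDs (alr units;
#'   per-mil).
#' @param mean_prey if `TRUE` predators consume species-mean prey rather
#'   than latent individual prey items.
#' @param seed mandatory integer seed.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_species = 3, n_fa = 12, n_isotopes = 2,
                          n_samples = 30, n_predators = 10,
                          separation = 2, within_sd = 0.3,
                          n_discriminative = NULL, collinearity = 0,
                          pi_true = NULL, evenness = NULL,
                          kappa_noise = 0, kappa_true = NULL, fat_true = NULL,
                          gamma_true = NULL, gamma_prior_sd = 0.3,
                          si_separation = 3, si_within_sd = 0.5,
                          si_center = c(-18, 10),
                          pred_fa_noise = 0.15, pred_si_noise = 0.5,
                          mean_prey = FALSE, seed) {
  if (missing(seed)) stop("scenario_spec: a seed is required", call. = FALSE)
  stopifnot(n_species >= 2, n_fa >= max(3, n_species), n_samples >= 2,
            n_predators >= 1, separation >= 0, within_sd > 0,
            collinearity >= 0, collinearity < 1, kappa_noise >= 0)
  if (is.null(pi_true)) pi_true <- closure(seq_len(n_species))
  stopifnot(length(pi_true) == n_species)
  if (!is.null(n_discriminative))
    stopifnot(n_discriminative >= 2, n_discriminative <= n_fa)
  if (is.null(fat_true)) fat_true <- rep(1, n_species)
  if (n_isotopes > 0 && is.null(gamma_true))
    gamma_true <- matrix(rep(c(1.0, 3.4, 0.5)[seq_len(n_isotopes)],
                             each = n_species), n_species)
  out <- as.list(environment())
  class(out) <- "scenario_spec"
  out
}

# n points with unit pairwise distances in `dims` dimensions (regular
# simplex when dims >= n-1, regular polygon otherwise).
.simplex_points <- function(n, dims) {
  if (dims >= n - 1L) {
    C <- diag(n) - 1 / n
    e <- eigen(C, symmetric = TRUE)
    pts <- e$vectors[, seq_len(n - 1L), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n - 1L)], 0)), n - 1L)
    pts <- pts / sqrt(2)                      # unit pairwise distance
    cbind(pts, matrix(0, n, dims - (n - 1L)))
  } else {
    ang <- 2 * pi * (seq_len(n) - 1L) / n
    r <- 1 / (2 * sin(pi / n))                # unit adjacent distance
    pts <- cbind(r * cos(ang), r * sin(ang))
    pts <- pts[, seq_len(min(2L, dims)), drop = FALSE]
    cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
}

# Species mean log-abundance matrix (n x p, rows to be closed).  Differences
# between species are zero-sum within the discriminative FA set, so clr
# contrasts are confined to exactly those fatty acids.
.species_log_means <- function(sp) {
  p <- sp$n_fa; n <- sp$n_species
  D <- seq_len(sp$n_discriminative %||% p)
  base <- seq(log(0.5), log(2), length.out = p)   # mildly uneven baseline
  dims <- length(D) - 1L
  pts <- .simplex_points(n, dims) * sp$separation
  Bz <- .ilr_basis(length(D))                     # zero-sum embedding
  if (dims > 1L) {                                # spread signal across D
    Q <- qr.Q(qr(matrix(stats::rnorm(dims^2), dims)))
    Bz <- Bz[, seq_len(dims), drop = FALSE] %*% Q
  }
  contrast <- pts %*% t(Bz[, seq_len(dims), drop = FALSE])
  L <- matrix(base, n, p, byrow = TRUE)
  L[, D] <- L[, D] + contrast
  if (sp$collinearity > 0) {
    if (n < 3) stop("collinearity axis needs at least 3 species", call. = FALSE)
    L[n, ] <- (1 - sp$collinearity) * L[n, ] +
      sp$collinearity * 0.5 * (L[1, ] + L[2, ])
  }
  L
}

#' Simulate a prey library
#'
#' Draws per-species FA samples multivariate-normally in alr space around
#' means placed at regular-simplex vertices scaled by the separation
#' parameter, then back-transforms to profiles; isotope samples analogously
#' in per-mil space.
#'
#' @param sp a [scenario_spec()].
#' @return list of class `prey_library`: `prey_fa`, `prey_si` (data frames
#'   in the [diet_data()] layout) and the true species means (`mu_alr`,
#'   `mean_profiles`, `mu_si`).
#' @export
simulate_prey <- function(sp) {
  stopifnot(inherits(sp, "scenario_spec"))
  set.seed(sp$seed)
  n <- sp$n_species; p <- sp$n_fa
  species <- paste0("prey", seq_len(n))
  fa_names <- paste0("FA", seq_len(p))
  L <- .species_log_means(sp)
  mean_profiles <- closure(exp(L))
  colnames(mean_profiles) <- fa_names; rownames(mean_profiles) <- species
  mu_alr <- alr(mean_profiles, p)
  X <- do.call(rbind, lapply(seq_len(n), function(s)
    alr_inv(matrix(stats::rnorm(sp$n_samples * (p - 1L), 0, sp$within_sd),
                   sp$n_samples, byrow = TRUE) +
              matrix(mu_alr[s, ], sp$n_samples, p - 1L, byrow = TRUE), p)))
  colnames(X) <- fa_names
  prey_fa <- data.frame(species = rep(species, each = sp$n_samples), X,
                        check.names = FALSE)
  out <- list(prey_fa = prey_fa, mu_alr = mu_alr,
              mean_profiles = mean_profiles, species = species,
              fa_names = fa_names)
  if (sp$n_isotopes > 0) {
    K <- sp$n_isotopes
    iso_names <- paste0("iso", seq_len(K))
    pts <- .simplex_points(n, max(K, n - 1L))[, seq_len(K), drop = FALSE]
    mu_si <- sweep(pts * sp$si_separation, 2L,
                   sp$si_center[seq_len(K)], "+")
    dimnames(mu_si) <- list(species, iso_names)
    Y <- do.call(rbind, lapply(seq_len(n), function(s)
      matrix(mu_si[s, ], sp$n_samples, K, byrow = TRUE) +
        matrix(stats::rnorm(sp$n_samples * K, 0, sp$si_within_sd),
               sp$n_samples)))
    colnames(Y) <- iso_names
    out$prey_si <- data.frame(species = rep(species, each = sp$n_samples), Y,
                              check.names = FALSE)
    out$mu_si <- mu_si
    out$iso_names <- iso_names
  }
  class(out) <- "prey_library"
  out
}

#' Simulate predator signatures from a prey library
#'
#' The forward model of the estimator: each predator's diet is either the
#' fixed population vector or a symmetric-Dirichlet draw; consumed prey
#' items are drawn from the species distributions (or fixed at the species
#' means in mean-prey mode); FA profiles mix through [compute_tau()] with
#' the true conversion coefficients and fat contents, isotopes through
#' [si_expected()] with the true fractionation; residual noise is added on
#' the alr / per-mil scale.
#'
#' @param prey a `prey_library` from [simulate_prey()].
#' @param sp the [scenario_spec()].
#' @return list of class `predator_samples`: `predator_fa`, `predator_si`
#'   data frames and the truth (`pi_true` matrix, `kappa_true`,
#'   `gamma_true`).
#' @export
simulate_predators <- function(prey, sp) {
  stopifnot(inherits(prey, "prey_library"), inherits(sp, "scenario_spec"))
  set.seed(sp$seed + 1L)
  n <- sp$n_species; p <- sp$n_fa; J <- sp$n_predators
  ids <- paste0("pred", seq_len(J))
  Pi <- if (!is.null(sp$evenness))
    .rdirichlet(J, rep(sp$evenness, n)) else
      matrix(sp$pi_true, J, n, byrow = TRUE)
  dimnames(Pi) <- list(ids, prey$species)
  kappa_true <- if (!is.null(sp$kappa_true)) {
    stopifnot(all(dim(sp$kappa_true) == c(n, p)), all(sp$kappa_true > 0))
    sp$kappa_true
  } else if (sp$kappa_noise > 0) {
    gp <- .gamma_pars(1, sp$kappa_noise)
    matrix(stats::rgamma(n * p, shape = gp$shape, rate = gp$rate), n, p)
  } else matrix(1, n, p)
  dimnames(kappa_true) <- list(prey$species, prey$fa_names)

  Tfa <- matrix(NA_real_, J, p, dimnames = list(ids, prey$fa_names))
  for (j in seq_len(J)) {
    phi <- if (sp$mean_prey) prey$mean_profiles else
      alr_inv(prey$mu_alr +
                matrix(stats::rnorm(n * (p - 1L), 0, sp$within_sd), n), p)
    tau <- compute_tau(Pi[j, ], kappa_true, phi, sp$fat_true)
    t_alr <- alr(tau, p) + stats::rnorm(p - 1L, 0, sp$pred_fa_noise)
    Tfa[j, ] <- alr_inv(t_alr, p)
  }
  out <- list(predator_fa = data.frame(id = ids, Tfa, check.names = FALSE),
              pi_true = Pi, kappa_true = kappa_true)
  if (sp$n_isotopes > 0) {
    K <- sp$n_isotopes
    Tsi <- matrix(NA_real_, J, K, dimnames = list(ids, prey$iso_names))
    for (j in seq_len(J)) {
      ysi <- if (sp$mean_prey) prey$mu_si else
        prey$mu_si + matrix(stats::rnorm(n * K, 0, sp$si_within_sd), n)
      Tsi[j, ] <- si_expected(Pi[j, ], ysi, sp$gamma_true) +
        stats::rnorm(K, 0, sp$pred_si_noise)
    }
    out$predator_si <- data.frame(id = ids, Tsi, check.names = FALSE)
    out$gamma_true <- sp$gamma_true
  }
  class(out) <- "predator_samples"
  out
}

#' Simulate a complete diet dataset with known truth
#'
#' Runs [simulate_prey()] and [simulate_predators()] and assembles a
#' validated [diet_data()] together with a truth record sufficient to score
#' any estimate.  The dataset's prior tables match the generative
#' conditions: conversion-coefficient priors with mean 1 and variance equal
#' to the scenario's `kappa_noise`, exact fat content, and fractionation
#' priors centred on the true values with SD `gamma_prior_sd`.
#'
#' @param sp a [scenario_spec()].
#' @return list of class `simulated_diet_data` with elements `data` (a
#'   `diet_data`) and `truth`.
#' @export
simulate_diet_data <- function(sp) {
  prey <- simulate_prey(sp)
  pred <- simulate_predators(prey, sp)
  n <- sp$n_species
  km <- kv <- NULL
  if (sp$kappa_noise > 0) {
    km <- data.frame(species = prey$species,
                     matrix(1, n, sp$n_fa, dimnames = list(NULL, prey$fa_names)),
                     check.names = FALSE)
    kv <- data.frame(species = prey$species,
                     matrix(sp$kappa_noise, n, sp$n_fa,
                            dimnames = list(NULL, prey$fa_names)),
                     check.names = FALSE)
  }
  fm <- fs <- NULL
  if (sp$n_isotopes > 0) {
    fm <- data.frame(species = prey$species, sp$gamma_true,
                     check.names = FALSE)
    names(fm)[-1L] <- prey$iso_names
    fs <- data.frame(species = prey$species,
                     matrix(sp$gamma_prior_sd, n, sp$n_isotopes),
                     check.names = FALSE)
    names(fs)[-1L] <- prey$iso_names
  }
  d <- diet_data(prey_fa = prey$prey_fa, predator_fa = pred$predator_fa,
                 prey_si = prey$prey_si, predator_si = pred$predator_si,
                 kappa_mean = km, kappa_var = kv,
                 fat_mean = stats::setNames(sp$fat_true, prey$species),
                 fat_var = stats::setNames(rep(0, n), prey$species),
                 frac_mean = fm, frac_sd = fs)
  truth <- list(pi_true = pred$pi_true,
                pi_pop = colMeans(pred$pi_true),
                kappa_true = pred$kappa_true,
                fat_true = sp$fat_true,
                gamma_true = pred$gamma_true,
                mu_alr = prey$mu_alr, mu_si = prey$mu_si,
                discriminative = prey$fa_names[
                  seq_len(sp$n_discriminative %||% sp$n_fa)])
  structure(list(data = d, truth = truth, spec = sp),
            class = "simulated_diet_data")
}

#' Run a grid of simulation scenarios
#'
#' For each level of one sensitivity axis and each replicate: simulate a
#' dataset, fit the population-level model, and score the posterior against
#' the truth (mean and maximum absolute error of the posterior-mean diet
#' proportions, and 90% credible-interval coverage).  Fully deterministic
#' given the base seed.
#'
#' @param base a [scenario_spec()] providing all non-varied conditions.
#' @param axis one of `"separation"`, `"evenness"`, `"kappa_noise"`,
#'   `"collinearity"`.
#' @param levels numeric vector of axis values.
#' @param replicates replicate datasets per level (seeds derived from the
#'   base seed).
#' @param markers,consumed,mcmc fitting options passed to [fit_diet()]; the
#'   defaults (marginal consumed-prey mode, short chains) are sized for
#'   scenario sweeps.
#' @return data frame with one row per level and replicate: `axis`, `level`,
#'   `replicate`, `seed`, `mae`, `max_err`, `coverage90`.
#' @export
run_scenario_grid <- function(base, axis = c("separation", "evenness",
                                             "kappa_noise", "collinearity"),
                              levels, replicates = 1,
                              markers = "fa", consumed = "marginal",
                              mcmc = mcmc_control(n_chains = 2, n_iter = 2500)) {
  stopifnot(inherits(base, "scenario_spec"))
  axis <- match.arg(axis)
  rows <- list()
  for (il in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      sp <- base
      sp[[axis]] <- levels[il]
      sp$seed <- base$seed + 7919L * (il - 1L) + 101L * (r - 1L)
      sim <- simulate_diet_data(sp)
      fit <- suppressWarnings(
        fit_diet(sim$data, markers = markers, grouping = "population",
                 consumed = consumed, mcmc = mcmc, seed = sp$seed))
      sm <- fit$summary
      sp_names <- sim$data$species
      ix <- match(paste0("pi[", sp_names, "]"), sm$parameter)
      err <- abs(sm$mean[ix] - sim$truth$pi_pop)
      cov <- mean(sm$lower_0.9[ix] <= sim$truth$pi_pop &
                    sim$truth$pi_pop <= sm$upper_0.9[ix])
      rows[[length(rows) + 1L]] <-
        data.frame(axis = axis, level = levels[il], replicate = r,
                   seed = sp$seed, mae = mean(err), max_err = max(err),
                   coverage90 = cov)
    }
  }
  do.call(rbind, rows)
}
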