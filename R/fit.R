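#' Sampler settings
#'
#' @param n_chains number of chains (default 3).
#' @param n_iter iterations per chain including warmup (default 20000).
#' @param n_warmup warmup iterations with proposal-scale adaptation
#'   (default half of `n_iter`).
#' @param thin keep every `thin`-th post-warmup draw.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3, n_iter = 20000,
                         n_warmup = floor(n_iter / 2), thin = 1) {
  stopifnot(n_chains >= 1, n_iter > n_warmup, n_warmup >= 0, thin >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
                 thin = thin), class = "mcmc_control")
}

#' Fit a Bayesian diet mixing model
#'
#' Estimates predator diet proportions from fatty-acid profiles, stable
#' isotopes, or both jointly.  Predator FA profiles are modelled as draws
#' around the additive-log-ratio transform of the closure-normalised mixture
#' of consumed prey profiles, weighted by diet proportions, prey fat content
#' and per-FA conversion coefficients; isotope signatures as draws around the
#' linear mixture of consumed prey values shifted by additive fractionation.
#' Diet proportions may be shared by all predators (`"population"`, Dirichlet
#' prior), vary by predator around a population distribution in log-ratio
#' space (`"individual"`), or follow a design-matrix mean (`"linear"`, via
#' `formula` over the covariate table in the data).
#'
#' @param data a [diet_data()] object.
#' @param markers `"fa"`, `"si"`, or `"both"`.
#' @param grouping `"population"`, `"individual"`, or `"linear"`.
#' @param formula covariate formula for `grouping = "linear"`.
#' @param latent_prey sample latent consumed prey items (default) or use the
#'   faster species-mean ("mean-prey") approximation.
#' @param consumed `"latent"`, `"mean"`, or `"marginal"` (latents integrated
#'   out of the predator likelihood; see [model_spec()]).  Overrides
#'   `latent_prey` when supplied.
#' @param prior a [prior_control()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed; the triple (data, settings, seed) fully
#'   determines the draws.
#' @param fixed advanced: named list of parameter blocks to fix (see
#'   [model_spec()]).
#' @return an object of class `diet_fit` with components `draws`
#'   (a [diet_draws]), `model`, `summary`, and the matched call.  Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `simulate`, `plot`.
#' @examples
#' \donttest{
#' sc <- scenario_spec(n_species = 2, n_fa = 5, n_samples = 10,
#'                     n_predators = 4, seed = 7)
#' d <- simulate_diet_data(sc)
#' fit <- fit_diet(d$data, markers = "fa", latent_prey = FALSE,
#'                 mcmc = mcmc_control(n_chains = 2, n_iter = 1500), seed = 1)
#' coef(fit)
#' }
#' @export
fit_diet <- function(data, markers = c("fa", "si", "both"),
                     grouping = c("population", "individual", "linear"),
                     formula = NULL, latent_prey = TRUE, consumed = NULL,
                     prior = prior_control(), mcmc = mcmc_control(),
                     seed = 1L, fixed = list()) {
  markers <- match.arg(markers)
  grouping <- match.arg(grouping)
  spec <- model_spec(markers = markers, grouping = grouping, formula = formula,
                     latent_prey = latent_prey, consumed = consumed,
                     prior = prior, fixed = fixed)
  model <- build_model(data, spec)
  draws <- run_chains(model, n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                      n_warmup = mcmc$n_warmup, thin = mcmc$thin, seed = seed)
  smry <- summarize_draws(draws)
  if (!is.null(smry$rhat) && max(smry$rhat) > 1.1)
    warning("fit_diet: max split-Rhat = ", round(max(smry$rhat), 3),
            " > 1.1; increase n_iter or adjust covariance prior scales",
            call. = FALSE)
  structure(list(draws = draws, model = model, summary = smry,
                 data = data, spec = spec, seed = seed, mcmc = mcmc,
                 call = match.call()),
            class = "diet_fit")
}

#' @export
print.diet_fit <- function(x, ...) {
  cat("Bayesian diet mixing model (", x$spec$markers, " markers, ",
      x$spec$grouping, " grouping, ",
      c(latent = "latent-prey", mean = "mean-prey",
        marginal = "marginal-prey")[x$spec$consumed], " mode)\n",
      sep = "")
  cat("Species:", paste(x$model$species, collapse = ", "), "\n")
  cm <- coef(x)
  cat("\nPosterior mean diet proportions:\n")
  if (is.matrix(cm)) print(round(cm, 3)) else print(round(cm, 3))
  if (!is.null(x$summary$rhat))
    cat("\nmax split-Rhat:", round(max(x$summary$rhat), 3),
        "| min ESS:", round(min(x$summary$ess)), "\n")
  invisible(x)
}

#' @export
summary.diet_fit <- function(object, levels = c(0.9, 0.95), ...) {
  summarize_draws(object$draws, levels)
}

#' Posterior mean diet proportions
#'
#' For population models, a named vector over species; for individual and
#' linear models, a predator-by-species matrix of posterior means (the
#' population-level composition is available in the summary under
#' `pi_pop[...]`).
#'
#' @param object a `diet_fit`.
#' @param ... unused.
#' @export
coef.diet_fit <- function(object, ...) {
  sm <- object$summary
  sp <- object$model$species
  if (object$spec$grouping == "population") {
    ix <- match(paste0("pi[", sp, "]"), sm$parameter)
    return(stats::setNames(sm$mean[ix], sp))
  }
  ids <- object$model$ids
  out <- matrix(NA_real_, length(ids), length(sp), dimnames = list(ids, sp))
  for (s in sp)
    out[, s] <- sm$mean[match(paste0("pi[", ids, ",", s, "]"), sm$parameter)]
  out
}

# Plug-in state from the accumulated posterior means of all blocks.
.plugin_state <- function(object) {
  st <- object$draws$plugin
  st$pi <- if (object$spec$grouping == "population" &&
               !is.matrix(st$pi)) closure(st$pi) else closure(st$pi)
  .refresh_caches(object$model, st)
}

#' Fitted predator signatures
#'
#' Plug-in expected predator signatures at the posterior means of all model
#' blocks: the alr of the expected FA mixture and/or the expected isotope
#' values, per predator.
#'
#' @param object a `diet_fit`.
#' @param ... unused.
#' @return a list with elements `fa` (predators x alr coordinates) and/or
#'   `si` (predators x isotopes).
#' @export
fitted.diet_fit <- function(object, ...) {
  m <- object$model
  st <- .plugin_state(object)
  out <- list()
  if (m$use_fa) {
    fa <- .tau_alr(m, st)
    if (!is.matrix(fa)) fa <- matrix(fa, nrow(m$T), m$dfa, byrow = TRUE)
    rownames(fa) <- m$data$pred_fa_ids %||% rownames(m$T)
    colnames(fa) <- colnames(m$T)
    out$fa <- fa
  }
  if (m$use_si) {
    si <- .si_mean(m, st)
    if (!is.matrix(si)) si <- matrix(si, nrow(m$Tsi), m$K, byrow = TRUE)
    rownames(si) <- m$data$pred_si_ids
    colnames(si) <- m$data$iso_names
    out$si <- si
  }
  out
}

#' Residual predator signatures
#'
#' Observed minus fitted predator signatures (alr scale for FA, per-mil for
#' isotopes) at the plug-in posterior means.
#'
#' @inheritParams fitted.diet_fit
#' @export
residuals.diet_fit <- function(object, ...) {
  f <- fitted(object)
  m <- object$model
  out <- list()
  if (!is.null(f$fa)) out$fa <- m$T - f$fa
  if (!is.null(f$si)) out$si <- m$Tsi - f$si
  out
}

#' Predict diet proportions for new covariate values
#'
#' For linear-model fits: posterior draws of the diet composition at each row
#' of `newdata` are obtained by pushing the design row through the posterior
#' draws of the regression coefficients and back-transforming; their
#' posterior means are returned.  For other groupings, returns [coef()].
#'
#' @param object a `diet_fit`.
#' @param newdata data frame of covariates (linear grouping only).
#' @param ... unused.
#' @export
predict.diet_fit <- function(object, newdata = NULL, ...) {
  if (object$spec$grouping != "linear" || is.null(newdata))
    return(coef(object))
  m <- object$model
  X <- stats::model.matrix(object$spec$formula, newdata)
  D <- .draws_matrix(object$draws)
  bcols <- grep("^B\\[", colnames(D))
  out <- matrix(0, nrow(X), m$n, dimnames = list(rownames(newdata), m$species))
  for (i in seq_len(nrow(X))) {
    pis <- t(apply(D[, bcols, drop = FALSE], 1L, function(b) {
      B <- matrix(b, m$q, m$n - 1L)
      .ilr_inv(as.vector(X[i, ] %*% B), m$V)
    }))
    out[i, ] <- colMeans(pis)
  }
  out
}

#' Simulate predator signatures from the fitted model
#'
#' Posterior-predictive draws at the plug-in posterior means: expected
#' signatures plus residual noise from the fitted residual covariances.
#'
#' @param object a `diet_fit`.
#' @param nsim number of replicate predator sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` lists with elements `fa` (profiles on the
#'   proportion scale) and/or `si`.
#' @export
simulate.diet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$model
  st <- .plugin_state(object)
  f <- fitted(object)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    one <- list()
    if (!is.null(f$fa)) {
      U <- chol(st$Sigma_tau)
      Y <- f$fa + matrix(stats::rnorm(length(f$fa)), nrow(f$fa)) %*% U
      one$fa <- alr_inv(Y, m$ref)
      colnames(one$fa) <- m$data$fa_names
    }
    if (!is.null(f$si)) {
      U <- chol(st$Sigma_tau_si)
      one$si <- f$si + matrix(stats::rnorm(length(f$si)), nrow(f$si)) %*% U
    }
    out[[k]] <- one
  }
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.diet_fit <- function(x, ...) {
  plot(x$draws, ...)
}

#' Estimate conversion coefficients from a feeding trial
#'
#' When predators have been fed known diets, the FA mixing model can be
#' inverted to estimate the per-FA conversion coefficients: diet proportions
#' are held fixed at the known values and the coefficients are sampled under
#' vague moment-matched gamma priors.  Because the closure makes the
#' coefficients identifiable only up to a multiplicative constant, posterior
#' draws are reported closure-normalised per species.
#'
#' @param data a [diet_data()] with FA tables from the feeding trial.
#' @param known_pi known diet composition: a vector over species (shared by
#'   all trial predators) or a predator-by-species matrix.
#' @param kappa_prior_var prior variance of the vague gamma prior
#'   (mean 1) on each coefficient.
#' @param latent_prey as in [fit_diet()].
#' @param prior,mcmc,seed as in [fit_diet()].
#' @return a `diet_fit` whose draws are the closure-normalised coefficients;
#'   use [as_kappa_priors()] to turn them into prior tables for a later diet
#'   analysis.
#' @export
estimate_conversion_coefficients <- function(data, known_pi,
                                             kappa_prior_var = 4,
                                             latent_prey = FALSE,
                                             prior = prior_control(),
                                             mcmc = mcmc_control(),
                                             seed = 1L) {
  stopifnot(inherits(data, "diet_data"))
  n <- data$n_species
  J <- nrow(data$pred_fa)
  if (J < 2L)
    warning("estimate_conversion_coefficients: fewer than 2 trial predators; ",
            "coefficients will be weakly identified", call. = FALSE)
  if (is.matrix(known_pi)) {
    stopifnot(nrow(known_pi) == J, ncol(known_pi) == n)
  } else {
    stopifnot(length(known_pi) == n)
    known_pi <- matrix(known_pi, J, n, byrow = TRUE)
  }
  known_pi <- closure(known_pi)
  colnames(known_pi) <- data$species
  # vague gamma priors, mean 1, on every coefficient
  data$kappa_mean[] <- 1
  data$kappa_var[] <- kappa_prior_var
  fit_diet(data, markers = "fa", grouping = "population",
           latent_prey = latent_prey, prior = prior, mcmc = mcmc, seed = seed,
           fixed = list(pi = known_pi))
}

#' Turn a feeding-trial fit into conversion-coefficient prior tables
#'
#' Posterior moments of the closure-normalised coefficients, rescaled by the
#' number of FAs so a neutral coefficient is 1, in the layout accepted by
#' [diet_data()].
#'
#' @param fit result of [estimate_conversion_coefficients()].
#' @return list with `kappa_mean` and `kappa_var` data frames.
#' @export
as_kappa_priors <- function(fit) {
  stopifnot(inherits(fit, "diet_fit"))
  sm <- fit$summary
  sp <- fit$model$species
  fa <- fit$data$fa_names
  p <- length(fa)
  km <- kv <- matrix(NA_real_, length(sp), p, dimnames = list(sp, fa))
  for (s in sp) {
    ix <- match(paste0("kappa[", s, ",", fa, "]"), sm$parameter)
    km[s, ] <- p * sm$mean[ix]
    kv[s, ] <- (p * sm$sd[ix])^2
  }
  list(kappa_mean = data.frame(species = sp, km, check.names = FALSE),
       kappa_var = data.frame(species = sp, kv, check.names = FALSE))
}
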