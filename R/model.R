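#' Prior settings for diet mixing models
#'
#' Collects the tunable prior hyperparameters.  Covariance matrices get
#' inverse-Wishart priors with degrees of freedom `dimension + 2` and a
#' scaled identity scale matrix; the scale arguments set the order of
#' magnitude of the diagonal, the one knob that in practice needs manual
#' adjustment to obtain good MCMC mixing when samples are few.
#'
#' @param alpha symmetric Dirichlet concentration for population-level diet
#'   proportions (1 = flat over the simplex).
#' @param mu_sd prior SD for prey alr-space means (vague, alr units).
#' @param mu_si_sd prior SD for prey isotope means (vague, per-mil).
#' @param sigma_prey_scale,sigma_pred_scale diagonal scale of the
#'   inverse-Wishart priors for the prey alr covariance and the predator
#'   alr residual covariance.
#' @param sigma_diet_scale diagonal scale for the between-predator diet
#'   covariance (hierarchical / linear-model formulations).
#' @param sigma_si_prey_scale,sigma_si_pred_scale analogous diagonal scales
#'   for the isotope covariances (per-mil squared).
#' @return a list of class `prior_control`.
#' @export
prior_control <- function(alpha = 1, mu_sd = 10, mu_si_sd = 100,
                          sigma_prey_scale = 0.1, sigma_pred_scale = 0.01,
                          sigma_diet_scale = 0.1,
                          sigma_si_prey_scale = 1, sigma_si_pred_scale = 0.1) {
  out <- as.list(environment())
  stopifnot(alpha > 0, mu_sd > 0, all(unlist(out[-(1:2)]) > 0))
  class(out) <- "prior_control"
  out
}

#' Declare a diet mixing model
#'
#' A declarative description of which model to build: which markers enter the
#' likelihood, how diet proportions are structured across predators, and
#' whether predators consume latent individual prey or species-mean prey.
#'
#' @param markers `"fa"`, `"si"`, or `"both"` (joint model; diet proportions
#'   are shared between the two likelihoods).
#' @param grouping `"population"` (one diet vector, Dirichlet prior),
#'   `"individual"` (per-predator diets drawn from a population distribution
#'   in log-ratio space), or `"linear"` (per-predator diets with a
#'   design-matrix mean; requires `formula` and a covariate table in the
#'   data).
#' @param formula right-hand-side formula over the predator covariate table,
#'   for `grouping = "linear"`.
#' @param latent_prey if `TRUE` (default) predators consume latent prey items
#'   drawn from the estimated species distributions; if `FALSE` the faster
#'   "mean-prey" approximation substitutes the species mean profile.
#' @param consumed finer-grained control over the consumed-prey treatment:
#'   `"latent"` and `"mean"` correspond to `latent_prey = TRUE/FALSE`;
#'   `"marginal"` integrates the latent consumed prey out of the predator
#'   likelihood — exactly for isotopes (linear mixing), to first order for
#'   fatty acids (delta method through the mixing Jacobian) — giving
#'   mean-prey speed with latent-model calibration.  Population grouping
#'   only.  Overrides `latent_prey` when supplied.
#' @param prior a [prior_control()] object.
#' @param fixed named list of parameter blocks to hold fixed instead of
#'   sampling: any of `pi` (diet proportions, vector or predator-by-species
#'   matrix), `mu`, `Sigma` (lists per species), `Sigma_tau`, `kappa`, `Phi`,
#'   `gamma`, `mu_si`, `Sigma_si`, `Sigma_tau_si`.  Mainly for feeding-trial
#'   coefficient estimation and for validation against low-dimensional
#'   reference posteriors.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(markers = c("fa", "si", "both"),
                       grouping = c("population", "individual", "linear"),
                       formula = NULL, latent_prey = TRUE,
                       prior = prior_control(), fixed = list(),
                       consumed = NULL) {
  markers <- match.arg(markers)
  grouping <- match.arg(grouping)
  if (is.null(consumed)) consumed <- if (isTRUE(latent_prey)) "latent" else "mean"
  consumed <- match.arg(consumed, c("latent", "mean", "marginal"))
  if (consumed == "marginal" && grouping != "population")
    stop("model_spec: the marginal consumed-prey mode supports population ",
         "grouping only", call. = FALSE)
  if (grouping == "linear" && is.null(formula) && is.null(fixed$pi))
    stop("model_spec: grouping = 'linear' requires a formula", call. = FALSE)
  structure(list(markers = markers, grouping = grouping, formula = formula,
                 latent_prey = consumed == "latent", consumed = consumed,
                 prior = prior, fixed = fixed),
            class = "model_spec")
}

#' Expected predator fatty-acid profile of a mixed diet
#'
#' The forward mixing rule: the predator's expected FA profile is the
#' closure of the fat-content-weighted, conversion-scaled sum of consumed
#' prey profiles,
#' \deqn{\tau = C\{ \sum_s (\pi_s \Phi_s) (\kappa_s \odot \phi_s) \}.}
#' Because the closure absorbs any common scale, both \eqn{\kappa} and
#' \eqn{\Phi} act only through ratios.
#'
#' @param pi diet proportions over the `n` prey species.
#' @param kappa `n x p` matrix of positive conversion coefficients.
#' @param phi `n x p` matrix whose rows are the consumed prey FA profiles.
#' @param fat length-`n` vector of positive relative fat contents.
#' @return a composition of `p` parts.
#' @export
compute_tau <- function(pi, kappa, phi, fat = rep(1, length(pi))) {
  n <- length(pi)
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = n)
  if (!is.matrix(kappa)) kappa <- matrix(kappa, n, ncol(phi))
  stopifnot(nrow(phi) == n, nrow(kappa) == n, ncol(kappa) == ncol(phi),
            length(fat) == n)
  pre <- as.vector(crossprod(kappa * phi, pi * fat))
  if (all(pre == 0)) stop("compute_tau: mixture collapses to zero", call. = FALSE)
  closure(pre)
}

#' Expected predator stable-isotope signature of a mixed diet
#'
#' Linear mixing with additive trophic fractionation:
#' \eqn{t = \sum_s \pi_s (y_s + \gamma_s)} per isotope.
#'
#' @param pi diet proportions over `n` prey species.
#' @param prey_si `n x k` matrix of consumed prey isotope values (per-mil).
#' @param gamma `n x k` matrix of additive fractionation coefficients.
#' @return length-`k` vector of expected isotope values.
#' @export
si_expected <- function(pi, prey_si, gamma = 0 * prey_si) {
  if (!is.matrix(prey_si)) prey_si <- matrix(prey_si, nrow = length(pi))
  if (!is.matrix(gamma)) gamma <- matrix(gamma, nrow = length(pi))
  stopifnot(nrow(prey_si) == length(pi), all(dim(gamma) == dim(prey_si)))
  as.vector(crossprod(prey_si + gamma, pi))
}

# ---------------------------------------------------------------------------
# Model assembly.  build_model() precomputes alr-transformed data and prior
# parametrisations and returns a `diet_model`: a log-posterior over a flat
# unconstrained parameter vector plus the block structure the sampler uses.
# ---------------------------------------------------------------------------

#' Build the log-posterior for a diet mixing model
#'
#' Assembles prior and likelihood terms for the requested marker set and
#' grouping into a single object: a callable log-density over a flat
#' unconstrained parameter vector, a parameter name map, and the block
#' structure used by [run_chains()].
#'
#' @param d a `diet_data` object.
#' @param spec a [model_spec()].
#' @return an object of class `diet_model` with elements `dim`, `param_map`,
#'   `fn` (the flat-vector log posterior; `-Inf` exactly on constraint
#'   violations) and internals consumed by the sampler.
#' @export
build_model <- function(d, spec = model_spec()) {
  stopifnot(inherits(d, "diet_data"), inherits(spec, "model_spec"))
  use_fa <- spec$markers %in% c("fa", "both")
  use_si <- spec$markers %in% c("si", "both")
  if (use_fa && is.null(d$prey_fa))
    stop("build_model: FA model requested but dataset has no FA tables",
         call. = FALSE)
  if (use_si && is.null(d$prey_si))
    stop("build_model: SI model requested but dataset has no SI tables",
         call. = FALSE)
  if (use_si && is.null(d$frac_mean))
    stop("build_model: SI model requested without fractionation priors ",
         "(frac_mean/frac_sd); supply them in diet_data()", call. = FALSE)

  n <- d$n_species
  m <- list(data = d, spec = spec, n = n, species = d$species,
            use_fa = use_fa, use_si = use_si,
            V = .ilr_basis(n), prior = spec$prior, fixed = spec$fixed)

  if (use_fa) {
    p <- length(d$fa_names); ref <- d$alr_ref
    m$p <- p; m$ref <- ref; m$dfa <- p - 1L
    m$Y <- lapply(seq_len(n), function(s)
      alr(d$prey_fa[d$prey_fa_species == d$species[s], , drop = FALSE], ref))
    m$Nfa <- vapply(m$Y, nrow, 1L)
    m$ybar <- lapply(m$Y, colMeans)
    m$T <- alr(d$pred_fa, ref)
    m$Jfa <- nrow(m$T)
    m$kap_shape <- m$kap_rate <- matrix(NA_real_, n, p)
    m$kap_mask <- d$kappa_var > 0
    gp <- .gamma_pars(d$kappa_mean[m$kap_mask], d$kappa_var[m$kap_mask])
    m$kap_shape[m$kap_mask] <- gp$shape
    m$kap_rate[m$kap_mask] <- gp$rate
    m$phi_mask <- d$fat_var > 0
    if (any(m$phi_mask)) {
      lp <- .lnorm_pars(d$fat_mean[m$phi_mask], d$fat_var[m$phi_mask])
      m$fat_meanlog <- rep(NA_real_, n); m$fat_sdlog <- rep(NA_real_, n)
      m$fat_meanlog[m$phi_mask] <- lp$meanlog
      m$fat_sdlog[m$phi_mask] <- lp$sdlog
    }
  }
  if (use_si) {
    K <- length(d$iso_names)
    m$K <- K
    m$Ysi <- lapply(seq_len(n), function(s)
      d$prey_si[d$prey_si_species == d$species[s], , drop = FALSE])
    m$Nsi <- vapply(m$Ysi, nrow, 1L)
    m$ysibar <- lapply(m$Ysi, colMeans)
    m$Tsi <- d$pred_si
    m$Jsi <- nrow(m$Tsi)
    m$gam_mask <- d$frac_sd > 0
  }

  # predators carrying individual diet vectors
  if (spec$grouping == "population") {
    m$J <- 1L
  } else {
    if (use_fa && use_si) {
      if (!setequal(d$pred_fa_ids, d$pred_si_ids))
        stop("build_model: individual/linear joint models need matching ",
             "predator ids across FA and SI tables", call. = FALSE)
      m$Tsi <- m$Tsi[match(d$pred_fa_ids, d$pred_si_ids), , drop = FALSE]
      m$ids <- d$pred_fa_ids
    } else m$ids <- if (use_fa) d$pred_fa_ids else d$pred_si_ids
    m$J <- length(m$ids)
    if (spec$grouping == "linear") {
      if (is.null(d$covariates))
        stop("build_model: linear grouping requires a covariate table",
             call. = FALSE)
      cv <- d$covariates[match(m$ids, d$covariates$id), , drop = FALSE]
      m$X <- stats::model.matrix(spec$formula, cv)
      m$q <- ncol(m$X)
    }
  }
  if (!is.null(spec$fixed$pi) && is.matrix(spec$fixed$pi))
    m$J <- nrow(spec$fixed$pi)

  m <- .model_layout(m)
  class(m) <- "diet_model"
  m$fn <- function(theta) .flat_logpost(m, theta)
  m
}

# Flat parameter layout: named blocks with unconstrained dimensions.
.model_layout <- function(m) {
  spec <- m$spec; n <- m$n; fx <- m$fixed
  lay <- list()
  add <- function(lay, name, d) { lay[[name]] <- d; lay }
  if (is.null(fx$pi)) {
    if (spec$grouping == "population") {
      lay <- add(lay, "z", n - 1L)
    } else {
      for (j in seq_len(m$J)) lay <- add(lay, paste0("z.", j), n - 1L)
      if (spec$grouping == "individual") lay <- add(lay, "Pi", n - 1L)
      if (spec$grouping == "linear") lay <- add(lay, "B", m$q * (n - 1L))
      lay <- add(lay, "Sigma_Pi", (n - 1L) * n / 2)
    }
  }
  if (m$use_fa) {
    dfa <- m$dfa
    for (s in seq_len(n)) if (is.null(fx$mu)) lay <- add(lay, paste0("mu.", s), dfa)
    for (s in seq_len(n)) if (is.null(fx$Sigma))
      lay <- add(lay, paste0("Sigma.", s), dfa * (dfa + 1L) / 2)
    if (is.null(fx$Sigma_tau)) lay <- add(lay, "Sigma_tau", dfa * (dfa + 1L) / 2)
    if (is.null(fx$kappa)) for (s in seq_len(n)) if (any(m$kap_mask[s, ]))
      lay <- add(lay, paste0("kappa.", s), sum(m$kap_mask[s, ]))
    if (is.null(fx$Phi) && any(m$phi_mask)) lay <- add(lay, "Phi", sum(m$phi_mask))
    if (spec$latent_prey) {
      Jl <- if (spec$grouping == "population") m$Jfa else m$J
      for (j in seq_len(Jl)) for (s in seq_len(n))
        lay <- add(lay, paste0("phi_lat.", j, ".", s), dfa)
    }
  }
  if (m$use_si) {
    K <- m$K
    for (s in seq_len(n)) if (is.null(fx$mu_si)) lay <- add(lay, paste0("mu_si.", s), K)
    for (s in seq_len(n)) if (is.null(fx$Sigma_si))
      lay <- add(lay, paste0("Sigma_si.", s), K * (K + 1L) / 2)
    if (is.null(fx$Sigma_tau_si)) lay <- add(lay, "Sigma_tau_si", K * (K + 1L) / 2)
    if (is.null(fx$gamma) && any(m$gam_mask)) lay <- add(lay, "gamma", sum(m$gam_mask))
    if (spec$latent_prey) {
      Jl <- if (spec$grouping == "population") m$Jsi else m$J
      for (j in seq_len(Jl)) for (s in seq_len(n))
        lay <- add(lay, paste0("si_lat.", j, ".", s), K)
    }
  }
  m$layout <- lay
  m$dim <- sum(unlist(lay))
  idx <- vector("list", length(lay)); names(idx) <- names(lay)
  at <- 0L
  for (nm in names(lay)) { idx[[nm]] <- at + seq_len(lay[[nm]]); at <- at + lay[[nm]] }
  m$index <- idx
  m$param_map <- unlist(lapply(names(lay), function(nm)
    paste0(nm, "[", seq_len(lay[[nm]]), "]")))
  m
}

# ---------------------------------------------------------------------------
# States.  A state is a plain list in natural parameter space:
#   pi      n vector (population) or J x n matrix
#   mu, Sigma, mu_si, Sigma_si   lists per species (mu_si as n x K matrix)
#   Sigma_tau, Sigma_tau_si      matrices
#   kappa   n x p, Phi  n vector, gamma  n x K
#   phi_lat list per species of J x (p-1) alr coordinates of consumed prey
#   si_lat  list per species of J x K consumed isotope values
#   Pi, Sigma_Pi, B              diet hyper-parameters
# plus derived caches added by .refresh_caches().
# ---------------------------------------------------------------------------

.refresh_caches <- function(m, st) {
  if (m$use_fa) {
    st$Sigma_chol <- lapply(st$Sigma, .chol_or_null)
    st$Sigma_tau_chol <- .chol_or_null(st$Sigma_tau)
    if (!m$spec$latent_prey) {
      phimat <- t(vapply(st$mu, function(mm) alr_inv(mm, m$ref), numeric(m$p)))
      st$A <- st$kappa * phimat
    } else {
      st$philat_comp <- lapply(st$phi_lat, function(Z) .alr_inv_rows(Z, m$ref))
      st$Acons <- lapply(seq_len(m$n), function(s)
        sweep(st$philat_comp[[s]], 2L, st$kappa[s, ], "*"))
      st <- .recompute_pre(m, st)
    }
  }
  if (m$use_si) {
    st$Sigma_si_chol <- lapply(st$Sigma_si, .chol_or_null)
    st$Sigma_tau_si_chol <- .chol_or_null(st$Sigma_tau_si)
    st$Sigma_si_inv <- lapply(st$Sigma_si_chol, function(U)
      if (is.null(U)) NULL else chol2inv(U))
    st$Sigma_tau_si_inv <- if (is.null(st$Sigma_tau_si_chol)) NULL else
      chol2inv(st$Sigma_tau_si_chol)
  }
  if (!is.null(st$Sigma_Pi)) st$Sigma_Pi_chol <- .chol_or_null(st$Sigma_Pi)
  st
}

# Pi as a J x n matrix of per-predator diet proportions (rows repeated for
# population grouping).
.pi_matrix <- function(m, st, J) {
  if (is.matrix(st$pi)) st$pi else matrix(st$pi, J, m$n, byrow = TRUE)
}

# Latent-mode cache: the pre-closure predator mixture, one row per predator.
# Maintained incrementally by the sampler's mutators; rebuilt here.
.recompute_pre <- function(m, st) {
  J <- if (m$spec$grouping == "population") m$Jfa else m$J
  Pi <- .pi_matrix(m, st, J)
  pre <- matrix(0, J, m$p)
  for (s in seq_len(m$n))
    pre <- pre + (Pi[, s] * st$Phi[s]) * st$Acons[[s]]
  st$pre <- pre
  st
}

# alr of expected predator FA profiles, J x (p-1).  alr is scale invariant,
# so the closure in the mixing rule can be skipped.
.tau_alr <- function(m, st, j = NULL) {
  J <- if (m$spec$grouping == "population") m$Jfa else m$J
  if (!m$spec$latent_prey) {
    if (!is.matrix(st$pi)) {
      # shared diet, mean-prey source matrix: one mean vector for all
      # predators (callers accept a vector in place of identical rows)
      pre <- as.vector(crossprod(st$A, st$pi * st$Phi))
      lg <- log(pre)
      return(lg[-m$ref] - lg[m$ref])
    }
    W <- sweep(st$pi, 2L, st$Phi, "*")
    if (!is.null(j)) {
      pre <- as.vector(crossprod(st$A, W[j, ]))
      lg <- log(pre)
      return(lg[-m$ref] - lg[m$ref])
    }
    pre <- W %*% st$A
  } else {
    pre <- st$pre
    if (!is.null(j)) {
      lg <- log(pre[j, ])
      return(lg[-m$ref] - lg[m$ref])
    }
  }
  lg <- log(pre)
  lg[, -m$ref, drop = FALSE] - lg[, m$ref]
}

# Expected predator SI signatures, J x K.
.si_mean <- function(m, st, j = NULL) {
  J <- if (m$spec$grouping == "population") m$Jsi else m$J
  if (!m$spec$latent_prey) {
    src <- st$mu_si + st$gamma                      # n x K
    if (!is.matrix(st$pi)) {
      return(as.vector(crossprod(src, st$pi)))      # shared expected row
    }
    if (!is.null(j)) return(as.vector(crossprod(src, st$pi[j, ])))
    return(st$pi %*% src)
  }
  Pi <- .pi_matrix(m, st, J)
  if (!is.null(j)) {
    out <- numeric(m$K)
    for (s in seq_len(m$n))
      out <- out + Pi[j, s] * (st$si_lat[[s]][j, ] + st$gamma[s, ])
    return(out)
  }
  out <- matrix(0, J, m$K)
  for (s in seq_len(m$n))
    out <- out + Pi[, s] * sweep(st$si_lat[[s]], 2L, st$gamma[s, ], "+")
  out
}

# Delta-method covariance of the alr predator mixture induced by latent
# consumed prey variation: C = sum_s J_s Sigma_s J_s', with J_s the Jacobian
# of alr(mixture) with respect to the alr coordinates of species s' consumed
# profile, evaluated at the species means.
.latent_mix_cov <- function(m, st) .marginal_parts(m, st)$C

# Shared computation for the marginal consumed-prey mode: delta-method
# covariance C and second-order mean correction, from one pass over the
# species.
.marginal_parts <- function(m, st) {
  w <- as.vector(st$pi) * st$Phi
  x <- as.vector(crossprod(st$A, w))          # pre-closure mixture
  nonref <- setdiff(seq_len(m$p), m$ref)
  C <- matrix(0, m$dfa, m$dfa)
  corr <- numeric(m$dfa)
  for (s in seq_len(m$n)) {
    phis <- st$A[s, ] / st$kappa[s, ]         # consumed profile (species mean)
    a <- w[s] * st$kappa[s, ] * phis / x
    # J_s = diag(a) - u v' with u = a - a_ref, v = consumed profile;
    # expand J S J' without forming J
    anr <- a[nonref]
    aref <- a[m$ref]
    u <- anr - aref
    v <- phis[nonref]
    S <- st$Sigma[[s]]
    sv <- as.vector(S %*% v)
    q <- sum(v * sv)
    t1 <- tcrossprod(anr * sv, u)
    C <- C + S * tcrossprod(anr) - t1 - t(t1) + q * tcrossprod(u)
    dS <- diag(S)
    sdd <- sum(v * dS)
    tr_k <- anr * (dS - 2 * sv - sdd + 2 * q) - anr^2 * (dS - 2 * sv + q)
    tr_ref <- aref * (2 * q - sdd) - aref^2 * q
    corr <- corr + 0.5 * (tr_k - tr_ref)
  }
  list(C = C, corr = corr)
}

# Exact marginal covariance of the predator isotope mixture.
.si_mix_cov <- function(m, st) {
  pi2 <- as.vector(st$pi)^2
  C <- matrix(0, m$K, m$K)
  for (s in seq_len(m$n)) C <- C + pi2[s] * st$Sigma_si[[s]]
  C
}

# -- likelihood factors -----------------------------------------------------

.ll_prey_fa <- function(m, st, s) {
  U <- st$Sigma_chol[[s]]
  if (is.null(U)) return(-Inf)
  .ldmvnorm_rows(m$Y[[s]], st$mu[[s]], U)
}

.ll_lat_fa <- function(m, st, s, j = NULL) {
  U <- st$Sigma_chol[[s]]
  if (is.null(U)) return(-Inf)
  Z <- if (is.null(j)) st$phi_lat[[s]] else st$phi_lat[[s]][j, , drop = FALSE]
  .ldmvnorm_rows(Z, st$mu[[s]], U)
}

.ll_pred_fa <- function(m, st, j = NULL) {
  if (m$spec$consumed == "marginal") {
    # Sigma_tau (PD) + delta-method covariance (PSD): PD by construction
    mp <- .marginal_parts(m, st)
    S2 <- st$Sigma_tau + mp$C
    if (any(!is.finite(S2))) return(-Inf)
    U <- chol(S2)
  } else U <- st$Sigma_tau_chol
  if (is.null(U)) return(-Inf)
  mu <- .tau_alr(m, st, j)
  if (m$spec$consumed == "marginal") {
    mu <- if (is.matrix(mu)) sweep(mu, 2L, mp$corr, "+") else mu + mp$corr
  }
  if (any(!is.finite(mu))) return(-Inf)
  X <- if (is.null(j)) m$T else m$T[j, , drop = FALSE]
  .ldmvnorm_rows(X, mu, U)   # vector mu = identical expected rows
}

.ll_prey_si <- function(m, st, s) {
  U <- st$Sigma_si_chol[[s]]
  if (is.null(U)) return(-Inf)
  .ldmvnorm_rows(m$Ysi[[s]], st$mu_si[s, ], U)
}

.ll_lat_si <- function(m, st, s, j = NULL) {
  U <- st$Sigma_si_chol[[s]]
  if (is.null(U)) return(-Inf)
  Z <- if (is.null(j)) st$si_lat[[s]] else st$si_lat[[s]][j, , drop = FALSE]
  .ldmvnorm_rows(Z, st$mu_si[s, ], U)
}

.ll_pred_si <- function(m, st, j = NULL) {
  if (m$spec$consumed == "marginal") {
    U <- chol(st$Sigma_tau_si + .si_mix_cov(m, st))
  } else U <- st$Sigma_tau_si_chol
  if (is.null(U)) return(-Inf)
  mu <- .si_mean(m, st, j)
  X <- if (is.null(j)) m$Tsi else m$Tsi[j, , drop = FALSE]
  .ldmvnorm_rows(X, mu, U)
}

# -- prior factors (natural space, no Jacobians) ----------------------------

.lp_diet <- function(m, st) {
  spec <- m$spec
  if (!is.null(m$fixed$pi)) return(0)
  if (spec$grouping == "population") {
    if (any(st$pi <= 0)) return(-Inf)
    return(.lddirichlet(st$pi, spec$prior$alpha))
  }
  Z <- t(apply(st$pi, 1L, .ilr, V = m$V))
  if (m$n == 2L) Z <- matrix(Z, ncol = 1L)
  U <- st$Sigma_Pi_chol
  if (is.null(U)) return(-Inf)
  mean_z <- if (spec$grouping == "individual")
    matrix(st$Pi, nrow(Z), m$n - 1L, byrow = TRUE) else m$X %*% st$B
  out <- .ldmvnorm_rows(Z, mean_z, U)
  if (spec$grouping == "individual")
    out <- out + sum(stats::dnorm(st$Pi, 0, spec$prior$mu_sd, log = TRUE))
  else
    out <- out + sum(stats::dnorm(st$B, 0, spec$prior$mu_sd, log = TRUE))
  out + .ldinvwish(st$Sigma_Pi, (m$n - 1L) + 2, diag(spec$prior$sigma_diet_scale,
                                                    m$n - 1L))
}

.lp_fa_blocks <- function(m, st) {
  pr <- m$spec$prior; out <- 0
  if (is.null(m$fixed$mu))
    out <- out + sum(vapply(st$mu, function(mm)
      sum(stats::dnorm(mm, 0, pr$mu_sd, log = TRUE)), 0))
  if (is.null(m$fixed$Sigma))
    out <- out + sum(vapply(st$Sigma, .ldinvwish, 0, nu = m$dfa + 2,
                            Psi = diag(pr$sigma_prey_scale, m$dfa)))
  if (is.null(m$fixed$Sigma_tau))
    out <- out + .ldinvwish(st$Sigma_tau, m$dfa + 2,
                            diag(pr$sigma_pred_scale, m$dfa))
  if (is.null(m$fixed$kappa) && any(m$kap_mask)) {
    k <- st$kappa[m$kap_mask]
    if (any(k <= 0)) return(-Inf)
    out <- out + sum(stats::dgamma(k, shape = m$kap_shape[m$kap_mask],
                                   rate = m$kap_rate[m$kap_mask], log = TRUE))
  }
  if (is.null(m$fixed$Phi) && any(m$phi_mask)) {
    ph <- st$Phi[m$phi_mask]
    if (any(ph <= 0)) return(-Inf)
    out <- out + sum(stats::dlnorm(ph, m$fat_meanlog[m$phi_mask],
                                   m$fat_sdlog[m$phi_mask], log = TRUE))
  }
  out
}

.lp_si_blocks <- function(m, st) {
  pr <- m$spec$prior; d <- m$data; out <- 0
  if (is.null(m$fixed$mu_si))
    out <- out + sum(stats::dnorm(st$mu_si, 0, pr$mu_si_sd, log = TRUE))
  if (is.null(m$fixed$Sigma_si))
    out <- out + sum(vapply(st$Sigma_si, .ldinvwish, 0, nu = m$K + 2,
                            Psi = diag(pr$sigma_si_prey_scale, m$K)))
  if (is.null(m$fixed$Sigma_tau_si))
    out <- out + .ldinvwish(st$Sigma_tau_si, m$K + 2,
                            diag(pr$sigma_si_pred_scale, m$K))
  if (is.null(m$fixed$gamma) && any(m$gam_mask))
    out <- out + sum(stats::dnorm(st$gamma[m$gam_mask],
                                  d$frac_mean[m$gam_mask],
                                  d$frac_sd[m$gam_mask], log = TRUE))
  out
}

# -- exported log densities -------------------------------------------------

.as_model <- function(data, spec) {
  if (inherits(data, "diet_model")) data else build_model(data, spec)
}

#' Fatty-acid log likelihood of a model state
#'
#' Sum of the prey-sample terms (alr prey profiles around species means),
#' the latent consumed-prey terms (omitted in mean-prey mode, where consumed
#' profiles are tied to the species means), and the predator terms (alr
#' predator profiles around the alr of the expected mixture
#' [compute_tau()]).
#'
#' @param data a `diet_data` or prebuilt `diet_model`.
#' @param state a model state: a list with entries `pi`, `mu`, `Sigma`
#'   (lists per species), `Sigma_tau`, `kappa`, `Phi` and, in latent mode,
#'   `phi_lat` (per-species matrices of alr consumed profiles).
#' @param spec a [model_spec()]; ignored when `data` is already a model.
#' @return scalar log likelihood; `-Inf` if a covariance is not positive
#'   definite or the state violates a constraint.
#' @export
fa_loglik <- function(data, state, spec = model_spec(markers = "fa")) {
  m <- .as_model(data, spec)
  st <- .refresh_caches(m, state)
  out <- sum(vapply(seq_len(m$n), function(s) .ll_prey_fa(m, st, s), 0))
  if (m$spec$latent_prey)
    out <- out + sum(vapply(seq_len(m$n), function(s) .ll_lat_fa(m, st, s), 0))
  out + .ll_pred_fa(m, st)
}

#' Stable-isotope log likelihood of a model state
#'
#' Prey isotope samples around species means, latent consumed isotope values
#' (omitted in mean-prey mode), and predator signatures around the mixture
#' expectation [si_expected()].  The fractionation coefficients' normal
#' prior-like term is part of [log_prior()].
#'
#' @inheritParams fa_loglik
#' @export
si_loglik <- function(data, state, spec = model_spec(markers = "si")) {
  m <- .as_model(data, spec)
  st <- .refresh_caches(m, state)
  out <- sum(vapply(seq_len(m$n), function(s) .ll_prey_si(m, st, s), 0))
  if (m$spec$latent_prey)
    out <- out + sum(vapply(seq_len(m$n), function(s) .ll_lat_si(m, st, s), 0))
  out + .ll_pred_si(m, st)
}

#' Log prior of a model state
#'
#' Dirichlet (population) or log-ratio-normal-with-hyperpriors
#' (individual/linear) prior on diet proportions; moment-matched gamma priors
#' on conversion coefficients and log-normal priors on fat content (entries
#' with zero prior variance are fixed constants and contribute no term);
#' normal fractionation priors; vague normal priors on prey means; and
#' inverse-Wishart priors on all covariances.  Densities are over the natural
#' parameter space.
#'
#' @inheritParams fa_loglik
#' @export
log_prior <- function(state, spec = model_spec(), data) {
  m <- .as_model(data, spec)
  st <- .refresh_caches(m, state)
  out <- .lp_diet(m, st)
  if (m$use_fa) out <- out + .lp_fa_blocks(m, st)
  if (m$use_si) out <- out + .lp_si_blocks(m, st)
  out
}

# Full natural-space log posterior of a state.
.state_logpost <- function(m, st) {
  out <- .lp_diet(m, st)
  if (m$use_fa) {
    out <- out + .lp_fa_blocks(m, st)
    if (!is.finite(out)) return(-Inf)
    out <- out + sum(vapply(seq_len(m$n), function(s) .ll_prey_fa(m, st, s), 0))
    if (m$spec$latent_prey)
      out <- out + sum(vapply(seq_len(m$n), function(s) .ll_lat_fa(m, st, s), 0))
    out <- out + .ll_pred_fa(m, st)
  }
  if (m$use_si) {
    out <- out + .lp_si_blocks(m, st)
    if (!is.finite(out)) return(-Inf)
    out <- out + sum(vapply(seq_len(m$n), function(s) .ll_prey_si(m, st, s), 0))
    if (m$spec$latent_prey)
      out <- out + sum(vapply(seq_len(m$n), function(s) .ll_lat_si(m, st, s), 0))
    out <- out + .ll_pred_si(m, st)
  }
  out
}
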