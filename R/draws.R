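#' Posterior draws with chain structure
#'
#' Container for labelled MCMC output: an array indexed (iteration, chain,
#' parameter) plus the seed, warmup/thinning record and acceptance
#' statistics.  Simplex-valued blocks (diet proportions, closure-normalised
#' conversion coefficients) are stored on the proportion scale.
#'
#' @param draws 3-d array (iteration, chain, parameter) with parameter names
#'   in `dimnames[[3]]`.
#' @param seed,n_warmup,thin provenance of the run.
#' @param accept named vector of mean post-warmup acceptance rates for the
#'   random-walk blocks.
#' @param species species names, when the draws come from a diet model.
#' @param model_info list describing the model variant.
#' @param plugin posterior means of the non-monitored blocks (used for
#'   plug-in fitted values).
#' @return an object of class `diet_draws`.
#' @export
diet_draws <- function(draws, seed = NA_integer_, n_warmup = 0L, thin = 1L,
                       accept = NULL, species = NULL, model_info = NULL,
                       plugin = NULL) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L)
  if (prod(dim(draws)) == 0L)
    stop("diet_draws: empty draws", call. = FALSE)
  structure(list(draws = draws, params = dimnames(draws)[[3L]],
                 n_iter = dim(draws)[1L], n_chains = dim(draws)[2L],
                 seed = seed, n_warmup = n_warmup, thin = thin,
                 accept = accept, species = species,
                 model_info = model_info, plugin = plugin),
            class = "diet_draws")
}

.draws_array <- function(x) {
  if (inherits(x, "diet_draws")) x$draws
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a diet_draws object", call. = FALSE)
}

# iterations*chains x parameters matrix
.draws_matrix <- function(x) {
  a <- .draws_array(x)
  d <- dim(a)
  matrix(a, d[1L] * d[2L], d[3L], dimnames = list(NULL, dimnames(a)[[3L]]))
}

#' @export
print.diet_draws <- function(x, ...) {
  cat("Posterior draws:", x$n_iter, "iterations x", x$n_chains, "chains x",
      length(x$params), "parameters\n")
  if (!is.null(x$model_info))
    cat("  model:", x$model_info$markers, "markers,", x$model_info$grouping,
        "grouping,", c(latent = "latent-prey", mean = "mean-prey",
                       marginal = "marginal-prey")[
                         x$model_info$consumed %||% "latent"], "mode\n")
  cat("  seed", x$seed, "| warmup", x$n_warmup, "| thin", x$thin, "\n")
  if (x$n_chains >= 2L && x$n_iter >= 10L) {
    r <- rhat(x)
    cat("  max split-Rhat:", round(max(r), 3), "\n")
    if (max(r) > 1.1)
      cat("  WARNING: Rhat > 1.1 for", sum(r > 1.1),
          "parameter(s); chains have not converged\n")
  }
  invisible(x)
}

#' Summarise posterior draws
#'
#' Per-parameter posterior mean, median, SD, central credible intervals at
#' the requested levels, and (with at least two chains) split-Rhat and
#' effective sample size.
#'
#' @param draws a [diet_draws] object.
#' @param levels credible-interval levels, e.g. `c(0.9, 0.95)`.
#' @return a data frame with one row per parameter.
#' @export
summarize_draws <- function(draws, levels = c(0.9, 0.95)) {
  stopifnot(all(levels > 0 & levels < 1))
  X <- .draws_matrix(draws)
  out <- data.frame(parameter = colnames(X),
                    mean = colMeans(X),
                    median = apply(X, 2L, stats::median),
                    sd = apply(X, 2L, stats::sd),
                    row.names = NULL)
  for (lv in sort(levels)) {
    qs <- apply(X, 2L, stats::quantile, probs = c((1 - lv) / 2, 1 - (1 - lv) / 2))
    out[[paste0("lower_", lv)]] <- qs[1L, ]
    out[[paste0("upper_", lv)]] <- qs[2L, ]
  }
  dd <- .draws_array(draws)
  if (dim(dd)[2L] >= 2L && dim(dd)[1L] >= 10L) {
    out$rhat <- unname(rhat(draws))
    out$ess <- unname(ess(draws))
  }
  out
}

#' @export
summary.diet_draws <- function(object, levels = c(0.9, 0.95), ...) {
  summarize_draws(object, levels)
}

# Families of diet-proportion columns: the population block plus one block
# per predator, each a full composition over species.
.pi_families <- function(draws) {
  sp <- draws$species
  if (is.null(sp)) stop("draws carry no species information", call. = FALSE)
  params <- draws$params
  fams <- list()
  pop <- match(paste0("pi[", sp, "]"), params)
  if (!anyNA(pop)) fams[["pi"]] <- stats::setNames(pop, sp)
  pop2 <- match(paste0("pi_pop[", sp, "]"), params)
  if (!anyNA(pop2)) fams[["pi_pop"]] <- stats::setNames(pop2, sp)
  ind <- grep("^pi\\[.+,.+\\]$", params, value = TRUE)
  if (length(ind)) {
    ids <- unique(sub("^pi\\[(.+),[^,]+\\]$", "\\1", ind))
    for (id in ids) {
      ix <- match(paste0("pi[", id, ",", sp, "]"), params)
      if (!anyNA(ix)) fams[[paste0("pi[", id, "]")]] <- stats::setNames(ix, sp)
    }
  }
  fams
}

#' Combine prey sources after fitting
#'
#' Post-hoc grouping of diet proportions: for every draw, the proportion of
#' a group is the sum of its members' proportions.  Useful when individual
#' species cannot be separated but their union can (e.g. combining all fish
#' species into one fish group).
#'
#' @param draws a [diet_draws] object from a diet model.
#' @param groups named character vector or list mapping each species to a
#'   group label; every species must appear exactly once (a partition).
#' @return a [diet_draws] object over group proportions (all diet-proportion
#'   families are grouped; other parameters are dropped).
#' @export
combine_sources <- function(draws, groups) {
  stopifnot(inherits(draws, "diet_draws"))
  sp <- draws$species
  if (is.list(groups)) {
    g <- rep(names(groups), lengths(groups))
    names(g) <- unlist(groups)
    groups <- g
  }
  if (!setequal(names(groups), sp) || anyDuplicated(names(groups)))
    stop("combine_sources: groups must assign every species exactly once",
         call. = FALSE)
  glabs <- unique(unname(groups[sp]))
  fams <- .pi_families(draws)
  if (!length(fams)) stop("combine_sources: no diet-proportion draws found",
                          call. = FALSE)
  a <- .draws_array(draws)
  nfam <- length(fams)
  out <- array(NA_real_, c(dim(a)[1L], dim(a)[2L], nfam * length(glabs)))
  nms <- character(0)
  k <- 0L
  for (f in names(fams)) {
    cols <- fams[[f]]
    for (g in glabs) {
      k <- k + 1L
      member <- cols[groups[names(cols)] == g]
      sl <- a[, , member, drop = FALSE]
      out[, , k] <- if (length(member) > 1L) rowSums(sl, dims = 2L) else
        array(sl, dim(a)[1:2])
      nms <- c(nms, if (f == "pi") paste0("pi[", g, "]") else
        if (f == "pi_pop") paste0("pi_pop[", g, "]") else
          sub("\\]$", paste0(",", g, "]"), f))
    }
  }
  dimnames(out)[[3L]] <- nms
  diet_draws(out, seed = draws$seed, n_warmup = draws$n_warmup,
             thin = draws$thin, accept = draws$accept, species = glabs,
             model_info = draws$model_info)
}

#' Compare posterior spread between two runs
#'
#' For every parameter present in both runs, the ratio of posterior standard
#' deviations and of central 95% interval widths, `a` relative to `b`.
#' Ratios below one mean run `a` is more concentrated — e.g. a joint
#' FA-and-isotope fit against a single-marker fit on the same data.
#'
#' @param draws_a,draws_b [diet_draws] objects.
#' @return data frame with columns `parameter`, `sd_ratio`, `width_ratio`.
#' @export
compare_spread <- function(draws_a, draws_b) {
  A <- .draws_matrix(draws_a); B <- .draws_matrix(draws_b)
  common <- intersect(colnames(A), colnames(B))
  if (!length(common))
    stop("compare_spread: no common parameters", call. = FALSE)
  w <- function(x) diff(stats::quantile(x, c(0.025, 0.975)))
  data.frame(parameter = common,
             sd_ratio = apply(A[, common, drop = FALSE], 2L, stats::sd) /
               apply(B[, common, drop = FALSE], 2L, stats::sd),
             width_ratio = apply(A[, common, drop = FALSE], 2L, w) /
               apply(B[, common, drop = FALSE], 2L, w),
             row.names = NULL)
}

#' Write posterior draws to delimited files
#'
#' Writes a long-format table (chain, iteration, parameter, value) and a
#' companion summary table (`<path>` and `<path base>_summary.csv`).  The
#' long table round-trips through [read_posterior()].
#'
#' @param draws a [diet_draws] object.
#' @param path output CSV path for the long table.
#' @return invisibly, the two paths written.
#' @export
write_posterior <- function(draws, path) {
  stopifnot(inherits(draws, "diet_draws"))
  a <- .draws_array(draws)
  long <- data.frame(
    chain = rep(rep(seq_len(dim(a)[2L]), each = dim(a)[1L]), dim(a)[3L]),
    iteration = rep(seq_len(dim(a)[1L]), dim(a)[2L] * dim(a)[3L]),
    parameter = rep(dimnames(a)[[3L]], each = dim(a)[1L] * dim(a)[2L]),
    value = as.vector(a))
  utils::write.csv(long, path, row.names = FALSE)
  spath <- sub("\\.csv$", "", path)
  spath <- paste0(spath, "_summary.csv")
  utils::write.csv(summarize_draws(draws), spath, row.names = FALSE)
  invisible(c(path, spath))
}

#' Read posterior draws written by [write_posterior()]
#'
#' @param path path to the long-format CSV.
#' @return a [diet_draws] object (provenance fields are not recovered).
#' @export
read_posterior <- function(path) {
  long <- utils::read.csv(path, check.names = FALSE)
  params <- unique(long$parameter)
  chains <- sort(unique(long$chain))
  iters <- sort(unique(long$iteration))
  a <- array(NA_real_, c(length(iters), length(chains), length(params)),
             dimnames = list(NULL, NULL, params))
  for (k in seq_along(params)) {
    sub <- long[long$parameter == params[k], ]
    a[cbind(sub$iteration, sub$chain, k)] <- sub$value
  }
  sp <- unique(sub("^pi\\[([^,]+)\\]$", "\\1",
                   grep("^pi\\[[^,]+\\]$", params, value = TRUE)))
  diet_draws(a, species = if (length(sp)) sp else NULL)
}

#' @export
plot.diet_draws <- function(x, pars = NULL, ...) {
  a <- .draws_array(x)
  if (is.null(pars)) {
    fams <- tryCatch(.pi_families(x), error = function(e) NULL)
    pars <- if (length(fams)) names(fams[[1L]]) |>
      (\(sp) x$params[fams[[1L]]])() else utils::head(x$params, 6L)
  }
  pars <- intersect(pars, x$params)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pp in pars) {
    v <- as.vector(a[, , pp])
    if (stats::sd(v) == 0) {
      plot(v[1], 0, type = "h", main = pp, xlab = "value", ylab = "density")
    } else {
      plot(stats::density(v), main = pp, xlab = "value")
    }
  }
  invisible(x)
}
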