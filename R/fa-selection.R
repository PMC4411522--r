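# Ordination-based fatty-acid selection: rank FAs by their contribution to
# among-species separation on constrained ordination axes, then add them
# greedily while watching the prey-matrix condition number as a
# collinearity guard.

#' Constrained ordination of prey fatty-acid profiles
#'
#' Constrained analysis of principal coordinates (CAP) of the prey FA
#' profiles with species membership as the constraint: principal coordinates
#' of Euclidean distances between clr-transformed profiles followed by
#' redundancy analysis on species indicators — equivalently, an RDA of the
#' clr data on the species factor (computed with \pkg{vegan}).  The per-FA
#' contribution to among-species separation is the eigenvalue-weighted
#' squared loading summed over the constrained axes, normalised to sum to 1.
#'
#' @param prey_fa matrix or data frame of prey FA profiles (zeros replaced),
#'   with a `species` column when a data frame, else `species` given
#'   separately.
#' @param species factor of species labels (when `prey_fa` is a matrix).
#' @return list of class `cap_ordination`: `scores` (constrained axis scores
#'   per sample), `eigenvalues`, `loadings` (per FA x axis),
#'   `contribution` (named, sums to 1), `among_variance` (fraction of total
#'   variance on the constrained axes), `axis_variance`.
#' @export
cap_ordination <- function(prey_fa, species = NULL) {
  if (is.data.frame(prey_fa)) {
    species <- factor(prey_fa$species)
    prey_fa <- as.matrix(prey_fa[, setdiff(names(prey_fa), "species"),
                                 drop = FALSE])
  }
  species <- droplevels(factor(species))
  stopifnot(nrow(prey_fa) == length(species), nlevels(species) >= 2)
  if (any(table(species) < 2))
    stop("cap_ordination: every species needs at least 2 samples", call. = FALSE)
  Z <- clr(replace_zeros(closure(prey_fa)))
  if (min(table(species)) <= nlevels(species) - 1L)
    warning("cap_ordination: a species has few samples relative to the ",
            "number of constrained axes; axes may be unstable", call. = FALSE)
  ord <- vegan::rda(Z ~ species, data = data.frame(species = species))
  ev <- ord$CCA$eig
  load <- ord$CCA$v                       # FA loadings on constrained axes
  contr <- as.vector((load^2) %*% ev)
  contr <- contr / sum(contr)
  names(contr) <- colnames(prey_fa)
  structure(list(scores = ord$CCA$u, eigenvalues = unname(ev),
                 loadings = load, contribution = contr,
                 among_variance = ord$CCA$tot.chi / ord$tot.chi,
                 axis_variance = unname(ev / ord$tot.chi)),
            class = "cap_ordination")
}

#' Prey-matrix condition number
#'
#' Collinearity diagnostic for a candidate FA subset: the ratio of largest
#' to smallest singular value of the species-by-FA matrix of mean
#' proportions, each species' mean profile re-closed on the subset.  Values
#' near 1 indicate well-spread, independent sources; large values indicate
#' nearly collinear prey signatures that make mixing proportions poorly
#' identified.
#'
#' @param prey_fa prey FA profiles (data frame with `species` column, or
#'   matrix plus `species`).
#' @param subset FA names to evaluate (default: all).
#' @param species species labels when `prey_fa` is a matrix.
#' @return a single number `>= 1` (`Inf`, with a warning, if the matrix is
#'   rank deficient).
#' @export
prey_condition_number <- function(prey_fa, subset = NULL, species = NULL) {
  if (is.data.frame(prey_fa)) {
    species <- factor(prey_fa$species)
    prey_fa <- as.matrix(prey_fa[, setdiff(names(prey_fa), "species"),
                                 drop = FALSE])
  }
  species <- droplevels(factor(species))
  if (is.null(subset)) subset <- colnames(prey_fa)
  stopifnot(length(subset) >= 2, all(subset %in% colnames(prey_fa)))
  M <- rowsum(prey_fa[, subset, drop = FALSE], species) /
    as.vector(table(species))
  M <- closure(M)
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) <= max(sv) * 1e-14) {
    warning("prey_condition_number: rank-deficient species-mean matrix",
            call. = FALSE)
    return(Inf)
  }
  max(sv) / min(sv)
}

#' Select fatty acids by contribution under a collinearity guard
#'
#' Ranks FAs by their [cap_ordination()] contribution to among-species
#' separation and adds them greedily: an FA is added while the cumulative
#' contribution of the chosen set is below `cum_var_target` and the
#' prey-matrix condition number of the extended set stays at or below
#' `cond_cap`.  The full trajectory (cumulative variance and condition
#' number at every prefix) is reported so the trade-off can be inspected.
#'
#' @param d a `diet_data` object with FA tables (or a prey FA data frame
#'   with a `species` column).
#' @param cum_var_target target cumulative fraction of among-species
#'   variance (default 0.75).
#' @param cond_cap maximum admissible condition number (default 20).
#' @return list of class `fa_selection`: `ranking` (FAs in contribution
#'   order), `contribution`, `cum_variance`, `condition_number` (both along
#'   the prefix trajectory), `selected`, and the thresholds used.  If no
#'   prefix of size 2 satisfies `cond_cap`, the best 2 FAs are returned with
#'   a warning.
#' @seealso [subset_fas()] to apply the selection to a dataset.
#' @export
select_fas <- function(d, cum_var_target = 0.75, cond_cap = 20) {
  if (inherits(d, "diet_data")) {
    if (is.null(d$prey_fa)) stop("select_fas: dataset has no FA tables",
                                 call. = FALSE)
    prey <- d$prey_fa; species <- d$prey_fa_species
  } else {
    species <- factor(d$species)
    prey <- as.matrix(d[, setdiff(names(d), "species"), drop = FALSE])
  }
  stopifnot(ncol(prey) >= 3, cum_var_target > 0, cum_var_target <= 1,
            cond_cap >= 1)
  ord <- cap_ordination(prey, species)
  ranking <- names(sort(ord$contribution, decreasing = TRUE))
  cumvar <- cumsum(sort(ord$contribution, decreasing = TRUE))
  cond <- c(NA_real_, vapply(2:length(ranking), function(k)
    prey_condition_number(prey, ranking[seq_len(k)], species), 0))
  # greedy: grow while below the variance target and within the cap
  k <- 2L
  while (k < length(ranking) && cumvar[k] < cum_var_target &&
         !is.na(cond[k + 1L]) && cond[k + 1L] <= cond_cap) k <- k + 1L
  fallback <- FALSE
  if (cond[k] > cond_cap) {
    # not even the best-2 subset passes the cap
    k <- 2L
    fallback <- TRUE
    warning("select_fas: no subset satisfies the condition-number cap; ",
            "returning the best 2 fatty acids", call. = FALSE)
  }
  structure(list(ranking = ranking, contribution = ord$contribution[ranking],
                 cum_variance = unname(cumvar),
                 condition_number = unname(cond),
                 selected = ranking[seq_len(k)],
                 cum_var_target = cum_var_target, cond_cap = cond_cap,
                 among_variance = ord$among_variance, fallback = fallback),
            class = "fa_selection")
}

#' @export
print.fa_selection <- function(x, ...) {
  cat("Fatty-acid selection (target cumulative variance ",
      x$cum_var_target, ", condition cap ", x$cond_cap, ")\n", sep = "")
  tab <- data.frame(fa = x$ranking,
                    contribution = round(unname(x$contribution), 4),
                    cum_variance = round(x$cum_variance, 4),
                    condition = round(x$condition_number, 2))
  print(tab, row.names = FALSE)
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  cat("Among-species fraction of total variance:",
      round(x$among_variance, 3), "\n")
  invisible(x)
}

#' @export
plot.fa_selection <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  k <- seq_along(x$ranking)
  plot(k, x$cum_variance, type = "b", ylim = c(0, 1), xaxt = "n",
       xlab = "", ylab = "cumulative among-species variance",
       main = "Contribution trajectory")
  graphics::axis(1, at = k, labels = x$ranking, las = 2, cex.axis = 0.7)
  graphics::abline(h = x$cum_var_target, lty = 2)
  graphics::abline(v = length(x$selected), col = 2)
  plot(k[-1], x$condition_number[-1], type = "b", log = "y", xaxt = "n",
       xlab = "", ylab = "prey-matrix condition number",
       main = "Collinearity guard")
  graphics::axis(1, at = k, labels = x$ranking, las = 2, cex.axis = 0.7)
  graphics::abline(h = x$cond_cap, lty = 2)
  graphics::abline(v = length(x$selected), col = 2)
  invisible(x)
}
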