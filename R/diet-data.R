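#' Assemble a diet-analysis dataset
#'
#' Bundles prey and predator biomarker tables with the prior tables for
#' conversion coefficients, fat content and isotopic fractionation into a
#' single validated object.  All fatty-acid (FA) rows are brought to a
#' canonical column order, re-closed to sum to one, and zeros are replaced by
#' the multiplicative rule (see [replace_zeros()]).  Tables given as
#' percentages (row sums near 100) are detected and rescaled.
#'
#' FA and stable-isotope (SI) tables may cover different individuals: no row
#' pairing between markers is required for prey, nor for predators in
#' population-level models.
#'
#' @param prey_fa data frame with a `species` column and one column per FA
#'   (proportions of total lipid); at least two samples per species.
#' @param predator_fa data frame of predator FA profiles, optionally with an
#'   `id` column.
#' @param prey_si,predator_si analogous tables of isotope signatures
#'   (per-mil); prey table needs a `species` column.
#' @param kappa_mean,kappa_var species-by-FA data frames (a `species` column
#'   plus FA columns) of conversion-coefficient prior means and variances.
#'   Default: mean one, variance zero for every FA — conversion treated as
#'   known and neutral.
#' @param fat_mean,fat_var named numeric vectors (names = species) of
#'   relative fat-content prior means and variances.  Default: one and zero.
#' @param frac_mean,frac_sd species-by-isotope data frames of fractionation
#'   prior means and standard deviations (per-mil).  Required before an SI
#'   model can be built; there is no safe universal default for trophic
#'   enrichment, so absence is an error at model-building time rather than a
#'   silent assumption.
#' @param covariates data frame keyed by an `id` column covering every
#'   predator id; used by the linear-model formulation.
#' @param alr_ref reference FA for the additive log-ratio transform, by name
#'   or index; defaults to the last FA in canonical order.
#' @param delta zero-replacement value; default half the smallest positive
#'   proportion observed across the FA tables.
#' @return an object of class `diet_data`.
#' @seealso [read_diet_data()], [subset_fas()], [fit_diet()]
#' @export
diet_data <- function(prey_fa = NULL, predator_fa = NULL,
                      prey_si = NULL, predator_si = NULL,
                      kappa_mean = NULL, kappa_var = NULL,
                      fat_mean = NULL, fat_var = NULL,
                      frac_mean = NULL, frac_sd = NULL,
                      covariates = NULL, alr_ref = NULL, delta = NULL) {
  if (is.null(prey_fa) && is.null(prey_si))
    stop("diet_data: need at least one prey table (FA or SI)", call. = FALSE)
  if (is.null(predator_fa) && is.null(predator_si))
    stop("diet_data: need at least one predator table (FA or SI)", call. = FALSE)
  if (!is.null(prey_fa) && is.null(predator_fa))
    stop("diet_data: prey FA table given without predator FA table", call. = FALSE)
  if (!is.null(prey_si) && is.null(predator_si))
    stop("diet_data: prey SI table given without predator SI table", call. = FALSE)

  fa <- si <- NULL
  if (!is.null(prey_fa)) {
    fa <- .parse_marker_tables(prey_fa, predator_fa, "FA")
    fa$prey <- .sanitize_fa(fa$prey, "prey FA")
    fa$pred <- .sanitize_fa(fa$pred, "predator FA")
  }
  if (!is.null(prey_si)) si <- .parse_marker_tables(prey_si, predator_si, "SI")

  species <- if (!is.null(fa)) levels(fa$species) else levels(si$species)
  if (!is.null(fa) && !is.null(si) && !setequal(species, levels(si$species)))
    stop("diet_data: FA and SI prey tables list different species sets",
         call. = FALSE)
  if (!is.null(si)) si$species <- factor(as.character(si$species), levels = species)
  n <- length(species)

  fa_names <- if (!is.null(fa)) colnames(fa$prey)
  iso_names <- if (!is.null(si)) colnames(si$prey)
  p <- length(fa_names)

  # zero replacement on FA tables (multiplicative rule, shared delta)
  if (!is.null(fa)) {
    pos <- c(fa$prey[fa$prey > 0], fa$pred[fa$pred > 0])
    if (is.null(delta)) delta <- 0.5 * min(pos)
    fa$prey <- replace_zeros(fa$prey, delta)
    fa$pred <- replace_zeros(fa$pred, delta)
  }

  kap <- .parse_kappa(kappa_mean, kappa_var, species, fa_names)
  fat <- .parse_fat(fat_mean, fat_var, species)
  frac <- .parse_frac(frac_mean, frac_sd, species, iso_names)

  if (!is.null(covariates)) {
    if (!"id" %in% names(covariates))
      stop("diet_data: covariate table needs an 'id' column", call. = FALSE)
    ids <- unique(c(if (!is.null(fa)) fa$ids, if (!is.null(si)) si$ids))
    miss <- setdiff(ids, covariates$id)
    if (length(miss))
      stop("diet_data: covariates missing for predator id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  if (!is.null(alr_ref) && !is.null(fa)) {
    if (is.character(alr_ref)) alr_ref <- match(alr_ref, fa_names)
    if (is.na(alr_ref) || alr_ref < 1 || alr_ref > p)
      stop("diet_data: alr_ref is not a known fatty acid", call. = FALSE)
  } else if (!is.null(fa)) alr_ref <- p

  structure(list(
    species = species, n_species = n,
    fa_names = fa_names, iso_names = iso_names,
    prey_fa = fa$prey, prey_fa_species = fa$species,
    pred_fa = fa$pred, pred_fa_ids = fa$ids,
    prey_si = si$prey, prey_si_species = si$species,
    pred_si = si$pred, pred_si_ids = si$ids,
    kappa_mean = kap$mean, kappa_var = kap$var,
    fat_mean = fat$mean, fat_var = fat$var,
    frac_mean = frac$mean, frac_sd = frac$sd,
    covariates = covariates,
    alr_ref = if (!is.null(fa)) alr_ref,
    delta = if (!is.null(fa)) delta,
    provenance = list(fa_subset = NULL, files = NULL)
  ), class = "diet_data")
}

# -- table parsing ----------------------------------------------------------

.parse_marker_tables <- function(prey, pred, what) {
  prey <- as.data.frame(prey)
  pred <- as.data.frame(pred)
  if (!"species" %in% names(prey))
    stop("diet_data: prey ", what, " table needs a 'species' column", call. = FALSE)
  sp <- factor(as.character(prey$species))
  vars <- setdiff(names(prey), "species")
  ids <- if ("id" %in% names(pred)) as.character(pred$id) else
    paste0("pred", seq_len(nrow(pred)))
  pvars <- setdiff(names(pred), "id")
  if (!setequal(vars, pvars))
    stop("diet_data: ", what, " columns differ between prey and predator tables",
         call. = FALSE)
  tab <- table(sp)
  if (any(tab < 2))
    stop("diet_data: every species needs at least 2 ", what, " samples; ",
         paste(names(tab)[tab < 2], collapse = ", "), " has fewer", call. = FALSE)
  X <- as.matrix(prey[, vars, drop = FALSE])
  Y <- as.matrix(pred[, vars, drop = FALSE])  # canonical column order from prey
  if (!is.numeric(X) || !is.numeric(Y))
    stop("diet_data: non-numeric entries in ", what, " table", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("diet_data: missing or non-finite entries in ", what, " table", call. = FALSE)
  rownames(Y) <- ids
  list(prey = X, pred = Y, species = sp, ids = ids)
}

# Re-close FA rows; accept percentage-scaled tables; flag bad rows precisely.
.sanitize_fa <- function(X, what) {
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1L, ]
    stop("diet_data: negative proportion in ", what, " table (row ", bad[1L],
         ", column ", colnames(X)[bad[2L]], ")", call. = FALSE)
  }
  s <- rowSums(X)
  if (stats::median(s) > 50) {      # percentage export
    message("Note: ", what, " table appears to be in percent; rescaling by 1/100.")
    X <- X / 100
    s <- s / 100
  }
  off <- abs(s - 1)
  if (any(off > 1e-3)) {
    bad <- which.max(off)
    stop("diet_data: ", what, " row ", bad, " sums to ", signif(s[bad], 4),
         ", not 1", call. = FALSE)
  }
  if (any(off > 1e-9)) {
    warning(what, " rows re-closed (sums deviated from 1 by up to ",
            signif(max(off), 3), ")", call. = FALSE)
    X <- closure(X)
  }
  X
}

.parse_kappa <- function(km, kv, species, fa_names) {
  p <- length(fa_names); n <- length(species)
  if (is.null(fa_names)) return(list(mean = NULL, var = NULL))
  as_mat <- function(tab, what, default) {
    if (is.null(tab))
      return(matrix(default, n, p, dimnames = list(species, fa_names)))
    tab <- as.data.frame(tab)
    if (!"species" %in% names(tab))
      stop("diet_data: ", what, " table needs a 'species' column", call. = FALSE)
    if (!setequal(setdiff(names(tab), "species"), fa_names))
      stop("diet_data: ", what, " FA columns do not match the prey FA table",
           call. = FALSE)
    M <- as.matrix(tab[, fa_names, drop = FALSE])
    rownames(M) <- as.character(tab$species)
    if (!setequal(rownames(M), species))
      stop("diet_data: ", what, " species do not match the prey table", call. = FALSE)
    M[species, , drop = FALSE]
  }
  m <- as_mat(km, "kappa_mean", 1)
  v <- as_mat(kv, "kappa_var", 0)
  if (any(m <= 0)) stop("diet_data: kappa means must be positive", call. = FALSE)
  if (any(v < 0)) stop("diet_data: kappa variances must be non-negative", call. = FALSE)
  list(mean = m, var = v)
}

.parse_fat <- function(fm, fv, species) {
  n <- length(species)
  as_vec <- function(v, what, default) {
    if (is.null(v)) return(stats::setNames(rep(default, n), species))
    if (is.data.frame(v)) v <- stats::setNames(v$mean %||% v[[2L]], v$species)
    if (is.null(names(v)) || !setequal(names(v), species))
      stop("diet_data: ", what, " must be named by species", call. = FALSE)
    v[species]
  }
  m <- as_vec(fm, "fat_mean", 1)
  v <- if (is.data.frame(fm) && "var" %in% names(fm))
    stats::setNames(fm$var, fm$species)[species] else as_vec(fv, "fat_var", 0)
  if (any(m <= 0)) stop("diet_data: fat means must be positive", call. = FALSE)
  if (any(v < 0)) stop("diet_data: fat variances must be non-negative", call. = FALSE)
  list(mean = m, var = v)
}

.parse_frac <- function(fm, fs, species, iso_names) {
  if (is.null(fm) || is.null(iso_names)) return(list(mean = NULL, sd = NULL))
  if (is.null(fs))
    stop("diet_data: frac_mean given without frac_sd", call. = FALSE)
  as_mat <- function(tab, what) {
    tab <- as.data.frame(tab)
    if (!"species" %in% names(tab))
      stop("diet_data: ", what, " table needs a 'species' column", call. = FALSE)
    if (!setequal(setdiff(names(tab), "species"), iso_names))
      stop("diet_data: ", what, " isotope columns do not match the prey SI table",
           call. = FALSE)
    M <- as.matrix(tab[, iso_names, drop = FALSE])
    rownames(M) <- as.character(tab$species)
    if (!setequal(rownames(M), species))
      stop("diet_data: ", what, " species do not match", call. = FALSE)
    M[species, , drop = FALSE]
  }
  m <- as_mat(fm, "frac_mean")
  s <- as_mat(fs, "frac_sd")
  if (any(s < 0)) stop("diet_data: fractionation SDs must be non-negative",
                       call. = FALSE)
  list(mean = m, sd = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a diet dataset from a run-configuration file
#'
#' Reads a YAML configuration naming the input tables (CSV, header row,
#' species label in a `species` column) and options, loads and validates them
#' through [diet_data()], and applies any FA subset via [subset_fas()].
#' Recognised keys: `prey_fa`, `predator_fa`, `prey_si`, `predator_si`,
#' `kappa_mean`, `kappa_var`, `fat`, `frac_mean`, `frac_sd`, `covariates`
#' (file paths, relative to the config file), and `alr_ref`, `delta`,
#' `fa_subset` (options).
#'
#' @param config path to the YAML run-configuration file.
#' @return a validated `diet_data` object with provenance recording the file
#'   paths and options used.
#' @export
read_diet_data <- function(config) {
  cfg <- yaml::read_yaml(config)
  base <- dirname(normalizePath(config))
  grab <- function(key) {
    if (is.null(cfg[[key]])) return(NULL)
    path <- cfg[[key]]
    if (!file.exists(path)) path <- file.path(base, cfg[[key]])
    if (!file.exists(path))
      stop("read_diet_data: file not found for '", key, "': ", cfg[[key]],
           call. = FALSE)
    utils::read.csv(path, check.names = FALSE)
  }
  fat <- grab("fat")
  d <- diet_data(
    prey_fa = grab("prey_fa"), predator_fa = grab("predator_fa"),
    prey_si = grab("prey_si"), predator_si = grab("predator_si"),
    kappa_mean = grab("kappa_mean"), kappa_var = grab("kappa_var"),
    fat_mean = fat,
    frac_mean = grab("frac_mean"), frac_sd = grab("frac_sd"),
    covariates = grab("covariates"),
    alr_ref = cfg$alr_ref, delta = cfg$delta)
  d$provenance$files <- cfg[intersect(names(cfg),
    c("prey_fa", "predator_fa", "prey_si", "predator_si", "kappa_mean",
      "kappa_var", "fat", "frac_mean", "frac_sd", "covariates"))]
  if (!is.null(cfg$fa_subset)) d <- subset_fas(d, cfg$fa_subset)
  d
}

#' Restrict a dataset to a subset of fatty acids
#'
#' Drops all other FA columns from the prey, predator and
#' conversion-coefficient tables and re-closes every FA row on the retained
#' parts.  Conversion-coefficient means are kept as given — they are
#' identified only up to a multiplicative constant, so no rescaling is
#' needed.  Typically used with the subset chosen by [select_fas()].
#'
#' @param d a `diet_data` object with FA tables.
#' @param fa_names character vector (length at least 2) of FAs to retain.
#' @return a `diet_data` object on the reduced FA set, with provenance noting
#'   the subset.
#' @export
subset_fas <- function(d, fa_names) {
  stopifnot(inherits(d, "diet_data"))
  if (is.null(d$fa_names)) stop("subset_fas: dataset has no FA tables", call. = FALSE)
  unknown <- setdiff(fa_names, d$fa_names)
  if (length(unknown))
    stop("subset_fas: unknown fatty acid(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- d$fa_names[d$fa_names %in% fa_names]   # canonical order
  if (length(keep) < 2) stop("subset_fas: need at least 2 fatty acids", call. = FALSE)
  ref_name <- d$fa_names[d$alr_ref]
  d$prey_fa <- closure(d$prey_fa[, keep, drop = FALSE])
  d$pred_fa <- closure(d$pred_fa[, keep, drop = FALSE])
  d$kappa_mean <- d$kappa_mean[, keep, drop = FALSE]
  d$kappa_var <- d$kappa_var[, keep, drop = FALSE]
  d$fa_names <- keep
  d$alr_ref <- if (ref_name %in% keep) match(ref_name, keep) else length(keep)
  d$provenance$fa_subset <- keep
  d
}

#' @export
print.diet_data <- function(x, ...) {
  cat("Diet dataset:", x$n_species, "prey species (",
      paste(x$species, collapse = ", "), ")\n")
  if (!is.null(x$prey_fa))
    cat("  FA : ", length(x$fa_names), " fatty acids; ",
        nrow(x$prey_fa), " prey samples, ", nrow(x$pred_fa),
        " predator profiles (alr reference: ", x$fa_names[x$alr_ref], ")\n",
        sep = "")
  if (!is.null(x$prey_si))
    cat("  SI : ", length(x$iso_names), " isotope(s) (",
        paste(x$iso_names, collapse = ", "), "); ", nrow(x$prey_si),
        " prey samples, ", nrow(x$pred_si), " predator signatures\n", sep = "")
  if (is.null(x$frac_mean) && !is.null(x$prey_si))
    cat("  (no fractionation priors loaded; SI models will refuse to build)\n")
  if (!is.null(x$provenance$fa_subset))
    cat("  FA subset applied:", paste(x$provenance$fa_subset, collapse = ", "), "\n")
  invisible(x)
}
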