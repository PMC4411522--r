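#' Plain-text report for a fitted diet model
#'
#' Produces a human-readable markdown report: posterior summaries of the
#' population-level (and, when fitted, per-predator) diet proportions,
#' convergence diagnostics, an optional grouped-source section, an optional
#' spread comparison against a second fit, and truth-overlay scores when a
#' truth record (e.g. from [simulate_diet_data()]) is available.
#'
#' @param fit a `diet_fit`.
#' @param truth optional truth record with a `pi_pop` element (and
#'   optionally `pi_true`), as produced by [simulate_diet_data()].
#' @param groups optional species-to-group mapping forwarded to
#'   [combine_sources()].
#' @param compare optional second `diet_fit` (or [diet_draws]) for a
#'   spread-ratio section, `fit` relative to `compare`.
#' @param file optional path; when given the report is also written there.
#' @return the report, invisibly, as a character vector of lines.
#' @export
report <- function(fit, truth = NULL, groups = NULL, compare = NULL,
                   file = NULL) {
  stopifnot(inherits(fit, "diet_fit"))
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  out <- c("# Diet mixing model report", "",
           paste0("Model: ", fit$spec$markers, " markers, ",
                  fit$spec$grouping, " grouping, ",
                  c(latent = "latent-prey", mean = "mean-prey",
                    marginal = "marginal-prey")[fit$spec$consumed],
                  " mode; seed ", fit$seed, "."))
  sm <- fit$summary
  pi_rows <- grep("^pi(_pop)?\\[", sm$parameter)
  out <- c(out, "", "## Diet proportions", "",
           paste0("| parameter | mean | sd | 90% interval |"),
           paste0("|---|---|---|---|"),
           vapply(pi_rows, function(i) paste0(
             "| ", sm$parameter[i], " | ", fmt(sm$mean[i]), " | ",
             fmt(sm$sd[i]), " | [", fmt(sm$lower_0.9[i]), ", ",
             fmt(sm$upper_0.9[i]), "] |"), ""))
  if (!is.null(sm$rhat))
    out <- c(out, "", paste0("Convergence: max split-Rhat ",
                             fmt(max(sm$rhat)), ", min ESS ",
                             round(min(sm$ess)), "."))
  if (!is.null(groups)) {
    g <- combine_sources(fit$draws, groups)
    gs <- summarize_draws(g)
    out <- c(out, "", "## Grouped sources", "",
             "| parameter | mean | sd | 90% interval |", "|---|---|---|---|",
             vapply(seq_len(nrow(gs)), function(i) paste0(
               "| ", gs$parameter[i], " | ", fmt(gs$mean[i]), " | ",
               fmt(gs$sd[i]), " | [", fmt(gs$lower_0.9[i]), ", ",
               fmt(gs$upper_0.9[i]), "] |"), ""))
  }
  if (!is.null(compare)) {
    cd <- if (inherits(compare, "diet_fit")) compare$draws else compare
    cs <- compare_spread(fit$draws, cd)
    cs <- cs[grep("^pi(_pop)?\\[", cs$parameter), , drop = FALSE]
    out <- c(out, "", "## Posterior spread vs. comparison fit", "",
             "| parameter | SD ratio | 95%-width ratio |", "|---|---|---|",
             vapply(seq_len(nrow(cs)), function(i) paste0(
               "| ", cs$parameter[i], " | ", fmt(cs$sd_ratio[i]), " | ",
               fmt(cs$width_ratio[i]), " |"), ""))
  }
  if (!is.null(truth)) {
    sp <- fit$model$species
    tr <- if (!is.null(truth$pi_pop)) truth$pi_pop else truth
    est_names <- if (fit$spec$grouping == "population")
      paste0("pi[", sp, "]") else paste0("pi_pop[", sp, "]")
    ix <- match(est_names, sm$parameter)
    if (!anyNA(ix)) {
      err <- sm$mean[ix] - tr
      out <- c(out, "", "## Recovery against truth", "",
               "| species | truth | posterior mean | abs. error |",
               "|---|---|---|---|",
               vapply(seq_along(sp), function(i) paste0(
                 "| ", sp[i], " | ", fmt(tr[i]), " | ", fmt(sm$mean[ix][i]),
                 " | ", fmt(abs(err[i])), " |"), ""),
               "", paste0("Mean absolute error: ", fmt(mean(abs(err))), "."))
    }
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
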