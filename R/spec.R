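#' Analysis specification for a two-group quantile decomposition
#'
#' Collects and validates every analysis setting: which columns play
#' which role, the estimation quantile grid, the quantiles to tabulate,
#' and the bootstrap configuration. The reference level is the
#' advantaged group whose coefficient process is donated to the
#' counterfactual; the comparison level is the disadvantaged group.
#'
#' @param outcome name of the numeric outcome column.
#' @param group name of the column holding the two-level group variable.
#' @param reference group value treated as the reference (coefficients
#'   donor).
#' @param comparison group value for the comparison group.
#' @param covariates character vector of covariate column names, in the
#'   order they enter the design matrix (after the intercept, which the
#'   package always prepends itself).
#' @param taus estimation grid of probabilities, strictly increasing,
#'   all in (0, 1). The default 99 equispaced points 0.01..0.99 is dense
#'   enough to reconstruct marginal distributions from the coefficient
#'   process.
#' @param report_taus quantiles at which results are tabulated; must lie
#'   within the range of `taus`.
#' @param bootstrap number of bootstrap replicates (0 disables interval
#'   estimation).
#' @param ci_level pointwise confidence level.
#' @param seed integer root seed; per-replicate seeds are derived from
#'   it so earlier replicates are unchanged when `bootstrap` grows.
#' @param outlier_rule `"none"` (default) or `"quantile"`; the latter
#'   trims outcome values outside the empirical `outlier_bounds`
#'   quantile interval before the groups are split.
#' @param outlier_bounds length-2 numeric `c(lo, hi)` with
#'   `0 <= lo < hi <= 1`; required when `outlier_rule = "quantile"`.
#' @param delim field delimiter for [load_dataset()] (`","` or `"\t"`).
#' @return an object of class `"decomp_spec"`.
#' @export
#' @examples
#' decomp_spec("intake", "education", reference = "high", comparison = "low",
#'             covariates = c("income", "network"))
decomp_spec <- function(outcome, group, reference, comparison, covariates,
                        taus = seq(0.01, 0.99, by = 0.01),
                        report_taus = c(0.10, 0.25, 0.50, 0.75, 0.90),
                        bootstrap = 100L, ci_level = 0.95, seed = 1L,
                        outlier_rule = c("none", "quantile"),
                        outlier_bounds = NULL, delim = ",") {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(group), length(group) == 1L,
            length(reference) == 1L, length(comparison) == 1L)
  if (identical(as.character(reference), as.character(comparison)))
    stop("configuration error: reference and comparison levels must differ",
         call. = FALSE)
  if (!is.character(covariates) || length(covariates) == 0L ||
      anyDuplicated(covariates))
    stop("configuration error: covariates must be a non-empty set of ",
         "distinct column names", call. = FALSE)
  taus <- as.numeric(taus)
  if (length(taus) && (any(!is.finite(taus)) || any(taus <= 0) ||
                       any(taus >= 1) || is.unsorted(taus, strictly = TRUE)))
    stop("configuration error: taus must be strictly increasing and in (0, 1)",
         call. = FALSE)
  report_taus <- as.numeric(report_taus)
  if (any(report_taus <= 0) || any(report_taus >= 1))
    stop("configuration error: report_taus must lie in (0, 1)", call. = FALSE)
  if (length(taus) &&
      (min(report_taus) < min(taus) || max(report_taus) > max(taus)))
    stop("configuration error: report_taus must lie within the range of taus",
         call. = FALSE)
  bootstrap <- as.integer(bootstrap)
  if (is.na(bootstrap) || bootstrap < 0L)
    stop("configuration error: bootstrap must be a non-negative integer",
         call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("configuration error: ci_level must be in (0, 1)", call. = FALSE)
  if (outlier_rule == "quantile") {
    if (is.null(outlier_bounds) || length(outlier_bounds) != 2L ||
        outlier_bounds[1] < 0 || outlier_bounds[2] > 1 ||
        outlier_bounds[1] >= outlier_bounds[2])
      stop("configuration error: outlier_bounds must satisfy 0 <= lo < hi <= 1",
           call. = FALSE)
  }
  structure(list(outcome = outcome, group = group,
                 reference = reference, comparison = comparison,
                 covariates = covariates, taus = taus,
                 report_taus = report_taus, bootstrap = bootstrap,
                 ci_level = ci_level, seed = as.integer(seed),
                 outlier_rule = outlier_rule,
                 outlier_bounds = outlier_bounds, delim = delim),
            class = "decomp_spec")
}

#' @export
print.decomp_spec <- function(x, ...) {
  cat("Two-group quantile decomposition specification\n")
  cat("  outcome:    ", x$outcome, "\n")
  cat("  group:      ", x$group, " (reference = ", x$reference,
      ", comparison = ", x$comparison, ")\n", sep = "")
  cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n")
  cat("  tau grid:   ", length(x$taus), " points in [",
      if (length(x$taus)) min(x$taus) else NA, ", ",
      if (length(x$taus)) max(x$taus) else NA, "]\n", sep = "")
  cat("  reported:   ", paste(x$report_taus, collapse = ", "), "\n")
  cat("  bootstrap:  ", x$bootstrap, " reps, ", x$ci_level * 100,
      "% pointwise CIs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
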