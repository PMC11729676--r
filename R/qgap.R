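#' Quantile decomposition of a between-group outcome gap
#'
#' Fits group-specific linear quantile coefficient processes by check-
#' loss minimization, builds factual and counterfactual marginal
#' quantile functions, decomposes the between-group gap at each
#' reported quantile into a covariates part and a coefficients part
#' (summing to the gap exactly), attaches percentile-bootstrap
#' pointwise confidence intervals, and classifies each quantile's
#' population-health strategy indication.
#'
#' @param formula model formula `outcome ~ cov1 + cov2 + ...`; an
#'   intercept is always included (and always prepended by the package
#'   itself).
#' @param data data.frame holding outcome, covariates and the group
#'   variable.
#' @param group name of the two-level grouping column, or a vector of
#'   group values of `nrow(data)`.
#' @param reference group level used as the reference (coefficients
#'   donor); defaults to the level with the larger median outcome.
#' @param comparison the other level; defaults to the remaining level.
#' @param taus estimation grid (see [decomp_spec()]).
#' @param report_taus quantiles to tabulate.
#' @param bootstrap number of bootstrap replicates.
#' @param ci_level pointwise confidence level.
#' @param seed integer root seed for the bootstrap.
#' @return object of class `"qgap"`; see [summary.qgap()],
#'   [coef.qgap()], [confint.qgap()], [plot.qgap()],
#'   [predict.qgap()].
#' @export
#' @examples
#' sim <- simulate_education_study(seed = 7)
#' d <- rbind(
#'   data.frame(intake = sim$reference$outcome,
#'              education = sim$reference$label,
#'              sim$reference$design[, -1]),
#'   data.frame(intake = sim$comparison$outcome,
#'              education = sim$comparison$label,
#'              sim$comparison$design[, -1]))
#' fit <- qgap(intake ~ income + network + support + literacy,
#'             data = d, group = "education", bootstrap = 0)
#' summary(fit)
qgap <- function(formula, data, group, reference = NULL, comparison = NULL,
                 taus = seq(0.01, 0.99, by = 0.01),
                 report_taus = c(0.10, 0.25, 0.50, 0.75, 0.90),
                 bootstrap = 100L, ci_level = 0.95, seed = 1L) {
  cl <- match.call()
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  if (is.character(group) && length(group) == 1L) {
    gname <- group
    if (!gname %in% names(data))
      stop("configuration error: missing column: ", gname, call. = FALSE)
    gval <- as.character(data[[gname]])
  } else {
    gname <- ".group"
    stopifnot(length(group) == nrow(data))
    gval <- as.character(group)
  }
  vars <- all.vars(formula)
  outcome_name <- vars[1]
  covariate_names <- vars[-1]
  lv <- unique(gval[!is.na(gval)])
  if (is.null(reference) && is.null(comparison)) {
    if (length(lv) != 2L)
      stop("configuration error: the group variable must have exactly ",
           "two levels (found ", length(lv), "); name reference and ",
           "comparison levels explicitly to subset", call. = FALSE)
    med <- vapply(lv, function(l)
      stats::median(data[[outcome_name]][gval == l], na.rm = TRUE),
      numeric(1))
    reference <- lv[which.max(med)]
    comparison <- setdiff(lv, reference)
  } else if (is.null(comparison)) {
    comparison <- setdiff(lv, reference)[1]
  } else if (is.null(reference)) {
    reference <- setdiff(lv, comparison)[1]
  }

  spec <- decomp_spec(outcome = outcome_name, group = gname,
                      reference = reference, comparison = comparison,
                      covariates = covariate_names, taus = taus,
                      report_taus = report_taus, bootstrap = bootstrap,
                      ci_level = ci_level, seed = seed)
  dat <- data[, c(outcome_name, covariate_names), drop = FALSE]
  dat[[gname]] <- gval
  loaded <- load_dataset(dat, spec)

  boot <- bootstrap_decomposition(loaded$reference, loaded$comparison, spec)
  agg <- boot$point$aggregate
  det <- boot$detailed
  indications <- classify_quantiles(agg, boot)
  floor <- 0.01 * abs(agg$difference)      # declared noise-floor convention
  gs <- sign(sum(sign(agg$difference))); if (gs == 0) gs <- 1
  flags <- detect_countervailing(boot$detailed, gap_sign = gs,
                                 floor = floor)
  report <- render_strategy_report(indications, flags, agg,
                                   boot$point$detailed)

  structure(list(call = cl, spec = spec, samples = loaded[1:2],
                 exclusions = loaded$exclusions,
                 fit_reference = boot$point$fit_ref,
                 fit_comparison = boot$point$fit_cmp,
                 aggregate = agg, detailed = det, bootstrap = boot,
                 strategy = report),
            class = "qgap")
}

#' @export
print.qgap <- function(x, ...) {
  cat("Quantile decomposition of a between-group outcome gap\n")
  cat("  reference:  '", x$spec$reference, "' (n = ",
      length(x$samples$reference$outcome), ")\n", sep = "")
  cat("  comparison: '", x$spec$comparison, "' (n = ",
      length(x$samples$comparison$outcome), ")\n", sep = "")
  cat("  bootstrap:  ", x$bootstrap$reps, " replicates\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' Summarize a fitted quantile gap decomposition
#'
#' @param object a `"qgap"` fit.
#' @param ... unused.
#' @return object of class `"summary.qgap"` printed as a
#'   decomposition table (predicted group quantiles, difference, both
#'   parts with pointwise CIs and contribution shares) followed by the
#'   strategy report.
#' @export
summary.qgap <- function(object, ...) {
  structure(list(spec = object$spec, aggregate = object$aggregate,
                 ci = object$bootstrap$aggregate,
                 strategy = object$strategy,
                 exclusions = object$exclusions),
            class = "summary.qgap")
}

#' @export
print.summary.qgap <- function(x, ...) {
  agg <- x$aggregate
  fmt <- function(v) sprintf("%.1f", v)
  ci_of <- function(tau, q) {
    r <- x$ci[x$ci$tau == tau & x$ci$quantity == q, ]
    if (!nrow(r) || anyNA(r[, c("lower", "upper")])) return("")
    sprintf("(%.1f, %.1f)", r$lower, r$upper)
  }
  cat("Quantile decomposition (reference '", x$spec$reference,
      "' vs comparison '", x$spec$comparison, "')\n\n", sep = "")
  tab <- rbind(
    `predicted, reference` = fmt(agg$q_reference),
    `predicted, comparison` = fmt(agg$q_comparison),
    difference = fmt(agg$difference),
    `  CI` = vapply(agg$tau, ci_of, "", q = "difference"),
    `covariates part` = fmt(agg$covariates_part),
    `  CI` = vapply(agg$tau, ci_of, "", q = "covariates_part"),
    `  contribution %` = fmt(agg$contribution_covariates),
    `coefficients part` = fmt(agg$coefficients_part),
    `  CI` = vapply(agg$tau, ci_of, "", q = "coefficients_part"),
    `  contribution %` = fmt(agg$contribution_coefficients))
  colnames(tab) <- paste0("Q", round(agg$tau * 100))
  print(tab, quote = FALSE, right = TRUE)
  cat("\n")
  print(x$strategy)
  invisible(x)
}

#' @export
coef.qgap <- function(object, ...) {
  list(reference = object$fit_reference$coef,
       comparison = object$fit_comparison$coef,
       tau = object$fit_reference$tau)
}

#' Pointwise confidence intervals of the decomposition quantities
#'
#' @param object a `"qgap"` fit.
#' @param parm quantity names (default: all of `q_reference`,
#'   `q_comparison`, `difference`, `covariates_part`,
#'   `coefficients_part`).
#' @param level unused (fixed at the fit's `ci_level`).
#' @param ... unused.
#' @return data.frame with `tau`, `quantity`, `estimate`, `lower`,
#'   `upper`.
#' @export
confint.qgap <- function(object, parm = NULL, level = NULL, ...) {
  out <- object$bootstrap$aggregate
  if (!is.null(parm)) out <- out[out$quantity %in% parm, ]
  out
}

#' Predicted marginal quantiles (factual and counterfactual)
#'
#' @param object a `"qgap"` fit.
#' @param taus probabilities (default: the fit's reported quantiles).
#' @param which `"reference"`, `"comparison"`, or `"counterfactual"`
#'   (reference coefficients with comparison covariates).
#' @param ... unused.
#' @return a `"counterfactual_qf"`.
#' @export
predict.qgap <- function(object,
                         taus = object$spec$report_taus,
                         which = c("reference", "comparison",
                                   "counterfactual"), ...) {
  which <- match.arg(which)
  switch(which,
    reference = marginal_qf(object$fit_reference,
                            object$samples$reference$design, taus),
    comparison = marginal_qf(object$fit_comparison,
                             object$samples$comparison$design, taus),
    counterfactual = marginal_qf(object$fit_reference,
                                 object$samples$comparison$design, taus))
}

#' Plot a fitted quantile gap decomposition
#'
#' Two base-graphics panels: kernel densities of the outcome by group,
#' and the decomposition parts across the estimation range with the
#' reported quantiles marked.
#'
#' @param x a `"qgap"` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qgap <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  dens <- density_summary(list(
    reference = x$samples$reference$outcome,
    comparison = x$samples$comparison$outcome))
  graphics::matplot(dens$grid, cbind(dens$density[[1]], dens$density[[2]]),
                    type = "l", lty = 1:2, col = c("black", "grey40"),
                    xlab = x$spec$outcome, ylab = "density",
                    main = "outcome by group", ...)
  graphics::legend("topright", bty = "n", lty = 1:2,
                   col = c("black", "grey40"),
                   legend = c(x$spec$reference, x$spec$comparison))
  taus <- x$spec$taus
  full <- aggregate_decompose(x$fit_reference, x$fit_comparison,
                              x$samples$reference$design,
                              x$samples$comparison$design, taus)
  graphics::matplot(full$tau,
                    cbind(full$difference, full$covariates_part,
                          full$coefficients_part),
                    type = "l", lty = 1:3, col = "black",
                    xlab = expression(tau), ylab = "outcome units",
                    main = "gap decomposition", ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(v = x$spec$report_taus, col = "grey90")
  graphics::legend("topleft", bty = "n", lty = 1:3,
                   legend = c("difference", "covariates part",
                              "coefficients part"))
  invisible(x)
}
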