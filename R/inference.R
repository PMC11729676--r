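# Percentile-bootstrap pointwise inference for every reported
# decomposition quantity. Resampling is with replacement within each
# group (groups are strata; group sizes stay fixed), and each replicate
# draws its indices under its own derived seed, so increasing the
# number of replicates never reshuffles earlier ones.

#' Percentile interval of a bootstrap sample
#'
#' Empirical `((1-level)/2, 1-(1-level)/2)` quantiles under the
#' package-wide interpolation convention (type 7).
#'
#' @param samples non-empty numeric vector of bootstrap draws.
#' @param level confidence level in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
#' @examples
#' percentile_interval(c(1, 2, 3), 0.999)
percentile_interval <- function(samples, level) {
  if (length(samples) == 0L)
    stop("inference error: empty bootstrap sample", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("inference error: level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  quantile(samples, probs = c(a, 1 - a), type = 7, names = FALSE)
}

agg_quantities <- c("q_reference", "q_comparison", "difference",
                    "covariates_part", "coefficients_part")

decompose_once <- function(y_ref, X_ref, y_cmp, X_cmp, spec) {
  fit_ref <- fit_process(X_ref, y_ref, spec$taus, label = spec$reference)
  fit_cmp <- fit_process(X_cmp, y_cmp, spec$taus, label = spec$comparison)
  agg <- aggregate_decompose(fit_ref, fit_cmp, X_ref, X_cmp,
                             spec$report_taus)
  det <- detailed_decompose(fit_ref, fit_cmp, X_ref, X_cmp, agg)
  list(fit_ref = fit_ref, fit_cmp = fit_cmp, aggregate = agg,
       detailed = det)
}

#' Bootstrap the full decomposition
#'
#' Draws `spec$bootstrap` independent within-group resamples (with
#' replacement, preserving each group's size), re-runs the entire
#' estimation pipeline (quantile process fits, aggregate and detailed
#' decomposition) on each, and returns pointwise percentile confidence
#' intervals for every reported quantity. A replicate whose resampled
#' design is rank-deficient is dropped and counted; more than 10%
#' failed replicates is an inference error. `bootstrap = 0` returns
#' point estimates with `NA` bounds.
#'
#' @param reference,comparison [group_sample()] objects.
#' @param spec a [decomp_spec()].
#' @return object of class `"gap_bootstrap"`: list with `reps`,
#'   `failed`, `seed`, `ci_level`, `point` (the point-estimate pipeline
#'   output of the original data), `aggregate` and `detailed`
#'   (data.frames with `estimate`, `lower`, `upper`), and the raw draw
#'   arrays `agg_draws` (reps x taus x quantity) and `det_draws`
#'   (reps x rows x 2) for audit.
#' @export
bootstrap_decomposition <- function(reference, comparison, spec) {
  stopifnot(inherits(reference, "group_sample"),
            inherits(comparison, "group_sample"),
            inherits(spec, "decomp_spec"))
  point <- decompose_once(reference$outcome, reference$design,
                          comparison$outcome, comparison$design, spec)
  reps <- spec$bootstrap
  taus <- spec$report_taus
  nt <- length(taus)
  det_rows <- nrow(point$detailed)

  agg_draws <- array(NA_real_, c(reps, nt, length(agg_quantities)),
                     dimnames = list(NULL, NULL, agg_quantities))
  det_draws <- array(NA_real_, c(reps, det_rows, 2),
                     dimnames = list(NULL, NULL,
                                     c("covariates_detail",
                                       "coefficients_detail")))
  failed <- 0L
  n_ref <- length(reference$outcome)
  n_cmp <- length(comparison$outcome)
  for (r in seq_len(reps)) {
    set.seed((spec$seed + r) %% .Machine$integer.max)
    i_ref <- sample.int(n_ref, n_ref, replace = TRUE)
    i_cmp <- sample.int(n_cmp, n_cmp, replace = TRUE)
    res <- tryCatch(
      decompose_once(reference$outcome[i_ref],
                     reference$design[i_ref, , drop = FALSE],
                     comparison$outcome[i_cmp],
                     comparison$design[i_cmp, , drop = FALSE], spec),
      error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    agg_draws[r, , ] <- as.matrix(res$aggregate[, agg_quantities])
    det_draws[r, , ] <- as.matrix(
      res$detailed[, c("covariates_detail", "coefficients_detail")])
  }
  if (reps > 0L && failed > 0.1 * reps)
    stop("inference error: ", failed, " of ", reps,
         " bootstrap replicates failed", call. = FALSE)
  ok <- if (reps > 0L) which(!is.na(agg_draws[, 1, 1])) else integer(0)

  ci_cell <- function(draws) {
    if (length(draws) == 0L) return(c(NA_real_, NA_real_))
    percentile_interval(draws, spec$ci_level)
  }
  agg_long <- do.call(rbind, lapply(seq_len(nt), function(i) {
    do.call(rbind, lapply(seq_along(agg_quantities), function(q) {
      ci <- ci_cell(agg_draws[ok, i, q])
      data.frame(tau = taus[i], quantity = agg_quantities[q],
                 estimate = point$aggregate[[agg_quantities[q]]][i],
                 lower = ci[1], upper = ci[2])
    }))
  }))
  det_long <- point$detailed
  det_ci <- lapply(1:2, function(q) t(vapply(seq_len(det_rows), function(i)
    ci_cell(det_draws[ok, i, q]), numeric(2))))
  det_long$covariates_lower <- det_ci[[1]][, 1]
  det_long$covariates_upper <- det_ci[[1]][, 2]
  det_long$coefficients_lower <- det_ci[[2]][, 1]
  det_long$coefficients_upper <- det_ci[[2]][, 2]

  structure(list(reps = reps, failed = failed, seed = spec$seed,
                 ci_level = spec$ci_level, point = point,
                 aggregate = agg_long, detailed = det_long,
                 agg_draws = agg_draws, det_draws = det_draws),
            class = "gap_bootstrap")
}

#' @export
print.gap_bootstrap <- function(x, ...) {
  cat("Percentile bootstrap: ", x$reps, " replicates (", x$failed,
      " failed), ", x$ci_level * 100, "% pointwise intervals, seed ",
      x$seed, "\n", sep = "")
  print.data.frame(x$aggregate, digits = 3, row.names = FALSE)
  invisible(x)
}

# CI slice for one tau and one quantity, from the long aggregate table.
ci_slice <- function(boot, tau, quantity) {
  row <- boot$aggregate[boot$aggregate$tau == tau &
                          boot$aggregate$quantity == quantity, ]
  c(lower = row$lower[1], upper = row$upper[1])
}
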