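# Maps decomposition output onto the population-health strategy
# framework. A significant covariates part (different risk-factor
# levels, same responses) is the empirical signature of proportionate
# universalism: universal action scaled to disadvantage can close that
# portion. A significant coefficients part (different risk-outcome
# responses) signals the need for a targeted, group-specific approach.
# "Dominant" means a contribution share above 50%; "significant" means
# the pointwise CI excludes 0. Both cutoffs are declared package
# conventions.

#' Classify one quantile's strategy indication
#'
#' @param agg_row one row of an [aggregate_decompose()] result.
#' @param ci list (or data.frame row set) giving `covariates_part`,
#'   `coefficients_part` and `difference` intervals as length-2
#'   numerics `c(lower, upper)`; `NA` bounds mean no interval.
#' @return one-row data.frame: `tau`, `dominant_part`,
#'   `covariates_significant`, `coefficients_significant`,
#'   `indication`, `share_covariates`, `share_coefficients`.
#'   Indications: both parts significant yields `"combined"`, exactly
#'   one yields that part's strategy (`"proportionate_universalism"`
#'   for the covariates part, `"targeted"` for the coefficients part)
#'   regardless of which part dominates, neither yields `"none"`.
#'   Dominance is recorded independently of significance.
#' @export
classify_quantile <- function(agg_row, ci) {
  excl0 <- function(iv) {
    if (is.null(iv) || anyNA(iv)) return(NA)
    iv[1] > 0 || iv[2] < 0
  }
  cov_sig <- excl0(ci$covariates_part)
  coef_sig <- excl0(ci$coefficients_part)
  sh_cov <- agg_row$contribution_covariates
  sh_coef <- agg_row$contribution_coefficients
  dominant <- if (is.na(sh_cov) || is.na(sh_coef) ||
                  abs(sh_cov) == abs(sh_coef)) "none"
              else if (abs(sh_cov) > abs(sh_coef)) "covariates"
              else "coefficients"
  cs <- isTRUE(cov_sig); fs <- isTRUE(coef_sig)
  indication <- if (cs && fs) "combined"
                else if (fs) "targeted"
                else if (cs) "proportionate_universalism"
                else "none"
  data.frame(tau = agg_row$tau, dominant_part = dominant,
             covariates_significant = cov_sig,
             coefficients_significant = coef_sig,
             indication = indication,
             share_covariates = sh_cov, share_coefficients = sh_coef,
             stringsAsFactors = FALSE)
}

#' Classify every reported quantile
#'
#' @param agg an [aggregate_decompose()] result.
#' @param boot the matching `"gap_bootstrap"` (or `NULL` for no
#'   intervals; then nothing is significant and all indications are
#'   driven by missing CIs).
#' @return data.frame, one row per reported tau (see
#'   [classify_quantile()]).
#' @export
classify_quantiles <- function(agg, boot = NULL) {
  out <- lapply(seq_len(nrow(agg)), function(i) {
    tau <- agg$tau[i]
    ci <- if (is.null(boot)) {
      list(covariates_part = c(NA_real_, NA_real_),
           coefficients_part = c(NA_real_, NA_real_),
           difference = c(NA_real_, NA_real_))
    } else {
      if (boot$reps > 0L &&
          !any(boot$aggregate$tau == tau))
        stop("internal consistency error: no bootstrap slice at tau = ",
             tau, call. = FALSE)
      list(covariates_part = ci_slice(boot, tau, "covariates_part"),
           coefficients_part = ci_slice(boot, tau, "coefficients_part"),
           difference = ci_slice(boot, tau, "difference"))
    }
    classify_quantile(agg[i, ], ci)
  })
  do.call(rbind, out)
}

#' Detect countervailing covariates
#'
#' Flags covariate k at tau when its covariates detail and coefficients
#' detail both carry the sign of the total gap and both exceed `floor`
#' in magnitude. Such a covariate closes part of the gap through its
#' level difference, yet the comparison group's weaker response means a
#' level-raising intervention would be blunted (or even widen the gap);
#' the flag therefore recommends a response-modifying, structural
#' intervention. The intercept and remainder terms are never flagged.
#'
#' @param detail a [detailed_decompose()] result.
#' @param gap_sign +1 or -1, the sign of the total difference.
#' @param floor non-negative noise floor in outcome units (may be a
#'   vector, one per reported tau, recycled across terms).
#' @return data.frame with columns `term`, `tau`, `covariates_detail`,
#'   `coefficients_detail`, `note`; zero rows when nothing is flagged.
#' @export
detect_countervailing <- function(detail, gap_sign = 1, floor = 0) {
  stopifnot(all(floor >= 0), gap_sign %in% c(-1, 1))
  taus <- unique(detail$tau)
  floor <- rep_len(floor, length(taus))
  keep <- !(detail$term %in% c("(Intercept)", "(remainder)"))
  d <- detail[keep, , drop = FALSE]
  fl <- floor[match(d$tau, taus)]
  hit <- sign(d$covariates_detail) == gap_sign &
         sign(d$coefficients_detail) == gap_sign &
         abs(d$covariates_detail) > fl &
         abs(d$coefficients_detail) > fl
  out <- d[hit, c("term", "tau", "covariates_detail",
                  "coefficients_detail"), drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out))
    out$note <- paste0(
      "raising '", out$term, "' levels in the comparison group would be ",
      "blunted by its weaker response; a structural intervention ",
      "modifying the response itself is indicated")
  else out$note <- character(0)
  out
}

#' Assemble the strategy report
#'
#' Combines per-quantile indications, countervailing flags and the
#' decomposition tables into a machine-readable report plus a
#' human-readable summary. When the intercept's coefficients detail
#' exceeds half of the coefficients part at a tau, an unmeasured-
#' factors caveat is emitted: the gap there is driven by the regression
#' constant, i.e. by factors outside the covariate set.
#'
#' @param indications output of [classify_quantiles()].
#' @param flags output of [detect_countervailing()].
#' @param agg an [aggregate_decompose()] result.
#' @param detail a [detailed_decompose()] result.
#' @return object of class `"strategy_report"`: list with `quantiles`
#'   (one record per tau), `flags`, `caveats`, and `text` (character
#'   vector of summary lines).
#' @export
render_strategy_report <- function(indications, flags, agg, detail) {
  stopifnot(isTRUE(all.equal(indications$tau, agg$tau)))
  caveats <- character(0)
  for (i in seq_len(nrow(agg))) {
    tau <- agg$tau[i]
    ic <- detail$coefficients_detail[detail$tau == tau &
                                       detail$term == "(Intercept)"]
    cp <- agg$coefficients_part[i]
    if (length(ic) == 1L && is.finite(cp) && cp != 0 &&
        abs(ic) > 0.5 * abs(cp))
      caveats <- c(caveats, paste0(
        "tau = ", tau, ": the regression constant drives the ",
        "coefficients part; unmeasured factors may explain the ",
        "disparity at this quantile"))
  }
  no_gap <- all(agg$difference == 0) &&
    all(agg$covariates_part == 0) && all(agg$coefficients_part == 0)
  text <- if (no_gap) {
    "no disparity detected: the decomposition is zero at every reported quantile"
  } else {
    vapply(seq_len(nrow(indications)), function(i) {
      r <- indications[i, ]
      fl <- flags$term[flags$tau == r$tau]
      paste0(
        "tau = ", r$tau, ": difference ",
        sprintf("%.1f", agg$difference[i]), "; dominant part: ",
        r$dominant_part,
        sprintf(" (covariates %.1f%%, coefficients %.1f%%)",
                r$share_covariates, r$share_coefficients),
        "; indicated strategy: ", r$indication,
        if (length(fl)) paste0("; countervailing covariate(s): ",
                               paste(fl, collapse = ", ")) else "")
    }, character(1))
  }
  structure(list(quantiles = indications, flags = flags,
                 caveats = caveats, text = c(text, caveats)),
            class = "strategy_report")
}

#' @export
print.strategy_report <- function(x, ...) {
  cat("Population health strategy report\n")
  cat(paste0("  ", x$text, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a strategy report as JSON and plain text
#'
#' @param report a `"strategy_report"`.
#' @param path output path for the JSON document; a sibling `.txt` file
#'   holds the plain-text summary.
#' @return `path`, invisibly.
#' @export
write_strategy_report <- function(report, path) {
  stopifnot(inherits(report, "strategy_report"))
  obj <- list(quantiles = report$quantiles, flags = report$flags,
              caveats = report$caveats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  writeLines(report$text,
             paste0(tools::file_path_sans_ext(path), ".txt"))
  invisible(path)
}
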