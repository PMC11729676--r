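#' One group's validated sample
#'
#' Bundles a group label, an outcome vector, and a design matrix whose
#' first column is the constant 1. The intercept is always prepended by
#' the package; user-supplied design columns never include it.
#'
#' @param label group value.
#' @param outcome numeric outcome vector, no missing values.
#' @param design numeric matrix of covariates (without intercept), one
#'   row per subject; column names are kept.
#' @return an object of class `"group_sample"` with elements `label`,
#'   `outcome`, and `design` (the full n x (p+1) matrix including the
#'   intercept column `"(Intercept)"`).
#' @export
group_sample <- function(label, outcome, design) {
  outcome <- as.numeric(outcome)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  X <- cbind("(Intercept)" = 1, design)
  if (anyNA(outcome) || anyNA(X))
    stop("group sample may not contain missing values", call. = FALSE)
  if (any(!is.finite(outcome)) || any(!is.finite(X)))
    stop("group sample may not contain non-finite values", call. = FALSE)
  if (nrow(X) < ncol(X) + 1L)
    stop("insufficient data: group '", label, "' has n = ", nrow(X),
         " < p + 2 = ", ncol(X) + 1L, call. = FALSE)
  structure(list(label = label, outcome = outcome, design = X),
            class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  cat("Group sample '", x$label, "': n = ", length(x$outcome),
      ", design columns: ", paste(colnames(x$design), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Outlier screening of an outcome vector
#'
#' With `rule = "none"` all observations are kept. With
#' `rule = "quantile"` only values inside the closed empirical
#' `[lo, hi]` quantile interval of `outcome` are kept.
#'
#' @param outcome numeric vector.
#' @param rule `"none"` or `"quantile"`.
#' @param bounds numeric `c(lo, hi)` with `0 <= lo < hi <= 1`; required
#'   for the quantile rule.
#' @return list with `keep` (integer indices retained) and `dropped`
#'   (count removed).
#' @export
#' @examples
#' apply_outlier_rule(1:100, "quantile", c(0.01, 0.99))$dropped  # 2
apply_outlier_rule <- function(outcome, rule = c("none", "quantile"),
                               bounds = NULL) {
  rule <- match.arg(rule)
  outcome <- as.numeric(outcome)
  if (rule == "none")
    return(list(keep = seq_along(outcome), dropped = 0L))
  if (is.null(bounds) || length(bounds) != 2L || bounds[1] < 0 ||
      bounds[2] > 1 || bounds[1] >= bounds[2])
    stop("configuration error: outlier bounds must satisfy 0 <= lo < hi <= 1",
         call. = FALSE)
  qq <- quantile(outcome, probs = bounds, type = 7, names = FALSE,
                 na.rm = TRUE)
  keep <- which(!is.na(outcome) & outcome >= qq[1] & outcome <= qq[2])
  list(keep = keep, dropped = sum(!is.na(outcome)) - length(keep))
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Row accounting (input rows:", x$input_rows, ")\n")
  cat("  dropped, other group level: ", x$other_group, "\n")
  cat("  dropped, missing outcome:   ", x$missing_outcome, "\n")
  cat("  dropped, missing covariate: ", x$missing_covariate, "\n")
  cat("  dropped, outcome outlier:   ", x$outlier, "\n")
  for (g in names(x$retained))
    cat("  retained in group '", g, "': ", x$retained[[g]], "\n", sep = "")
  invisible(x)
}

num_or_parse_error <- function(v, what, rows) {
  if (is.numeric(v)) return(as.numeric(v))
  vc <- trimws(as.character(v))
  vc[vc == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(vc))
  bad <- which(is.na(out) & !is.na(vc))
  if (length(bad))
    stop("parse error: non-numeric value in column '", what,
         "' at input row ", rows[bad[1]], call. = FALSE)
  out
}

#' Load a delimited dataset and split it into two group samples
#'
#' Reads a delimited text file (header required), keeps the rows whose
#' group value equals the spec's reference or comparison level (other
#' levels are dropped with a warning), applies complete-case deletion
#' over the outcome and covariates, applies the spec's outlier rule to
#' the outcome, and returns one validated [group_sample()] per group
#' plus a full row-accounting log.
#'
#' @param path file path, or a data.frame to use directly.
#' @param spec a [decomp_spec()].
#' @return list with elements `reference`, `comparison` (both
#'   [group_sample()]) and `exclusions` (class `"exclusion_log"`).
#' @export
load_dataset <- function(path, spec) {
  stopifnot(inherits(spec, "decomp_spec"))
  if (is.data.frame(path)) {
    dat <- path
  } else {
    if (!file.exists(path))
      stop("configuration error: file not found: ", path, call. = FALSE)
    dat <- read.table(path, header = TRUE, sep = spec$delim,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8")
  }
  needed <- c(spec$outcome, spec$group, spec$covariates)
  miss <- setdiff(needed, names(dat))
  if (length(miss))
    stop("configuration error: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  n_in <- nrow(dat)
  rows <- seq_len(n_in)
  gval <- as.character(dat[[spec$group]])
  lv <- c(as.character(spec$reference), as.character(spec$comparison))
  in_groups <- !is.na(gval) & gval %in% lv
  n_other <- sum(!in_groups)
  if (n_other > 0L)
    warning(n_other, " row(s) with group levels outside {",
            paste(lv, collapse = ", "), "} dropped", call. = FALSE)
  dat <- dat[in_groups, , drop = FALSE]
  rows <- rows[in_groups]
  gval <- gval[in_groups]

  y <- num_or_parse_error(dat[[spec$outcome]], spec$outcome, rows)
  Xc <- matrix(NA_real_, nrow(dat), length(spec$covariates),
               dimnames = list(NULL, spec$covariates))
  for (v in spec$covariates)
    Xc[, v] <- num_or_parse_error(dat[[v]], v, rows)

  n_missing_y <- sum(is.na(y))
  ok_y <- !is.na(y)
  n_missing_x <- sum(ok_y & !complete.cases(Xc))
  cc <- ok_y & complete.cases(Xc)
  y <- y[cc]; Xc <- Xc[cc, , drop = FALSE]; gval <- gval[cc]

  ol <- apply_outlier_rule(y, spec$outlier_rule, spec$outlier_bounds)
  y <- y[ol$keep]; Xc <- Xc[ol$keep, , drop = FALSE]; gval <- gval[ol$keep]

  make_one <- function(level) {
    idx <- which(gval == level)
    if (length(idx) < length(spec$covariates) + 2L)
      stop("insufficient data: group '", level, "' has n = ", length(idx),
           " after exclusions (need at least p + 2 = ",
           length(spec$covariates) + 2L, ")", call. = FALSE)
    group_sample(level, y[idx], Xc[idx, , drop = FALSE])
  }
  ref <- make_one(as.character(spec$reference))
  cmp <- make_one(as.character(spec$comparison))

  log <- structure(list(
    input_rows = n_in, other_group = n_other,
    missing_outcome = n_missing_y, missing_covariate = n_missing_x,
    outlier = ol$dropped,
    retained = stats::setNames(
      list(length(ref$outcome), length(cmp$outcome)),
      c(ref$label, cmp$label))), class = "exclusion_log")
  stopifnot(n_in == n_other + n_missing_y + n_missing_x + ol$dropped +
              length(ref$outcome) + length(cmp$outcome))
  list(reference = ref, comparison = cmp, exclusions = log)
}

#' Write two group samples back to the delimited format load_dataset reads
#'
#' @param reference,comparison [group_sample()] objects.
#' @param spec a [decomp_spec()] supplying the column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(reference, comparison, spec, path) {
  stopifnot(inherits(spec, "decomp_spec"))
  one <- function(s) {
    d <- as.data.frame(s$design[, -1, drop = FALSE])
    names(d) <- spec$covariates
    d[[spec$outcome]] <- s$outcome
    d[[spec$group]] <- s$label
    d[, c(spec$outcome, spec$group, spec$covariates)]
  }
  out <- rbind(one(reference), one(comparison))
  write.table(out, path, sep = spec$delim, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
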