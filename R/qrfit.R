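#' Check (pinball) loss
#'
#' The objective whose minimizer over a linear predictor defines the
#' tau-th conditional quantile: `sum(u * (tau - (u < 0)))`.
#'
#' @param residuals numeric vector of residuals.
#' @param tau probability in (0, 1).
#' @return non-negative scalar.
#' @export
#' @examples
#' check_loss(2, 0.9)        # 1.8
#' check_loss(-2, 0.9)       # 0.2
#' check_loss(c(-1, 1), 0.5) # 1
check_loss <- function(residuals, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("domain error: tau must be in (0, 1)", call. = FALSE)
  sum(residuals * (tau - (residuals < 0)))
}

assert_full_rank <- function(design) {
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[seq(qd$rank + 1L, ncol(design))]]
    stop("singular design: collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit one linear quantile regression
#'
#' Minimizes the check loss of `outcome - design %*% beta` at a single
#' quantile. The design matrix must already carry its intercept column
#' (as built by [group_sample()]).
#'
#' @param design full-column-rank numeric matrix, n x (p+1).
#' @param outcome numeric vector of length n.
#' @param tau probability in (0, 1).
#' @return named coefficient vector with attributes `loss` (achieved
#'   check loss) and `tau`.
#' @export
fit_quantile <- function(design, outcome, tau) {
  design <- as.matrix(design)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("domain error: tau must be in (0, 1)", call. = FALSE)
  if (nrow(design) != length(outcome))
    stop("shape error: design rows and outcome length differ", call. = FALSE)
  if (nrow(design) < ncol(design))
    stop("insufficient data: need at least p + 1 observations",
         call. = FALSE)
  assert_full_rank(design)
  f <- .qr_fit_cpp(design, as.numeric(outcome), tau)
  beta <- drop(f$coefficients)
  if (any(!is.finite(beta)))
    stop("solver error: non-finite coefficients at tau = ", tau,
         call. = FALSE)
  names(beta) <- colnames(design)
  attr(beta, "loss") <- f$loss
  attr(beta, "tau") <- tau
  beta
}

#' Fit the full quantile coefficient process
#'
#' Runs [fit_quantile()] over an entire grid of probabilities and
#' returns the coefficient process, the basis of the counterfactual
#' decomposition.
#'
#' @param design full-column-rank numeric matrix, n x (p+1).
#' @param outcome numeric vector.
#' @param taus strictly increasing probabilities in (0, 1); an empty
#'   grid yields an empty (but valid) fit.
#' @param label optional group label carried along.
#' @return object of class `"qr_process"`: list with `tau`, `coef`
#'   (M x (p+1) matrix, row m = coefficients at `tau[m]`), `loss`,
#'   `label`, `n`.
#' @export
fit_process <- function(design, outcome, taus, label = NULL) {
  design <- as.matrix(design)
  taus <- as.numeric(taus)
  if (any(taus <= 0) || any(taus >= 1))
    stop("domain error: all taus must be in (0, 1)", call. = FALSE)
  if (length(taus) == 0L) {
    out <- list(tau = numeric(0),
                coef = matrix(numeric(0), 0, ncol(design),
                              dimnames = list(NULL, colnames(design))),
                loss = numeric(0), label = label, n = nrow(design))
    return(structure(out, class = "qr_process"))
  }
  if (nrow(design) != length(outcome))
    stop("shape error: design rows and outcome length differ", call. = FALSE)
  if (nrow(design) < ncol(design))
    stop("insufficient data: need at least p + 1 observations",
         call. = FALSE)
  assert_full_rank(design)
  f <- .qr_process_cpp(design, as.numeric(outcome), taus)
  coef <- f$coef
  dimnames(coef) <- list(NULL, colnames(design))
  if (any(!is.finite(coef))) {
    bad <- taus[which(rowSums(!is.finite(coef)) > 0)[1]]
    stop("solver error: non-finite coefficients at tau = ", bad,
         call. = FALSE)
  }
  structure(list(tau = taus, coef = coef, loss = drop(f$loss),
                 label = label, n = nrow(design)),
            class = "qr_process")
}

#' @export
coef.qr_process <- function(object, ...) object$coef

#' @export
print.qr_process <- function(x, ...) {
  cat("Quantile coefficient process",
      if (!is.null(x$label)) paste0(" for group '", x$label, "'"),
      ": ", length(x$tau), " quantiles, n = ", x$n, "\n", sep = "")
  if (length(x$tau)) {
    show <- x$tau %in% quantile(x$tau, c(0, 0.25, 0.5, 0.75, 1),
                                type = 1, names = FALSE)
    print(round(cbind(tau = x$tau, x$coef)[show, , drop = FALSE], 4))
  }
  invisible(x)
}

#' Evaluate the coefficient process at arbitrary quantiles
#'
#' Linear interpolation in tau, columnwise; exact at grid points.
#' Requested quantiles must lie within the fitted grid range.
#'
#' @param fit a `"qr_process"`.
#' @param taus probabilities inside the fitted grid range.
#' @return matrix length(taus) x (p+1).
#' @export
coef_at <- function(fit, taus) {
  stopifnot(inherits(fit, "qr_process"))
  if (length(fit$tau) == 0L)
    stop("empty quantile process", call. = FALSE)
  if (min(taus) < min(fit$tau) || max(taus) > max(fit$tau))
    stop("domain error: requested tau outside the fitted grid range",
         call. = FALSE)
  if (length(fit$tau) == 1L)
    return(fit$coef[rep(1L, length(taus)), , drop = FALSE])
  out <- vapply(seq_len(ncol(fit$coef)), function(j)
    approx(fit$tau, fit$coef[, j], xout = taus, ties = "ordered")$y,
    numeric(length(taus)))
  out <- matrix(out, nrow = length(taus),
                dimnames = list(NULL, colnames(fit$coef)))
  out
}

#' Write a per-group coefficient table
#'
#' One row per tau: tau, each coefficient, achieved check loss.
#'
#' @param fit a `"qr_process"`.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(fit, path, delim = ",") {
  stopifnot(inherits(fit, "qr_process"))
  tab <- data.frame(tau = fit$tau, fit$coef, loss = fit$loss,
                    check.names = FALSE)
  write.table(tab, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
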