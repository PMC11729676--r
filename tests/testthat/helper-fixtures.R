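# Shared fixtures and independent mini-oracles for the test suite.

# A coefficient-process object built directly from a matrix of "true"
# coefficients, bypassing estimation: lets decomposition operations be
# tested against hand-constructed processes.
process_from_matrix <- function(coef, taus, label = "synthetic") {
  structure(list(tau = taus,
                 coef = matrix(coef, nrow = length(taus),
                               dimnames = list(NULL, colnames(coef))),
                 loss = rep(0, length(taus)), label = label, n = NA),
            class = "qr_process")
}

# Location-scale truth beta + gamma * qnorm(tau) as a process matrix.
true_process <- function(beta, gamma, taus, label = "truth") {
  coef <- outer(qnorm(taus), gamma) + rep(beta, each = length(taus))
  colnames(coef) <- names(beta) %||% paste0("b", seq_along(beta) - 1)
  process_from_matrix(coef, taus, label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-group data.frame for io tests.
toy_df <- function() {
  data.frame(
    intake = c(10, 12, 14, 16, 20, 22, 24, 26),
    edu = rep(c("low", "high"), each = 4),
    income = c(1, 2, 3, 4, 5, 6, 7, 8))
}

toy_spec <- function(...) {
  decomp_spec(outcome = "intake", group = "edu", reference = "high",
              comparison = "low", covariates = "income",
              taus = c(0.25, 0.5, 0.75), report_taus = 0.5,
              bootstrap = 0L, ...)
}

# Empirical-quantile standard error sqrt(tau(1-tau)/n) / fhat(q),
# kernel density at the quantile; used as the Monte-Carlo noise scale
# when comparing estimates against zero or an oracle.
se_quantile <- function(y, taus, q = quantile(y, taus, type = 7,
                                              names = FALSE)) {
  d <- density(y, n = 1024)
  fhat <- pmax(approx(d$x, d$y, xout = q, rule = 2)$y, 1e-12)
  sqrt(taus * (1 - taus) / length(y)) / fhat
}

# Check-loss evaluated in R, independent of the package's C++ path.
loss_r <- function(res, tau) sum(res * (tau - (res < 0)))
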