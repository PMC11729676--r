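test_that("monotone rearrangement sorts and preserves the multiset", {
  expect_identical(rearrange_monotone(c(1, 2, 3)), c(1, 2, 3))
  expect_identical(rearrange_monotone(c(3, 1, 2)), c(1, 2, 3))
  set.seed(5)
  v <- rnorm(50)
  expect_identical(sort(rearrange_monotone(v)), sort(v))
})

test_that("marginal quantile functions handle degenerate pools", {
  taus <- c(0.2, 0.5, 0.8)
  # flat intercept, zero covariate effects: every quantile equals c
  fit <- process_from_matrix(cbind(b0 = rep(7, 3), b1 = 0), taus)
  q <- marginal_qf(fit, cbind(1, rnorm(10)), c(0.1, 0.5, 0.9))
  expect_equal(q$values, rep(7, 3))
  # single row, predictions {1,2,3} over a 3-point grid: pooled median 2
  fit2 <- process_from_matrix(cbind(b0 = c(1, 2, 3)), taus)
  q2 <- marginal_qf(fit2, matrix(1, 1, 1), 0.5)
  expect_equal(q2$values, 2)
  # width mismatch is a shape error
  expect_error(marginal_qf(fit, cbind(1, 1, 1:3), 0.5), "shape error")
})

test_that("counterfactual quantiles stay within the prediction pool", {
  set.seed(8)
  taus <- seq(0.05, 0.95, by = 0.05)
  fit <- process_from_matrix(
    cbind(b0 = qnorm(taus), b1 = 1 + 0.5 * qnorm(taus)), taus)
  X <- cbind(1, runif(40))
  q <- marginal_qf(fit, X, c(0.01, 0.5, 0.99))
  pool <- X %*% t(fit$coef)
  expect_true(all(q$values >= min(pool) & q$values <= max(pool)))
})

test_that("marginal construction matches direct location-scale simulation", {
  # oracle: y = x'beta + (x'gamma) eps with x resampled from the design
  beta <- c(1, 1, 0.5); gamma <- c(0.5, 0.1, 0)
  sc <- dgp_scenario("null")
  X <- generate_group(sc$reference, seed = 31, n = 1000)$design
  grid <- seq(0.005, 0.995, by = 0.005)
  fit <- true_process(beta, gamma, grid)
  taus_out <- seq(0.1, 0.9, by = 0.1)
  est <- marginal_qf(fit, X, taus_out)$values
  set.seed(32)
  draws <- 2e5
  idx <- sample.int(nrow(X), draws, replace = TRUE)
  ysim <- drop(X[idx, ] %*% beta) + drop(X[idx, ] %*% gamma) * rnorm(draws)
  oracle <- quantile(ysim, taus_out, type = 7, names = FALSE)
  tol <- 3 * se_quantile(ysim, taus_out, oracle) +
    max(X %*% gamma) * max(diff(qnorm(seq(0.05, 0.95, by = 0.005)))) / 2
  expect_true(all(abs(est - oracle) < tol))
})

test_that("aggregate decomposition is additive and null for self-comparison", {
  set.seed(9)
  taus <- seq(0.1, 0.9, by = 0.1)
  fit <- true_process(c(2, 1), c(1, 0.2), taus)
  X <- cbind(1, runif(30, 0, 2))
  agg <- aggregate_decompose(fit, fit, X, X, c(0.25, 0.5, 0.75))
  expect_true(all(agg$difference == 0))
  expect_true(all(agg$covariates_part == 0))
  expect_true(all(agg$coefficients_part == 0))
  # additivity holds exactly for distinct groups too
  fit2 <- true_process(c(1.5, 0.8), c(1, 0.2), taus)
  X2 <- cbind(1, runif(25, 0, 1.5))
  agg2 <- aggregate_decompose(fit, fit2, X, X2, taus)
  expect_equal(agg2$covariates_part + agg2$coefficients_part,
               agg2$difference, tolerance = 1e-12)
})

test_that("a pure location shift loads entirely on the coefficients part", {
  set.seed(10)
  taus <- seq(0.05, 0.95, by = 0.05)
  X <- cbind(1, rnorm(50))
  fit_cmp <- true_process(c(1, 0.5), c(1, 0), taus)
  fit_ref <- true_process(c(2, 0.5), c(1, 0), taus)   # intercept + 1
  agg <- aggregate_decompose(fit_ref, fit_cmp, X, X, c(0.2, 0.5, 0.8))
  expect_equal(agg$covariates_part, rep(0, 3), tolerance = 1e-12)
  expect_equal(agg$coefficients_part, rep(1, 3), tolerance = 1e-12)
})

test_that("swapping the reference group negates the total difference", {
  set.seed(12)
  taus <- seq(0.1, 0.9, by = 0.1)
  fit_a <- true_process(c(2, 1), c(1, 0.1), taus)
  fit_b <- true_process(c(1, 0.7), c(0.8, 0.1), taus)
  Xa <- cbind(1, runif(40)); Xb <- cbind(1, runif(35, 0, 2))
  f <- aggregate_decompose(fit_a, fit_b, Xa, Xb, taus)
  r <- aggregate_decompose(fit_b, fit_a, Xb, Xa, taus)
  expect_equal(r$difference, -f$difference, tolerance = 1e-12)
})

test_that("detailed decomposition matches hand-computed mean-based terms", {
  taus <- c(0.25, 0.5, 0.75)
  # intercept-only model with a pure intercept gap d(tau)
  d_tau <- c(1, 2, 3)
  f_ref <- process_from_matrix(cbind("(Intercept)" = 5 + d_tau), taus)
  f_cmp <- process_from_matrix(cbind("(Intercept)" = rep(5, 3)), taus)
  X1 <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  agg <- aggregate_decompose(f_ref, f_cmp, X1, X1, taus)
  det <- detailed_decompose(f_ref, f_cmp, X1, X1, agg)
  icpt <- det[det$term == "(Intercept)", ]
  expect_equal(icpt$coefficients_detail, d_tau)
  expect_equal(icpt$covariates_detail, rep(0, 3))
  expect_equal(det$covariates_detail[det$term == "(remainder)"], rep(0, 3),
               tolerance = 1e-12)
  expect_equal(det$coefficients_detail[det$term == "(remainder)"], rep(0, 3),
               tolerance = 1e-12)

  # two-covariate fixture: spreadsheet-style recomputation from the
  # coefficient tables and column means
  set.seed(13)
  fr <- true_process(c(2, 1, -0.5), c(1, 0.2, 0), taus,
                     label = "ref")
  fc <- true_process(c(1, 0.6, -0.2), c(1, 0.1, 0), taus)
  colnames(fr$coef) <- colnames(fc$coef) <- c("(Intercept)", "u", "v")
  Xr <- cbind(1, u = runif(30), v = rnorm(30))
  Xc <- cbind(1, u = runif(25, 0, 2), v = rnorm(25, 1))
  colnames(Xr)[1] <- colnames(Xc)[1] <- "(Intercept)"
  agg2 <- aggregate_decompose(fr, fc, Xr, Xc, taus)
  det2 <- detailed_decompose(fr, fc, Xr, Xc, agg2)
  for (i in seq_along(taus)) {
    for (k in c("u", "v")) {
      expect_equal(
        det2$covariates_detail[det2$tau == taus[i] & det2$term == k],
        unname((mean(Xr[, k]) - mean(Xc[, k])) * fr$coef[i, k]),
        tolerance = 1e-12)
      expect_equal(
        det2$coefficients_detail[det2$tau == taus[i] & det2$term == k],
        unname(mean(Xc[, k]) * (fr$coef[i, k] - fc$coef[i, k])),
        tolerance = 1e-12)
    }
    # details + remainder reconstruct each aggregate part exactly
    sl <- det2[det2$tau == taus[i], ]
    expect_equal(sum(sl$covariates_detail),
                 agg2$covariates_part[i], tolerance = 1e-12)
    expect_equal(sum(sl$coefficients_detail),
                 agg2$coefficients_part[i], tolerance = 1e-12)
  }
  # equal covariate means across groups: all non-intercept covariate
  # details vanish
  Xs <- Xr
  det3 <- detailed_decompose(fr, fc, Xr, Xs,
                             aggregate_decompose(fr, fc, Xr, Xs, taus))
  expect_equal(det3$covariates_detail[det3$term %in% c("u", "v")],
               rep(0, 6), tolerance = 1e-12)
})

test_that("contribution percentages follow the published convention", {
  expect_equal(round(contribution_percent(17.1, 21.3), 1), 80.3)
  expect_equal(contribution_percent(0, 5), 0)
  expect_equal(contribution_percent(7.2, 7.2), 100)
  expect_true(is.na(contribution_percent(1, 0)))
})
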