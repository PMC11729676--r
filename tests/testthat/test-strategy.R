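# Published-table fixture: predicted group quantiles, parts and the
# pointwise CIs of an education-gap decomposition of energy-adjusted
# fruit/vegetable intake, keyed in at their printed precision. CI cells
# not printed are NA.
table_fixture <- function() {
  taus <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  agg <- data.frame(
    tau = taus,
    q_reference = c(78.7, 112.4, 158.4, 208.9, 269.7),
    q_comparison = c(65.3, 91.1, 134.6, 174.5, 228.3),
    difference = c(13.4, 21.3, 23.8, 34.4, 41.4),
    covariates_part = c(5.3, 4.2, 5.0, 8.7, 15.1),
    coefficients_part = c(8.1, 17.1, 18.9, 25.7, 26.3))
  agg$contribution_covariates <-
    contribution_percent(agg$covariates_part, agg$difference)
  agg$contribution_coefficients <-
    contribution_percent(agg$coefficients_part, agg$difference)
  class(agg) <- c("aggregate_decomposition", "data.frame")
  ci <- list(
    difference = list(`0.1` = c(3.3, 23.5), `0.25` = c(10.0, 32.7),
                      `0.5` = c(12.8, 34.8), `0.75` = c(18.1, 50.6),
                      `0.9` = c(18.4, 64.4)),
    covariates_part = list(`0.1` = c(1.6, 9.0), `0.25` = c(-1.0, 9.4),
                           `0.5` = c(NA_real_, NA_real_),
                           `0.75` = c(NA_real_, NA_real_),
                           `0.9` = c(5.4, 24.8)),
    coefficients_part = list(`0.1` = c(-2.1, 18.3), `0.25` = c(4.5, 29.8),
                             `0.5` = c(NA_real_, NA_real_),
                             `0.75` = c(NA_real_, NA_real_),
                             `0.9` = c(NA_real_, NA_real_)))
  list(agg = agg, ci = ci)
}

ci_at <- function(fx, tau) {
  key <- as.character(tau)
  list(covariates_part = fx$ci$covariates_part[[key]],
       coefficients_part = fx$ci$coefficients_part[[key]],
       difference = fx$ci$difference[[key]])
}

test_that("quantile classification follows significance and dominance", {
  fx <- table_fixture()
  # lowest quantile: coefficients dominant but only covariates part
  # significant -> proportionate universalism as the supplement
  r10 <- classify_quantile(fx$agg[1, ], ci_at(fx, 0.1))
  expect_identical(r10$dominant_part, "coefficients")
  expect_true(r10$covariates_significant)
  expect_false(r10$coefficients_significant)
  expect_identical(r10$indication, "proportionate_universalism")
  # first quartile: only coefficients part significant -> targeted
  r25 <- classify_quantile(fx$agg[2, ], ci_at(fx, 0.25))
  expect_identical(r25$indication, "targeted")
  # both significant -> combined
  r <- classify_quantile(fx$agg[1, ],
                         list(covariates_part = c(1.6, 9.0),
                              coefficients_part = c(2.1, 18.3),
                              difference = c(3.3, 23.5)))
  expect_identical(r$indication, "combined")
  # no disparity at all -> none
  zero <- fx$agg[1, ]
  zero$difference <- zero$covariates_part <- zero$coefficients_part <- 0
  zero$contribution_covariates <- zero$contribution_coefficients <- NA
  r0 <- classify_quantile(zero, list(covariates_part = c(0, 0),
                                     coefficients_part = c(0, 0),
                                     difference = c(0, 0)))
  expect_identical(r0$indication, "none")
  expect_identical(r0$dominant_part, "none")
})

test_that("classification is invariant to positive outcome rescaling", {
  fx <- table_fixture()
  scaled <- fx$agg
  for (v in c("q_reference", "q_comparison", "difference",
              "covariates_part", "coefficients_part"))
    scaled[[v]] <- scaled[[v]] * 3.7
  for (i in c(1, 2)) {
    tau <- fx$agg$tau[i]
    ci <- ci_at(fx, tau)
    ci_s <- lapply(ci, function(v) v * 3.7)
    expect_identical(classify_quantile(fx$agg[i, ], ci)$indication,
                     classify_quantile(scaled[i, ], ci_s)$indication)
  }
})

test_that("countervailing covariates are flagged by the sign rule", {
  det <- data.frame(
    tau = rep(0.5, 4),
    term = c("(Intercept)", "income", "network", "(remainder)"),
    covariates_detail = c(0, 2.0, 1.5, 0.1),
    coefficients_detail = c(4, 3.0, -1.0, 0.2))
  fl <- detect_countervailing(det, gap_sign = 1, floor = 0.5)
  expect_identical(fl$term, "income")       # (+,+) above floor
  expect_match(fl$note, "structural")
  # (+,-) never flags; below-floor never flags; intercept never flags
  fl2 <- detect_countervailing(det, gap_sign = 1, floor = 2.5)
  expect_identical(nrow(fl2), 0L)
  det0 <- det; det0$covariates_detail <- det0$coefficients_detail <- 0
  expect_identical(nrow(detect_countervailing(det0, 1, 0)), 0L)
})

test_that("the strategy report narrates the published pattern", {
  fx <- table_fixture()
  ind <- do.call(rbind, lapply(seq_len(5), function(i)
    classify_quantile(fx$agg[i, ], ci_at(fx, fx$agg$tau[i]))))
  det <- data.frame(tau = rep(fx$agg$tau, each = 2),
                    term = rep(c("(Intercept)", "income"), 5),
                    covariates_detail = rep(c(0, 1), 5),
                    coefficients_detail = rep(c(1, 2), 5))
  rep <- render_strategy_report(ind, detect_countervailing(det, 1, 0),
                                fx$agg, det)
  expect_true(all(ind$dominant_part == "coefficients"))
  expect_identical(which(ind$covariates_significant), c(1L, 5L))
  expect_false(any(ind$covariates_significant[2]))
  txt <- paste(rep$text, collapse = "\n")
  expect_match(txt, "dominant part: coefficients")
  expect_match(txt, "countervailing covariate.*income")
})

test_that("an all-zero decomposition reports no disparity", {
  agg <- data.frame(tau = 0.5, q_reference = 1, q_comparison = 1,
                    difference = 0, covariates_part = 0,
                    coefficients_part = 0,
                    contribution_covariates = NA,
                    contribution_coefficients = NA)
  class(agg) <- c("aggregate_decomposition", "data.frame")
  ind <- classify_quantile(agg[1, ], list(covariates_part = c(0, 0),
                                          coefficients_part = c(0, 0),
                                          difference = c(0, 0)))
  det <- data.frame(tau = 0.5, term = "(Intercept)",
                    covariates_detail = 0, coefficients_detail = 0)
  rep <- render_strategy_report(ind, detect_countervailing(det, 1, 0),
                                agg, det)
  expect_match(paste(rep$text, collapse = " "), "no disparity detected")
})

test_that("an intercept-driven coefficients part triggers the caveat", {
  agg <- data.frame(tau = 0.1, q_reference = 10, q_comparison = 5,
                    difference = 5, covariates_part = 1,
                    coefficients_part = 4,
                    contribution_covariates = 20,
                    contribution_coefficients = 80)
  class(agg) <- c("aggregate_decomposition", "data.frame")
  ind <- classify_quantile(agg[1, ], list(covariates_part = c(0.5, 1.5),
                                          coefficients_part = c(2, 6),
                                          difference = c(3, 7)))
  det <- data.frame(tau = 0.1, term = c("(Intercept)", "income"),
                    covariates_detail = c(0, 1),
                    coefficients_detail = c(3.5, 0.5))
  rep <- render_strategy_report(ind, detect_countervailing(det, 1, 0),
                                agg, det)
  expect_match(paste(rep$caveats, collapse = " "), "unmeasured factors")
})

test_that("strategy reports serialize to JSON and text", {
  fx <- table_fixture()
  ind <- do.call(rbind, lapply(seq_len(5), function(i)
    classify_quantile(fx$agg[i, ], ci_at(fx, fx$agg$tau[i]))))
  det <- data.frame(tau = fx$agg$tau, term = "(Intercept)",
                    covariates_detail = 0, coefficients_detail = 1)
  rep <- render_strategy_report(ind, detect_countervailing(det, 1, 0),
                                fx$agg, det)
  path <- withr::local_tempfile(fileext = ".json")
  write_strategy_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_identical(length(back$quantiles), 5L)
  expect_identical(back$quantiles[[1]]$indication,
                   "proportionate_universalism")
  expect_true(file.exists(sub("json$", "txt", path)))
})
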