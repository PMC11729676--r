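test_that("density summaries match known normal values and normalize", {
  set.seed(20)
  y <- rnorm(1e4)
  d <- density_summary(list(a = y, b = y))
  at0 <- approx(d$grid, d$density$a, xout = 0)$y
  expect_equal(at0, 0.3989, tolerance = 0.05)
  step <- diff(d$grid[1:2])
  expect_equal(sum(d$density$a) * step, 1, tolerance = 0.01)
  expect_identical(d$density$a, d$density$b)   # identical groups
  expect_error(density_summary(list(a = rep(3, 10))), "'a' has zero variance")
  expect_error(density_summary(list(a = 1)), "fewer than 2")
})

test_that("display tables round half-up and flag undefined contributions", {
  agg <- data.frame(tau = c(0.25, 0.5), q_reference = c(39.55, 1),
                    q_comparison = c(10, 1), difference = c(29.55, 0),
                    covariates_part = c(10.04, 0),
                    coefficients_part = c(19.51, 0))
  agg$contribution_covariates <-
    contribution_percent(agg$covariates_part, agg$difference)
  agg$contribution_coefficients <-
    contribution_percent(agg$coefficients_part, agg$difference)
  class(agg) <- c("aggregate_decomposition", "data.frame")
  path <- withr::local_tempfile(fileext = ".csv")
  write_decomposition_table(agg, NULL, path)
  disp <- read.csv(path, check.names = FALSE, colClasses = "character")
  expect_identical(disp$Q25[disp$quantity == "predicted reference"], "39.6")
  expect_identical(disp$Q50[disp$quantity == "difference"], "0.0")
  expect_identical(disp$Q50[disp$quantity == "covariates contribution"],
                   "undefined")
  # machine-readable twin re-reads to the in-memory values exactly
  full <- read.csv(sub("\\.csv$", "_full.csv", path))
  expect_equal(full$difference, agg$difference, tolerance = 1e-12)
  expect_equal(full$covariates_part, agg$covariates_part,
               tolerance = 1e-12)
})

test_that("the end-to-end runner writes every artifact and is exact", {
  sim <- simulate_education_study(seed = 33)
  input <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$reference, sim$comparison, sim$spec, input)
  outdir <- withr::local_tempdir()
  spec <- sim$spec
  spec$taus <- seq(0.1, 0.9, by = 0.1)
  spec$report_taus <- c(0.25, 0.5, 0.75)
  spec$bootstrap <- 5L
  man <- run_decompose(spec, input = input, outdir = outdir)
  expect_s3_class(man, "run_manifest")
  expect_true(all(file.exists(man$outputs)))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  # every number in the outputs is reproducible by library calls alone
  loaded <- load_dataset(input, spec)
  fr <- fit_process(loaded$reference$design, loaded$reference$outcome,
                    spec$taus)
  fc <- fit_process(loaded$comparison$design, loaded$comparison$outcome,
                    spec$taus)
  agg <- aggregate_decompose(fr, fc, loaded$reference$design,
                             loaded$comparison$design, spec$report_taus)
  full <- read.csv(file.path(outdir, "decomposition_full.csv"))
  expect_equal(full$difference, agg$difference, tolerance = 1e-10)
  expect_equal(full$covariates_part, agg$covariates_part,
               tolerance = 1e-10)
  # determinism: a rerun with the same seed is byte-identical
  outdir2 <- withr::local_tempdir()
  run_decompose(spec, input = input, outdir = outdir2)
  expect_identical(
    readLines(file.path(outdir, "decomposition_full.csv")),
    readLines(file.path(outdir2, "decomposition_full.csv")))
})

test_that("zero-replicate runs leave the CI columns empty", {
  sim <- simulate_education_study(seed = 34)
  input <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$reference, sim$comparison, sim$spec, input)
  outdir <- withr::local_tempdir()
  spec <- sim$spec
  spec$taus <- seq(0.25, 0.75, by = 0.25)
  spec$report_taus <- 0.5
  spec$bootstrap <- 0L
  run_decompose(spec, input = input, outdir = outdir)
  disp <- read.csv(file.path(outdir, "decomposition.csv"),
                   colClasses = "character")
  expect_identical(disp$Q50[disp$quantity == "difference CI"], "")
  expect_false(disp$Q50[disp$quantity == "difference"] == "")
})

test_that("configuration can come from a flat YAML file", {
  sim <- simulate_education_study(seed = 35)
  input <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$reference, sim$comparison, sim$spec, input)
  outdir <- withr::local_tempdir()
  cfg <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    input = input, outdir = outdir,
    outcome = "intake", group = "education",
    reference = sim$spec$reference, comparison = sim$spec$comparison,
    covariates = sim$spec$covariates,
    taus = c(0.25, 0.5, 0.75), report_taus = 0.5,
    bootstrap = 0, seed = 9), cfg)
  man <- run_decompose(cfg)
  expect_true(file.exists(file.path(outdir, "decomposition.csv")))
  expect_identical(man$seed, 9L)
})

test_that("the command-line wrapper is syntactically valid R", {
  cli <- system.file("cli", "quantgap.R", package = "quantgap")
  expect_true(nzchar(cli))
  expect_silent(parse(file = cli))
})
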