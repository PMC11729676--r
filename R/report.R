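# Output rendering and the end-to-end run orchestrator. Display tables
# round half-up to one decimal; a parallel machine-readable file always
# keeps full precision, so printed-rounding artifacts can never leak
# into downstream computation.

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1))

#' Kernel density summary of the outcome by group
#'
#' Gaussian-kernel densities on a shared grid; bandwidth per group by
#' Silverman's rule of thumb ([stats::bw.nrd0()]), recorded in the
#' result. Each curve integrates to 1 on the grid within 1%.
#'
#' @param outcomes named list of numeric vectors, one per group, each
#'   of length at least 2.
#' @param n_grid number of grid points.
#' @return list with `grid`, `density` (named list of curves),
#'   `bandwidth` (named numeric).
#' @export
density_summary <- function(outcomes, n_grid = 512) {
  stopifnot(is.list(outcomes), length(outcomes) >= 1L,
            !is.null(names(outcomes)))
  for (g in names(outcomes)) {
    y <- outcomes[[g]]
    if (length(y) < 2L)
      stop("density error: group '", g, "' has fewer than 2 observations",
         call. = FALSE)
    if (sd(y) == 0)
      stop("density error: group '", g, "' has zero variance", call. = FALSE)
  }
  bw <- vapply(outcomes, stats::bw.nrd0, numeric(1))
  lo <- min(vapply(outcomes, min, numeric(1))) - 3 * max(bw)
  hi <- max(vapply(outcomes, max, numeric(1))) + 3 * max(bw)
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- lapply(names(outcomes), function(g)
    density(outcomes[[g]], bw = bw[[g]], from = lo, to = hi,
            n = n_grid)$y)
  names(dens) <- names(outcomes)
  list(grid = grid, density = dens, bandwidth = bw)
}

#' Write the decomposition table
#'
#' Mirrors the canonical layout: predicted quantiles per group, the
#' difference, each part with its pointwise CI and contribution share.
#' `path` gets the one-decimal display table (half-up rounding);
#' `<path minus extension>_full.csv` keeps full precision and
#' round-trips through [utils::read.table()].
#'
#' @param agg an [aggregate_decompose()] result.
#' @param ci the matching `"gap_bootstrap"` aggregate table (or `NULL`
#'   for empty CI columns).
#' @param path output path for the display table.
#' @param delim field delimiter.
#' @return invisible character vector of the two paths written.
#' @export
write_decomposition_table <- function(agg, ci, path, delim = ",") {
  qn <- paste0("Q", round(agg$tau * 100))
  ci_txt <- function(q) vapply(agg$tau, function(tau) {
    if (is.null(ci)) return("")
    r <- ci[ci$tau == tau & ci$quantity == q, ]
    if (!nrow(r) || anyNA(r[, c("lower", "upper")])) return("")
    sprintf("(%s; %s)", fmt1(r$lower), fmt1(r$upper))
  }, "")
  pct <- function(v) ifelse(is.na(v), "undefined", paste0(fmt1(v), "%"))
  disp <- data.frame(
    row = c("predicted reference", "predicted comparison", "difference",
            "difference CI", "covariates part", "covariates CI",
            "covariates contribution", "coefficients part",
            "coefficients CI", "coefficients contribution"),
    rbind(fmt1(agg$q_reference), fmt1(agg$q_comparison),
          fmt1(agg$difference), ci_txt("difference"),
          fmt1(agg$covariates_part), ci_txt("covariates_part"),
          pct(agg$contribution_covariates),
          fmt1(agg$coefficients_part), ci_txt("coefficients_part"),
          pct(agg$contribution_coefficients)))
  names(disp) <- c("quantity", qn)
  write.table(disp, path, sep = delim, row.names = FALSE, quote = FALSE)

  full_path <- paste0(tools::file_path_sans_ext(path), "_full.csv")
  full <- as.data.frame(agg)
  if (!is.null(ci)) {
    for (q in c("difference", "covariates_part", "coefficients_part")) {
      r <- ci[ci$quantity == q, ]
      full[[paste0(q, "_lower")]] <- r$lower[match(agg$tau, r$tau)]
      full[[paste0(q, "_upper")]] <- r$upper[match(agg$tau, r$tau)]
    }
  }
  write.table(full, full_path, sep = delim, row.names = FALSE,
              quote = FALSE)
  invisible(c(path, full_path))
}

#' Run the full decomposition pipeline and write all artifacts
#'
#' Loads the data (or takes pre-built samples), fits, decomposes,
#' bootstraps, classifies strategies, and writes: the decomposition
#' table (display + full precision), one coefficient table per group,
#' the detailed per-covariate table, the strategy report (JSON + text),
#' and a run manifest. Any stage error aborts with a stage-named
#' message.
#'
#' @param config either a [decomp_spec()] plus `input` path given
#'   separately, or a named list / YAML file path with fields mirroring
#'   [decomp_spec()] plus `input` (data file) and `outdir`.
#' @param input path of the delimited input data (overrides config).
#' @param outdir output directory (created if needed; overrides
#'   config).
#' @return the run manifest (class `"run_manifest"`), invisibly.
#' @export
run_decompose <- function(config, input = NULL, outdir = NULL) {
  t0 <- Sys.time()
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "decomp_spec")) {
    spec <- config
    config <- list()
  } else {
    stopifnot(is.list(config))
    input <- input %||% config$input
    outdir <- outdir %||% config$outdir
    args <- config[intersect(names(config),
                             names(formals(decomp_spec)))]
    spec <- do.call(decomp_spec, args)
  }
  if (is.null(input)) stop("stage config: no input file given", call. = FALSE)
  if (is.null(outdir)) outdir <- "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  loaded <- tryCatch(load_dataset(input, spec), error = function(e)
    stop("stage load: ", conditionMessage(e), call. = FALSE))
  boot <- tryCatch(
    bootstrap_decomposition(loaded$reference, loaded$comparison, spec),
    error = function(e)
      stop("stage estimate: ", conditionMessage(e), call. = FALSE))
  agg <- boot$point$aggregate
  strat <- tryCatch({
    ind <- classify_quantiles(agg, boot)
    gs <- sign(sum(sign(agg$difference))); if (gs == 0) gs <- 1
    fl <- detect_countervailing(boot$detailed, gap_sign = gs,
                                floor = 0.01 * abs(agg$difference))
    render_strategy_report(ind, fl, agg, boot$point$detailed)
  }, error = function(e)
    stop("stage strategy: ", conditionMessage(e), call. = FALSE))

  out <- function(f) file.path(outdir, f)
  paths <- tryCatch({
    p1 <- write_decomposition_table(agg, boot$aggregate,
                                    out("decomposition.csv"))
    write_coef_table(boot$point$fit_ref, out("coefficients_reference.csv"))
    write_coef_table(boot$point$fit_cmp, out("coefficients_comparison.csv"))
    write.table(boot$detailed, out("detailed_decomposition.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    write_strategy_report(strat, out("strategy_report.json"))
    c(p1, out("coefficients_reference.csv"),
      out("coefficients_comparison.csv"),
      out("detailed_decomposition.csv"), out("strategy_report.json"),
      sub("json$", "txt", out("strategy_report.json")))
  }, error = function(e)
    stop("stage write: ", conditionMessage(e), call. = FALSE))

  manifest <- structure(list(
    package_version = as.character(packageVersion("quantgap")),
    started = format(t0, usetz = TRUE),
    finished = format(Sys.time(), usetz = TRUE),
    seed = spec$seed,
    input = if (is.character(input)) input else "<data.frame>",
    input_md5 = if (is.character(input))
      unname(tools::md5sum(input)) else NA_character_,
    config = unclass(spec),
    exclusions = unclass(loaded$exclusions),
    bandwidth = tryCatch(density_summary(list(
      reference = loaded$reference$outcome,
      comparison = loaded$comparison$outcome))$bandwidth,
      error = function(e) NULL),
    outputs = paths), class = "run_manifest")
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  stopifnot(all(file.exists(paths)))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("quantgap run manifest (v", x$package_version, ", seed ", x$seed,
      ")\n", sep = "")
  cat("  input:  ", x$input, "\n")
  cat("  outputs:\n")
  for (p in x$outputs) cat("    ", p, "\n")
  invisible(x)
}
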