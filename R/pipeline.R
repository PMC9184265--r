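# End-to-end orchestration: cohort -> staging window -> indeterminate
# resolution -> imputation -> model validation -> decision curves, with
# every output written as delimited text and a manifest for reproduction.

#' Summarize a cohort the way a registry characteristics table is laid out
#'
#' Per-variable summaries (counts/percentages for categorical variables,
#' median and IQR or mean and range for continuous ones) stratified by
#' staging-scan result, plus per-variable missingness percentages.
#' Percentages are rounded half-up to one decimal by default; `truncate`
#' reproduces tables that truncate instead (e.g. an indeterminate fraction
#' printed as 3.6% for 150/4079).
#'
#' @param cohort cohort table.
#' @param percent_mode `"half-up"` (default) or `"truncate"`.
#' @return `data.frame` with columns variable, statistic, overall,
#'   negative, positive, no_scan.
#' @export
summarize_cohort <- function(cohort, percent_mode = c("half-up",
                                                      "truncate")) {
  percent_mode <- match.arg(percent_mode)
  if (nrow(cohort) == 0) stop_stage("summary", "empty cohort")
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    p <- 100 * num / den
    if (percent_mode == "truncate") floor(p * 10) / 10
    else round_half_up(p, 1)
  }
  strata <- list(
    overall = rep(TRUE, nrow(cohort)),
    negative = cohort$scan_result == "negative",
    positive = cohort$scan_result == "positive",
    no_scan = cohort$scan_result == "none"
  )
  row <- function(variable, statistic, fn) {
    vals <- vapply(strata, function(s) fn(cohort[s, , drop = FALSE]),
                   character(1))
    data.frame(variable = variable, statistic = statistic,
               overall = vals[1], negative = vals[2], positive = vals[3],
               no_scan = vals[4], stringsAsFactors = FALSE)
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75))
    sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
  }
  mean_range <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    sprintf("%.2f [%.0f, %.0f]", mean(x), min(x), max(x))
  }
  count_pct <- function(flag) {
    function(d) {
      f <- flag(d)
      sprintf("%d (%.1f)", sum(f, na.rm = TRUE),
              pct(sum(f, na.rm = TRUE), sum(!is.na(f))))
    }
  }
  miss_pct <- function(col) {
    function(d) sprintf("%.1f%%", pct(sum(is.na(d[[col]])), nrow(d)))
  }
  gg <- isup_grade_group(cohort$gleason_primary, cohort$gleason_secondary)
  cohort$..gg <- gg
  n_scanned <- sum(cohort$scan_result != "none")
  n_pos <- sum(cohort$scan_result == "positive")
  n_ind <- sum(cohort$scan_result == "indeterminate")
  out <- rbind(
    row("n", "count", function(d) sprintf("%d", nrow(d))),
    row("age_years", "mean [range]", function(d) mean_range(d$age_years)),
    row("psa_ng_ml", "median [IQR]", function(d) med_iqr(d$psa_ng_ml)),
    row("psa_ng_ml", "missing", miss_pct("psa_ng_ml")),
    row("gleason <=6", "n (%)", count_pct(function(d) d$..gg == 1)),
    row("gleason 3+4", "n (%)", count_pct(function(d) d$..gg == 2)),
    row("gleason 4+3", "n (%)", count_pct(function(d) d$..gg == 3)),
    row("gleason >=8", "n (%)", count_pct(function(d) d$..gg >= 4)),
    row("gleason", "missing", miss_pct("gleason_primary")),
    row("pct_pos_cores", "median [IQR]",
        function(d) med_iqr(d$pct_pos_cores)),
    row("pct_pos_cores", "missing", miss_pct("pct_pos_cores")),
    row("t_stage T1", "n (%)",
        count_pct(function(d) t_stage_rank(d$t_stage) <= 3)),
    row("t_stage T2", "n (%)",
        count_pct(function(d) t_stage_rank(d$t_stage) %in% 4:6)),
    row("t_stage T3", "n (%)",
        count_pct(function(d) t_stage_rank(d$t_stage) %in% 7:9)),
    row("t_stage T4", "n (%)",
        count_pct(function(d) t_stage_rank(d$t_stage) == 10)),
    row("t_stage", "missing", miss_pct("t_stage")),
    row("nodal positive", "n (%)",
        count_pct(function(d) d$n_stage_positive)),
    row("nodal", "missing", miss_pct("n_stage_positive")),
    data.frame(variable = "scan positivity", statistic = "% of scanned",
               overall = sprintf("%d/%d (%.1f)", n_pos, n_scanned,
                                 pct(n_pos, n_scanned)),
               negative = "-", positive = "-", no_scan = "-"),
    data.frame(variable = "scan indeterminate", statistic = "% of scanned",
               overall = sprintf("%d/%d (%.1f)", n_ind, n_scanned,
                                 pct(n_ind, n_scanned)),
               negative = "-", positive = "-", no_scan = "-")
  )
  rownames(out) <- NULL
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `generator` (a [generator_config()]) or `cohort_path`
#' (a delimited cohort file) supplies the input cohort.
#'
#' @param generator optional [generator_config()].
#' @param cohort_path optional path to a cohort CSV.
#' @param m,iterations,seed imputation settings.
#' @param models model names to validate (default: all registered).
#' @param strategies strategy names for the decision curves (default: all).
#' @param grid threshold grid.
#' @param window_days staging-scan window.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = NULL, cohort_path = NULL, m = 5,
                       iterations = 10, seed = 42, models = NULL,
                       strategies = NULL, grid = pt_grid(),
                       window_days = 140, out_dir = tempfile("bonedca_")) {
  if (is.null(generator) == is.null(cohort_path)) {
    stop_stage("config",
               "exactly one of generator/cohort_path must be supplied")
  }
  if (any(grid <= 0 | grid >= 1)) {
    stop_stage("config", "grid bounds must lie in (0, 1)")
  }
  structure(list(generator = generator, cohort_path = cohort_path, m = m,
                 iterations = iterations, seed = seed, models = models,
                 strategies = strategies, grid = grid,
                 window_days = window_days, out_dir = out_dir),
            class = "run_config")
}

#' Serialize / load a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$generator)) x$generator <- unclass(x$generator)
  # 17 significant digits: doubles survive the round trip bit-exactly,
  # so a reloaded config re-runs to identical outputs
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- NULL
  if (!is.null(x$generator)) {
    g <- x$generator
    # JSON stores arrays without names/dimnames; restore the canonical ones
    # (element order is fixed by the writer)
    dn <- list(c("public", "private"), c("low", "intermediate", "high"))
    for (nm in names(g$missingness)) {
      g$missingness[[nm]] <- matrix(unlist(g$missingness[[nm]]), nrow = 2,
                                    dimnames = dn)
    }
    g$scanning$prob <- matrix(unlist(g$scanning$prob), nrow = 2,
                              dimnames = dn)
    g$predictors$t_group_probs <- stats::setNames(
      unlist(g$predictors$t_group_probs), c("T1", "T2", "T3", "T4"))
    g$predictors$t_within <- list(
      T1 = stats::setNames(unlist(g$predictors$t_within$T1),
                           c("T1a", "T1b", "T1c")),
      T2 = stats::setNames(unlist(g$predictors$t_within$T2),
                           c("T2a", "T2b", "T2c")),
      T3 = stats::setNames(unlist(g$predictors$t_within$T3),
                           c("T3a", "T3b", "T3c")))
    gen <- generator_config(
      n_patients = g$n_patients, seed = g$seed,
      predictors = g$predictors, risk = g$risk, scanning = g$scanning,
      missingness = g$missingness, survival = g$survival)
  }
  run_config(generator = gen, cohort_path = x$cohort_path, m = x$m,
             iterations = x$iterations, seed = x$seed, models = x$models,
             strategies = x$strategies, grid = x$grid,
             window_days = x$window_days, out_dir = x$out_dir)
}

#' Run the full staging-strategy evaluation pipeline
#'
#' Generates (or loads) the cohort, restricts scans to the staging window,
#' resolves indeterminate scans with follow-up labels, imputes missing
#' predictors and scan outcomes, validates every model (calibration and
#' AUC, Rubin-pooled) and builds the decision curves and optimal-strategy
#' map. All outputs are written to `config$out_dir` as delimited text,
#' along with a JSON manifest embedding the configuration. Deterministic
#' given the seed; a failure at any stage aborts with a stage-labelled
#' message and removes partial outputs.
#'
#' @param config a [run_config()].
#' @param registry a [model_registry()] (default registry if omitted).
#' @param quiet suppress progress messages?
#' @return invisibly, a list with `cohort_summary`, `validation`, `dca`,
#'   `imputed_set`, and `out_dir`.
#' @export
run_pipeline <- function(config, registry = model_registry(),
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    stop_stage("config", "config must be a run_config object")
  }
  say <- function(...) if (!quiet) message("[bonedca] ", ...)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok && created) unlink(out_dir, recursive = TRUE)
  })

  unknown <- setdiff(config$models %||% character(0),
                     names(registry$models))
  if (length(unknown)) {
    stop_stage("config", "unregistered model: ",
               paste(unknown, collapse = ", "))
  }

  say("stage 1/5: cohort")
  cohort <- if (!is.null(config$generator)) {
    generate_cohort(config$generator)
  } else {
    read_cohort(config$cohort_path)
  }
  labels <- attr(cohort, "followup_labels")
  cohort <- flag_staging_scans(cohort, config$window_days)
  cohort <- reclassify_indeterminate(cohort, labels)
  summary_tab <- summarize_cohort(cohort)
  utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE, na = "")
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  say("stage 2/5: imputation (m = ", config$m, ")")
  imp <- mice_impute(cohort, m = config$m, iterations = config$iterations,
                     seed = derive_seed(config$seed, "imputation"))

  say("stage 3/5: model validation")
  val <- pooled_validation(imp, registry,
                           models = config$models %||%
                             names(registry$models))
  write_validation(val, file.path(out_dir, "validation.csv"))

  say("stage 4/5: decision curves")
  d <- dca(imp, registry,
           strategies = config$strategies %||%
             names(registry_strategies(registry)),
           grid = config$grid)
  write_dca(d, out_dir)
  rvb <- recommended_vs_best_table(imp, registry, grid = config$grid)
  utils::write.csv(rvb, file.path(out_dir, "recommended_vs_best.csv"),
                   row.names = FALSE, na = "")

  say("stage 5/5: manifest")
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg <- config
  cfg$out_dir <- NULL
  manifest <- list(
    package = "bonedca",
    package_version = as.character(utils::packageVersion("bonedca")),
    seed = config$seed,
    config = {
      tmp <- tempfile(fileext = ".json")
      write_run_config(cfg, tmp)   # out_dir omitted: machine-specific
      on.exit(unlink(tmp), add = TRUE)
      jsonlite::read_json(tmp)
    },
    outputs = c("cohort_summary.csv", "cohort.csv", "validation.csv",
                "curves.csv", "optimal_map.csv", "recommended_vs_best.csv"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  ok <- TRUE
  invisible(list(cohort_summary = summary_tab, validation = val, dca = d,
                 imputed_set = imp, out_dir = out_dir))
}
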