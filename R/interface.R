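# File I/O and end-to-end orchestration: cohort CSV schema, run config,
# pipeline (simulate -> filter -> estimate -> calibrate -> compare ->
# report), and a small CLI front-end.

cohort_columns <- function() {
  c("id", "age", "sex", "smoker", "sbp", "tc", "ldl", "hdl", "weight",
    "cvd_history", "diabetes", "statin_use")
}

#' Read a cohort CSV
#'
#' Schema: header `id,age,sex,smoker,sbp,tc,ldl,hdl,weight,cvd_history,
#' diabetes,statin_use`; `sex` in `{M, F}`; booleans in `{0, 1}`; decimal
#' point; UTF-8. Violations are reported with the offending row number
#' (header = line 1).
#'
#' @param path File path.
#' @return Cohort `data.frame` with typed columns (logical flags).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing))
    stop(sprintf("cohort file %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[cohort_columns()]
  row_err <- function(col, bad, what) {
    stop(sprintf("cohort file %s: invalid %s '%s' in column '%s' (row %d)",
                 path, what, df[[col]][bad[1L]], col, bad[1L] + 1L),
         call. = FALSE)
  }
  if (nrow(df)) {
    bad <- which(!df$sex %in% c("M", "F"))
    if (length(bad)) row_err("sex", bad, "sex code")
    for (col in c("smoker", "cvd_history", "diabetes", "statin_use")) {
      bad <- which(!df[[col]] %in% c("0", "1", "TRUE", "FALSE"))
      if (length(bad)) row_err(col, bad, "boolean")
      df[[col]] <- df[[col]] %in% c("1", "TRUE")
    }
    for (col in c("age", "sbp", "tc", "ldl", "hdl", "weight")) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num))
      if (length(bad)) row_err(col, bad, "number")
      df[[col]] <- num
    }
  } else {
    for (col in c("smoker", "cvd_history", "diabetes", "statin_use"))
      df[[col]] <- logical(0)
    for (col in c("age", "sbp", "tc", "ldl", "hdl", "weight"))
      df[[col]] <- numeric(0)
  }
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]: numeric columns at full precision
#' (`%.15g`), booleans as 0/1, newline-terminated UTF-8.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[cohort_columns()]
  for (col in c("smoker", "cvd_history", "diabetes", "statin_use"))
    out[[col]] <- as.integer(out[[col]])
  for (col in c("age", "sbp", "tc", "ldl", "hdl", "weight"))
    out[[col]] <- sprintf("%.15g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-person estimates joined to the cohort
#'
#' @param cohort,estimates Row-aligned frames.
#' @param path Output path.
#' @export
write_estimates_csv <- function(cohort, estimates, path) {
  joined <- cbind(cohort,
                  estimates[setdiff(names(estimates), "id")])
  joined$risk_stratum <- as.character(joined$risk_stratum)
  utils::write.csv(joined, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' One explicit document holding every pipeline default: generator settings,
#' risk model (`NULL` = built-in stand-in), treatment spec, the risk
#' threshold whose event prevention the benefit threshold is calibrated to
#' match, and bootstrap settings.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param out Output directory.
#' @return Nested list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 42L, out = tempfile("sbrun")) {
  structure(list(
    generator = list(n = 7287L, seed = seed),
    risk_model = NULL,
    treatment = list(ldl_reduction_prop = 0.40, rr_mode = "constant",
                     rr_constant = 0.78),
    risk_threshold = 0.10,
    moderate_risk_threshold = 0.075,
    bootstrap = list(reps = 1000L, seed = seed),
    target_population = 324.6e6,
    out = out
  ), class = "run_config")
}

resolve_run_config <- function(config) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (inherits(config, "run_config")) return(config)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

stage_message <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' simulate -> filter -> rescale weights -> per-person estimates ->
#' calibrate the high-benefit threshold to match the risk strategy's events
#' averted -> project both strategies (with bootstrap CIs) -> concordance
#' report. All outputs are written under `config$out`; a JSON manifest with
#' the effective configuration, seeds and output checksums makes runs
#' auditable. Identical config and seed give byte-identical numeric outputs.
#'
#' @param config A [default_run_config()]-style list (partial lists are
#'   merged over the defaults), or `NULL` for the defaults.
#' @param verbose Emit stage-level progress messages with record counts.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = NULL, verbose = FALSE) {
  cfg <- resolve_run_config(config)
  if (!is.null(cfg$risk_model) && is.character(cfg$risk_model) &&
      !file.exists(cfg$risk_model))
    stop(sprintf("stage config: risk model file not found: %s",
                 cfg$risk_model), call. = FALSE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  # -- simulate -------------------------------------------------------------
  gen_cfg <- do.call(generator_config, cfg$generator)
  cohort_raw <- generate_cohort(gen_cfg)
  stage_message(verbose, "simulate: %d records drawn", nrow(cohort_raw))

  # -- filter + rescale -----------------------------------------------------
  filt <- apply_inclusion_filters(cohort_raw)
  if (nrow(filt$kept) == 0L)
    stop("stage filter: no records pass the inclusion filters",
         call. = FALSE)
  cohort <- rescale_weights(filt$kept, cfg$target_population)
  stage_message(verbose, "filter: %d kept, %d excluded (%s)",
                nrow(cohort), sum(filt$exclusion_tally),
                paste(sprintf("%s=%d", names(filt$exclusion_tally),
                              filt$exclusion_tally), collapse = ", "))

  # -- estimate -------------------------------------------------------------
  risk_model <- if (is.null(cfg$risk_model)) default_risk_model()
                else if (inherits(cfg$risk_model, "risk_model_spec"))
                  cfg$risk_model
                else read_risk_model(cfg$risk_model)
  treatment <- do.call(treatment_spec, cfg$treatment)
  est <- compute_estimates(cohort, risk_model, treatment)
  stage_message(verbose, "estimate: median untreated risk %.1f%%",
                100 * stats::median(est$untreated_risk))

  # -- calibrate ------------------------------------------------------------
  risk_strat <- strategy("risk_threshold", cfg$risk_threshold,
                         label = sprintf("high risk (score >= %.0f%%)",
                                         100 * cfg$risk_threshold))
  elig_risk <- eligible(est, risk_strat)
  target <- events_averted(cohort$weight, est$iarr, elig_risk)
  cal <- calibrate_benefit_threshold(est, cohort$weight, target)
  min_thr <- minimum_benefit_threshold(est, elig_risk)
  # moderate-benefit threshold: calibrated against the intermediate-or-higher
  # risk strategy (capped at the high-benefit threshold so the categories
  # stay ordered on cohorts where the two calibrations cross)
  elig_mod_risk <- est$untreated_risk >= cfg$moderate_risk_threshold
  target_mod <- events_averted(cohort$weight, est$iarr, elig_mod_risk)
  cal_mod <- calibrate_benefit_threshold(est, cohort$weight, target_mod)
  moderate_thr <- min(cal_mod$threshold, cal$threshold)
  benefit_strat <- strategy("benefit_threshold", cal$threshold,
                            label = sprintf("high benefit (iARR >= %.1f%%)",
                                            cal$rounded_threshold))
  expansion_strat <- strategy("benefit_threshold", min_thr,
                              label = sprintf(
                                "minimum benefit (iARR >= %.1f%%)",
                                100 * min_thr))
  stage_message(verbose,
                "calibrate: high-benefit threshold %.2f%%, minimum %.2f%%",
                100 * cal$threshold, 100 * min_thr)

  # -- compare --------------------------------------------------------------
  reps <- cfg$bootstrap$reps
  bseed <- cfg$bootstrap$seed
  strategies <- list(risk = risk_strat, benefit = benefit_strat,
                     minimum_benefit = expansion_strat)
  results <- lapply(strategies, function(s)
    strategy_result(cohort, est, s, bootstrap_reps = reps, seed = bseed))

  # -- report ---------------------------------------------------------------
  elig_benefit <- eligible(est, benefit_strat)
  elig_expansion <- eligible(est, expansion_strat) | elig_risk
  conc <- cross_tabulate(elig_risk, elig_benefit, cohort$weight)
  benefit_cat <- classify_benefit(
    est$iarr, high_threshold = cal$threshold,
    moderate_threshold = moderate_thr)
  flows <- flow_matrix(est$risk_stratum, benefit_cat, cohort$weight)
  subgroups <- subgroup_efficiency(elig_risk, elig_benefit, elig_expansion,
                                   est$iarr, cohort$weight)
  characteristics <-
    if (any(elig_risk & !elig_benefit) && any(elig_benefit & !elig_risk)) {
      compare_characteristics(cohort,
                              group_a = elig_risk & !elig_benefit,
                              group_b = elig_benefit & !elig_risk)
    } else NULL

  paths <- list(
    cohort = file.path(cfg$out, "cohort.csv"),
    estimates = file.path(cfg$out, "estimates.csv"),
    calibration = file.path(cfg$out, "calibration.json"),
    results = file.path(cfg$out, "results.csv"),
    concordance = file.path(cfg$out, "concordance.csv"),
    flows = file.path(cfg$out, "flows.csv"),
    subgroups = file.path(cfg$out, "subgroups.csv"),
    characteristics = file.path(cfg$out, "characteristics.csv"),
    manifest = file.path(cfg$out, "manifest.json")
  )
  write_cohort_csv(cohort, paths$cohort)
  write_estimates_csv(cohort, est, paths$estimates)
  jsonlite::write_json(
    list(threshold = cal$threshold,
         rounded_threshold = cal$rounded_threshold,
         achieved_events = cal$achieved_events,
         target_events = cal$target_events,
         moderate_benefit_threshold = moderate_thr,
         minimum_benefit_threshold = min_thr),
    paths$calibration, auto_unbox = TRUE, digits = NA)
  utils::write.csv(results_table(results), paths$results,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(cell = c("both", "only_risk", "only_benefit", "neither",
                        "either", "overlap_prop"),
               value = c(conc$both, conc$only_a, conc$only_b, conc$neither,
                         conc$either, conc$overlap_prop)),
    paths$concordance, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(as.table(flows),
                                 responseName = "weight"),
                   paths$flows, row.names = FALSE, quote = FALSE)
  utils::write.csv(subgroups, paths$subgroups, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(characteristics)) {
    utils::write.csv(characteristics, paths$characteristics,
                     row.names = FALSE, quote = FALSE)
  } else {
    paths$characteristics <- NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("statinbenefit")),
    seed = cfg$generator$seed,
    bootstrap_seed = bseed,
    config = cfg[setdiff(names(cfg), "risk_model")],
    calibration = list(high_benefit_threshold = cal$threshold,
                       minimum_benefit_threshold = min_thr),
    outputs = lapply(paths[setdiff(names(paths), "manifest")],
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(results = results, concordance = conc,
                             calibration = cal, paths = paths)))
}

# One column per strategy, rows mirroring a strategy-comparison table.
results_table <- function(results) {
  row <- function(name, fn) {
    vals <- vapply(results, fn, numeric(1))
    data.frame(statistic = name, t(vals), check.names = FALSE)
  }
  rbind(
    row("events_averted_thousands",
        function(r) project_to_population(r$events_averted, "thousands")),
    row("eligible_millions",
        function(r) project_to_population(r$eligible_persons, "millions")),
    row("eligible_pct", function(r) round(100 * r$eligible_prop, 1)),
    row("average_nnt", function(r) round(r$average_nnt)),
    row("iarr_median_pct",
        function(r) round(100 * r$iarr_summary["median"], 1)),
    row("iarr_min_pct", function(r) round(100 * r$iarr_summary["min"], 1)),
    row("iarr_max_pct", function(r) round(100 * r$iarr_summary["max"], 1)),
    row("max_innt", function(r) round(r$max_innt))
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `estimate`, `calibrate`, `compare`, `report`,
#' `run` (all-in-one). Every subcommand is a thin wrapper over the exported
#' library functions and produces identical results to calling them
#' directly. See `inst/cli/statinbenefit` for the launcher script.
#'
#' @param args Character vector of CLI arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the value of the underlying library call.
#' @export
statinbenefit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: statinbenefit <simulate|estimate|calibrate|run> [options]",
    "  simulate  --n INT --seed INT --out cohort.csv",
    "  estimate  --cohort cohort.csv [--risk-model spec.json] --out est.csv",
    "  calibrate --estimates est.csv --risk-threshold 0.10 --out cal.json",
    "  run       [--seed INT] --out DIR   (full pipeline incl. compare/report)",
    sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  switch(cmd,
    simulate = {
      cfg <- generator_config(n = as.integer(get_opt("n", 7287L)),
                              seed = as.integer(get_opt("seed", 1L)))
      cohort <- generate_cohort(cfg)
      write_cohort_csv(cohort, get_opt("out", "cohort.csv"))
      invisible(cohort)
    },
    estimate = {
      cohort <- read_cohort_csv(get_opt("cohort"))
      rm_path <- get_opt("risk-model")
      rm_spec <- if (is.null(rm_path)) default_risk_model()
                 else read_risk_model(rm_path)
      est <- compute_estimates(cohort, rm_spec)
      write_estimates_csv(cohort, est, get_opt("out", "estimates.csv"))
      invisible(est)
    },
    calibrate = {
      df <- utils::read.csv(get_opt("estimates"))
      thr <- as.numeric(get_opt("risk-threshold", 0.10))
      elig_risk <- df$untreated_risk >= thr
      target <- sum(df$weight[elig_risk] * df$iarr[elig_risk])
      cal <- calibrate_benefit_threshold(df, df$weight, target)
      jsonlite::write_json(
        list(threshold = cal$threshold,
             rounded_threshold = cal$rounded_threshold,
             achieved_events = cal$achieved_events,
             target_events = cal$target_events),
        get_opt("out", "calibration.json"), auto_unbox = TRUE, digits = NA)
      invisible(cal)
    },
    run = {
      run_pipeline(list(generator = list(
                          seed = as.integer(get_opt("seed", 42L))),
                        bootstrap = list(
                          reps = as.integer(get_opt("bootstrap", 1000L)),
                          seed = as.integer(get_opt("seed", 42L))),
                        out = get_opt("out", "statinbenefit_run")),
                   verbose = !is.null(opts[["verbose"]]))
    },
    stop(sprintf("unknown subcommand '%s'\n%s", cmd, usage), call. = FALSE)
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- substring(a, 3L)
    if (identical(key, "verbose")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        stop(sprintf("flag --%s needs a value", key), call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
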