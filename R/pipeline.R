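#' Pipeline run configuration
#'
#' Validated settings for an end-to-end run: cohort simulation,
#' descriptive statistics and the Bayesian joint fit. Group parameter
#' overrides are named lists forwarded to [group_params()].
#'
#' @param seed Master seed for every random stage.
#' @param n_per_group Simulated subjects per group.
#' @param n_iter,burn_in,thin Sampler settings.
#' @param hdi_mass HDI probability mass.
#' @param out_dir Output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @param adult,child Named lists of [group_params()] overrides.
#' @return List of class `om_run_config`.
#' @export
pipeline_config <- function(seed = 1, n_per_group = 32, n_iter = 60000,
                            burn_in = 10000, thin = 1, hdi_mass = 0.95,
                            out_dir = NULL, adult = list(), child = list()) {
  stopifnot(n_per_group >= 2, burn_in < n_iter, hdi_mass > 0, hdi_mass < 1,
            seed == as.integer(seed))
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 hdi_mass = hdi_mass, out_dir = out_dir,
                 adult = adult, child = child),
            class = "om_run_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config An [pipeline_config()] object.
#' @param path JSON file path.
#' @return `read_config` returns an `om_run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$adult <- as.list(raw$adult)
  raw$child <- as.list(raw$child)
  do.call(pipeline_config, raw)
}

trial_columns <- c("subject_id", "group", "task", "operand1", "operand2",
                   "correct", "range_flag", "area_mode", "alternatives",
                   "chosen", "rt_ms", "response_correct")

#' Read and validate a trial-record CSV
#'
#' The on-disk contract: UTF-8 comma-separated values with a header row,
#' `.` decimal separator, and the six response alternatives
#' semicolon-joined in a single column. Rows whose chosen value is not
#' among their alternatives are flagged (kept, with a warning naming the
#' line numbers); an empty file yields an empty table.
#'
#' @param path CSV file path.
#' @return Data frame of trial records; flagged row indices are attached
#'   as attribute `invalid_rows`.
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(trial_columns)),
                                  trial_columns))
    attr(out, "invalid_rows") <- integer(0)
    return(out)
  }
  out <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(out))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  alts <- alts_split(out$alternatives)
  bad <- which(!mapply(function(a, ch) ch %in% a, alts, out$chosen))
  if (length(bad)) {
    warning("chosen value not among alternatives on line(s): ",
            paste(head(bad + 1L, 20), collapse = ", "))
  }
  attr(out, "invalid_rows") <- bad
  out
}

#' @rdname read_trials
#' @param trials Trial-record data frame.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline on a simulated (or supplied) cohort
#'
#' Stages: stimulus design, cohort simulation (skipped when `trials` and
#' `cueing` are supplied), descriptive statistics (OM bias,
#' coefficient-of-variation profile, choice-rank distributions, memory
#' regression, cueing effects, OM-by-reorienting correlation) and the
#' Bayesian heteroscedastic joint fit. Every intermediate is written to
#' `config$out_dir` as CSV/JSON when that is set.
#'
#' @param config An [pipeline_config()] object.
#' @param trials,cueing Optional user-supplied trial tables replacing the
#'   simulation stage.
#' @return List of class `om_run_report`: stage row counts, the
#'   descriptive tables, the `om_bayes` fit, and built-in invariant
#'   checks.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         cueing = NULL) {
  stopifnot(inherits(config, "om_run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    write.csv(obj, file.path(out_dir, file), row.names = FALSE)
  }
  if (!is.null(out_dir)) write_config(config, file.path(out_dir, "config.json"))

  truth <- NULL
  if (is.null(trials)) {
    cohort <- simulate_cohort(
      n_per_group = config$n_per_group, seed = config$seed,
      adult = do.call(group_params, c(list(group = "adult"), config$adult)),
      child = do.call(group_params, c(list(group = "child"), config$child)))
    trials <- cohort$trials
    cueing <- cohort$cueing
    truth <- cohort$truth
    if (!is.null(out_dir)) {
      write_trials(trials, file.path(out_dir, "trials.csv"))
      write.csv(cueing, file.path(out_dir, "cueing.csv"), row.names = FALSE)
      write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    }
  }

  bias <- om_bias(trials)
  cv <- cv_profile(trials)
  ranks <- rank_distribution(trials)
  memreg <- memory_regression(trials)
  emit(bias, "bias.csv")
  emit(cv, "cv.csv")
  emit(ranks, "ranks.csv")

  cue_eff <- NULL
  om_correlations <- NULL
  if (!is.null(cueing) && nrow(cueing) > 0) {
    cue_eff <- cueing_effects(cueing)
    emit(cue_eff, "cueing_effects.csv")
    merged <- merge(bias, cue_eff, by = "subject")
    if (nrow(merged) >= 3) {
      om_correlations <- list(
        om_reorienting = correlate(merged$om_difference, merged$reorienting),
        om_orienting = correlate(merged$om_difference, merged$orienting))
      if (!is.null(out_dir)) {
        jsonlite::write_json(om_correlations,
                             file.path(out_dir, "correlations.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  fit <- om_bayes(x = bias[, c("group", "bias_addition", "bias_subtraction")],
                  n_iter = config$n_iter, burn_in = config$burn_in,
                  thin = config$thin, seed = config$seed,
                  hdi_mass = config$hdi_mass)
  if (!is.null(out_dir)) {
    write.csv(as.data.frame(summary(fit)),
              file.path(out_dir, "posterior_summary.csv"), row.names = FALSE)
  }

  checks <- c(
    trials_per_subject_44 = all(table(trials$subject_id) == 44),
    rank_props_sum_to_1 = all(abs(
      stats::aggregate(p ~ task + range_flag, data = ranks, FUN = sum)$p - 1) < 1e-9),
    posterior_rows_13 = nrow(summary(fit)) == 13
  )

  structure(list(
    config = config,
    counts = list(subjects = length(unique(trials$subject_id)),
                  arithmetic_rows = nrow(trials),
                  cueing_rows = if (is.null(cueing)) 0L else nrow(cueing),
                  rejected_rank_rows = attr(ranks, "n_rejected")),
    bias = bias, cv = cv, ranks = ranks, memory_regression = memreg,
    cueing_effects = cue_eff, correlations = om_correlations,
    fit = fit, truth = truth, checks = checks),
    class = "om_run_report")
}

#' @export
print.om_run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("Subjects:", x$counts$subjects,
      "| arithmetic rows:", x$counts$arithmetic_rows,
      "| cueing rows:", x$counts$cueing_rows, "\n")
  gm <- stats::aggregate(om_difference ~ group, data = x$bias, FUN = mean)
  cat("Mean OM difference by group:\n")
  print(gm, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat(sprintf("OM x reorienting correlation: r = %.3f (p = %.3f, n = %d)\n",
                x$correlations$om_reorienting$r, x$correlations$om_reorienting$p,
                x$correlations$om_reorienting$n))
  }
  cat("\n")
  print(x$fit)
  cat("\nInvariant checks:",
      paste(names(x$checks), ifelse(x$checks, "ok", "FAILED"), collapse = ", "),
      "\n")
  invisible(x)
}
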