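PIPELINE_KEYS <- c("simulate", "task", "exposure", "models", "seed",
                   "out_dir", "log_level")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with per-stage sections:
#' `simulate` ([gen_config()] arguments), `task` ([task_config()]
#' arguments), `exposure` (k_hour, k_date, rho, min_hours, bounds,
#' max_flag_fraction), `models` (alpha, candidate interactions), plus
#' `seed`, `out_dir` and `log_level`. Unknown keys are rejected before any
#' stage runs.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("simulate", "task", "exposure", "models")) {
    if (!is.null(config[[sec]]) && !is.list(config[[sec]]))
      stop("config section '", sec, "' must be a mapping")
  }
  allowed <- list(simulate = names(formals(gen_config)),
                  task = names(formals(task_config)),
                  exposure = c("k_hour", "k_date", "rho", "min_hours",
                               "bounds", "max_flag_fraction",
                               "sample_interval_s"),
                  models = c("alpha", "candidates"))
  for (sec in names(allowed)) {
    bad <- setdiff(names(config[[sec]]), allowed[[sec]])
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  config
}

log_line <- function(path, stage, msg, ...) {
  rec <- c(list(stage = stage, message = msg), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
}

#' Assemble analysis-cell tables from scored trials
#'
#' Builds the participant x year x load-level tables the association models
#' use: mean "first-look no-change" and "first-look change" change
#' preference per cell, mean shift rate per cell (over all classified
#' trials), the per-participant-year LookingWindow1 covariate, household
#' demographics, and (optionally) the centered exposure score as `aqi`.
#'
#' @param scored Result of [score_dataset()].
#' @param households Household table (participant_id, household_id,
#'   ses_score, cohort).
#' @param exposure Optional result of [extract_exposure()].
#' @return list of data.frames: `cp_no_change`, `cp_change`, `shift`.
#' @export
build_analysis_tables <- function(scored, households, exposure = NULL) {
  sc <- scored$scores
  lw1 <- aggregate(looking_window1 ~ participant_id + year, data = sc,
                   FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  names(lw1)[3] <- "lw1"
  demo <- households[, c("participant_id", "household_id", "ses_score",
                         "cohort")]
  finish <- function(d) {
    d <- merge(d, lw1, by = c("participant_id", "year"))
    d <- merge(d, demo, by = "participant_id")
    if (!is.null(exposure)) {
      d <- merge(d, exposure[, c("household_id", "exposure_score")],
                 by = "household_id")
      names(d)[names(d) == "exposure_score"] <- "aqi"
    }
    d
  }
  agg <- scored$aggregates
  cp_part <- function(class) {
    d <- agg[agg$first_look == class,
             c("participant_id", "year", "load_level", "change_preference",
               "n_trials")]
    names(d)[4] <- "cp"
    finish(d[!is.na(d$cp), , drop = FALSE])
  }
  ok <- sc[sc$first_look != "unclassified" & !is.na(sc$shift_rate), ]
  shift <- aggregate(shift_rate ~ participant_id + year + load_level,
                     data = ok, FUN = mean)
  names(shift)[4] <- "shift"
  list(cp_no_change = cp_part("no_change"),
       cp_change = cp_part("change"),
       shift = finish(shift))
}

#' Run the full pipeline
#'
#' Stages run in order: simulate (when a `simulate` section is present) ->
#' score -> exposure -> associate -> report. Every stage writes its outputs
#' under `out_dir` and appends machine-parseable JSON log lines (one per
#' warning or exclusion tally) to `pipeline_log.jsonl`; a provenance record
#' (config, seed, package version) accompanies the run. Reruns with the
#' same config and seed produce identical outputs for the deterministic
#' stages.
#'
#' @param config Named list or YAML path (see [validate_config()]).
#' @param seed Overrides `config$seed`.
#' @param out_dir Overrides `config$out_dir`.
#' @return (invisibly) the artifact directory path.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  config <- validate_config(config)
  seed <- if (!is.null(seed)) seed else config$seed %||% 1
  out_dir <- if (!is.null(out_dir)) out_dir else config$out_dir %||%
    stop("out_dir must be given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(logf)) file.remove(logf)
  jsonlite::write_json(list(config = config, seed = seed,
                            package_version =
                              as.character(utils::packageVersion("gazecog"))),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- simulate ---------------------------------------------------------
  in_dir <- file.path(out_dir, "input")
  if (!is.null(config$simulate)) {
    cfg <- do.call(gen_config, config$simulate)
    simulate_dataset(cfg, seed = seed, out_dir = in_dir)
    log_line(logf, "simulate", "synthetic dataset written",
             n_households = cfg$n_households)
  }
  need <- file.path(in_dir, c("households.csv", "aqi_log.csv",
                              "gaze_samples.csv", "trials.csv"))
  if (!all(file.exists(need)))
    stop("missing input file(s): ",
         paste(basename(need[!file.exists(need)]), collapse = ", "),
         " (run with a simulate section or place inputs under ", in_dir, ")")
  households <- read.csv(file.path(in_dir, "households.csv"),
                         stringsAsFactors = FALSE)

  # -- score ------------------------------------------------------------
  tcfg <- do.call(task_config, config$task %||% list())
  samples <- read_gaze_csv(file.path(in_dir, "gaze_samples.csv"))
  meta <- read.csv(file.path(in_dir, "trials.csv"), stringsAsFactors = FALSE)
  et <- samples[samples$source == "eyetracker", ]
  vid <- samples[samples$source == "video", ]
  trials <- attach_metadata(merge_sources(et, vid), meta)
  scored <- score_dataset(trials, tcfg)
  write.csv(scored$scores, file.path(out_dir, "trial_scores.csv"),
            row.names = FALSE)
  write.csv(scored$aggregates, file.path(out_dir, "score_aggregates.csv"),
            row.names = FALSE)
  for (nm in names(scored$exclusions))
    log_line(logf, "score", "exclusion tally", filter = nm,
             n = unname(scored$exclusions[nm]))

  # -- exposure ---------------------------------------------------------
  ecfg <- config$exposure %||% list()
  aqi <- read.csv(file.path(in_dir, "aqi_log.csv"), stringsAsFactors = FALSE)
  filt <- device_plausibility_filter(
    aqi, bounds = ecfg$bounds %||% c(1, 500),
    max_flag_fraction = ecfg$max_flag_fraction %||% 0.1)
  log_line(logf, "exposure", "device filter", n_retired = nrow(filt$retired))
  qc <- qc_rounds(filt$records, min_hours = ecfg$min_hours %||% 5,
                  sample_interval_s = ecfg$sample_interval_s %||% 10)
  log_line(logf, "exposure", "round QC",
           n_dropped = sum(!qc$report$retained))
  hourly <- downsample_hourly(qc$records)
  emod <- fit_exposure_model(hourly,
                             k_hour = ecfg$k_hour %||% 11,
                             k_date = ecfg$k_date %||% 11,
                             rho = ecfg$rho %||% 0.6)
  exposure <- extract_exposure(emod)
  write.csv(exposure, file.path(out_dir, "household_exposure.csv"),
            row.names = FALSE)

  # -- associate --------------------------------------------------------
  mcfg <- config$models %||% list()
  alpha <- mcfg$alpha %||% 0.05
  tabs <- build_analysis_tables(scored, households, exposure)
  summaries <- list()
  for (oc in c("cp_no_change", "shift")) {
    d <- tabs[[oc]]
    ycol <- if (oc == "shift") "shift" else "cp"
    coded <- code_predictors(d)$data
    mains <- if (oc == "shift") c("Year", "Load", "SES", "Age")
             else c("Year", "Load", "SES", "LW1", "Age")
    base <- build_baseline(coded, ycol, main_effects = mains,
                           candidates = unlist(mcfg$candidates %||%
                                                 list("Year:SES")),
                           alpha = alpha)
    aug <- add_air_quality(base, coded, alpha = alpha)
    summaries[[oc]] <- list(baseline = model_summary(base),
                            augmented = model_summary(aug))
  }
  if (file.exists(file.path(in_dir, "assessments.csv"))) {
    assess <- read.csv(file.path(in_dir, "assessments.csv"),
                       stringsAsFactors = FALSE)
    am <- fit_assessment_models(assess, households, exposure)
    summaries$assessments <- lapply(am, function(x)
      list(baseline = x$baseline_coefs, augmented = x$augmented_coefs))
  }
  jsonlite::write_json(summaries, file.path(out_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)

  # -- report -----------------------------------------------------------
  render_report(out_dir)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  paste(c(paste(names(df), collapse = " | "),
          paste(rep("---", ncol(df)), collapse = " | "),
          apply(df, 1, paste, collapse = " | ")),
        collapse = "\n")
}

#' Render a human-readable report from pipeline outputs
#'
#' Reads the output files of a pipeline run — never recomputing any number —
#' and writes `report.md` with descriptive panels (change preference by
#' cohort and load, shift rate by load, exposure by cooking fuel,
#' score-vs-exposure summaries) and the model tables in the standard column
#' layout (Estimate, Std. Error, DF, t value, Pr(>|t|)). Missing output
#' files become "section absent" notes, not errors.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @return (invisibly) the report path.
#' @export
render_report <- function(artifact_dir) {
  out <- c("# Pipeline report", "")
  scores_f <- file.path(artifact_dir, "trial_scores.csv")
  if (file.exists(scores_f)) {
    sc <- read.csv(scores_f, stringsAsFactors = FALSE)
    ok <- sc[sc$first_look != "unclassified", ]
    cp_by_load <- aggregate(change_preference ~ load_level, data = ok,
                            FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
    sr_by_load <- aggregate(shift_rate ~ load_level, data = ok, FUN = mean,
                            na.rm = TRUE, na.action = stats::na.pass)
    out <- c(out, "## Change preference by load", "",
             fmt_table(cp_by_load), "",
             "## Shift rate by load", "", fmt_table(sr_by_load), "")
  } else {
    out <- c(out, "_Section absent: trial scores not found._", "")
  }
  exp_f <- file.path(artifact_dir, "household_exposure.csv")
  hh_f <- file.path(artifact_dir, "input", "households.csv")
  if (file.exists(exp_f) && file.exists(hh_f)) {
    ex <- read.csv(exp_f, stringsAsFactors = FALSE)
    hh <- read.csv(hh_f, stringsAsFactors = FALSE)
    d <- merge(ex, hh, by = "household_id")
    d$aqi_scale <- d$exposure_score + d$grand_mean
    by_fuel <- aggregate(aqi_scale ~ cooking_fuel, data = d, FUN = mean)
    out <- c(out, "## Exposure (grand mean + score) by cooking fuel", "",
             fmt_table(by_fuel), "",
             sprintf("Grand mean AQI: %.3f", ex$grand_mean[1]), "")
  } else {
    out <- c(out, "_Section absent: exposure output not found._", "")
  }
  ms_f <- file.path(artifact_dir, "model_summary.json")
  if (file.exists(ms_f)) {
    ms <- jsonlite::read_json(ms_f, simplifyVector = TRUE)
    for (oc in intersect(c("cp_no_change", "shift"), names(ms))) {
      for (kind in c("baseline", "augmented")) {
        cf <- ms[[oc]][[kind]]$coefficients
        if (is.null(cf)) next
        out <- c(out, sprintf("## %s model (%s)", oc, kind), "",
                 fmt_table(as.data.frame(cf)), "")
      }
    }
  } else {
    out <- c(out, "_Section absent: model summaries not found._", "")
  }
  path <- file.path(artifact_dir, "report.md")
  writeLines(out, path)
  invisible(path)
}
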