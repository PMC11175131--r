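# End-to-end orchestration: simulate (or load) -> preprocess -> score ->
# aggregate -> recovery, with CSV/JSON outputs and an exclusion log.

#' Percentage of participants reporting significant fatigue
#'
#' Rounded half-up to 2 decimals, as conventionally tabulated.
#'
#' @param count Participants reporting fatigue (0..total).
#' @param total Total participants (>= 1).
#' @return Percentage with 2 decimals.
#' @export
#' @examples
#' proportion_reporting_fatigue(28, 72)  # 38.89
proportion_reporting_fatigue <- function(count, total) {
  if (any(total < 1)) stop("proportion_reporting_fatigue: total must be >= 1", call. = FALSE)
  if (any(count < 0 | count > total)) {
    stop("proportion_reporting_fatigue: count must lie in 0..total", call. = FALSE)
  }
  floor(100 * count / total * 100 + 0.5) / 100
}

#' Build a pipeline configuration
#'
#' Exactly one of `simulation` (arguments for [cohort_spec()]) or `manifest`
#' (path to a manifest JSON written by [generate_cohort()]) must be given.
#'
#' @param simulation Named list of [cohort_spec()] arguments, or NULL.
#' @param manifest Path to `manifest.json`, or NULL.
#' @param out_dir Output directory, or NULL for in-memory results only.
#' @param min_period,prominence Gait-detector parameters
#'   (see [detect_gait_cycles()]).
#' @param hampel_window,hampel_threshold Outlier-filter parameters
#'   (see [filter_outliers()]).
#' @param verbose Print per-stage progress lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, manifest = NULL, out_dir = NULL,
                            min_period = 0.4, prominence = 0.5,
                            hampel_window = 11L, hampel_threshold = 3,
                            verbose = FALSE) {
  if (is.null(simulation) == is.null(manifest)) {
    stop("pipeline_config: provide exactly one of simulation or manifest", call. = FALSE)
  }
  structure(list(simulation = simulation, manifest = manifest,
                 out_dir = out_dir, min_period = min_period,
                 prominence = prominence, hampel_window = hampel_window,
                 hampel_threshold = hampel_threshold, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments, with `simulation` a
#' mapping of [cohort_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

log_ <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[gaitstab] ", fmt), ...))
}

load_manifest_trials_ <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  trials <- lapply(man, function(m) {
    p <- file.path(base, m$trace_path)
    if (!file.exists(p)) {
      stop(sprintf("pipeline: manifest references missing trace %s", p), call. = FALSE)
    }
    hw <- lapply(m$hazard_windows, function(w) as.numeric(unlist(w)))
    list(trace = read_trace_csv(p,
                                participant_id = m$participant_id,
                                environment = m$environment,
                                fatigue_level = as.integer(m$fatigue_level),
                                hazard_windows = hw),
         ground_truth = NULL)
  })
  names(trials) <- vapply(man, function(m) {
    sprintf("%s_%s_L%d", m$participant_id, m$environment, as.integer(m$fatigue_level))
  }, character(1))
  trials
}

#' Run the full stability pipeline
#'
#' Simulates (or loads) a cohort of walking trials, extracts each
#' participant's reference gait from their unfatigued non-obstacle trial,
#' scores every trial's gait cycles by DTW against that reference, and
#' aggregates hazard-zone stability and recovery time by environment and
#' fatigue level. Trials where no gait or no decreasing recovery trend is
#' found are excluded with a logged reason, not aborted on.
#'
#' @param config A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @return A `pipeline_result`: list with `condition_table`, `records`
#'   (long per-cycle data frame), `recovery` (per-trial data frame),
#'   `exclusions` (data frame), and `summary` (run metadata). If
#'   `config$out_dir` is set, writes `condition_table.csv`, `records.csv`,
#'   `recovery.csv`, `run_summary.json` there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    t0 <<- Sys.time()
  }

  # stage 1: obtain trials
  if (!is.null(config$simulation)) {
    spec <- do.call(cohort_spec, config$simulation)
    log_(config$verbose, "simulating cohort: %d participants", spec$n_participants)
    cohort <- generate_cohort(spec)
    trials <- cohort$trials
    seed <- spec$seed
  } else {
    log_(config$verbose, "loading manifest %s", config$manifest)
    trials <- load_manifest_trials_(config$manifest)
    seed <- NA_integer_
  }
  tick("acquire")

  # stage 2: per-participant reference gaits from the (A, level 0) trial
  meta <- data.frame(
    key = names(trials),
    participant = vapply(trials, function(t) t$trace$participant_id, character(1)),
    environment = vapply(trials, function(t) t$trace$environment, character(1)),
    level = vapply(trials, function(t) t$trace$fatigue_level, integer(1)))
  refs <- list()
  exclusions <- list()
  for (p in unique(meta$participant)) {
    k <- meta$key[meta$participant == p & meta$environment == "A" & meta$level == 0]
    if (!length(k)) {
      stop(sprintf("pipeline: participant %s has no non-obstacle level-0 trial for the reference gait", p),
           call. = FALSE)
    }
    refs[[p]] <- tryCatch(
      reference_from_trial(trials[[k[1]]]$trace,
                           min_period = config$min_period,
                           prominence = config$prominence),
      error = function(e) NULL)
    if (is.null(refs[[p]])) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(trial = k[1], reason = "reference extraction failed")
    }
  }
  tick("reference")

  # stage 3: score all trials
  records <- list()
  for (key in names(trials)) {
    tr <- trials[[key]]$trace
    ref <- refs[[tr$participant_id]]
    if (is.null(ref)) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(trial = key, reason = "no reference gait")
      next
    }
    rec <- tryCatch(
      analyze_trial(tr, ref, min_period = config$min_period,
                    prominence = config$prominence),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      log_(config$verbose, "excluding %s: %s", key, rec)
      exclusions[[length(exclusions) + 1L]] <- data.frame(trial = key, reason = rec)
      next
    }
    records[[key]] <- rec
  }
  if (!length(records)) stop("pipeline: all trials excluded", call. = FALSE)
  tick("score")

  # stage 4: aggregate
  condition_table <- aggregate_condition_table(records)
  recovery <- do.call(rbind, lapply(records, function(r) {
    f <- r$recovery
    ok <- !is.null(f) && isTRUE(f$converged)
    data.frame(
      participant = r$participant_id, environment = r$environment,
      level = r$fatigue_level,
      baseline = if (ok) f$baseline else NA_real_,
      peak_index = if (ok) f$peak_index else NA_integer_,
      peak_value = if (ok) f$peak_value else NA_real_,
      a = if (ok) f$a else NA_real_, b = if (ok) f$b else NA_real_,
      recovery_time_cycles = if (ok) f$recovery_time else NA_real_,
      recovery_time_seconds = if (ok) cycles_to_seconds(f$recovery_time, r$cycles, 128) else NA_real_,
      converged = ok)
  }))
  rownames(recovery) <- NULL
  records_df <- do.call(rbind, lapply(records, function(r) {
    data.frame(participant = r$participant_id, environment = r$environment,
               level = r$fatigue_level,
               cycle_index = seq_along(r$per_cycle_dtw) - 1L,
               dtw = r$per_cycle_dtw, in_hazard = r$in_hazard)
  }))
  rownames(records_df) <- NULL
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(trial = character(0), reason = character(0))
  tick("aggregate")

  summary <- list(
    n_trials = length(trials), n_scored = length(records),
    n_excluded = nrow(exclusions), seed = seed,
    package_version = as.character(utils::packageVersion("gaitstab")),
    stage_seconds = as.list(timings))

  res <- structure(
    list(condition_table = condition_table, records = records_df,
         recovery = recovery, recovery_summary = recovery_summary_by_level(records),
         stability_records = records, exclusions = exclusions, summary = summary),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    utils::write.csv(condition_table, file.path(d, "condition_table.csv"), row.names = FALSE)
    utils::write.csv(records_df, file.path(d, "records.csv"), row.names = FALSE)
    utils::write.csv(recovery, file.path(d, "recovery.csv"), row.names = FALSE)
    utils::write.csv(exclusions, file.path(d, "exclusions.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(d, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d/%d trials scored (%d excluded)\n",
              x$summary$n_scored, x$summary$n_trials, x$summary$n_excluded))
  print(x$condition_table, row.names = FALSE)
  invisible(x)
}
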