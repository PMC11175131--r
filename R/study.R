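#' Cohort-mean hazard-zone DTW for selected conditions
#'
#' Runs the full scoring pipeline (simulation, segmentation, per-cycle DTW
#' against each participant's own unfatigued non-obstacle reference gait,
#' hazard-zone aggregation) for every requested environment x fatigue-level
#' condition, replicated over independent cohort seeds. References are
#' extracted once per participant per seed and shared across conditions.
#'
#' @param conditions Data frame with columns `environment`, `level`.
#' @param n_participants Participants per cohort (the study design has 72).
#' @param seeds Integer vector of cohort seeds.
#' @param cycles Gait cycles per trial.
#' @param presets Named list of [environment_preset()]s.
#' @param recovery Also fit recovery trendlines (slower; default FALSE).
#' @param verbose Print one line per seed.
#' @return Data frame with one row per condition x seed: `environment`,
#'   `level`, `seed`, `mean_dtw`, `n` (trials contributing), and when
#'   `recovery` is TRUE `mean_recovery_cycles` and `n_recovery`.
#' @export
simulate_condition_means <- function(conditions, n_participants = 72,
                                     seeds = 1:10, cycles = 30,
                                     presets = environment_presets(),
                                     recovery = FALSE, verbose = FALSE) {
  stopifnot(all(c("environment", "level") %in% names(conditions)))
  out <- list()
  for (seed in seeds) {
    spec <- cohort_spec(n_participants = n_participants, environments = "A",
                        cycles_per_trial = cycles, seed = seed,
                        environment_presets = presets["A"])
    profiles <- sample_failure_counts(spec)
    refs <- lapply(seq_len(n_participants), function(r) {
      tr <- synth_trial(profiles[r, ], presets$A, level = 0, cycles = cycles,
                        seed = trial_seed_(seed, r))
      tryCatch(reference_from_trial(tr$trace), error = function(e) NULL)
    })
    for (ci in seq_len(nrow(conditions))) {
      env <- conditions$environment[ci]
      lev <- conditions$level[ci]
      vals <- rts <- rep(NA_real_, n_participants)
      for (r in seq_len(n_participants)) {
        if (is.null(refs[[r]])) next
        tt <- synth_trial(profiles[r, ], presets[[env]], level = lev,
                          cycles = cycles,
                          seed = trial_seed_(seed, (ci + 1L) * n_participants + r))
        rec <- tryCatch(
          analyze_trial(tt$trace, refs[[r]], recovery = recovery),
          error = function(e) NULL)
        if (is.null(rec)) next
        vals[r] <- rec$hazard_mean
        if (recovery && isTRUE(rec$recovery$converged)) {
          rts[r] <- rec$recovery$recovery_time
        }
      }
      row <- data.frame(environment = env, level = lev, seed = seed,
                        mean_dtw = mean(vals, na.rm = TRUE), n = sum(!is.na(vals)))
      if (recovery) {
        row$mean_recovery_cycles <- mean(rts, na.rm = TRUE)
        row$n_recovery <- sum(!is.na(rts))
      }
      out[[length(out) + 1L]] <- row
    }
    if (verbose) message(sprintf("[gaitstab] seed %d done", seed))
  }
  do.call(rbind, out)
}
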