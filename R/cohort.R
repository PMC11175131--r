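# Synthetic walking-trial generator.
#
# Emulates the study design: a cohort of workers, each fatigued to k*10% of
# their individual step-test failure count (fatigue level k in 0..5) and
# walked through four surface conditions with a hazard zone partway along
# the walkway, recorded by a waist-worn tri-axial accelerometer at 128 Hz.

# generator defaults (fixed study conditions; see the methods vignette)
.gen_defaults <- list(
  timing_jitter_sd = 0.02,   # sd of per-cycle period multiplier at level 0
  amp_jitter_sd = 0.05,      # sd of per-cycle amplitude multiplier at level 0
  fatigue_mult_max = 3.0,    # jitter multiplier at level 5 (level 0 -> 1.0)
  gravity = 9.81,            # m/s^2, traces are gravity-inclusive
  hazard_n_cycles = 2L,      # cycles spanned by the hazard burst
  hazard_frac = 0.4,         # hazard start as fraction of the walk
  hazard_inset = 3L,         # samples trimmed from each recorded window end
  step_freq_mean = 1.8, step_freq_sd = 0.12,   # steps/s
  base_amp_mean = 3.0, base_amp_sd = 0.3       # m/s^2
)

#' Specification of a synthetic cohort
#'
#' @param n_participants Number of participants (>= 1); the study design has
#'   72.
#' @param fatigue_levels Integer subset of 0..5; level k means the
#'   participant performed k x 10% of their individual step-test failure
#'   count before the walk.
#' @param environments Character subset of `c("A","B","C","D")`.
#' @param cycles_per_trial Gait cycles per walking trial (>= 5; default 30).
#' @param sampling_rate Hz (default 128, the study hardware rate).
#' @param seed Integer; the cohort is a pure function of the spec including
#'   this seed.
#' @param failure_count_distribution Named numeric `c(mean, sd, min)` of the
#'   truncated-normal step-test failure counts (default 120, 30, 40).
#' @param environment_presets Named list of [environment_preset()]s covering
#'   `environments`.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_participants = 72,
                        fatigue_levels = 0:5,
                        environments = c("A", "B", "C", "D"),
                        cycles_per_trial = 30,
                        sampling_rate = 128,
                        seed = 1,
                        failure_count_distribution = c(mean = 120, sd = 30, min = 40),
                        environment_presets = gaitstab::environment_presets()) {
  if (n_participants < 1) stop("cohort_spec: n_participants must be >= 1", call. = FALSE)
  if (cycles_per_trial < 5) stop("cohort_spec: cycles_per_trial must be >= 5", call. = FALSE)
  if (sampling_rate <= 0) stop("cohort_spec: sampling_rate must be > 0", call. = FALSE)
  fatigue_levels <- sort(unique(as.integer(fatigue_levels)))
  if (any(fatigue_levels < 0 | fatigue_levels > 5)) {
    stop("cohort_spec: fatigue levels must lie in 0..5", call. = FALSE)
  }
  environments <- sort(unique(environments))
  if (!all(environments %in% c("A", "B", "C", "D"))) {
    stop("cohort_spec: environments must be drawn from A, B, C, D", call. = FALSE)
  }
  if (!all(environments %in% names(environment_presets))) {
    stop("cohort_spec: missing preset for a requested environment", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         fatigue_levels = fatigue_levels,
         environments = environments,
         cycles_per_trial = as.integer(cycles_per_trial),
         sampling_rate = sampling_rate,
         seed = as.integer(seed),
         failure_count_distribution = failure_count_distribution,
         environment_presets = environment_presets),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d participants x levels {%s} x environments {%s}, %d cycles/trial @ %g Hz, seed %d\n",
              x$n_participants, paste(x$fatigue_levels, collapse = ","),
              paste(x$environments, collapse = ","),
              x$cycles_per_trial, x$sampling_rate, x$seed))
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed_ <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic per-trial seed derived from the cohort seed
trial_seed_ <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + index * 7919) %% 2147483647L)
}

#' Sample participant profiles
#'
#' Draws one profile per participant: step-test failure count from a
#' truncated normal (resampled below the minimum, then rounded), step
#' frequency, base acceleration amplitude and sensor noise scale.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `participant_id`, `failure_count`,
#'   `step_frequency`, `base_amplitude`, `noise_scale`.
#' @export
sample_failure_counts <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  fd <- spec$failure_count_distribution
  g <- .gen_defaults
  with_seed_(spec$seed, {
    fc <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      fc[todo] <- rnorm(length(todo), fd[["mean"]], fd[["sd"]])
      todo <- todo[fc[todo] < fd[["min"]]]
    }
    sf <- pmin(2.9, pmax(0.6, rnorm(n, g$step_freq_mean, g$step_freq_sd)))
    amp <- pmax(1, rnorm(n, g$base_amp_mean, g$base_amp_sd))
    data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      failure_count = pmax(as.integer(round(fc)), as.integer(ceiling(fd[["min"]]))),
      step_frequency = sf,
      base_amplitude = amp,
      noise_scale = rep(0.05, n))
  })
}

#' Step count administered for a fatigue level
#'
#' Level k corresponds to k x 10% of the participant's failure count,
#' rounded to the nearest step with ties rounding up.
#'
#' @param failure_count Steps to failure on the step test (>= 1).
#' @param level Integer fatigue level 0..5.
#' @return Integer step count.
#' @export
#' @examples
#' steps_for_level(200, 5)  # 100
#' steps_for_level(183, 5)  # 92 (91.5 ties up)
steps_for_level <- function(failure_count, level) {
  if (any(failure_count < 1)) stop("steps_for_level: failure_count must be >= 1", call. = FALSE)
  if (any(level < 0 | level > 5 | level != round(level))) {
    stop("steps_for_level: level must be an integer in 0..5", call. = FALSE)
  }
  as.integer(floor(level * 0.1 * failure_count + 0.5))
}

# symmetric per-step SVM waveform template (peak exactly at phase 0)
step_template_ <- function(phase) {
  (cos(phase) + 0.45 * cos(2 * phase) + 0.2 * cos(3 * phase)) / 1.65
}

# unit-energy burst waveform over n samples
burst_shape_ <- function(n, shape) {
  if (n < 2) return(rep(0, n))
  u <- seq(0, 1, length.out = n)
  p <- switch(shape,
    hann_sway = sin(pi * u) * sin(2 * pi * 3 * u),
    constant = rep(1, n),
    stop(sprintf("unknown perturbation shape '%s'", shape), call. = FALSE))
  p / sqrt(sum(p^2))
}

#' Synthesise one walking trial
#'
#' Builds a quasi-periodic tri-axial trace: each gait cycle is a fixed
#' 3-harmonic waveform of the participant's step frequency, with per-cycle
#' timing and amplitude jitter whose standard deviations grow linearly with
#' fatigue level (1x at level 0 to 3x at level 5), plus white sensor noise.
#' A hazard burst of the preset's shape and the given (or calibrated)
#' magnitude is added over `hazard_n_cycles` whole cycles, and after each
#' hazard the per-cycle deviation decays along the preset's `-a ln(k) + b`
#' curve, floored at zero excess.
#'
#' @param profile One row of [sample_failure_counts()] output (data frame or
#'   list with `step_frequency`, `base_amplitude`, `noise_scale`,
#'   `participant_id`).
#' @param preset An [environment_preset()].
#' @param level Fatigue level 0..5.
#' @param cycles Gait cycles in the trial (>= 5).
#' @param seed Integer seed; the trial is a pure function of its arguments.
#' @param sampling_rate Hz.
#' @param hazard_start_cycles 0-based cycle indices where hazards start; the
#'   default places one hazard at 40% of the walk. Two entries give the
#'   consecutive-hazard layout.
#' @param hazard_n_cycles Whole cycles each hazard burst spans.
#' @param hazard_magnitude Burst scale; `NULL` takes the preset's calibrated
#'   magnitude for `level`.
#' @return List with `trace` ([accel_trace()]) and `ground_truth` (list:
#'   `cycle_boundaries` data frame, `hazard_windows`, `injected_magnitude`,
#'   `decay_coefficients`).
#' @export
synth_trial <- function(profile, preset, level, cycles = 30, seed = 1,
                        sampling_rate = 128,
                        hazard_start_cycles = NULL,
                        hazard_n_cycles = .gen_defaults$hazard_n_cycles,
                        hazard_magnitude = NULL) {
  stopifnot(inherits(preset, "environment_preset"))
  if (cycles < 5) stop("synth_trial: cycles must be >= 5", call. = FALSE)
  if (level < 0 || level > 5) stop("synth_trial: level must be in 0..5", call. = FALSE)
  g <- .gen_defaults
  if (is.null(hazard_start_cycles)) {
    hazard_start_cycles <- floor(g$hazard_frac * cycles)
  }
  hazard_end_cycles <- hazard_start_cycles + hazard_n_cycles
  if (any(hazard_start_cycles < 1) || any(hazard_end_cycles > cycles - 1)) {
    stop("synth_trial: hazard must not start in the first or end in the last cycle",
         call. = FALSE)
  }
  if (is.null(hazard_magnitude)) {
    hazard_magnitude <- preset$hazard_magnitude_by_level[level + 1]
  }
  decay <- preset$recovery_decay_by_level[level + 1, ]
  fmult <- 1 + (g$fatigue_mult_max - 1) * level / 5
  fs <- sampling_rate
  f0 <- profile$step_frequency
  A <- profile$base_amplitude

  with_seed_(seed, {
    # per-cycle periods and amplitude multipliers (cycles + 1 waveform peaks)
    n_per <- cycles + 1L
    periods <- (1 / f0) * pmax(0.5, 1 + g$timing_jitter_sd * fmult * rnorm(n_per))
    amp_mult <- pmax(0.2, 1 + g$amp_jitter_sd * fmult * rnorm(n_per + 1L))
    lead <- 0.6 * periods[1]
    tail_ <- 0.6 * periods[n_per]
    peak_times <- lead + c(0, cumsum(periods))[seq_len(n_per)]
    total_t <- peak_times[n_per] + tail_
    n_samp <- floor(total_t * fs)
    t <- (seq_len(n_samp) - 1) / fs

    # piecewise-linear phase: 2*pi*k at the k-th peak
    knots_t <- c(0, peak_times, total_t)
    knots_ph <- c(-2 * pi * lead / periods[1],
                  2 * pi * (seq_len(n_per) - 1),
                  2 * pi * (n_per - 1) + 2 * pi * tail_ / periods[n_per])
    phase <- stats::approx(knots_t, knots_ph, xout = t, rule = 2)$y

    # per-sample amplitude multiplier by enclosing inter-peak interval
    seg <- findInterval(t, peak_times) + 1L  # 1 = lead-in, n_per + 1 = tail
    amp_s <- amp_mult[seg]

    h <- step_template_(phase)
    az <- g$gravity + A * amp_s * h
    ax <- 0.3 * A * amp_s * step_template_(2 * phase) * 0.5
    ay <- -0.2 * A * amp_s * cos(phase)
    ns <- profile$noise_scale * fmult
    ax <- ax + rnorm(n_samp, 0, ns)
    ay <- ay + rnorm(n_samp, 0, ns)
    az <- az + rnorm(n_samp, 0, ns)

    # ground-truth cycle boundaries: peak-to-peak, 0-based half-open
    bidx <- pmin(n_samp, pmax(1L, round(peak_times * fs) + 1L)) - 1L
    cycle_df <- data.frame(start = bidx[-n_per], end = bidx[-1])

    cyc_range <- function(k) (cycle_df$start[k + 1L] + 1L):cycle_df$end[k + 1L]  # 0-based cycle k
    hazard_windows <- list()
    for (hi in seq_along(hazard_start_cycles)) {
      h0 <- hazard_start_cycles[hi]
      for (hc in h0:(h0 + hazard_n_cycles - 1L)) {
        idx <- cyc_range(hc)
        if (length(idx) < 4) stop("synth_trial: hazard window degenerate", call. = FALSE)
        az[idx] <- az[idx] + hazard_magnitude *
          burst_shape_(length(idx), preset$perturbation_shape)
      }
      w0 <- cycle_df$start[h0 + 1L] + g$hazard_inset
      w1 <- cycle_df$end[h0 + hazard_n_cycles] - g$hazard_inset
      hazard_windows[[hi]] <- c(w0, w1)

      # post-hazard recovery: injected deviation decays as -a ln(k) + b,
      # floored at zero excess over the pre-hazard behaviour
      next_start <- if (hi < length(hazard_start_cycles)) {
        hazard_start_cycles[hi + 1]
      } else cycles
      post <- seq_len(max(0, next_start - (h0 + hazard_n_cycles)))
      for (k in post) {
        e_k <- max(0, decay[["b"]] - decay[["a"]] * log(k))
        if (e_k == 0) break
        amp_k <- hazard_magnitude * sqrt(e_k / decay[["b"]])
        ridx <- cyc_range(h0 + hazard_n_cycles + k - 1L)
        az[ridx] <- az[ridx] + amp_k * burst_shape_(length(ridx), preset$perturbation_shape)
      }
    }

    trace <- accel_trace(ax, ay, az, sampling_rate = fs,
                         participant_id = profile$participant_id,
                         environment = preset$name,
                         fatigue_level = as.integer(level),
                         hazard_windows = hazard_windows)
    list(trace = trace,
         ground_truth = list(cycle_boundaries = cycle_df,
                             hazard_windows = hazard_windows,
                             injected_magnitude = hazard_magnitude,
                             decay_coefficients = decay))
  })
}

#' Calibrate the hazard-burst magnitude for one condition
#'
#' Finds the burst scale at which the mean hazard-zone DTW of pilot
#' simulations matches the preset's target for the given fatigue level.
#' Because the mean hazard-zone DTW is monotone in the scale, bisection with
#' common random numbers (the same pilot seeds at every evaluation) converges
#' to the stated relative tolerance. Pilot references are each participant's
#' own unfatigued non-obstacle medoid cycle, exactly as in the full pipeline.
#'
#' @param preset An [environment_preset()].
#' @param level Fatigue level 0..5.
#' @param n_rep Pilot replicates per evaluation (>= 50 recommended).
#' @param seed Seed for the pilot cohort.
#' @param tol Relative tolerance on the pilot mean (default 0.01).
#' @param max_scale Upper bracket for the scale; expanded automatically if
#'   `NULL`, error if the target is unreachable below it.
#' @param cycles Cycles per pilot trial.
#' @return The calibrated scale (non-negative scalar) with attribute
#'   `pilot_mean`.
#' @export
calibrate_hazard_magnitude <- function(preset, level, n_rep = 60, seed = 1,
                                       tol = 0.01, max_scale = NULL,
                                       cycles = 30) {
  stopifnot(inherits(preset, "environment_preset"))
  target <- preset$target_hazard_dtw_by_level[level + 1]
  if (target == 0) return(structure(0, pilot_mean = 0))

  spec <- cohort_spec(n_participants = n_rep, fatigue_levels = 0:5,
                      environments = "A", cycles_per_trial = cycles,
                      seed = seed,
                      environment_presets = list(A = environment_preset("A")))
  profiles <- sample_failure_counts(spec)
  refA <- environment_preset("A")

  # fixed pilot references (scale-independent)
  refs <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    prof <- profiles[r, ]
    ref_trial <- synth_trial(prof, refA, level = 0, cycles = cycles,
                             seed = trial_seed_(seed, r))
    refs[[r]] <- trial_reference_(ref_trial$trace)
  }

  eval_mean <- function(s) {
    vals <- vapply(seq_len(n_rep), function(r) {
      prof <- profiles[r, ]
      tr <- synth_trial(prof, preset, level = level, cycles = cycles,
                        seed = trial_seed_(seed, n_rep + r),
                        hazard_magnitude = s)
      rec <- analyze_trial(tr$trace, refs[[r]], recovery = FALSE)
      rec$hazard_mean
    }, numeric(1))
    mean(vals)
  }

  base_mean <- eval_mean(0)
  if (base_mean >= target) {
    return(structure(0, pilot_mean = base_mean))
  }
  hi <- if (is.null(max_scale)) max(1, sqrt(target)) else max_scale
  while (eval_mean(hi) < target) {
    hi <- hi * 2
    if (hi > 1e3) stop("calibrate_hazard_magnitude: failed to bracket target", call. = FALSE)
  }
  lo <- 0
  m <- NA_real_
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    m <- eval_mean(mid)
    if (abs(m - target) <= tol * target) {
      return(structure(mid, pilot_mean = m))
    }
    if (m < target) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, pilot_mean = m)
}

#' Generate a full synthetic cohort
#'
#' One trial per requested participant x fatigue level x environment, with a
#' manifest row per trial. Deterministic: the same spec (including seed)
#' reproduces the cohort byte for byte.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, each trace is written
#'   as `trace_<participant>_<env>_L<level>.csv`, ground truth as JSON, and
#'   the manifest as `manifest.json`.
#' @return List with `profiles`, `trials` (named list of [synth_trial()]
#'   results) and `manifest` (data frame).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  profiles <- sample_failure_counts(spec)
  envs <- spec$environments
  levels <- spec$fatigue_levels
  trials <- list()
  rows <- list()
  idx <- 0L
  for (p in seq_len(spec$n_participants)) {
    prof <- profiles[p, ]
    for (env in envs) {
      preset <- spec$environment_presets[[env]]
      for (lev in levels) {
        idx <- idx + 1L
        tr <- synth_trial(prof, preset, level = lev,
                          cycles = spec$cycles_per_trial,
                          seed = trial_seed_(spec$seed, idx),
                          sampling_rate = spec$sampling_rate)
        key <- sprintf("%s_%s_L%d", prof$participant_id, env, lev)
        trials[[key]] <- tr
        rows[[idx]] <- data.frame(
          trial = key,
          trace_path = sprintf("trace_%s.csv", key),
          ground_truth_path = sprintf("gt_%s.json", key),
          participant_id = prof$participant_id,
          environment = env,
          fatigue_level = lev,
          steps_administered = steps_for_level(prof$failure_count, lev),
          hazard_start = tr$ground_truth$hazard_windows[[1]][1],
          hazard_end = tr$ground_truth$hazard_windows[[1]][2])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (key in names(trials)) {
      write_trace_csv(trials[[key]]$trace, file.path(dir, sprintf("trace_%s.csv", key)))
      gt <- trials[[key]]$ground_truth
      jsonlite::write_json(
        list(cycle_boundaries = gt$cycle_boundaries,
             hazard_windows = gt$hazard_windows,
             injected_magnitude = gt$injected_magnitude,
             decay_coefficients = as.list(gt$decay_coefficients)),
        file.path(dir, sprintf("gt_%s.json", key)), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      lapply(seq_len(nrow(manifest)), function(i) {
        r <- manifest[i, ]
        list(trace_path = r$trace_path, participant_id = r$participant_id,
             environment = r$environment, fatigue_level = r$fatigue_level,
             hazard_windows = list(c(r$hazard_start, r$hazard_end)),
             ground_truth_path = r$ground_truth_path)
      }),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, trials = trials, manifest = manifest)
}
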