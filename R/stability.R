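# Per-cycle DTW stability scoring and hazard-zone aggregation.

#' Score gait cycles against a reference cycle
#'
#' Element k is the DTW cost between the reference gait cycle and test cycle
#' k; higher cost = larger deviation from the person's unfatigued gait =
#' lower body stability.
#'
#' @param cycles List of SVM sub-series (non-empty numeric vectors).
#' @param reference Non-empty numeric vector (the reference gait cycle).
#' @return Non-negative numeric vector, one score per cycle.
#' @export
score_cycles <- function(cycles, reference) {
  check_series(reference, "reference")
  if (!is.list(cycles) || length(cycles) < 1) {
    stop("score_cycles: need at least one cycle", call. = FALSE)
  }
  vapply(seq_along(cycles), function(k) {
    if (length(cycles[[k]]) == 0) {
      stop(sprintf("score_cycles: cycle %d is empty", k), call. = FALSE)
    }
    dtw_distance(reference, cycles[[k]])
  }, numeric(1))
}

# half-open interval overlap
overlaps_ <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}

#' Which cycles overlap a set of hazard windows
#'
#' @param cycles Data frame of 0-based half-open `start`, `end` sample
#'   intervals.
#' @param hazard_windows List of length-2 vectors `c(start, end)`, same
#'   convention.
#' @return Logical vector, or an integer matrix of per-window flags if
#'   `by_window = TRUE`.
#' @param by_window Return per-window overlap flags instead of any-window.
#' @export
hazard_cycle_overlap <- function(cycles, hazard_windows, by_window = FALSE) {
  m <- vapply(hazard_windows, function(w) {
    overlaps_(cycles$start, cycles$end, w[1], w[2])
  }, logical(nrow(cycles)))
  m <- matrix(m, nrow = nrow(cycles))
  if (by_window) m else rowSums(m) > 0
}

#' Mean per-cycle DTW over the hazard zone
#'
#' Averages the DTW scores of cycles whose sample interval overlaps (shares
#' at least one sample with) any hazard window. Cycles touching a window
#' only at a boundary are excluded by the half-open convention.
#'
#' @param per_cycle_dtw Numeric scores, one per cycle.
#' @param cycles Data frame of 0-based half-open `start`, `end` intervals.
#' @param hazard_windows List of `c(start, end)` sample windows.
#' @return Non-negative scalar.
#' @export
hazard_zone_mean <- function(per_cycle_dtw, cycles, hazard_windows) {
  stopifnot(length(per_cycle_dtw) == nrow(cycles))
  hit <- hazard_cycle_overlap(cycles, hazard_windows)
  if (!any(hit)) stop("hazard_zone_mean: no cycle overlaps a hazard window", call. = FALSE)
  mean(per_cycle_dtw[hit])
}

#' Extract the reference gait cycle from an unfatigued non-obstacle trial
#'
#' Runs the preprocessing chain (SVM, Hampel filter, cycle segmentation) and
#' returns the medoid cycle under DTW. When the trace carries hazard
#' windows, only the cycles ending before the first hazard are used — the
#' portion of the walk that is plain, undisturbed walking — so neither the
#' hazard response nor the recovery transient can contaminate the reference.
#'
#' @param trace An [accel_trace()] from the participant's level-0
#'   non-obstacle walk.
#' @param ... Passed to [detect_gait_cycles()].
#' @return Numeric vector (the reference cycle).
#' @export
reference_from_trial <- function(trace, ...) {
  s <- filter_outliers(compute_svm(trace))
  cyc <- detect_gait_cycles(s, ...)
  if (length(trace$hazard_windows)) {
    first <- min(vapply(trace$hazard_windows, `[`, numeric(1), 1))
    pre <- cyc[cyc$end <= first, , drop = FALSE]
    if (nrow(pre) >= 3) cyc <- pre
  }
  extract_reference_gait(cycle_series(s, cyc))
}

trial_reference_ <- reference_from_trial

#' Analyze one walking trial against a reference gait
#'
#' The per-trial scoring path: SVM, outlier filter, gait-cycle segmentation,
#' per-cycle DTW against the reference, hazard-zone mean, and (optionally)
#' the recovery fit for the first hazard window.
#'
#' @param trace An [accel_trace()] with at least one hazard window.
#' @param reference Reference gait cycle (numeric vector), e.g. from
#'   [reference_from_trial()].
#' @param recovery Fit the post-hazard recovery trendline (default TRUE).
#' @param ... Passed to [detect_gait_cycles()].
#' @return A `stability_record`: list with `participant_id`, `environment`,
#'   `fatigue_level`, `cycles`, `per_cycle_dtw`, `in_hazard`, `hazard_mean`,
#'   `hazard_peaks` (max score per hazard window) and `recovery` (a
#'   `recovery_fit` or NULL).
#' @export
analyze_trial <- function(trace, reference, recovery = TRUE, ...) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!length(trace$hazard_windows)) {
    stop("analyze_trial: trace has no hazard windows", call. = FALSE)
  }
  s <- filter_outliers(compute_svm(trace))
  cyc <- detect_gait_cycles(s, ...)
  scores <- score_cycles(cycle_series(s, cyc), reference)
  hit <- hazard_cycle_overlap(cyc, trace$hazard_windows, by_window = TRUE)
  any_hit <- rowSums(hit) > 0
  if (!any(any_hit)) stop("analyze_trial: no cycle overlaps a hazard window", call. = FALSE)
  peaks <- apply(hit, 2, function(h) if (any(h)) max(scores[h]) else NA_real_)

  fit <- NULL
  if (recovery) {
    w1 <- which(hit[, 1])
    cap <- if (ncol(hit) > 1) min(which(hit[, 2])) - 1L else length(scores)
    fit <- tryCatch(
      recovery_fit(scores, hazard_cycle_window = c(min(w1) - 1L, max(w1)),
                   fit_end_cycle = cap),
      error = function(e) structure(list(converged = FALSE, message = conditionMessage(e)),
                                    class = "recovery_fit"))
  }
  structure(
    list(participant_id = trace$participant_id,
         environment = trace$environment,
         fatigue_level = trace$fatigue_level,
         cycles = cyc,
         per_cycle_dtw = scores,
         in_hazard = any_hit,
         hazard_mean = mean(scores[any_hit]),
         hazard_peaks = peaks,
         recovery = fit),
    class = "stability_record")
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("stability_record %s env %s L%d: %d cycles, hazard mean %.2f (peak %.2f)\n",
              x$participant_id, x$environment, x$fatigue_level,
              length(x$per_cycle_dtw), x$hazard_mean, max(x$hazard_peaks)))
  invisible(x)
}

#' Condition table: mean hazard-zone DTW by environment and fatigue level
#'
#' Unweighted mean over trials (each trial, hence each participant,
#' contributes equally to its cell).
#'
#' @param records List of `stability_record`s (from [analyze_trial()]).
#' @return Data frame `environment`, `level`, `mean_dtw`, `n`, sorted by
#'   environment then level.
#' @export
aggregate_condition_table <- function(records) {
  if (!length(records)) stop("aggregate_condition_table: no records", call. = FALSE)
  df <- data.frame(
    environment = vapply(records, function(r) r$environment, character(1)),
    level = vapply(records, function(r) r$fatigue_level, integer(1)),
    hazard_mean = vapply(records, function(r) r$hazard_mean, numeric(1)))
  agg <- stats::aggregate(hazard_mean ~ environment + level, df,
                          function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(environment = agg$environment, level = agg$level,
                    mean_dtw = agg$hazard_mean[, "mean"],
                    n = as.integer(agg$hazard_mean[, "n"]))
  out[order(out$environment, out$level), , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()]: requires equal lengths of at
#' least 3 and non-constant inputs.
#'
#' @param x,y Numeric vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_r: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Percent increase in DTW between two consecutive hazards
#'
#' @param first_peak_dtw,second_peak_dtw Peak DTW at the first and second
#'   hazard; `first_peak_dtw` must be positive.
#' @return Percent change `100 * (second - first) / first`.
#' @export
#' @examples
#' consecutive_hazard_increase(27.98, 30.56)  # 9.22...
consecutive_hazard_increase <- function(first_peak_dtw, second_peak_dtw) {
  if (any(first_peak_dtw <= 0)) {
    stop("consecutive_hazard_increase: first peak must be positive", call. = FALSE)
  }
  100 * (second_peak_dtw - first_peak_dtw) / first_peak_dtw
}
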