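# Recovery-time estimation from post-hazard per-cycle DTW decay.
#
# Constructs: the pre-hazard baseline ("Before Hazard Peak Average Line"),
# the peak point (hazard-zone cycle with maximal DTW, i.e. lowest
# stability), a logarithmic trendline y = -a ln(x) + b fitted to the
# post-peak scores, and the meeting point where the trendline returns to
# the baseline; its x-coordinate is the recovery time.

#' Pre-hazard baseline DTW level
#'
#' Mean per-cycle DTW strictly before the first hazard cycle.
#'
#' @param per_cycle_dtw Numeric scores, one per cycle.
#' @param hazard_start_cycle 0-based index of the first cycle overlapping
#'   the hazard; at least 3 cycles must precede it.
#' @return Scalar baseline.
#' @export
before_hazard_baseline <- function(per_cycle_dtw, hazard_start_cycle) {
  if (hazard_start_cycle < 3) {
    stop("before_hazard_baseline: need at least 3 pre-hazard cycles", call. = FALSE)
  }
  mean(per_cycle_dtw[seq_len(hazard_start_cycle)])
}

#' Peak point within the hazard zone
#'
#' The hazard-zone cycle with the highest DTW (lowest stability); ties take
#' the earliest cycle.
#'
#' @param per_cycle_dtw Numeric scores, one per cycle.
#' @param hazard_window_cycles Half-open 0-based cycle-index interval
#'   `c(start, end)` of the hazard zone.
#' @return List with `index` (0-based cycle index) and `value`.
#' @export
find_peak_point <- function(per_cycle_dtw, hazard_window_cycles) {
  s <- hazard_window_cycles[1]; e <- hazard_window_cycles[2]
  if (e <= s) stop("find_peak_point: empty hazard window", call. = FALSE)
  idx <- (s + 1L):e
  k <- idx[which.max(per_cycle_dtw[idx])]
  list(index = k - 1L, value = per_cycle_dtw[k])
}

#' Fit the logarithmic recovery trendline
#'
#' Least-squares fit of `y = -a ln(x) + b` to the post-peak scores, with
#' `x = 1, 2, ...` the cycle offset after the peak (ln is undefined at 0).
#'
#' @param post_peak_dtw At least 4 post-peak per-cycle DTW values, the first
#'   being one cycle after the peak.
#' @return Named numeric `c(a, b)`.
#' @export
#' @examples
#' y <- -1.497 * log(1:50) + 18.202
#' fit_log_recovery(y)  # recovers a = 1.497, b = 18.202
fit_log_recovery <- function(post_peak_dtw) {
  n <- length(post_peak_dtw)
  if (n < 4) stop("fit_log_recovery: need at least 4 post-peak points", call. = FALSE)
  lx <- log(seq_len(n))
  fit <- stats::lm(post_peak_dtw ~ lx)
  c(a = -unname(coef(fit)[2]), b = unname(coef(fit)[1]))
}

#' Recovery time from the fitted trendline
#'
#' The meeting point: the smallest x at which `-a ln(x) + b` has fallen to
#' the pre-hazard baseline, i.e. `x* = exp((b - baseline) / a)`. Returned in
#' cycle units (cycles after the peak); convert to seconds with
#' [cycles_to_seconds()].
#'
#' @param fit Named numeric `c(a, b)` from [fit_log_recovery()]; `a` must be
#'   positive (a decreasing trend).
#' @param baseline Pre-hazard baseline from [before_hazard_baseline()].
#' @return Non-negative scalar (cycles after the peak).
#' @export
recovery_time <- function(fit, baseline) {
  a <- fit[["a"]]; b <- fit[["b"]]
  if (!is.finite(a) || a <= 0) {
    stop("recovery_time: trend not decreasing (a <= 0), no recovery", call. = FALSE)
  }
  exp((b - baseline) / a)
}

#' Convert a cycle count to seconds
#'
#' @param x Cycles (e.g. a recovery time).
#' @param cycles Data frame of cycle `start`, `end` sample intervals.
#' @param sampling_rate Hz.
#' @return Seconds, using the mean cycle duration of the trial.
#' @export
cycles_to_seconds <- function(x, cycles, sampling_rate) {
  x * mean(cycles$end - cycles$start) / sampling_rate
}

#' Full recovery construction for one trial
#'
#' Baseline, peak point, trendline fit over the post-peak window, and the
#' analytic meeting point.
#'
#' @param per_cycle_dtw Numeric scores, one per cycle.
#' @param hazard_cycle_window Half-open 0-based cycle-index interval of the
#'   hazard zone.
#' @param fit_end_cycle Last cycle (1-based count) included in the fit
#'   window; defaults to the end of the trial.
#' @return A `recovery_fit`: list with `baseline`, `peak_index`,
#'   `peak_value`, `a`, `b`, `recovery_time` (cycles after peak) and
#'   `converged`.
#' @export
recovery_fit <- function(per_cycle_dtw, hazard_cycle_window,
                         fit_end_cycle = length(per_cycle_dtw)) {
  baseline <- before_hazard_baseline(per_cycle_dtw, hazard_cycle_window[1])
  pk <- find_peak_point(per_cycle_dtw, hazard_cycle_window)
  if (fit_end_cycle < pk$index + 5L) {
    stop("recovery_fit: fewer than 4 post-peak cycles in the fit window", call. = FALSE)
  }
  post <- per_cycle_dtw[seq.int(pk$index + 2L, fit_end_cycle)]
  ab <- fit_log_recovery(post)
  rt <- recovery_time(ab, baseline)
  structure(
    list(baseline = baseline, peak_index = pk$index, peak_value = pk$value,
         a = ab[["a"]], b = ab[["b"]], recovery_time = rt, converged = TRUE),
    class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("recovery_fit: baseline %.2f, peak %.2f @ cycle %d, y = -%.3f ln(x) + %.3f, recovery %.1f cycles\n",
                x$baseline, x$peak_value, x$peak_index, x$a, x$b, x$recovery_time))
  } else {
    cat(sprintf("recovery_fit: not converged (%s)\n", x$message))
  }
  invisible(x)
}

#' Mean recovery time by environment and fatigue level
#'
#' Non-converged fits are excluded from the means and counted.
#'
#' @param records List of `stability_record`s with recovery fits (from
#'   [analyze_trial()]).
#' @return Data frame `environment`, `level`, `mean_recovery_cycles`, `n`,
#'   `n_excluded`.
#' @export
recovery_summary_by_level <- function(records) {
  df <- data.frame(
    environment = vapply(records, function(r) r$environment, character(1)),
    level = vapply(records, function(r) r$fatigue_level, integer(1)),
    rt = vapply(records, function(r) {
      if (!is.null(r$recovery) && isTRUE(r$recovery$converged)) r$recovery$recovery_time else NA_real_
    }, numeric(1)))
  cells <- unique(df[, c("environment", "level")])
  cells <- cells[order(cells$environment, cells$level), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$environment == cells$environment[i] & df$level == cells$level[i], ]
    ok <- !is.na(sub$rt)
    data.frame(environment = cells$environment[i], level = cells$level[i],
               mean_recovery_cycles = if (any(ok)) mean(sub$rt[ok]) else NA_real_,
               n = sum(ok), n_excluded = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}
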