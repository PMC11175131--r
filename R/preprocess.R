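#' Construct an acceleration trace
#'
#' A waist-worn IMU recording: tri-axial acceleration in m/s^2 (gravity
#' included) sampled at a fixed rate, with trial metadata and optional hazard
#' windows in 0-based half-open sample coordinates.
#'
#' @param ax,ay,az Equal-length finite numeric vectors, m/s^2.
#' @param sampling_rate Samples per second, > 0 (the study hardware records
#'   at 128 Hz).
#' @param participant_id,environment,fatigue_level Trial metadata.
#'   `environment` is one of `"A"` (non-obstacle), `"B"` (obstacle),
#'   `"C"` (water), `"D"` (oil); `fatigue_level` an integer 0..5.
#' @param hazard_windows List of length-2 integer vectors `c(start, end)`,
#'   0-based half-open, each within `[0, length)`.
#' @return An `accel_trace` object.
#' @export
accel_trace <- function(ax, ay, az, sampling_rate = 128,
                        participant_id = NA_character_,
                        environment = NA_character_,
                        fatigue_level = NA_integer_,
                        hazard_windows = list()) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n || n == 0) {
    stop("accel_trace: ax, ay, az must be non-empty and equal length", call. = FALSE)
  }
  bad <- which(!is.finite(ax) | !is.finite(ay) | !is.finite(az))
  if (length(bad)) {
    stop(sprintf("accel_trace: non-finite sample at index %d", bad[1] - 1L), call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("accel_trace: sampling_rate must be > 0", call. = FALSE)
  }
  for (w in hazard_windows) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > n) {
      stop("accel_trace: hazard window outside [0, length)", call. = FALSE)
    }
  }
  structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         sampling_rate = sampling_rate,
         participant_id = participant_id, environment = environment,
         fatigue_level = fatigue_level,
         hazard_windows = hazard_windows),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("accel_trace: %d samples @ %g Hz (%.1f s), participant %s, env %s, level %s, %d hazard window(s)\n",
              length(x$ax), x$sampling_rate, length(x$ax) / x$sampling_rate,
              x$participant_id, x$environment, x$fatigue_level,
              length(x$hazard_windows)))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' Read / write a trace CSV
#'
#' The on-disk form is a CSV with header `t,ax,ay,az`, `t` in seconds at
#' `1/sampling_rate` spacing.
#'
#' @param path File path.
#' @param ... Metadata passed on to [accel_trace()].
#' @return An `accel_trace`.
#' @export
read_trace_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop(sprintf("trace CSV %s must have columns t,ax,ay,az", path), call. = FALSE)
  }
  fs <- if (nrow(df) > 1) 1 / stats::median(diff(df$t)) else 128
  accel_trace(df$ax, df$ay, df$az, sampling_rate = round(fs, 6), ...)
}

#' @rdname read_trace_csv
#' @param trace An `accel_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$ax)
  df <- data.frame(t = (seq_len(n) - 1) / trace$sampling_rate,
                   ax = trace$ax, ay = trace$ay, az = trace$az)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Signal vector magnitude of a tri-axial trace
#'
#' Collapses the three acceleration axes to the per-sample Euclidean norm
#' `sqrt(ax^2 + ay^2 + az^2)`. The scalar SVM series is orientation-free
#' (invariant under sensor rotation) and is the series all downstream gait
#' segmentation and DTW scoring operate on.
#'
#' @param trace An [accel_trace()].
#' @return An `svm_series`: list with `values` (non-negative, same length as
#'   the trace) and `sampling_rate`.
#' @export
compute_svm <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  v <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  structure(list(values = v, sampling_rate = trace$sampling_rate),
            class = "svm_series")
}

#' @export
print.svm_series <- function(x, ...) {
  cat(sprintf("svm_series: %d samples @ %g Hz, range [%.3f, %.3f] m/s^2\n",
              length(x$values), x$sampling_rate, min(x$values), max(x$values)))
  invisible(x)
}

#' Hampel outlier filter
#'
#' Replaces any sample further than `threshold` scaled median absolute
#' deviations from its centred rolling-window median by that median. Window
#' edges use the truncated window. Length is preserved.
#'
#' @param series An `svm_series` or numeric vector.
#' @param window Odd window width in samples, >= 3 (default 11).
#' @param threshold Multiplier on the scaled MAD (1.4826 * MAD), > 0
#'   (default 3).
#' @return Same type as the input, filtered.
#' @export
filter_outliers <- function(series, window = 11L, threshold = 3) {
  x <- if (inherits(series, "svm_series")) series$values else series
  n <- length(x)
  if (window < 3 || window %% 2 == 0) {
    stop("filter_outliers: window must be odd and >= 3", call. = FALSE)
  }
  if (threshold <= 0) stop("filter_outliers: threshold must be > 0", call. = FALSE)
  if (window > n) stop("filter_outliers: window larger than series", call. = FALSE)
  out <- hampel_filter_cpp(as.numeric(x), as.integer(window), threshold)
  if (inherits(series, "svm_series")) {
    series$values <- out
    series
  } else {
    out
  }
}

#' Segment gait cycles from an SVM series
#'
#' Smooths the SVM series with a centred moving average, finds local maxima
#' with at least the requested topographic prominence (expressed as a
#' fraction of the series inter-quartile range, so the detector is invariant
#' to amplitude scaling) and at least `min_period` seconds apart, and returns
#' consecutive peak-to-peak intervals as gait cycles.
#'
#' @param series An `svm_series`.
#' @param min_period Minimum seconds between step peaks (default 0.4 s).
#' @param prominence Required peak prominence as a fraction of the series
#'   IQR (default 0.5).
#' @param smooth_window Moving-average width in seconds (default 0.25 s).
#' @return Data frame with 0-based half-open columns `start`, `end`, one row
#'   per cycle, ordered and non-overlapping.
#' @export
detect_gait_cycles <- function(series, min_period = 0.4, prominence = 0.5,
                               smooth_window = 0.25) {
  stopifnot(inherits(series, "svm_series"))
  x <- series$values
  fs <- series$sampling_rate
  if (length(x) <= 2 * min_period * fs) {
    stop("detect_gait_cycles: series shorter than two minimum periods", call. = FALSE)
  }
  k <- max(1L, round(smooth_window * fs))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # pad the filter's NA edges with the nearest computed value
  first <- which(!is.na(sm))[1]
  last <- max(which(!is.na(sm)))
  sm[seq_len(first - 1)] <- sm[first]
  if (last < length(sm)) sm[(last + 1):length(sm)] <- sm[last]

  pk <- find_prominent_peaks(sm, min_dist = round(min_period * fs),
                             min_prom = prominence * stats::IQR(sm))
  if (length(pk) < 2) {
    stop("detect_gait_cycles: fewer than 2 step peaks found (no gait)", call. = FALSE)
  }
  data.frame(start = pk[-length(pk)] - 1L, end = pk[-1] - 1L)
}

# Local maxima with a minimum topographic prominence and minimum spacing.
# Prominence of a peak = height above the higher of the two lowest saddles
# separating it from higher terrain on each side (or from the series end).
find_prominent_peaks <- function(x, min_dist = 1L, min_prom = 0) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > -Inf]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- h
    i <- p
    while (i > 1 && x[i] <= h) { i <- i - 1L; lmin <- min(lmin, x[i]) }
    left <- if (x[i] > h) h - lmin else h - min(x[seq_len(p)])
    rmin <- h
    i <- p
    while (i < n && x[i] <= h) { i <- i + 1L; rmin <- min(rmin, x[i]) }
    right <- if (x[i] > h) h - rmin else h - min(x[p:n])
    min(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (!length(keep)) return(integer(0))
  # enforce spacing greedily, highest peak first
  ord <- keep[order(-x[keep])]
  sel <- integer(0)
  for (p in ord) {
    if (all(abs(p - sel) >= min_dist)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Slice SVM sub-series for a set of cycles
#'
#' @param series An `svm_series`.
#' @param cycles Data frame with 0-based half-open `start`, `end` columns.
#' @return List of numeric vectors, one per cycle.
#' @export
cycle_series <- function(series, cycles) {
  lapply(seq_len(nrow(cycles)), function(k) {
    series$values[(cycles$start[k] + 1L):cycles$end[k]]
  })
}

#' Reference gait cycle (medoid under DTW)
#'
#' From a participant's unfatigued, non-obstacle walking trial, selects the
#' gait cycle minimising the total DTW distance to all other cycles. Staying
#' in DTW's own metric avoids averaging cycles of unequal length; the medoid
#' is also robust to a few perturbed cycles, whose total distance is
#' inflated. Ties take the earliest cycle.
#'
#' @param cycles List of >= 3 SVM sub-series (numeric vectors).
#' @return The medoid cycle (numeric vector), with attribute `medoid_index`.
#' @export
extract_reference_gait <- function(cycles) {
  if (!is.list(cycles) || length(cycles) < 3) {
    stop("extract_reference_gait: need at least 3 cycles", call. = FALSE)
  }
  dm <- dtw_pairwise_cpp(cycles)
  tot <- rowSums(dm)
  idx <- which.min(tot)  # which.min takes the earliest on ties
  structure(cycles[[idx]], medoid_index = idx)
}
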