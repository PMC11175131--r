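# Walking-environment presets.
#
# Each preset carries the expected hazard-zone DTW per fatigue level that the
# synthetic generator is calibrated to reproduce, the shape of the hazard
# perturbation, the post-hazard recovery decay coefficients, and the
# calibrated perturbation magnitudes themselves.

# Hazard-zone DTW targets by fatigue level 0..5. The non-obstacle level-4
# entry is not part of the published series; the packaged preset fills it
# with the midpoint of its neighbours and it is configurable like the rest.
.hazard_targets <- list(
  A = c(8.0, 9.4, 9.7, 10.7, 16.9, 23.1),   # non-obstacle
  B = c(9.5, 11.2, 12.0, 15.3, 18.9, 24.8),  # obstacle
  C = c(9.7, 10.3, 13.0, 15.9, 18.9, 26.7),  # water surface
  D = c(10.5, 15.5, 16.3, 19.1, 20.1, 34.5)  # oil surface
)

# Analytic recovery time (gait cycles after the peak) injected per fatigue
# level; the decay curve is constructed so that the fitted trendline meets
# the pre-hazard baseline at this many cycles (see recovery_decay_for).
.recovery_cycles <- c(15, 20, 26, 33, 41, 50)

# Calibrated hazard perturbation magnitudes (m/s^2, unit-energy burst scale)
# by environment and level, produced by calibrate_hazard_magnitude() with the
# generator defaults (see scripts/calibrate.R). Regenerate after changing any
# generator default.
.calibrated_magnitudes <- list(
  A = c(3.7786, 3.9522, 3.9418, 4.0122, 4.8175, 5.5572),
  B = c(4.0936, 4.2879, 4.3572, 4.7672, 5.1286, 5.7581),
  C = c(4.1364, 4.1120, 4.5069, 4.8597, 5.1286, 5.9746),
  D = c(4.2530, 4.9828, 5.0151, 5.2922, 5.3239, 6.8373)
)

.env_labels <- c(A = "non-obstacle", B = "obstacle", C = "water", D = "oil")

#' Construct a walking-environment preset
#'
#' @param name One of `"A"` (non-obstacle), `"B"` (obstacle), `"C"` (water),
#'   `"D"` (oil).
#' @param target_hazard_dtw_by_level Length-6 positive, non-decreasing vector
#'   of expected hazard-zone DTW for fatigue levels 0..5.
#' @param perturbation_shape `"hann_sway"` (Hann-windowed sway oscillation)
#'   or `"constant"` (constant offset; used in analytic checks).
#' @param recovery_decay_by_level 6 x 2 matrix of `(a, b)` coefficients of
#'   the injected post-hazard decay `y = -a ln(x) + b` per level; defaults
#'   derived from the DTW targets and [recovery_decay_for()].
#' @param hazard_magnitude_by_level Length-6 non-negative vector of
#'   perturbation scales; defaults to the packaged calibrated values.
#' @return An `environment_preset` object.
#' @export
environment_preset <- function(name,
                               target_hazard_dtw_by_level = .hazard_targets[[name]],
                               perturbation_shape = "hann_sway",
                               recovery_decay_by_level = NULL,
                               hazard_magnitude_by_level = .calibrated_magnitudes[[name]]) {
  if (!name %in% c("A", "B", "C", "D")) {
    stop("environment_preset: name must be one of A, B, C, D", call. = FALSE)
  }
  tg <- target_hazard_dtw_by_level
  if (length(tg) != 6 || any(tg <= 0)) {
    stop("environment_preset: need 6 strictly positive level targets", call. = FALSE)
  }
  if (any(diff(tg) < 0)) {
    stop("environment_preset: level targets must be non-decreasing", call. = FALSE)
  }
  if (is.null(recovery_decay_by_level)) {
    recovery_decay_by_level <- t(vapply(0:5, function(l) {
      recovery_decay_for(tg[l + 1], .recovery_cycles[l + 1])
    }, numeric(2)))
  }
  colnames(recovery_decay_by_level) <- c("a", "b")
  structure(
    list(name = name, label = .env_labels[[name]],
         target_hazard_dtw_by_level = tg,
         perturbation_shape = perturbation_shape,
         recovery_decay_by_level = recovery_decay_by_level,
         hazard_magnitude_by_level = hazard_magnitude_by_level),
    class = "environment_preset")
}

#' Injected recovery-decay coefficients for one condition
#'
#' The generator injects a post-hazard deviation whose per-cycle DTW excess
#' follows `e(k) = max(0, b - a ln k)` with `b` equal to the condition's
#' hazard DTW target and `a = b / ln(K)`, so the decay reaches the floor at
#' `K` cycles after the peak. Because measured DTW is affine in the injected
#' excess, the analytic meeting point of the fitted trendline with the
#' pre-hazard baseline then sits at `K` cycles, independent of the noise
#' floor.
#'
#' @param target Hazard-zone DTW target (`b`).
#' @param recovery_cycles `K`, cycles after the peak at which the decay
#'   reaches baseline.
#' @return Named numeric `c(a, b)`.
#' @export
recovery_decay_for <- function(target, recovery_cycles) {
  stopifnot(target > 0, recovery_cycles > 1)
  c(a = target / log(recovery_cycles), b = target)
}

#' All four packaged environment presets
#'
#' @return Named list `A`, `B`, `C`, `D` of [environment_preset()] objects.
#' @export
environment_presets <- function() {
  setNames(lapply(c("A", "B", "C", "D"), environment_preset),
           c("A", "B", "C", "D"))
}

#' @export
print.environment_preset <- function(x, ...) {
  cat(sprintf("environment_preset %s (%s): targets %s, shape %s\n",
              x$name, x$label,
              paste(x$target_hazard_dtw_by_level, collapse = "/"),
              x$perturbation_shape))
  invisible(x)
}
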