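#' Squared local distance between two scalar samples
#'
#' The elementary cost of matching one sample of the reference (class)
#' sequence against one sample of the test sequence: the squared Euclidean
#' distance `(c - t)^2`.
#'
#' @param c,t Finite numeric scalars (or equal-length vectors, compared
#'   elementwise).
#' @return Non-negative numeric of the common length.
#' @export
#' @examples
#' local_distance(0, 2)  # 4
local_distance <- function(c, t) {
  if (!is.numeric(c) || !is.numeric(t) || any(!is.finite(c)) || any(!is.finite(t))) {
    stop("local_distance: inputs must be finite numerics", call. = FALSE)
  }
  (c - t)^2
}

#' Local-distance matrix between two sequences
#'
#' Builds the I x J matrix `d[i, j] = (C[i] - T[j])^2` that the DTW dynamic
#' program runs over.
#'
#' @param C Reference sequence (non-empty finite numeric vector).
#' @param T_ Test sequence (non-empty finite numeric vector).
#' @return An `length(C)` x `length(T_)` non-negative matrix.
#' @export
build_distance_matrix <- function(C, T_) {
  check_series(C, "C")
  check_series(T_, "T")
  outer(C, T_, function(a, b) (a - b)^2)
}

#' Dynamic time warping alignment
#'
#' Computes the minimal cumulative warping cost between a reference sequence
#' `C` and a test sequence `T_` under the standard step pattern (each path
#' step advances the row index, the column index, or both), with squared
#' Euclidean local distance, no global window and no path-length
#' normalisation. Backtracking returns one minimising warp path; ties are
#' broken deterministically (diagonal, then vertical, then horizontal).
#'
#' Higher DTW cost against a person's own reference gait cycle means the test
#' cycle deviates more from their unfatigued walking pattern, i.e. lower body
#' stability.
#'
#' @param C,T_ Non-empty finite numeric vectors.
#' @return A `dtw_result`: list with `distance` (non-negative scalar) and
#'   `path` (Q x 2 integer matrix of 1-based (i, j) pairs from (1,1) to
#'   (I,J)).
#' @export
#' @examples
#' dtw_align(c(1, 3, 2), c(1, 2))$distance  # 1
dtw_align <- function(C, T_) {
  check_series(C, "C")
  check_series(T_, "T")
  res <- dtw_align_cpp(as.numeric(C), as.numeric(T_))
  colnames(res$path) <- c("i", "j")
  structure(res, class = "dtw_result")
}

#' DTW cost only (no path)
#'
#' Same recurrence as [dtw_align()] but O(min(I,J)) memory and no
#' backtracking; used in the scoring hot loop.
#'
#' @inheritParams dtw_align
#' @return Non-negative scalar.
#' @export
dtw_distance <- function(C, T_) {
  check_series(C, "C")
  check_series(T_, "T")
  dtw_cost_cpp(as.numeric(C), as.numeric(T_))
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW alignment: distance %.6g, path length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

#' Exhaustive-enumeration DTW oracle
#'
#' Enumerates every warp path satisfying the boundary, monotonicity and
#' continuity constraints (path length Q with max(I,J) <= Q <= I+J-1) and
#' returns the minimum-cost one. Exponential in I+J; capped at length 8 per
#' sequence. Exists as an independent check of [dtw_align()].
#'
#' @inheritParams dtw_align
#' @param return_count If `TRUE`, also return the number of enumerated paths.
#' @return A list with `distance`, `path`, and optionally `n_paths`.
#' @export
dtw_bruteforce_oracle <- function(C, T_, return_count = FALSE) {
  check_series(C, "C")
  check_series(T_, "T")
  I <- length(C); J <- length(T_)
  if (I > 8 || J > 8) {
    stop("dtw_bruteforce_oracle: sequences longer than 8 not supported", call. = FALSE)
  }
  d <- build_distance_matrix(C, T_)
  best <- list(distance = Inf, path = NULL)
  n_paths <- 0L
  walk <- function(i, j, cost, path) {
    cost <- cost + d[i, j]
    path[[length(path) + 1L]] <- c(i, j)
    if (i == I && j == J) {
      n_paths <<- n_paths + 1L
      if (cost < best$distance) {
        best <<- list(distance = cost, path = do.call(rbind, path))
      }
      return(invisible())
    }
    if (i < I)          walk(i + 1L, j,      cost, path)
    if (j < J)          walk(i,      j + 1L, cost, path)
    if (i < I && j < J) walk(i + 1L, j + 1L, cost, path)
  }
  walk(1L, 1L, 0, list())
  colnames(best$path) <- c("i", "j")
  if (return_count) best$n_paths <- n_paths
  best
}

check_series <- function(x, name) {
  if (length(x) == 0) {
    stop(sprintf("%s: series must be non-empty", name), call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("%s: series must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}
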