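test_that("SVM is the per-sample Euclidean norm", {
  tr <- accel_trace(c(0, 3), c(0, 4), c(0, 0))
  expect_equal(compute_svm(tr)$values, c(0, 5))
  set.seed(3)
  n <- 200
  tr <- accel_trace(rnorm(n), rnorm(n), rnorm(n))
  s <- compute_svm(tr)
  oracle <- vapply(seq_len(n), function(i) {
    sqrt(sum(c(tr$ax[i], tr$ay[i], tr$az[i])^2))
  }, numeric(1))
  expect_equal(s$values, oracle, tolerance = 1e-12)
  expect_error(accel_trace(c(1, NaN), c(0, 0), c(0, 0)), "non-finite sample at index 1")
})

test_that("SVM is invariant under rotations of the axes", {
  set.seed(4)
  n <- 100
  a <- matrix(rnorm(3 * n), ncol = 3)
  for (rep in 1:10) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    b <- a %*% R
    s1 <- compute_svm(accel_trace(a[, 1], a[, 2], a[, 3]))$values
    s2 <- compute_svm(accel_trace(b[, 1], b[, 2], b[, 3]))$values
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("Hampel filter replaces spikes by the window median and nothing else", {
  expect_equal(filter_outliers(rep(2, 50), window = 11), rep(2, 50))

  # hand evaluation on a 7-point window: x = 1..13 with x[7] = 100;
  # window of index 7 is (4,5,6,100,8,9,10), median 8, MAD-based scale
  # 1.4826*2 = 2.9652, |100-8| > 3*2.9652 so x[7] -> 8
  x <- as.numeric(1:13); x[7] <- 100
  f <- filter_outliers(x, window = 7, threshold = 3)
  expect_equal(f[7], 8)
  expect_equal(f[-7], x[-7])

  # infinite threshold is the identity
  expect_equal(filter_outliers(x, window = 7, threshold = Inf), x)
  expect_error(filter_outliers(1:5, window = 4), "odd")
  expect_error(filter_outliers(1:5, window = 7), "larger than series")
})

test_that("cycle segmentation recovers ground truth on a noise-free trace", {
  prof <- test_profile(noise_scale = 0)
  tt <- synth_trial(prof, environment_preset("A"), level = 0, cycles = 10,
                    seed = 5, hazard_magnitude = 0)
  s <- compute_svm(tt$trace)
  cyc <- detect_gait_cycles(s)
  gt <- tt$ground_truth$cycle_boundaries
  expect_equal(nrow(cyc), nrow(gt))
  expect_true(all(abs(cyc$start - gt$start) <= 2))
  expect_true(all(abs(cyc$end - gt$end) <= 2))
})

test_that("segmentation rejects flat series and is amplitude-scale invariant", {
  flat <- structure(list(values = rep(9.81, 1000), sampling_rate = 128),
                    class = "svm_series")
  expect_error(detect_gait_cycles(flat), "no gait")

  prof <- test_profile()
  tt <- synth_trial(prof, environment_preset("A"), level = 2, seed = 6)
  s <- compute_svm(tt$trace)
  cyc1 <- detect_gait_cycles(s)
  s2 <- s; s2$values <- 2 * s$values
  expect_equal(detect_gait_cycles(s2), cyc1)
})

test_that("segmentation is idempotent after outlier filtering", {
  prof <- test_profile()
  tt <- synth_trial(prof, environment_preset("B"), level = 3, seed = 8)
  s <- filter_outliers(compute_svm(tt$trace))
  cyc1 <- detect_gait_cycles(s)
  cyc2 <- detect_gait_cycles(filter_outliers(s))
  expect_equal(cyc1, cyc2)
})

test_that("cycle counts match ground truth across seeds at default noise", {
  prof <- test_profile()
  for (seed in 1:20) {
    tt <- synth_trial(prof, environment_preset("A"), level = 0, cycles = 20,
                      seed = seed)
    cyc <- detect_gait_cycles(filter_outliers(compute_svm(tt$trace)))
    expect_equal(nrow(cyc), 20)
  }
  # fatigue raises jitter but cycles must still be found
  for (seed in 1:5) {
    tt <- synth_trial(prof, environment_preset("D"), level = 5, cycles = 20,
                      seed = seed)
    cyc <- detect_gait_cycles(filter_outliers(compute_svm(tt$trace)))
    expect_equal(nrow(cyc), 20)
  }
})

test_that("reference gait is the DTW medoid", {
  # all cycles identical: earliest wins
  cyc <- rep(list(c(1, 2, 3, 2, 1)), 4)
  ref <- extract_reference_gait(cyc)
  expect_equal(attr(ref, "medoid_index"), 1L)

  # agreement with an exhaustive all-pairs evaluation
  set.seed(9)
  cyc <- lapply(1:5, function(i) rnorm(sample(8:12, 1)))
  ref <- extract_reference_gait(cyc)
  tot <- vapply(1:5, function(i) {
    sum(vapply(1:5, function(j) dtw_align(cyc[[i]], cyc[[j]])$distance, numeric(1)))
  }, numeric(1))
  expect_equal(attr(ref, "medoid_index"), which.min(tot))

  # a corrupted cycle is never chosen
  clean <- lapply(1:5, function(i) sin(seq(0, 2 * pi, length.out = 30)) + rnorm(30, 0, 0.05))
  bad <- clean[[3]] + 50
  ref <- extract_reference_gait(c(clean[1:2], list(bad), clean[4:5]))
  expect_true(attr(ref, "medoid_index") != 3)

  expect_error(extract_reference_gait(cyc[1:2]), "at least 3")
})
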