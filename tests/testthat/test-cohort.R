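test_that("fatigue-level step counts are 10% increments with ties rounding up", {
  expect_equal(steps_for_level(200, 5), 100L)
  expect_equal(steps_for_level(200, 0), 0L)
  expect_equal(steps_for_level(183, 5), 92L)  # 91.5 ties up
  expect_equal(steps_for_level(183, 1), 18L)  # 18.3 rounds down
  expect_error(steps_for_level(100, 6), "0..5")
  expect_error(steps_for_level(0, 1), ">= 1")
})

test_that("participant profiles are seed-deterministic and respect the floor", {
  spec <- cohort_spec(n_participants = 25, seed = 13,
                      failure_count_distribution = c(mean = 120, sd = 30, min = 40))
  p1 <- sample_failure_counts(spec)
  p2 <- sample_failure_counts(spec)
  expect_identical(p1, p2)
  expect_true(all(p1$failure_count >= 40))
  expect_true(all(p1$step_frequency > 0.5 & p1$step_frequency < 3))

  spec2 <- cohort_spec(n_participants = 25, seed = 13,
                       failure_count_distribution = c(mean = 60, sd = 30, min = 40))
  expect_true(all(sample_failure_counts(spec2)$failure_count >= 40))
})

test_that("failure-count sample mean matches the distribution at large n", {
  spec <- cohort_spec(n_participants = 10000, seed = 17)
  fc <- sample_failure_counts(spec)$failure_count
  # truncation at 40 (2.67 sd below the mean) shifts the mean by ~0.3
  expect_lt(abs(mean(fc) - 120), 1)
})

test_that("trials are pure functions of their seed", {
  prof <- test_profile()
  a <- synth_trial(prof, environment_preset("C"), level = 2, seed = 99)
  b <- synth_trial(prof, environment_preset("C"), level = 2, seed = 99)
  expect_identical(a$trace$az, b$trace$az)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- synth_trial(prof, environment_preset("C"), level = 2, seed = 100)
  expect_false(identical(a$trace$az, c_$trace$az))
})

test_that("trial construction honours the requested cycle count and hazard placement", {
  prof <- test_profile()
  tt <- synth_trial(prof, environment_preset("D"), level = 1, cycles = 20, seed = 3)
  gt <- tt$ground_truth
  expect_equal(nrow(gt$cycle_boundaries), 20)
  n <- length(tt$trace$ax)
  expect_true(all(gt$cycle_boundaries$start < gt$cycle_boundaries$end))
  expect_true(all(diff(gt$cycle_boundaries$start) > 0))
  w <- gt$hazard_windows[[1]]
  expect_gt(w[1], gt$cycle_boundaries$end[1])   # not in the first cycle
  expect_lt(w[2], gt$cycle_boundaries$start[20])  # not in the last cycle
  expect_error(synth_trial(prof, environment_preset("D"), level = 1, cycles = 20,
                           seed = 3, hazard_start_cycles = 19),
               "hazard")
})

test_that("a quiet level-0 trial scores below the level-0 target", {
  # per-cycle DTW against the trial's own reference, no perturbation
  prof <- test_profile()
  target0 <- environment_preset("A")$target_hazard_dtw_by_level[1]
  means <- vapply(1:20, function(seed) {
    tt <- synth_trial(prof, environment_preset("A"), level = 0, seed = seed,
                      hazard_magnitude = 0)
    s <- filter_outliers(compute_svm(tt$trace))
    cyc <- detect_gait_cycles(s)
    mean(score_cycles(cycle_series(s, cyc), extract_reference_gait(cycle_series(s, cyc))))
  }, numeric(1))
  expect_lt(mean(means), target0)
})

test_that("hazard-zone DTW increases monotonically with injected magnitude", {
  prof <- test_profile()
  ref <- test_reference(prof)
  mags <- c(0, 2, 4, 6, 8)
  means <- vapply(mags, function(m) {
    mean(vapply(1:10, function(seed) {
      tt <- synth_trial(prof, environment_preset("B"), level = 2, seed = seed,
                        hazard_magnitude = m)
      analyze_trial(tt$trace, ref, recovery = FALSE)$hazard_mean
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(means, mags, method = "spearman"), 1)
})

test_that("constant-offset perturbation has the closed-form DTW cost", {
  # offset delta on a pair whose optimal path is the diagonal (a constant
  # series: every cell costs delta^2, so the shortest path wins):
  # DTW = L * delta^2, and the scale for a target is sqrt(target/L)
  ref <- rep(9.81, 40)
  L <- length(ref)
  target <- 12
  delta <- sqrt(target / L)
  r <- dtw_align(ref, ref + delta)
  expect_equal(r$distance, target, tolerance = 1e-9)
  expect_equal(nrow(r$path), L)  # diagonal path
})

test_that("calibration returns zero scale for an already-met target", {
  p <- environment_preset("A",
                          target_hazard_dtw_by_level = rep(1e-9, 6) + (0:5) * 1e-12)
  s <- calibrate_hazard_magnitude(p, 0, n_rep = 5, seed = 1, cycles = 12)
  expect_equal(as.numeric(s), 0)
})

test_that("cohort generation is a pure function of the spec", {
  spec <- cohort_spec(n_participants = 2, fatigue_levels = c(0, 4),
                      environments = c("A", "D"), cycles_per_trial = 12,
                      seed = 21)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$manifest), 8)  # 2 x 2 x 2
  expect_equal(length(co$trials), 8)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.json"))),
                   unname(tools::md5sum(file.path(d2, "manifest.json"))))
  tr <- list.files(d1, pattern = "^trace_.*csv$")
  expect_length(tr, 8)
  expect_identical(unname(tools::md5sum(file.path(d1, tr))),
                   unname(tools::md5sum(file.path(d2, tr))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("environment presets enforce positive non-decreasing targets", {
  expect_error(environment_preset("D", target_hazard_dtw_by_level = c(10, 9, 11, 12, 13, 14)),
               "non-decreasing")
  expect_error(environment_preset("D", target_hazard_dtw_by_level = c(-1, 2, 3, 4, 5, 6)),
               "positive")
  expect_error(environment_preset("E"), "one of")
})
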