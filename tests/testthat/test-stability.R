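test_that("cycle scores are DTW distances to the reference", {
  ref <- sin(seq(0, 2 * pi, length.out = 30))
  cycles <- rep(list(ref), 3)
  expect_equal(score_cycles(cycles, ref), rep(0, 3))

  set.seed(10)
  cycles <- lapply(1:4, function(i) ref + rnorm(30, 0, 0.3))
  sc <- score_cycles(cycles, ref)
  oracle <- vapply(cycles, function(cy) dtw_align(ref, cy)$distance, numeric(1))
  expect_equal(sc, oracle, tolerance = 1e-12)

  # squared-distance homogeneity: scaling everything by k scales scores by k^2
  k <- 2.5
  expect_equal(score_cycles(lapply(cycles, `*`, k), ref * k), k^2 * sc,
               tolerance = 1e-9)
  expect_error(score_cycles(list(numeric(0)), ref), "cycle 1")
})

test_that("hazard-zone mean uses exactly the overlapping cycles", {
  cyc <- data.frame(start = c(0, 10, 20, 30), end = c(10, 20, 30, 40))
  dtw <- c(20, 30, 40, 7)

  expect_equal(hazard_zone_mean(dtw, cyc, list(c(30, 40))), 7)
  expect_equal(hazard_zone_mean(dtw, cyc, list(c(5, 18))), mean(c(20, 30)))
  expect_equal(hazard_zone_mean(c(20, 30, 40, 7), cyc, list(c(0, 30))), 30)

  # half-open: a window starting exactly at a cycle's end excludes it
  expect_equal(hazard_zone_mean(dtw, cyc, list(c(10, 12))), 30)
  # and cycles outside the windows never matter
  dtw2 <- dtw; dtw2[c(1, 4)] <- 1e6
  expect_equal(hazard_zone_mean(dtw2, cyc, list(c(12, 18))),
               hazard_zone_mean(dtw, cyc, list(c(12, 18))))
  expect_error(hazard_zone_mean(dtw, cyc, list(c(40, 45))), "no cycle overlaps")
})

test_that("condition table averages hazard means per cell, order-invariantly", {
  mk <- function(env, lev, hm) {
    structure(list(participant_id = "P", environment = env,
                   fatigue_level = as.integer(lev), hazard_mean = hm),
              class = "stability_record")
  }
  recs <- list(mk("A", 0, 10), mk("A", 0, 20), mk("D", 5, 34.5))
  tab <- aggregate_condition_table(recs)
  expect_equal(tab$mean_dtw[tab$environment == "A"], 15)
  expect_equal(tab$n[tab$environment == "A"], 2L)
  expect_equal(tab$mean_dtw[tab$environment == "D"], 34.5)
  expect_equal(aggregate_condition_table(rev(recs)), tab)
})

test_that("pearson_r matches the covariance-formula oracle", {
  x <- 0:5
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)

  # fatigue levels vs obstacle-condition hazard means
  y <- c(9.5, 11.2, 12.0, 15.3, 18.9, 24.8)
  expect_equal(pearson_r(x, y), 0.959, tolerance = 5e-4)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)

  set.seed(12)
  for (rep in 1:25) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(1:2, 1:2), "lengths")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})

test_that("consecutive-hazard increase is the percent change of peak DTW", {
  expect_equal(consecutive_hazard_increase(10, 12), 20)
  expect_equal(consecutive_hazard_increase(27.98, 30.56), 9.22, tolerance = 5e-4)
  expect_equal(consecutive_hazard_increase(3.7, 3.7), 0)
  expect_error(consecutive_hazard_increase(0, 5), "positive")
})

test_that("two-hazard trials score both windows and the second peak grows when dense", {
  prof <- test_profile()
  ref <- test_reference(prof)
  tt <- synth_trial(prof, environment_preset("D"), level = 3, cycles = 30,
                    seed = 31, hazard_start_cycles = c(8, 14))
  rec <- analyze_trial(tt$trace, ref)
  expect_length(rec$hazard_peaks, 2)
  expect_true(all(is.finite(rec$hazard_peaks)))
  inc <- consecutive_hazard_increase(rec$hazard_peaks[1], rec$hazard_peaks[2])
  expect_true(is.finite(inc))
})
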