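test_that("pre-hazard baseline is the mean of strictly earlier cycles", {
  expect_equal(before_hazard_baseline(rep(4.2, 10), 6), 4.2)
  expect_equal(before_hazard_baseline(c(8, 10, 12, 99, 99), 3), 10)
  x <- c(8, 10, 12, 1, 2, 3)
  y <- c(8, 10, 12, 900, 900, 900)
  expect_equal(before_hazard_baseline(x, 3), before_hazard_baseline(y, 3))
  expect_error(before_hazard_baseline(1:10, 2), "at least 3")
})

test_that("peak point is the hazard-zone argmax with earliest-tie rule", {
  x <- c(1, 2, 5, 9, 7, 3, 50)
  p <- find_peak_point(x, c(2, 5))  # cycles 2,3,4 (0-based)
  expect_equal(p$index, 3)
  expect_equal(p$value, 9)
  # global max outside the window is ignored
  expect_equal(find_peak_point(x, c(2, 6))$value, 9)
  # ties take the first
  expect_equal(find_peak_point(c(0, 9, 9, 0), c(1, 3))$index, 1)
  expect_error(find_peak_point(x, c(3, 3)), "empty")
})

test_that("log trendline fit recovers exact coefficients to 1e-9", {
  y <- -1.497 * log(1:50) + 18.202
  ab <- fit_log_recovery(y)
  expect_equal(ab[["a"]], 1.497, tolerance = 1e-9)
  expect_equal(ab[["b"]], 18.202, tolerance = 1e-9)

  flat <- fit_log_recovery(rep(3.5, 10))
  expect_equal(flat[["a"]], 0)
  expect_equal(flat[["b"]], 3.5)
  expect_error(fit_log_recovery(1:3), "at least 4")
})

test_that("noisy log fits recover the decay coefficient on average", {
  set.seed(14)
  a_hat <- vapply(1:20, function(i) {
    y <- -1.497 * log(1:50) + 18.202 + rnorm(50, 0, 0.1)
    fit_log_recovery(y)[["a"]]
  }, numeric(1))
  expect_lt(abs(mean(a_hat) - 1.497), 0.05)
})

test_that("recovery time is the closed-form baseline intersection", {
  expect_equal(recovery_time(c(a = 1.3, b = 7), 7), 1)
  expect_equal(recovery_time(c(a = 2, b = 20), 10), exp(5))
  expect_equal(recovery_time(c(a = 1.497, b = 18.202), 10.82), 138.545,
               tolerance = 1e-3)
  expect_error(recovery_time(c(a = 0, b = 5), 1), "no recovery")
  expect_error(recovery_time(c(a = -1, b = 5), 1), "no recovery")
})

test_that("recovery time rises with b and falls with baseline", {
  a <- 1.5
  bs <- seq(10, 20, by = 2)
  rt_b <- vapply(bs, function(b) recovery_time(c(a = a, b = b), 5), numeric(1))
  expect_true(all(diff(rt_b) > 0))
  bases <- seq(2, 9, by = 1)
  rt_k <- vapply(bases, function(k) recovery_time(c(a = a, b = 10), k), numeric(1))
  expect_true(all(diff(rt_k) < 0))
})

test_that("noise-free synthetic decay reproduces its own meeting point", {
  baseline <- 2.5; a <- 2.2; b <- 19
  y <- c(rep(baseline, 5), 40, pmax(baseline, -a * log(1:24) + b))
  fit <- recovery_fit(y, hazard_cycle_window = c(5, 6), fit_end_cycle = 20)
  expect_equal(fit$baseline, baseline)
  expect_equal(fit$peak_index, 5)
  expect_equal(fit$peak_value, 40)
  expect_equal(fit$a, a, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
  expect_equal(fit$recovery_time, exp((b - baseline) / a), tolerance = 1e-9)
})

test_that("recovery summary averages converged fits per condition", {
  mk <- function(env, lev, rt) {
    structure(list(participant_id = "P", environment = env,
                   fatigue_level = as.integer(lev), hazard_mean = 1,
                   recovery = if (is.na(rt)) {
                     structure(list(converged = FALSE), class = "recovery_fit")
                   } else {
                     structure(list(converged = TRUE, recovery_time = rt),
                               class = "recovery_fit")
                   }),
              class = "stability_record")
  }
  tab <- recovery_summary_by_level(list(mk("A", 0, 100), mk("A", 0, 200),
                                        mk("A", 5, 300), mk("D", 5, NA)))
  a0 <- tab[tab$environment == "A" & tab$level == 0, ]
  expect_equal(a0$mean_recovery_cycles, 150)
  expect_equal(a0$n, 2L)
  d5 <- tab[tab$environment == "D" & tab$level == 5, ]
  expect_equal(d5$n_excluded, 1L)
  expect_true(is.na(d5$mean_recovery_cycles))
})
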