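test_that("noiseless sessions yield the exact deviation every cycle", {
  sess <- simulate_subject_session(noiseless_params(15), default_schedule())
  cyc <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
  usable <- cyc[cyc$usable, ]
  expect_gte(nrow(usable), 9)
  expect_equal(usable$deviation_deg, rep(15, nrow(usable)), tolerance = 1e-12)
  expect_equal(usable$post_window_mean_deg, rep(0, nrow(usable)))

  # orthotropic: all-zero cycles
  sess0 <- simulate_subject_session(noiseless_params(0), default_schedule())
  cyc0 <- extract_cycle_deviations(sess0$left, sess0$right, sess0$schedule)
  expect_equal(cyc0$deviation_deg[cyc0$usable],
               rep(0, sum(cyc0$usable)))
})

test_that("blanked covered eye still yields the deviation via the fallback window", {
  sess <- simulate_subject_session(noiseless_params(12), default_schedule(),
                                   blank_covered = TRUE)
  cyc <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
  usable <- cyc[cyc$usable, ]
  expect_gte(nrow(usable), 9)
  expect_equal(usable$deviation_deg, rep(12, nrow(usable)), tolerance = 1e-12)
})

test_that("session deviation is recovered from noisy sessions", {
  set.seed(30)
  n_sessions <- 30
  errs <- vapply(seq_len(n_sessions), function(i) {
    dev <- runif(1, 5, 25)
    p <- sim_params(true_deviation_deg = dev, phoria_noise_sd_deg = 0,
                    trace_noise_sd_deg = 0.2, blink_rate_hz = 0,
                    seed = 1000 + i)
    sess <- simulate_subject_session(p, default_schedule())
    cyc <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
    aggregate_session(cyc)$deviation_deg - dev
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.3)
})

test_that("a blink inside each measurement window barely moves the median", {
  p <- sim_params(true_deviation_deg = 14, phoria_noise_sd_deg = 0,
                  trace_noise_sd_deg = 0.2, blink_rate_hz = 0, seed = 77)
  sess <- simulate_subject_session(p, default_schedule())
  cyc <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
  base <- aggregate_session(cyc)$deviation_deg

  # knock out 150 ms at the middle of every pre-window
  covers <- as.data.frame(sess$schedule)
  covers <- covers[covers$covered_eye != "none", ]
  for (i in seq_len(nrow(covers))) {
    tr <- if (covers$covered_eye[i] == "left") "left" else "right"
    t0 <- covers$end_s[i] - 0.6
    hit <- sess[[tr]]$time_s >= t0 & sess[[tr]]$time_s < t0 + 0.15
    sess[[tr]]$confidence[hit] <- 0
    sess[[tr]]$x_deg[hit] <- NA_real_
  }
  cyc2 <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
  withgaps <- aggregate_session(cyc2)$deviation_deg
  expect_lt(abs(withgaps - base), 0.2)
})

test_that("transitions with too few valid samples are flagged, not errors", {
  sess <- simulate_subject_session(noiseless_params(10), default_schedule())
  # kill the whole first left pre-window and its fallback
  hit <- sess$left$time_s >= 14 & sess$left$time_s < 15.2
  sess$left$confidence[hit] <- 0
  cyc <- extract_cycle_deviations(sess$left, sess$right, sess$schedule)
  expect_false(cyc$usable[1])
  expect_true(all(cyc$usable[2:9]))
})

test_that("session aggregation honors method and flags", {
  cyc <- data.frame(deviation_deg = c(14, 15, 16, 100, 15),
                    usable = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(aggregate_session(cyc, "median")$deviation_deg, 15)
  expect_equal(aggregate_session(cyc, "mean")$deviation_deg, 15)
  expect_equal(aggregate_session(cyc, "first")$deviation_deg, 14)
  m <- aggregate_session(cyc)
  expect_equal(m$n_usable_cycles, 4)
  none <- data.frame(deviation_deg = 1, usable = FALSE)
  expect_error(aggregate_session(none), "unmeasurable")
})

test_that("repeated-session value selection supports first and mean", {
  v <- c(15.2, 15.8, 15.4)
  expect_equal(select_test_value(v, "first"), 15.2)
  expect_equal(select_test_value(v, "mean"), mean(v))
  expect_equal(select_test_value(7.5, "first"), 7.5)
})
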