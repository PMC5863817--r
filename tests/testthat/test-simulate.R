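test_that("noiseless subject traces are exact piecewise steps", {
  p <- noiseless_params(deviation = 15)
  sess <- simulate_subject_session(p, default_schedule())
  for (tr in list(sess$left, sess$right)) {
    expect_equal(nrow(tr), 60 * 120)
    expect_true(all(tr$confidence == 1))
    # positions only ever at 0, the deviated position, or on a ramp
    expect_true(all(tr$x_deg >= -1e-12 & tr$x_deg <= 15 + 1e-12))
  }
  # deviated position held at exactly the true deviation while covered
  covered_left <- sess$left$time_s >= 11 & sess$left$time_s < 15
  expect_equal(unique(sess$left$x_deg[covered_left]), 15)
  # fixating at exactly 0 while the other eye is covered
  fixating_left <- sess$left$time_s >= 16 & sess$left$time_s < 20
  expect_equal(unique(sess$left$x_deg[fixating_left]), 0)
})

test_that("orthotropic subject gives flat traces at zero", {
  sess <- simulate_subject_session(noiseless_params(deviation = 0),
                                   default_schedule())
  expect_equal(unique(sess$left$x_deg), 0)
  expect_equal(unique(sess$right$x_deg), 0)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- sim_params(true_deviation_deg = 12, seed = 42)
  a <- simulate_subject_session(p, default_schedule())
  b <- simulate_subject_session(p, default_schedule())
  expect_identical(a, b)
  c <- simulate_subject_session(sim_params(true_deviation_deg = 12, seed = 43),
                                default_schedule())
  expect_false(identical(a$left$x_deg, c$left$x_deg))
})

test_that("blinks appear as confidence-0 gaps and covered eyes can be blanked", {
  p <- sim_params(true_deviation_deg = 10, blink_rate_hz = 1, seed = 7)
  sess <- simulate_subject_session(p, default_schedule())
  gaps <- sess$left$confidence == 0
  expect_gt(sum(gaps), 0)
  expect_true(all(is.na(sess$left$x_deg[gaps])))

  blanked <- simulate_subject_session(noiseless_params(10, seed = 7),
                                      default_schedule(),
                                      blank_covered = TRUE)
  covered_left <- blanked$left$time_s >= 10 & blanked$left$time_s < 15
  expect_true(all(blanked$left$confidence[covered_left] == 0))
})

test_that("deviations at or above the 50 PD bound are rejected", {
  expect_error(sim_params(true_deviation_deg = 27), "50 prism diopters")
  expect_silent(sim_params(true_deviation_deg = 26.5))
})

test_that("model-eye session produces the dwell staircase", {
  geom <- test_geometry()
  sess <- simulate_model_eye_session(geom, sample_rate_hz = 2)
  expect_equal(nrow(sess$dwells), 16)
  expect_equal(sess$dwells$true_deg, seq(0, 30, 2))
  expect_equal(length(sess$frames), 16 * 10)
  # ideal device at rest: pupil renders exactly at the resting position
  sess0 <- simulate_model_eye_session(geom, angles_deg = 0,
                                      sample_rate_hz = 1)
  fit <- detect_pupil(sess0$frames[[1]], detect_params_for(geom))
  expect_equal(fit$center_x_px, geom$rest_x_px, tolerance = 1e-3)
  expect_error(simulate_model_eye_session(geom, angles_deg = c(0, 31)),
               "0, 30")
  expect_error(simulate_model_eye_session(geom, dwell_s = 2), "dwell_s")
})

test_that("frame sequences round-trip through PNG directories", {
  geom <- test_geometry()
  sess <- simulate_model_eye_session(geom, angles_deg = c(0, 10),
                                     sample_rate_hz = 1)
  dir <- withr::local_tempdir()
  write_frames(sess, dir)
  back <- read_frames(dir)
  expect_equal(length(back$frames), length(sess$frames))
  expect_equal(back$sample_rate_hz, sess$sample_rate_hz)
  expect_equal(back$dwells$true_deg, sess$dwells$true_deg)
  # 8-bit quantization: within half a gray level
  expect_lt(max(abs(back$frames[[1]] - sess$frames[[1]])), 1 / 255)
})
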