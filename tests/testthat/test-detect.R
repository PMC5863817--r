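test_that("noiseless disc is localized to subpixel accuracy", {
  geom <- test_geometry()
  fr <- render_eye_frame(geom, 64, 48)
  fit <- detect_pupil(fr, detect_params_for(geom))
  expect_true(fit$valid)
  expect_lt(abs(fit$center_x_px - 64), 0.1)
  expect_lt(abs(fit$center_y_px - 48), 0.1)
  expect_lt(abs(fit$radius_px - 16.5), 0.5)  # 5.5 mm * 6 px/mm / 2
  expect_gt(fit$confidence, 0.8)
})

test_that("detection is translation-equivariant", {
  geom <- test_geometry()
  p <- detect_params_for(geom)
  base <- detect_pupil(render_eye_frame(geom, 50, 45), p)
  for (shift in list(c(7.3, 0), c(0, -4.6), c(12.5, 6.25))) {
    fit <- detect_pupil(render_eye_frame(geom, 50 + shift[1], 45 + shift[2]), p)
    expect_lt(abs(fit$center_x_px - base$center_x_px - shift[1]), 0.1)
    expect_lt(abs(fit$center_y_px - base$center_y_px - shift[2]), 0.1)
  }
})

test_that("uniform and pupil-free frames are flagged invalid", {
  fit <- detect_pupil(matrix(1, 96, 128))
  expect_false(fit$valid)
  expect_equal(fit$confidence, 0)
  # pure noise, no dark disc: area/circularity gates must reject
  set.seed(5)
  noise <- matrix(runif(96 * 128, 0.7, 1), 96, 128)
  fitn <- detect_pupil(noise, detect_params_for(test_geometry()))
  expect_false(fitn$valid)
})

test_that("center error stays small under pixel noise", {
  geom <- test_geometry()
  p <- detect_params_for(geom)
  set.seed(11)
  errs <- replicate(100, {
    cx <- runif(1, 40, 80); cy <- runif(1, 40, 56)
    fr <- render_eye_frame(geom, cx, cy)
    fr <- pmin(pmax(fr + matrix(rnorm(length(fr), 0, 0.05),
                                nrow(fr), ncol(fr)), 0), 1)
    fit <- detect_pupil(fr, p)
    expect_true(fit$valid)
    sqrt((fit$center_x_px - cx)^2 + (fit$center_y_px - cy)^2)
  })
  expect_lt(mean(errs), 0.3)
})

test_that("frames_to_trace inverts the camera projection", {
  geom <- test_geometry()
  # exact inversion of a known displacement
  dx <- angle_to_px(geom, 14)
  expect_equal(px_to_angle(geom, dx), 14, tolerance = 1e-12)
  expect_equal(px_to_angle(geom, 0), 0)
  # round trip through rendered frames over the whole supported range
  p <- detect_params_for(geom)
  angles <- seq(0, 30, by = 5)
  fits <- do.call(rbind, lapply(seq_along(angles), function(i) {
    fr <- render_eye_frame(geom, geom$rest_x_px + angle_to_px(geom, angles[i]),
                           geom$rest_y_px)
    detect_pupil(fr, p, frame_index = i)
  }))
  tr <- frames_to_trace(fits, geom, sample_rate_hz = 120)
  expect_lt(max(abs(tr$x_deg - angles)), 0.05)
  expect_equal(tr$time_s, (seq_along(angles) - 1) / 120)
})

test_that("out-of-domain displacements become warned gaps", {
  geom <- test_geometry()
  fits <- data.frame(frame_index = 1:2,
                     center_x_px = c(geom$rest_x_px,
                                     geom$rest_x_px + 2 * 6 * 13),
                     center_y_px = geom$rest_y_px,
                     radius_px = 16.5, confidence = 1, valid = TRUE)
  expect_warning(tr <- frames_to_trace(fits, geom, 120), "globe radius")
  expect_true(is.na(tr$x_deg[2]))
  expect_equal(tr$confidence[2], 0)
})

test_that("dwell medians recover the staircase on noiseless frames", {
  geom <- test_geometry()
  sess <- simulate_model_eye_session(geom, angles_deg = seq(0, 30, 10),
                                     sample_rate_hz = 2)
  fits <- detect_frames(sess)
  tr <- frames_to_trace(fits, geom, sess$sample_rate_hz)
  dw <- dwell_values(tr, sess$dwells)
  expect_equal(dw$vog_deg, dw$camera_deg, tolerance = 0.1)
})
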