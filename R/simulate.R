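#' Subject simulation parameters
#'
#' Parameters of the forward model for an exotropic subject undergoing the
#' alternate cover test.  While an eye is covered it drifts out to its
#' dissociated (exodeviated) position; when uncovered it re-fixates the
#' target with a corrective saccade.  The deviation revealed at each
#' uncover transition is the quantity the pipeline measures.
#'
#' @param true_deviation_deg Exodeviation magnitude, degrees.  Must be
#'   below 26.57 degrees (50 prism diopters), the upper bound of the
#'   deviations this method is intended for.
#' @param phoria_noise_sd_deg SD of the cycle-to-cycle variation of the
#'   dissociated position, degrees (the deviated position is not perfectly
#'   repeatable in real subjects).
#' @param trace_noise_sd_deg SD of additive Gaussian measurement noise per
#'   sample, degrees.
#' @param blink_rate_hz Mean blink rate (Poisson), per second per eye.
#'   Blinks appear as 100-300 ms gaps with confidence 0.
#' @param saccade_duration_s Duration of the re-fixation saccade ramp,
#'   seconds.
#' @param refixation_latency_s Reaction time between the uncover and the
#'   onset of the re-fixation saccade, seconds; the eye holds its
#'   dissociated position during this interval.
#' @param cover_drift_s Time the covered eye takes to drift out to its
#'   dissociated position, seconds.
#' @param sample_rate_hz Camera sampling rate, Hz.
#' @param seed Integer seed; every random draw in the simulation derives
#'   from it, so equal seeds give identical sessions.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(true_deviation_deg = 15,
                       phoria_noise_sd_deg = 0.5,
                       trace_noise_sd_deg = 0.2,
                       blink_rate_hz = 0.25,
                       saccade_duration_s = 0.05,
                       refixation_latency_s = 0.15,
                       cover_drift_s = 0.5,
                       sample_rate_hz = 120,
                       seed = NULL) {
  stopifnot(true_deviation_deg >= 0,
            phoria_noise_sd_deg >= 0, trace_noise_sd_deg >= 0,
            blink_rate_hz >= 0, saccade_duration_s > 0,
            refixation_latency_s >= 0,
            cover_drift_s > 0, sample_rate_hz > 0)
  if (true_deviation_deg >= pd_to_deg(50)) {
    stop("true_deviation_deg must be below ", round(pd_to_deg(50), 2),
         " degrees (50 prism diopters)", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate an alternate-cover session for an exotropic subject
#'
#' Generates the left- and right-eye gaze traces produced by a subject
#' with a given exodeviation following a [cover_schedule()].  The covered
#' eye drifts to its dissociated position (deviation plus per-cycle phoria
#' noise) over `cover_drift_s`; at each alternation the newly uncovered
#' eye re-fixates to 0 degrees with a linear saccade ramp of
#' `saccade_duration_s`.  Gaussian trace noise is added per sample and
#' blinks are inserted as confidence-0 gaps.  With all noise sources at
#' zero the traces are piecewise constant outside the ramps and every
#' uncover step equals `true_deviation_deg` exactly.
#'
#' @param params A [sim_params()].
#' @param schedule A [cover_schedule()].
#' @param blank_covered If `TRUE`, the covered eye's samples get
#'   confidence 0 (an occluder the camera cannot see through); by default
#'   the infrared camera keeps tracking behind the cover.
#' @return A list with elements `left` and `right` ([gaze_trace()]s),
#'   `truth` (the parameters and per-cover-interval dissociated
#'   positions) and `schedule`.
#' @examples
#' sess <- simulate_subject_session(
#'   sim_params(true_deviation_deg = 14, seed = 1), default_schedule())
#' head(sess$left)
#' @export
simulate_subject_session <- function(params, schedule,
                                     blank_covered = FALSE) {
  stopifnot(inherits(params, "sim_params"),
            inherits(schedule, "cover_schedule"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sample_rate_hz
  total <- attr(schedule, "total_duration_s")
  n <- floor(total * fs)
  t <- (seq_len(n) - 1) / fs

  covers <- cover_intervals(schedule)
  # dissociated position per cover interval (deviation + phoria noise, >= 0)
  dissoc <- pmax(0, params$true_deviation_deg +
                   stats::rnorm(nrow(covers), 0, params$phoria_noise_sd_deg))

  traces <- list()
  for (eye in c("left", "right")) {
    mine <- which(covers$covered_eye == eye)
    # piecewise-linear position: 0 when fixating, d_k while covered,
    # linear ramps at cover onset (drift) and uncover (saccade)
    kt <- 0
    kx <- 0
    for (k in mine) {
      s <- covers$start_s[k]; e <- covers$end_s[k]; d <- dissoc[k]
      e_hold <- e + params$refixation_latency_s
      kt <- c(kt, s, s + params$cover_drift_s, e_hold,
              e_hold + params$saccade_duration_s)
      kx <- c(kx, 0, d, d, 0)
    }
    kt_end <- max(kt) + 1
    kt <- c(kt, kt_end)
    kx <- c(kx, 0)
    x <- stats::approx(kt, kx, xout = t, rule = 2)$y
    if (params$trace_noise_sd_deg > 0) {
      x <- x + stats::rnorm(n, 0, params$trace_noise_sd_deg)
    }
    y <- if (params$trace_noise_sd_deg > 0) {
      stats::rnorm(n, 0, params$trace_noise_sd_deg)
    } else rep(0, n)
    conf <- rep(1, n)

    # blinks: Poisson count, uniform onsets, 100-300 ms each
    if (params$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, params$blink_rate_hz * total)
      if (n_blinks > 0) {
        onsets <- stats::runif(n_blinks, 0, total)
        durs <- stats::runif(n_blinks, 0.1, 0.3)
        for (b in seq_len(n_blinks)) {
          gap <- t >= onsets[b] & t < onsets[b] + durs[b]
          x[gap] <- NA_real_; y[gap] <- NA_real_; conf[gap] <- 0
        }
      }
    }
    if (blank_covered) {
      for (k in mine) {
        occluded <- t >= covers$start_s[k] & t < covers$end_s[k]
        x[occluded] <- NA_real_; y[occluded] <- NA_real_; conf[occluded] <- 0
      }
    }
    traces[[eye]] <- gaze_trace(
      data.frame(time_s = t, x_deg = x, y_deg = y, confidence = conf),
      eye = eye, sample_rate_hz = fs)
  }

  list(left = traces$left, right = traces$right,
       truth = list(true_deviation_deg = params$true_deviation_deg,
                    dissociated_deg = dissoc, params = params),
       schedule = schedule)
}

#' Simulate a model-eye calibration session
#'
#' Renders the frame sequence of a physical model eye rotated through a
#' staircase of known angles, dwelling at each step.  The mapping from
#' true rotation to the angle the camera sees is distorted by an affine
#' device response (`true = device_slope * seen + device_intercept`), so
#' the calibration stage has a nontrivial model to recover; with
#' `device_slope = 1, device_intercept = 0` the camera is ideal.
#'
#' @param geometry An [eye_geometry()].
#' @param angles_deg True rotation angles of the staircase, degrees, each
#'   in `[0, 30]`.  Default: 0 to 30 in 2 degree steps (16 dwells).
#' @param dwell_s Dwell time at each angle, seconds (at least 5).
#' @param device_slope,device_intercept Affine device response mapping the
#'   camera-space angle to the true rotation.
#' @param sample_rate_hz Frame rate, Hz.
#' @param noise_sd Pixel noise SD as a fraction of the intensity range
#'   (0 = noiseless).
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `model_eye_session`: a list with `frames`
#'   (list of matrices in `[0,1]`, row = y, column = x), `dwells` (ground
#'   truth: `dwell_index`, `start_s`, `end_s`, `true_deg`, `camera_deg`),
#'   `geometry` and `sample_rate_hz`.
#' @export
simulate_model_eye_session <- function(geometry = eye_geometry(),
                                       angles_deg = seq(0, 30, by = 2),
                                       dwell_s = 5,
                                       device_slope = 1,
                                       device_intercept = 0,
                                       sample_rate_hz = 120,
                                       noise_sd = 0,
                                       seed = NULL) {
  stopifnot(inherits(geometry, "eye_geometry"), dwell_s >= 5,
            sample_rate_hz > 0, noise_sd >= 0, device_slope != 0)
  if (any(angles_deg < 0 | angles_deg > 30)) {
    stop("model-eye angles must lie in [0, 30] degrees", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_per <- floor(dwell_s * sample_rate_hz)
  camera_deg <- (angles_deg - device_intercept) / device_slope
  dwells <- data.frame(
    dwell_index = seq_along(angles_deg),
    start_s = dwell_s * (seq_along(angles_deg) - 1),
    end_s   = dwell_s * seq_along(angles_deg),
    true_deg = angles_deg,
    camera_deg = camera_deg
  )
  cx <- geometry$rest_x_px + angle_to_px(geometry, camera_deg)
  frames <- vector("list", n_per * length(angles_deg))
  f <- 0
  for (k in seq_along(angles_deg)) {
    base <- render_eye_frame(geometry, cx[k], geometry$rest_y_px)
    for (j in seq_len(n_per)) {
      f <- f + 1
      frames[[f]] <- if (noise_sd > 0) {
        clip01(base + matrix(stats::rnorm(length(base), 0, noise_sd),
                             nrow(base), ncol(base)))
      } else base
    }
  }
  structure(list(frames = frames, dwells = dwells, geometry = geometry,
                 sample_rate_hz = sample_rate_hz),
            class = "model_eye_session")
}

#' Render one synthetic eye frame
#'
#' Draws the pupil as a dark anti-aliased disc on a uniform light
#' background, using the orthographic camera model of [eye_geometry()].
#'
#' @param geometry An [eye_geometry()].
#' @param cx,cy Pupil centre in pixel coordinates (centre-of-pixel,
#'   origin top-left, x rightward, y downward).
#' @param bg,pupil_dark Background and pupil intensities in `[0, 1]`.
#' @return Intensity matrix (row = y, column = x) in `[0, 1]`.
#' @export
render_eye_frame <- function(geometry, cx, cy, bg = 0.85, pupil_dark = 0.08) {
  w <- geometry$image_width_px; h <- geometry$image_height_px
  r <- pupil_radius_px(geometry)
  if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1) {
    stop("pupil disc leaves the frame", call. = FALSE)
  }
  xs <- (seq_len(w) - 1) - cx
  ys <- (seq_len(h) - 1) - cy
  d <- sqrt(outer(ys^2, xs^2, `+`))
  coverage <- pmin(pmax(r - d + 0.5, 0), 1)   # 1-px linear edge
  bg - (bg - pupil_dark) * coverage
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @export
print.model_eye_session <- function(x, ...) {
  cat(sprintf("<model_eye_session> %d frames @ %g Hz, %d dwells (%g-%g deg)\n",
              length(x$frames), x$sample_rate_hz, nrow(x$dwells),
              min(x$dwells$true_deg), max(x$dwells$true_deg)))
  invisible(x)
}

#' Write and read frame sequences as PNG directories
#'
#' Frames are stored as 8-bit grayscale PNGs (`frame_000001.png`, ...)
#' plus a `manifest.json` holding the sampling rate and geometry; for
#' simulated sessions the ground-truth dwell table is stored alongside as
#' `dwells.json`.
#'
#' @param session A `model_eye_session` (or a list with `frames`,
#'   `geometry`, `sample_rate_hz`).
#' @param dir Directory to write to (created if needed).
#' @return `write_frames()` returns `dir` invisibly; `read_frames()`
#'   returns a `model_eye_session`-shaped list (with `dwells` present
#'   only if `dwells.json` exists).
#' @export
write_frames <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(session$frames)) {
    png::writePNG(session$frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(
    list(sample_rate_hz = session$sample_rate_hz,
         n_frames = length(session$frames),
         geometry = unclass(session$geometry)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(session$dwells)) {
    jsonlite::write_json(session$dwells, file.path(dir, "dwells.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  g <- man$geometry
  geometry <- eye_geometry(g$globe_diameter_mm, g$pupil_diameter_mm,
                           g$pixels_per_mm, g$image_width_px,
                           g$image_height_px, g$rest_x_px, g$rest_y_px)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  dwell_path <- file.path(dir, "dwells.json")
  dwells <- if (file.exists(dwell_path)) {
    as.data.frame(jsonlite::read_json(dwell_path, simplifyVector = TRUE))
  }
  structure(list(frames = frames, dwells = dwells, geometry = geometry,
                 sample_rate_hz = man$sample_rate_hz),
            class = "model_eye_session")
}
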