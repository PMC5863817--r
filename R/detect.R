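#' Pupil detection configuration
#'
#' Tunables for [detect_pupil()].  The pupil is segmented by thresholding:
#' Otsu's method applied to the darkest-quartile histogram (falling back
#' to a fixed low percentile when that histogram is degenerate), followed
#' by morphological opening and connected-component gating on area and
#' circularity.
#'
#' @param expected_radius_px Expected pupil radius in pixels (from the
#'   geometry); used for the area gate and the area-plausibility factor of
#'   the confidence score.  `NULL` disables both.
#' @param min_area_frac,max_area_frac Area gate as fractions of the
#'   expected pupil area (defaults: 25 to 400 percent).
#' @param circularity_min Minimum circularity \eqn{4\pi A / P^2} for a
#'   component to count as a pupil; rejects elongated shadows.
#' @param min_confidence Confidence below which a fit is marked invalid.
#' @param dark_quantile Quantile defining the dark sub-histogram given to
#'   Otsu's method.
#' @param fallback_percentile Fixed percentile threshold used when the
#'   dark sub-histogram is degenerate.
#' @return An object of class `detect_params`.
#' @export
detect_params <- function(expected_radius_px = NULL,
                          min_area_frac = 0.25,
                          max_area_frac = 4,
                          circularity_min = 0.6,
                          min_confidence = 0.25,
                          dark_quantile = 0.25,
                          fallback_percentile = 0.05) {
  stopifnot(min_area_frac > 0, max_area_frac > min_area_frac,
            circularity_min >= 0, circularity_min <= 1,
            min_confidence >= 0, min_confidence <= 1)
  structure(as.list(environment()), class = "detect_params")
}

#' @rdname detect_params
#' @param geometry An [eye_geometry()]; its pupil size seeds
#'   `expected_radius_px`.
#' @param ... Passed on to [detect_params()].
#' @export
detect_params_for <- function(geometry, ...) {
  detect_params(expected_radius_px = pupil_radius_px(geometry), ...)
}

# Otsu's threshold on a vector of intensities (maximises between-class
# variance over a 256-bin histogram); NA when the input cannot be split.
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  if (length(v) < 2 || diff(range(v)) == 0) return(NA_real_)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  mu1 <- cumsum(counts * mids) / pmax(w1, 1)
  mu2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (mu1 - mu2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  if (!any(is.finite(between))) return(NA_real_)
  mids[which.max(between)]
}

invalid_fit <- function(frame_index) {
  data.frame(frame_index = frame_index, center_x_px = NA_real_,
             center_y_px = NA_real_, radius_px = NA_real_,
             confidence = 0, valid = FALSE)
}

#' Locate the pupil centre in a grayscale frame
#'
#' Segments the dark pupil disc (threshold from Otsu's method on the
#' darkest-quartile histogram), cleans the mask by morphological opening,
#' keeps the largest connected component that passes the area and
#' circularity gates, and reports its intensity-weighted centroid at
#' subpixel resolution together with an equivalent-disc radius.  The
#' confidence score is circularity times an area-plausibility factor;
#' frames without a plausible pupil (blink, occluder, uniform image)
#' return an invalid fit with confidence 0 rather than an error.
#'
#' @param frame Numeric intensity matrix (row = y, column = x); any
#'   non-negative range is accepted and rescaled internally.
#' @param params A [detect_params()].
#' @param frame_index Index recorded in the returned fit.
#' @return A one-row data frame with columns `frame_index`,
#'   `center_x_px`, `center_y_px`, `radius_px`, `confidence`, `valid`
#'   (coordinates are centre-of-pixel, origin at the top-left pixel).
#' @examples
#' geom <- eye_geometry()
#' fr <- render_eye_frame(geom, 50, 47.5)
#' detect_pupil(fr, detect_params_for(geom))
#' @export
detect_pupil <- function(frame, params = detect_params(), frame_index = 1L) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < 0.02 * max(rng[2], 1e-12)) {
    return(invalid_fit(frame_index))  # uniform frame: nothing to segment
  }
  frame01 <- (frame - rng[1]) / diff(rng)

  dark <- frame01[frame01 <= stats::quantile(frame01, params$dark_quantile)]
  thr <- otsu_threshold(dark)
  if (!is.finite(thr)) {
    thr <- stats::quantile(frame01, params$fallback_percentile)
  }
  mask <- frame01 <= thr
  if (!any(mask)) return(invalid_fit(frame_index))

  # morphological opening + labelling (EBImage works in x,y order)
  img <- EBImage::Image(t(mask) * 1)
  img <- EBImage::opening(img, EBImage::makeBrush(3, shape = "disc"))
  lab <- EBImage::bwlabel(img)
  labmat <- t(EBImage::imageData(lab))
  n_obj <- max(labmat)
  if (n_obj < 1) return(invalid_fit(frame_index))

  shp <- EBImage::computeFeatures.shape(lab)
  areas <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * areas / perim^2, 1)

  pass <- circ >= params$circularity_min
  if (!is.null(params$expected_radius_px)) {
    a_exp <- pi * params$expected_radius_px^2
    pass <- pass & areas >= params$min_area_frac * a_exp &
      areas <= params$max_area_frac * a_exp
  }
  if (!any(pass)) return(invalid_fit(frame_index))
  id <- which(pass)[which.max(areas[pass])]

  # subpixel centroid: weight by darkness relative to the local background
  # over the component dilated by one pixel (captures anti-aliased rim)
  comp <- labmat == id
  comp_d <- t(EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(comp) * 1),
                    EBImage::makeBrush(3, shape = "box")))) > 0
  bg_est <- stats::median(frame01[!comp_d])
  w <- pmax(bg_est - frame01, 0) * comp_d
  sw <- sum(w)
  if (sw <= 0) return(invalid_fit(frame_index))
  cols <- matrix(seq_len(ncol(frame01)) - 1, nrow(frame01), ncol(frame01),
                 byrow = TRUE)
  rows <- matrix(seq_len(nrow(frame01)) - 1, nrow(frame01), ncol(frame01))
  cx <- sum(w * cols) / sw
  cy <- sum(w * rows) / sw

  # equivalent radius from the darkness-weighted area (full-coverage
  # pixels carry weight ~ bg - pupil; rim pixels carry partial weight)
  w_full <- stats::quantile(w[comp], 0.9)
  radius <- if (w_full > 0) sqrt(sw / w_full / pi) else sqrt(sum(comp) / pi)

  plaus <- if (!is.null(params$expected_radius_px)) {
    a_exp <- pi * params$expected_radius_px^2
    min(areas[id], a_exp) / max(areas[id], a_exp)
  } else 1
  confidence <- unname(circ[id] * plaus)
  in_frame <- cx >= 0 && cx <= ncol(frame01) - 1 &&
    cy >= 0 && cy <= nrow(frame01) - 1
  valid <- confidence >= params$min_confidence && in_frame
  if (!valid) confidence <- min(confidence, params$min_confidence)
  data.frame(frame_index = frame_index, center_x_px = unname(cx),
             center_y_px = unname(cy), radius_px = unname(radius),
             confidence = confidence, valid = valid)
}

#' Detect the pupil in every frame of a sequence
#'
#' @param frames List of intensity matrices, or a `model_eye_session`.
#' @param params A [detect_params()]; defaults to gates derived from the
#'   session geometry when a session is given.
#' @return Data frame of per-frame fits (see [detect_pupil()]).
#' @export
detect_frames <- function(frames, params = NULL) {
  if (inherits(frames, "model_eye_session") ||
      (is.list(frames) && !is.null(frames$frames))) {
    if (is.null(params)) params <- detect_params_for(frames$geometry)
    frames <- frames$frames
  }
  if (is.null(params)) params <- detect_params()
  fits <- lapply(seq_along(frames), function(i) {
    detect_pupil(frames[[i]], params, frame_index = i)
  })
  do.call(rbind, fits)
}

#' Convert per-frame pupil fits to an angular gaze trace
#'
#' Inverts the orthographic camera model: the horizontal angle is
#' \eqn{\arcsin(\Delta x / (p R))} where \eqn{\Delta x} is the pixel
#' displacement from the resting position, \eqn{p} the camera scale and
#' \eqn{R} the globe radius (vertical likewise).  Invalid fits become
#' `NA` gaps with confidence 0; displacements outside the arcsin domain
#' also become gaps, with a warning.
#'
#' @param fits Data frame of fits from [detect_frames()].
#' @param geometry The [eye_geometry()] used to acquire the frames.
#' @param sample_rate_hz Frame rate, Hz.
#' @param eye Which eye the frames show.
#' @return A [gaze_trace()] with `time_s = (frame_index - 1) / sample_rate_hz`.
#' @export
frames_to_trace <- function(fits, geometry, sample_rate_hz,
                            eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(is.data.frame(fits), !is.unsorted(fits$frame_index))
  x <- px_to_angle(geometry, fits$center_x_px - geometry$rest_x_px)
  y <- px_to_angle(geometry, fits$center_y_px - geometry$rest_y_px)
  conf <- fits$confidence
  bad <- !fits$valid | !is.finite(x)
  x[bad] <- NA_real_; y[bad] <- NA_real_; conf[bad] <- 0
  gaze_trace(
    data.frame(time_s = (fits$frame_index - 1) / sample_rate_hz,
               x_deg = x, y_deg = y, confidence = conf),
    eye = eye, sample_rate_hz = sample_rate_hz)
}

#' Per-dwell trace values for calibration
#'
#' Summarises a staircase trace into one angle per dwell segment: the
#' median of the valid samples inside the dwell after trimming `trim_s`
#' seconds at each boundary (the trimming excludes the transition between
#' steps).
#'
#' @param trace A [gaze_trace()].
#' @param dwells Data frame with `start_s`, `end_s` (and ground-truth
#'   columns, passed through).
#' @param trim_s Seconds trimmed from each dwell boundary.
#' @param min_confidence Minimum sample confidence.
#' @return `dwells` with columns `vog_deg` (measured) and `n_samples`
#'   appended.
#' @export
dwell_values <- function(trace, dwells, trim_s = 0.5, min_confidence = 0.5) {
  stopifnot(inherits(trace, "gaze_trace"), is.data.frame(dwells))
  out <- dwells
  res <- mapply(function(s, e) {
    st <- window_stat(trace, s + trim_s, e - trim_s,
                      min_confidence = min_confidence)
    c(st$value, st$n)
  }, dwells$start_s, dwells$end_s)
  out$vog_deg <- res[1, ]
  out$n_samples <- as.integer(res[2, ])
  out
}
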