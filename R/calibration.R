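#' Fit the model-eye linear calibration
#'
#' Ordinary least-squares regression of the true rotation angle of a
#' model eye on the angle reported by the video-oculography device.  The
#' fitted line converts raw device angles to true rotation angles via
#' [apply_calibration()].  The regression direction matches the use of
#' the equation (predicting the true rotation from the device reading);
#' no errors-in-variables correction is applied.
#'
#' @param vog_deg Device (VOG) angles, degrees.
#' @param true_deg True rotation angles of the model eye, degrees.
#' @return An object of class `calibration_model`: a list with `slope`,
#'   `intercept` (degrees), `r_squared`, `pearson_r`, `n_points`.
#' @examples
#' m <- fit_calibration(vog_deg = c(0, 10, 20, 30),
#'                      true_deg = 0.978 * c(0, 10, 20, 30) - 0.549)
#' apply_calibration(m, 15.47)
#' @export
fit_calibration <- function(vog_deg, true_deg) {
  stopifnot(is.numeric(vog_deg), is.numeric(true_deg),
            length(vog_deg) == length(true_deg), length(vog_deg) >= 2)
  keep <- is.finite(vog_deg) & is.finite(true_deg)
  vog_deg <- vog_deg[keep]; true_deg <- true_deg[keep]
  if (length(vog_deg) < 2) stop("need at least 2 finite pairs", call. = FALSE)
  if (stats::sd(vog_deg) == 0) {
    stop("degenerate predictor: all VOG values identical", call. = FALSE)
  }
  fit <- stats::lm(true_deg ~ vog_deg)
  co <- unname(stats::coef(fit))
  # R^2 computed directly: summary.lm() warns on near-perfect fits,
  # which are the normal case for model-eye data
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((true_deg - mean(true_deg))^2)
  calibration_model(
    slope = co[2], intercept = co[1],
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    pearson_r = stats::cor(vog_deg, true_deg),
    n_points = length(vog_deg)
  )
}

#' @rdname fit_calibration
#' @param slope,intercept Line coefficients (intercept in degrees).
#' @param r_squared,pearson_r Fit diagnostics, if known.
#' @param n_points Number of calibration points behind the model.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              pearson_r = NA_real_, n_points = NA_integer_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (is.finite(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (is.finite(pearson_r) && abs(pearson_r) > 1) {
    stop("|pearson_r| must be <= 1", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, pearson_r = pearson_r,
                 n_points = as.integer(n_points)),
            class = "calibration_model")
}

#' @rdname fit_calibration
#' @export
identity_calibration <- function() {
  calibration_model(slope = 1, intercept = 0)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> true = %.4f x VOG %+.4f deg (R^2 = %s, r = %s, n = %s)\n",
    x$slope, x$intercept,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.4f", x$pearson_r)),
    x$n_points))
  invisible(x)
}

#' Apply a calibration model to device angles
#'
#' @param model A `calibration_model`.
#' @param vog_deg Device angle(s), degrees.
#' @return Calibrated rotation angle(s), degrees:
#'   `slope * vog_deg + intercept`.
#' @export
apply_calibration <- function(model, vog_deg) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(vog_deg))
  model$slope * vog_deg + model$intercept
}

#' Convert between degrees and prism diopters
#'
#' A prism diopter (PD) is 1 cm of displacement at 1 m, so a rotation of
#' \eqn{\theta} degrees corresponds to \eqn{100 \tan\theta} PD.
#' `pd_to_deg()` is the exact inverse.
#'
#' @param angle_deg Rotation angle(s), degrees; must satisfy
#'   `abs(angle_deg) < 90`.
#' @param pd Deviation(s) in prism diopters.
#' @return `deg_to_pd()` returns prism diopters; `pd_to_deg()` degrees.
#' @examples
#' deg_to_pd(45)      # 100
#' pd_to_deg(100)     # 45
#' @export
deg_to_pd <- function(angle_deg) {
  stopifnot(is.numeric(angle_deg), all(abs(angle_deg) < 90, na.rm = TRUE))
  tan(angle_deg * pi / 180) * 100
}

#' @rdname deg_to_pd
#' @export
pd_to_deg <- function(pd) {
  stopifnot(is.numeric(pd))
  atan(pd / 100) * 180 / pi
}

#' Serialize calibration models as JSON
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `read_calibration()` returns a `calibration_model`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(obj$slope, obj$intercept,
                    r_squared = obj$r_squared %||% NA_real_,
                    pearson_r = obj$pearson_r %||% NA_real_,
                    n_points = obj$n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate a staircase session end to end
#'
#' Convenience wrapper for the model-eye round trip: detect the pupil in
#' every frame, convert fits to an angular trace, summarise each dwell,
#' and regress the known rotation angles on the measured dwell values.
#'
#' @param session A `model_eye_session` (frames plus ground-truth dwell
#'   table).
#' @param params Optional [detect_params()].
#' @param trim_s Boundary trim for [dwell_values()], seconds.
#' @return A list with `model` (the fitted [calibration_model()]) and
#'   `dwells` (per-dwell measured vs true angles).
#' @export
calibrate_model_eye <- function(session, params = NULL, trim_s = 0.5) {
  fits <- detect_frames(session, params)
  trace <- frames_to_trace(fits, session$geometry, session$sample_rate_hz)
  dw <- dwell_values(trace, session$dwells, trim_s = trim_s)
  list(model = fit_calibration(dw$vog_deg, dw$true_deg), dwells = dw)
}
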