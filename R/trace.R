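#' Gaze traces
#'
#' A gaze trace is the time-indexed angular position of one eye: columns
#' `time_s`, `x_deg`, `y_deg`, `confidence`, with strictly increasing
#' times and confidences in `[0, 1]`.  Angles are measured from the
#' primary position; the horizontal sign convention is positive
#' temporal-ward for each eye.  Samples where the pupil could not be
#' tracked (blinks, occlusion) carry `NA` angles and confidence 0.
#'
#' @param samples Data frame with columns `time_s`, `x_deg`, `y_deg`,
#'   `confidence`.
#' @param eye `"left"` or `"right"`.
#' @param sample_rate_hz Nominal sampling rate, Hz.
#' @return An object of class `gaze_trace` (a data frame with attributes
#'   `eye` and `sample_rate_hz`).
#' @export
gaze_trace <- function(samples, eye = c("left", "right"), sample_rate_hz) {
  eye <- match.arg(eye)
  stopifnot(is.data.frame(samples),
            all(c("time_s", "x_deg", "y_deg", "confidence") %in% names(samples)),
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  samples <- as.data.frame(samples)[, c("time_s", "x_deg", "y_deg", "confidence")]
  if (is.unsorted(samples$time_s, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (any(samples$confidence < 0 | samples$confidence > 1, na.rm = TRUE)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  rownames(samples) <- NULL
  structure(samples, eye = eye, sample_rate_hz = sample_rate_hz,
            class = c("gaze_trace", "data.frame"))
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %s eye, %d samples @ %g Hz, %.1f-%.1f s\n",
              attr(x, "eye"), nrow(x), attr(x, "sample_rate_hz"),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Read and write gaze traces as CSV
#'
#' The file format is one row per sample with header
#' `time_s,eye,x_deg,y_deg,confidence`; a single file may hold both eyes.
#'
#' @param traces A `gaze_trace` or list of them.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a named list of `gaze_trace` objects
#'   (one per eye present in the file).
#' @param sample_rate_hz Sampling rate to attach on read; if `NULL`,
#'   inferred from the median time step.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(time_s = tr$time_s, eye = attr(tr, "eye"),
               x_deg = tr$x_deg, y_deg = tr$y_deg,
               confidence = tr$confidence, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, sample_rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "eye", "x_deg", "y_deg", "confidence")
  if (!all(needed %in% names(df))) {
    stop("trace CSV must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  out <- lapply(split(df, df$eye), function(d) {
    d <- d[order(d$time_s), ]
    fs <- sample_rate_hz
    if (is.null(fs)) {
      dt <- stats::median(diff(d$time_s))
      fs <- if (is.finite(dt) && dt > 0) 1 / dt else 120
    }
    gaze_trace(d[, c("time_s", "x_deg", "y_deg", "confidence")],
               eye = d$eye[1], sample_rate_hz = fs)
  })
  out[order(names(out))]
}

# median of valid samples of one channel within [t0, t1)
window_stat <- function(trace, t0, t1, channel = "x_deg", min_confidence = 0.5) {
  sel <- trace$time_s >= t0 & trace$time_s < t1 &
    trace$confidence >= min_confidence & is.finite(trace[[channel]])
  vals <- trace[[channel]][sel]
  list(value = if (length(vals)) stats::median(vals) else NA_real_,
       n = length(vals))
}
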