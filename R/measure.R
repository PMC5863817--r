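#' Measurement window configuration
#'
#' Windows used by [extract_cycle_deviations()] around each
#' cover-to-uncover transition.  The deviated position is read in the
#' last `pre_window_s` seconds of the covered interval; the re-fixated
#' position is read in `[transition + settle_start_s, transition +
#' settle_end_s]`, which skips the corrective saccade.  Medians over
#' valid samples are used in both windows.
#'
#' @param pre_window_s Length of the pre-transition window, seconds.
#' @param settle_start_s,settle_end_s Settle window bounds relative to
#'   the transition, seconds.
#' @param min_valid_samples Minimum valid samples per window; a
#'   transition with fewer in either window is kept but flagged unusable.
#' @param min_confidence Minimum sample confidence for a sample to count.
#' @param pre_fallback_s When the covered eye was not trackable behind
#'   the occluder (no valid samples in the pre-window), the dissociated
#'   position is instead read in the first `pre_fallback_s` seconds after
#'   the uncover, which fall inside the re-fixation latency and still
#'   show the deviated position.
#' @return An object of class `cycle_windows`.
#' @export
cycle_windows <- function(pre_window_s = 1,
                          settle_start_s = 0.3,
                          settle_end_s = 1.5,
                          min_valid_samples = 10L,
                          min_confidence = 0.5,
                          pre_fallback_s = 0.12) {
  stopifnot(pre_window_s > 0, settle_start_s >= 0,
            settle_end_s > settle_start_s, min_valid_samples >= 1,
            pre_fallback_s > 0)
  structure(as.list(environment()), class = "cycle_windows")
}

#' Extract the per-alternation deviation from a dissociated session
#'
#' For every cover-to-uncover transition in the schedule, measures the
#' re-fixation step of the newly uncovered eye: the absolute difference
#' between the median position while that eye was still covered (last
#' part of the covered interval, when it sits at its dissociated
#' position) and the median position after it has re-fixated the target.
#' Only the horizontal channel enters the deviation; low-confidence
#' samples and the saccade ramp are excluded by the window design.
#'
#' @param trace_left,trace_right [gaze_trace()]s spanning the schedule.
#' @param schedule A [cover_schedule()].
#' @param windows A [cycle_windows()].
#' @return Data frame with one row per transition: `cycle_index`, `eye`,
#'   `pre_window_mean_deg`, `post_window_mean_deg`, `deviation_deg`
#'   (absolute step height), `n_valid_samples` (minimum over the two
#'   windows) and `usable`.
#' @export
extract_cycle_deviations <- function(trace_left, trace_right, schedule,
                                     windows = cycle_windows()) {
  stopifnot(inherits(trace_left, "gaze_trace"),
            inherits(trace_right, "gaze_trace"),
            inherits(schedule, "cover_schedule"),
            inherits(windows, "cycle_windows"))
  if (attr(trace_left, "eye") != "left" || attr(trace_right, "eye") != "right") {
    stop("traces must be given as (left, right)", call. = FALSE)
  }
  covers <- cover_intervals(schedule)
  if (nrow(covers) == 0) stop("schedule has no cover intervals", call. = FALSE)
  out <- vector("list", nrow(covers))
  for (i in seq_len(nrow(covers))) {
    eye <- covers$covered_eye[i]
    tr <- if (eye == "left") trace_left else trace_right
    t_u <- covers$end_s[i]  # uncover transition
    pre <- window_stat(tr, t_u - windows$pre_window_s, t_u,
                       min_confidence = windows$min_confidence)
    if (pre$n < windows$min_valid_samples) {
      # occluder blanked the covered eye: read the dissociated position
      # just after the uncover, inside the re-fixation latency
      fb <- window_stat(tr, t_u, t_u + windows$pre_fallback_s,
                        min_confidence = windows$min_confidence)
      if (fb$n > pre$n) pre <- fb
    }
    post <- window_stat(tr, t_u + windows$settle_start_s,
                        t_u + windows$settle_end_s,
                        min_confidence = windows$min_confidence)
    n_valid <- min(pre$n, post$n)
    usable <- n_valid >= windows$min_valid_samples
    out[[i]] <- data.frame(
      cycle_index = i, eye = eye,
      pre_window_mean_deg = pre$value,
      post_window_mean_deg = post$value,
      deviation_deg = abs(pre$value - post$value),
      n_valid_samples = as.integer(n_valid),
      usable = usable
    )
  }
  do.call(rbind, out)
}

#' Aggregate per-cycle deviations into one session measurement
#'
#' @param cycles Data frame from [extract_cycle_deviations()] (or any
#'   data frame with `deviation_deg` and `usable`).
#' @param method Aggregation over usable cycles: `"median"` (default,
#'   robust to a stray cycle), `"mean"`, or `"first"`.
#' @return An object of class `session_measurement`: a list with
#'   `deviation_deg`, `per_cycle`, `n_usable_cycles`, `method`.
#' @export
aggregate_session <- function(cycles, method = c("median", "mean", "first")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cycles),
            all(c("deviation_deg", "usable") %in% names(cycles)))
  ok <- cycles$usable & is.finite(cycles$deviation_deg)
  if (!any(ok)) {
    stop("no usable cycles: session deviation is unmeasurable", call. = FALSE)
  }
  vals <- cycles$deviation_deg[ok]
  deviation <- switch(method,
                      median = stats::median(vals),
                      mean = mean(vals),
                      first = vals[1])
  structure(list(deviation_deg = deviation, per_cycle = cycles,
                 n_usable_cycles = sum(ok), method = method),
            class = "session_measurement")
}

#' @export
print.session_measurement <- function(x, ...) {
  cat(sprintf("<session_measurement> %.2f deg (%s of %d usable cycles)\n",
              x$deviation_deg, x$method, x$n_usable_cycles))
  invisible(x)
}

#' Select the reported value from repeated sessions
#'
#' When a subject is measured in several repeated sessions, the reported
#' test value is either the first session's value (the default for
#' comparison against a reference test) or the mean of all sessions (as
#' used for test-retest summaries).
#'
#' @param session_values Ordered numeric vector of session deviations.
#' @param rule `"first"` or `"mean"`.
#' @return A single value.
#' @export
select_test_value <- function(session_values, rule = c("first", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(session_values), length(session_values) >= 1)
  switch(rule, first = session_values[1], mean = mean(session_values))
}
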