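#' Cover schedules for the alternate cover test
#'
#' A cover schedule is an ordered, contiguous partition of the session
#' `[0, total_duration_s]` into intervals, each with a covered eye
#' (`"left"`, `"right"`, or `"none"` for binocular viewing).  The first
#' interval is always binocular: initial alignment is verified with both
#' eyes open before dissociation begins.
#'
#' `default_schedule()` builds the standard protocol: a binocular lead-in,
#' then `n_cycles` alternations in which each eye in turn is covered for
#' `cover_s` seconds (so each eye also gets `cover_s` of uncovered time per
#' cycle).  With the defaults (5 cycles, 10 s lead, 5 s cover) the session
#' lasts 60 s and has 11 intervals.
#'
#' @param intervals A data frame with columns `start_s`, `end_s`,
#'   `covered_eye` (each `"left"`, `"right"` or `"none"`).
#' @param n_cycles Number of alternation cycles (each covers left then
#'   right once).
#' @param binocular_lead_s Binocular verification time before the first
#'   cover, seconds.  May be zero (the empty interval is dropped).
#' @param cover_s Covered time per eye per cycle, seconds.
#' @param first_covered Which eye is covered first, `"left"` or `"right"`.
#' @return An object of class `cover_schedule`: a data frame of intervals
#'   with attribute `total_duration_s`.
#' @examples
#' sched <- default_schedule()
#' nrow(sched)                        # 11 intervals
#' attr(sched, "total_duration_s")   # 60 s
#' @export
default_schedule <- function(n_cycles = 5, binocular_lead_s = 10, cover_s = 5,
                             first_covered = c("left", "right")) {
  first_covered <- match.arg(first_covered)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("n_cycles must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(binocular_lead_s) || binocular_lead_s < 0) {
    stop("binocular_lead_s must be non-negative", call. = FALSE)
  }
  if (!is.numeric(cover_s) || cover_s <= 0) {
    stop("cover_s must be positive", call. = FALSE)
  }
  eyes <- if (first_covered == "left") c("left", "right") else c("right", "left")
  covered <- rep(eyes, n_cycles)
  starts <- binocular_lead_s + cover_s * (seq_along(covered) - 1)
  df <- data.frame(
    start_s = c(if (binocular_lead_s > 0) 0, starts),
    end_s   = c(if (binocular_lead_s > 0) binocular_lead_s, starts + cover_s),
    covered_eye = c(if (binocular_lead_s > 0) "none", covered),
    stringsAsFactors = FALSE
  )
  cover_schedule(df)
}

#' @rdname default_schedule
#' @export
cover_schedule <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("start_s", "end_s", "covered_eye") %in% names(intervals)))
  intervals <- intervals[order(intervals$start_s),
                         c("start_s", "end_s", "covered_eye")]
  rownames(intervals) <- NULL
  if (nrow(intervals) < 1) stop("schedule needs at least one interval", call. = FALSE)
  if (!all(intervals$covered_eye %in% c("left", "right", "none"))) {
    stop("covered_eye must be 'left', 'right' or 'none'", call. = FALSE)
  }
  if (any(intervals$end_s <= intervals$start_s)) {
    stop("schedule intervals must have positive length", call. = FALSE)
  }
  if (intervals$start_s[1] != 0) stop("schedule must start at 0 s", call. = FALSE)
  if (nrow(intervals) > 1) {
    gaps <- intervals$start_s[-1] - intervals$end_s[-nrow(intervals)]
    if (any(abs(gaps) > 1e-9)) {
      stop("schedule intervals must be contiguous and non-overlapping",
           call. = FALSE)
    }
  }
  # a binocular interval, when present, must come first and be unique:
  # dissociation is never interrupted once it has begun
  none_idx <- which(intervals$covered_eye == "none")
  if (length(none_idx) > 1 || (length(none_idx) == 1 && none_idx != 1)) {
    stop("at most one binocular interval is allowed and it must be first",
         call. = FALSE)
  }
  structure(intervals,
            total_duration_s = intervals$end_s[nrow(intervals)],
            class = c("cover_schedule", "data.frame"))
}

#' @export
print.cover_schedule <- function(x, ...) {
  cat(sprintf("<cover_schedule> %d intervals, %.1f s total\n",
              nrow(x), attr(x, "total_duration_s")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read and write cover schedules as JSON
#'
#' @param schedule A [cover_schedule()].
#' @param path File path.
#' @return `read_schedule()` returns a `cover_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cover_schedule"))
  jsonlite::write_json(
    list(total_duration_s = attr(schedule, "total_duration_s"),
         intervals = as.data.frame(schedule)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cover_schedule(as.data.frame(obj$intervals))
}

# helper: cover intervals (covered_eye != "none") in schedule order
cover_intervals <- function(schedule) {
  schedule[schedule$covered_eye != "none", , drop = FALSE]
}
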