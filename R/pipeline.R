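#' Pipeline configuration
#'
#' Collects every tunable of the measurement pipeline with defaults equal
#' to the standard protocol: 120 Hz sampling, a 10 s binocular lead-in,
#' and 5 alternation cycles of 5 s covered / 5 s uncovered per eye.
#'
#' @param sample_rate_hz Camera sampling rate, Hz.
#' @param n_cycles,binocular_lead_s,cover_s Schedule parameters (see
#'   [default_schedule()]).
#' @param windows A [cycle_windows()].
#' @param aggregation Within-session cycle aggregation method (see
#'   [aggregate_session()]).
#' @param calibration A [calibration_model()], a path to a calibration
#'   JSON, or `NULL` for the identity calibration.
#' @param seed Integer seed recorded in reports and used by any
#'   simulation step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_rate_hz = 120,
                            n_cycles = 5,
                            binocular_lead_s = 10,
                            cover_s = 5,
                            windows = cycle_windows(),
                            aggregation = "median",
                            calibration = NULL,
                            seed = NULL) {
  stopifnot(sample_rate_hz > 0, inherits(windows, "cycle_windows"))
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  if (is.null(calibration)) calibration <- identity_calibration()
  stopifnot(inherits(calibration, "calibration_model"))
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full measurement pipeline on one session
#'
#' Chains segmentation, per-cycle deviation extraction, within-session
#' aggregation, calibration and prism-diopter conversion into one
#' auditable report.  Any stage failure is re-raised with the stage name
#' prefixed.
#'
#' @param input Either a list with `left` and `right` [gaze_trace()]s, or
#'   a path to a trace CSV holding both eyes.
#' @param schedule A [cover_schedule()] or path to a schedule JSON; if
#'   `NULL`, the schedule implied by the config is used.
#' @param config A [pipeline_config()].
#' @return An object of class `vog_report`: a list with
#'   `deviation_vog_deg` (raw device-space measurement),
#'   `deviation_deg` (calibrated), `deviation_pd`, `per_cycle`,
#'   `n_usable_cycles`, `calibration`, and `provenance`.
#' @examples
#' sess <- simulate_subject_session(
#'   sim_params(true_deviation_deg = 14, trace_noise_sd_deg = 0,
#'              phoria_noise_sd_deg = 0, blink_rate_hz = 0, seed = 1),
#'   default_schedule())
#' run_pipeline(sess, config = pipeline_config(seed = 1))
#' @export
run_pipeline <- function(input, schedule = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  traces <- stage("input", {
    if (is.character(input)) {
      if (!file.exists(input)) stop("trace file not found: ", input)
      read_trace_csv(input, sample_rate_hz = config$sample_rate_hz)
    } else if (is.list(input) && !is.null(input$left) && !is.null(input$right)) {
      input
    } else {
      stop("input must be a trace CSV path or a list with $left and $right")
    }
  })
  schedule <- stage("schedule", {
    if (is.null(schedule)) {
      if (!is.null(traces$schedule)) traces$schedule
      else default_schedule(config$n_cycles, config$binocular_lead_s,
                            config$cover_s)
    } else if (is.character(schedule)) {
      if (!file.exists(schedule)) stop("schedule file not found: ", schedule)
      read_schedule(schedule)
    } else schedule
  })
  cycles <- stage("measure", {
    extract_cycle_deviations(traces$left, traces$right, schedule,
                             config$windows)
  })
  session <- stage("aggregate", aggregate_session(cycles, config$aggregation))
  calibrated <- stage("calibrate", {
    apply_calibration(config$calibration, session$deviation_deg)
  })
  pd <- stage("convert", deg_to_pd(calibrated))
  structure(list(
    deviation_vog_deg = session$deviation_deg,
    deviation_deg = calibrated,
    deviation_pd = pd,
    per_cycle = session$per_cycle,
    n_usable_cycles = session$n_usable_cycles,
    aggregation = session$method,
    calibration = config$calibration,
    provenance = list(
      package = "vogcover",
      version = as.character(utils::packageVersion("vogcover")),
      seed = config$seed,
      config_hash = config_hash(config),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "vog_report")
}

#' @export
print.vog_report <- function(x, ...) {
  cat(sprintf(
    paste0("<vog_report> VOG %.2f deg -> calibrated %.2f deg -> %.2f PD ",
           "(%s of %d usable cycles)\n"),
    x$deviation_vog_deg, x$deviation_deg, x$deviation_pd,
    x$aggregation, x$n_usable_cycles))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `vog_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "vog_report"))
  obj <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
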