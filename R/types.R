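#' @keywords internal
"_PACKAGE"

N_CELLS <- 18L
RAW_MAX <- 255L

#' Construct an insole recording
#'
#' An `insole_recording` holds one foot's time series of 18-cell plantar
#' pressure frames with its sampling metadata. Pressures are stored in
#' kg/cm^2; an optional parallel matrix of 8-bit raw sensor counts may be
#' attached (event-detection thresholds act on the raw-count sum when it is
#' present, since the detection constants live on the digital-count scale).
#'
#' @param cell_pressures numeric matrix, frames x 18 cells, values >= 0
#'   (kg/cm^2).
#' @param sample_rate_hz positive sampling frequency; the device value is
#'   110 Hz.
#' @param foot_side `"left"` or `"right"`.
#' @param raw_counts optional integer matrix of the same shape with values
#'   in \[0, 255\].
#' @param start_time_s time of the first frame, seconds.
#' @return an object of class `insole_recording`.
#' @export
insole_recording <- function(cell_pressures, sample_rate_hz = 110,
                             foot_side = c("left", "right"),
                             raw_counts = NULL, start_time_s = 0) {
  foot_side <- match.arg(foot_side)
  cell_pressures <- as.matrix(cell_pressures)
  if (ncol(cell_pressures) != N_CELLS)
    stop("insole_recording: expected ", N_CELLS, " cells per frame, got ",
         ncol(cell_pressures), call. = FALSE)
  if (nrow(cell_pressures) < 1L)
    stop("insole_recording: at least one frame required", call. = FALSE)
  if (anyNA(cell_pressures) || any(cell_pressures < 0))
    stop("insole_recording: pressures must be non-negative and non-missing",
         call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("insole_recording: sample_rate_hz must be a positive scalar",
         call. = FALSE)
  if (!is.null(raw_counts)) {
    raw_counts <- as.matrix(raw_counts)
    if (!identical(dim(raw_counts), dim(cell_pressures)))
      stop("insole_recording: raw_counts shape must match cell_pressures",
           call. = FALSE)
    if (anyNA(raw_counts) || any(raw_counts < 0L) || any(raw_counts > RAW_MAX))
      stop("insole_recording: raw counts must lie in [0, ", RAW_MAX, "]",
           call. = FALSE)
    storage.mode(raw_counts) <- "integer"
  }
  structure(
    list(foot_side = foot_side,
         sample_rate_hz = as.numeric(sample_rate_hz),
         cell_pressures = unname(cell_pressures),
         raw_counts = if (is.null(raw_counts)) NULL else unname(raw_counts),
         start_time_s = as.numeric(start_time_s)),
    class = "insole_recording")
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> %s foot, %d frames @ %g Hz (%.1f s)%s\n",
              x$foot_side, nrow(x$cell_pressures), x$sample_rate_hz,
              nrow(x$cell_pressures) / x$sample_rate_hz,
              if (is.null(x$raw_counts)) "" else ", 8-bit raw counts attached"))
  invisible(x)
}

#' Number of frames in a recording
#' @param recording an [insole_recording()].
#' @return integer frame count.
#' @export
n_frames <- function(recording) nrow(recording$cell_pressures)

#' Frame timestamps of a recording
#' @param recording an [insole_recording()].
#' @return numeric vector of times in seconds; frame k is at
#'   `start_time_s + (k - 1) / sample_rate_hz`.
#' @export
frame_times <- function(recording) {
  recording$start_time_s +
    (seq_len(n_frames(recording)) - 1) / recording$sample_rate_hz
}

#' Construct a validated gait event sequence
#'
#' Events must strictly alternate initial contact (IC) / toe-off (TO) and
#' start with an IC; use [build_event_sequence()] to coerce raw detector
#' output into this form.
#'
#' @param foot_side `"left"` or `"right"`.
#' @param kind character vector of `"initial_contact"` / `"toe_off"`.
#' @param time_s event times in seconds.
#' @param sample_index 0-based sample indices such that
#'   `time_s = start_time_s + sample_index / sample_rate_hz`.
#' @param diagnostics optional list of counters from sequence validation.
#' @return an object of class `gait_event_sequence` (a data frame with
#'   columns `kind`, `time_s`, `sample_index`).
#' @export
gait_event_sequence <- function(foot_side, kind, time_s, sample_index,
                                diagnostics = list()) {
  stopifnot(length(kind) == length(time_s),
            length(kind) == length(sample_index))
  if (length(kind)) {
    if (!all(kind %in% c("initial_contact", "toe_off")))
      stop("gait_event_sequence: unknown event kind", call. = FALSE)
    if (is.unsorted(time_s, strictly = TRUE))
      stop("gait_event_sequence: event times must strictly increase",
           call. = FALSE)
    expected <- rep_len(c("initial_contact", "toe_off"), length(kind))
    if (!identical(kind, expected))
      stop("gait_event_sequence: kinds must alternate IC, TO, ... starting ",
           "with an initial contact", call. = FALSE)
  }
  out <- data.frame(kind = as.character(kind),
                    time_s = as.numeric(time_s),
                    sample_index = as.integer(sample_index),
                    stringsAsFactors = FALSE)
  structure(out, foot_side = match.arg(foot_side, c("left", "right")),
            diagnostics = diagnostics,
            class = c("gait_event_sequence", "data.frame"))
}

#' @export
print.gait_event_sequence <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat(sprintf("<gait_event_sequence> %s foot: %d events (%d cycles)%s\n",
              attr(x, "foot_side"), nrow(x), nrow(x) %/% 2L,
              if (length(d) && sum(unlist(d)) > 0)
                sprintf(", %d raw detections dropped", sum(unlist(d)))
              else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Stance intervals of an event sequence
#' @param seq a [gait_event_sequence()].
#' @return two-column matrix of `(ic_time, to_time)` pairs in seconds, one
#'   row per complete stance.
#' @export
stance_intervals <- function(seq) {
  ic <- seq$time_s[seq$kind == "initial_contact"]
  to <- seq$time_s[seq$kind == "toe_off"]
  n <- min(length(ic), length(to))
  cbind(ic = ic[seq_len(n)], to = to[seq_len(n)])
}

#' Assemble a condition dataset
#'
#' A `condition_dataset` groups the repeated trials of one named walking
#' condition: for each trial, per-foot tables of cycle parameters and
#' per-foot matrices of stance-normalized force curves.
#'
#' @param condition_name one of the condition labels in
#'   [condition_presets()].
#' @param trials list of trials; each trial is a list with elements
#'   `left`, `right` (cycle-parameter data frames from
#'   [extract_cycle_parameters()]) and optionally `left_curves`,
#'   `right_curves` (cycles x grid matrices).
#' @param require_n if not `NULL`, error unless exactly this many trials are
#'   present (the protocol repeats each condition 3 times).
#' @return an object of class `condition_dataset`.
#' @export
condition_dataset <- function(condition_name, trials, require_n = 3L) {
  if (!is.null(require_n) && length(trials) != require_n)
    stop("condition_dataset: expected ", require_n, " trials for ",
         condition_name, ", got ", length(trials), call. = FALSE)
  for (t in trials)
    if (is.null(t$left) || is.null(t$right))
      stop("condition_dataset: every trial needs both feet", call. = FALSE)
  structure(list(condition_name = condition_name, trials = trials),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  nc <- vapply(x$trials, function(t) nrow(t$left) + nrow(t$right), 0)
  cat(sprintf("<condition_dataset> %s: %d trials, %s cycles\n",
              x$condition_name, length(x$trials),
              paste(nc, collapse = "+")))
  invisible(x)
}

#' Names of the five analysed gait parameters
#'
#' Mean vertical force during single stance (kg/cm^2) and the four phase
#' durations (ms).
#' @return character vector of column names used throughout the package.
#' @export
gait_parameter_names <- function() {
  c("mean_force", "stance_ms", "single_stance_ms", "double_stance_ms",
    "swing_ms")
}
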