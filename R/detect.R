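#' Detection thresholds and filter settings
#'
#' Constants of the thresholded pressure-sum event detector: an initial
#' contact is declared at sample t when dS/dt exceeds `derivative_min` at t
#' and the summed signal exceeds `sum_min_ic` one look-ahead window (100 ms)
#' later; a toe-off when the summed signal is below `sum_max_to` both at t
#' and at t + 100 ms. The constants 0.2 / 50 / 30 live on the 8-bit
#' raw-count sum scale, so detection works on the raw-count channel when a
#' recording carries one, else on the pressure sum (see `channel`).
#'
#' @param derivative_min minimum dS/dt at an initial contact (signal units
#'   per sample; default 0.2).
#' @param sum_min_ic minimum summed signal 100 ms after an initial contact
#'   (default 50).
#' @param sum_max_to maximum summed signal at and 100 ms after a toe-off
#'   (default 30).
#' @param lookahead_ms look-ahead horizon (default 100; exactly 11 samples
#'   at 110 Hz, other rates round to nearest sample).
#' @param min_phase_ms debounce between like events (default 100).
#' @param sg_window_samples odd Savitzky-Golay window length (default 11).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param smooth_derivative take dS/dt from the smoothed sum (`TRUE`) or
#'   from the unsmoothed sum (`FALSE`, default). A centred least-squares
#'   filter leaks a sharp loading edge a few samples backwards; with the
#'   tiny 0.2 slope threshold that pre-echo fires early, so the derivative
#'   test uses the unsmoothed sum by default while the amplitude tests use
#'   the smoothed one.
#' @param channel `"auto"` (raw counts when present), `"raw"` or
#'   `"pressure"`.
#' @return an object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(derivative_min = 0.2, sum_min_ic = 50,
                                 sum_max_to = 30, lookahead_ms = 100,
                                 min_phase_ms = 100,
                                 sg_window_samples = 11L, sg_polyorder = 3L,
                                 smooth_derivative = FALSE,
                                 channel = c("auto", "raw", "pressure")) {
  if (sg_window_samples %% 2L != 1L || sg_window_samples <= sg_polyorder)
    stop("detection_thresholds: sg_window_samples must be odd and greater ",
         "than sg_polyorder", call. = FALSE)
  if (lookahead_ms <= 0)
    stop("detection_thresholds: lookahead_ms must be positive",
         call. = FALSE)
  vals <- c(derivative_min, sum_min_ic, sum_max_to, min_phase_ms)
  if (!all(is.finite(vals)))
    stop("detection_thresholds: thresholds must be finite", call. = FALSE)
  structure(list(derivative_min = derivative_min, sum_min_ic = sum_min_ic,
                 sum_max_to = sum_max_to, lookahead_ms = lookahead_ms,
                 min_phase_ms = min_phase_ms,
                 sg_window_samples = as.integer(sg_window_samples),
                 sg_polyorder = as.integer(sg_polyorder),
                 smooth_derivative = isTRUE(smooth_derivative),
                 channel = match.arg(channel)),
            class = "detection_thresholds")
}

#' Summed cell signal of a recording
#'
#' S(t): the sum over the 18 cells of frame t, on the recording's working
#' channel — raw counts when present (and permitted by
#' `thresholds$channel`), else calibrated pressure.
#'
#' @param recording an [insole_recording()].
#' @param thresholds a [detection_thresholds()] (only its `channel` field
#'   is consulted).
#' @return numeric vector, one value per frame.
#' @export
total_pressure <- function(recording, thresholds = detection_thresholds()) {
  use_raw <- switch(thresholds$channel,
                    auto = !is.null(recording$raw_counts),
                    raw = TRUE, pressure = FALSE)
  if (use_raw) {
    if (is.null(recording$raw_counts))
      stop("total_pressure: channel 'raw' requested but recording has no ",
           "raw counts", call. = FALSE)
    rowSums(recording$raw_counts)
  } else {
    rowSums(recording$cell_pressures)
  }
}

#' Savitzky-Golay smoothing of a series
#'
#' Least-squares local polynomial smoothing with the window and order given
#' in `thresholds`; output length equals input length. Polynomials up to
#' the filter order are reproduced exactly.
#'
#' @param series numeric vector.
#' @param thresholds a [detection_thresholds()].
#' @return smoothed numeric vector of the same length.
#' @export
smooth_series <- function(series, thresholds = detection_thresholds()) {
  if (length(series) < thresholds$sg_window_samples)
    stop("smooth_series: series length ", length(series),
         " is shorter than the filter window ",
         thresholds$sg_window_samples, call. = FALSE)
  as.numeric(signal::sgolayfilt(series, p = thresholds$sg_polyorder,
                                n = thresholds$sg_window_samples))
}

#' Discrete derivative of a series
#'
#' First difference per sample: `d[k] = s[k] - s[k-1]`, with `d[1] = 0`.
#' The per-sample (not per-second) scale is deliberate: the 0.2 slope
#' threshold lives on the per-sample scale, where it sits above
#' quantization noise; a per-second scaling at 110 Hz would let single-count
#' flicker cross it.
#'
#' @param series numeric vector of length >= 2.
#' @param sample_rate_hz kept for interface symmetry; unused in the
#'   per-sample scaling.
#' @return numeric vector of the same length.
#' @export
series_derivative <- function(series, sample_rate_hz = 110) {
  if (length(series) < 2L)
    stop("series_derivative: need at least 2 samples", call. = FALSE)
  c(0, diff(series))
}

# Collapse a logical predicate vector to the first index of each maximal
# TRUE run, then debounce: successive detections closer than min_gap
# samples keep only the earlier one.
first_of_runs <- function(ok, min_gap) {
  idx <- which(ok & !c(FALSE, ok[-length(ok)]))
  if (length(idx) <= 1L) return(idx)
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= min_gap)
    keep <- c(keep, i)
  keep
}

#' Detect initial contacts
#'
#' Sample t is an initial-contact candidate when `dSdt[t] > derivative_min`
#' and `S[t + L] > sum_min_ic`, L being the look-ahead in samples
#' (11 at 110 Hz). The first sample of each rising episode is reported,
#' debounced by `min_phase_ms`. The final look-ahead window cannot host
#' detections.
#'
#' @param S smoothed summed signal.
#' @param dSdt its derivative series (see [series_derivative()]).
#' @param thresholds a [detection_thresholds()].
#' @param sample_rate_hz sampling rate of the series.
#' @return integer vector of 0-based sample indices (possibly empty).
#' @export
detect_initial_contacts <- function(S, dSdt,
                                    thresholds = detection_thresholds(),
                                    sample_rate_hz = 110) {
  stopifnot(length(S) == length(dSdt))
  L <- lookahead_samples(thresholds, sample_rate_hz)
  if (length(S) <= L) {
    warning("detect_initial_contacts: recording shorter than the ",
            "look-ahead window; no events detectable")
    return(integer(0))
  }
  n <- length(S)
  ok <- logical(n)
  t <- seq_len(n - L)
  ok[t] <- dSdt[t] > thresholds$derivative_min &
    S[t + L] > thresholds$sum_min_ic
  min_gap <- max(1L, round(thresholds$min_phase_ms * sample_rate_hz / 1000))
  first_of_runs(ok, min_gap) - 1L
}

#' Detect toe-offs
#'
#' Sample t is a toe-off candidate when `S[t] < sum_max_to` and
#' `S[t + L] < sum_max_to`. The first sample of each qualifying episode is
#' reported, debounced by `min_phase_ms`; episodes starting before the
#' first initial contact are discarded later by [build_event_sequence()].
#'
#' @inheritParams detect_initial_contacts
#' @return integer vector of 0-based sample indices (possibly empty).
#' @export
detect_toe_offs <- function(S, thresholds = detection_thresholds(),
                            sample_rate_hz = 110) {
  L <- lookahead_samples(thresholds, sample_rate_hz)
  if (length(S) <= L) {
    warning("detect_toe_offs: recording shorter than the look-ahead ",
            "window; no events detectable")
    return(integer(0))
  }
  n <- length(S)
  ok <- logical(n)
  t <- seq_len(n - L)
  ok[t] <- S[t] < thresholds$sum_max_to & S[t + L] < thresholds$sum_max_to
  min_gap <- max(1L, round(thresholds$min_phase_ms * sample_rate_hz / 1000))
  first_of_runs(ok, min_gap) - 1L
}

lookahead_samples <- function(thresholds, sample_rate_hz) {
  as.integer(round(thresholds$lookahead_ms * sample_rate_hz / 1000))
}

#' Merge detections into a validated event sequence
#'
#' Initial contacts and toe-offs are merged in time order and coerced to a
#' strictly alternating IC, TO, IC, ... sequence starting at the first IC:
#' leading toe-offs and any event repeating the previous kind are dropped
#' and counted in the diagnostics attribute.
#'
#' @param ics,tos sorted 0-based sample indices from the detectors.
#' @param recording the [insole_recording()] they came from.
#' @return a [gait_event_sequence()]; its `diagnostics` attribute counts
#'   `dropped_ic` and `dropped_to`.
#' @export
build_event_sequence <- function(ics, tos, recording) {
  fs <- recording$sample_rate_hz
  ev <- rbind(
    data.frame(kind = rep("initial_contact", length(ics)),
               sample_index = as.integer(ics)),
    data.frame(kind = rep("toe_off", length(tos)),
               sample_index = as.integer(tos)))
  ev <- ev[order(ev$sample_index, ev$kind != "initial_contact"), ,
           drop = FALSE]
  keep <- logical(nrow(ev))
  dropped <- c(initial_contact = 0L, toe_off = 0L)
  expect <- "initial_contact"
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == expect) {
      keep[i] <- TRUE
      expect <- if (expect == "initial_contact") "toe_off"
      else "initial_contact"
    } else {
      dropped[ev$kind[i]] <- dropped[ev$kind[i]] + 1L
    }
  }
  ev <- ev[keep, , drop = FALSE]
  # drop a trailing unpaired nothing: a trailing IC is legal (open cycle)
  if (nrow(ev) < 2L && nrow(ev) > 0L)
    warning("build_event_sequence: no complete initial-contact/toe-off ",
            "pair for the ", recording$foot_side, " foot")
  if (nrow(ev) == 0L)
    warning("build_event_sequence: empty event sequence for the ",
            recording$foot_side, " foot")
  gait_event_sequence(recording$foot_side, ev$kind,
                      recording$start_time_s + ev$sample_index / fs,
                      ev$sample_index,
                      diagnostics = list(dropped_ic =
                                           unname(dropped["initial_contact"]),
                                         dropped_to =
                                           unname(dropped["toe_off"])))
}

#' Run the full event detector on a recording
#'
#' Convenience wrapper: summed signal, smoothing, derivative, both
#' detectors, sequence validation.
#'
#' @param recording an [insole_recording()].
#' @param thresholds a [detection_thresholds()].
#' @return a [gait_event_sequence()].
#' @export
detect_events <- function(recording, thresholds = detection_thresholds()) {
  S_raw <- total_pressure(recording, thresholds)
  S <- smooth_series(S_raw, thresholds)
  dSdt <- series_derivative(
    if (thresholds$smooth_derivative) S else S_raw,
    recording$sample_rate_hz)
  ics <- detect_initial_contacts(S, dSdt, thresholds,
                                 recording$sample_rate_hz)
  tos <- detect_toe_offs(S, thresholds, recording$sample_rate_hz)
  build_event_sequence(ics, tos, recording)
}
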