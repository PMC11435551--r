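#' Segment an event sequence into gait cycles
#'
#' A gait cycle runs from one initial contact to the next ipsilateral
#' initial contact; each complete cycle is the triple
#' `(IC_i, TO_i, IC_{i+1})`. The first and last cycles of a trial are
#' excluded by default (edge effects of detection and of the trial
#' boundaries).
#'
#' @param seq a [gait_event_sequence()].
#' @param trim_boundary drop the first and last complete cycle (default
#'   `TRUE`).
#' @return data frame with columns `cycle_index`, `ic_s`, `to_s`,
#'   `next_ic_s` (seconds); zero rows when fewer than 3 cycles are
#'   available.
#' @export
segment_cycles <- function(seq, trim_boundary = TRUE) {
  ic <- seq$time_s[seq$kind == "initial_contact"]
  to <- seq$time_s[seq$kind == "toe_off"]
  n <- min(length(to), length(ic) - 1L)  # a trailing open cycle is dropped
  empty <- data.frame(cycle_index = integer(0), ic_s = numeric(0),
                      to_s = numeric(0), next_ic_s = numeric(0))
  if (n < 1L) return(empty)
  out <- data.frame(cycle_index = seq_len(n), ic_s = ic[seq_len(n)],
                    to_s = to[seq_len(n)], next_ic_s = ic[seq_len(n) + 1L])
  if (trim_boundary) {
    if (n < 3L) {
      warning("segment_cycles: fewer than 3 cycles; none usable after ",
              "boundary trimming")
      return(empty)
    }
    out <- out[-c(1L, n), , drop = FALSE]
  }
  out
}

# Total overlap (seconds) of [a, b) with a set of [start, end) intervals.
interval_overlap <- function(a, b, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  sum(pmax(0, pmin(b, intervals[, 2]) - pmax(a, intervals[, 1])))
}

#' Phase durations of segmented cycles
#'
#' For each cycle `(IC, TO, IC')`: stance is `TO - IC`, swing `IC' - TO`;
#' double support is the time within `[IC, TO)` during which the
#' contralateral foot is also in stance (two sub-periods in normal gait,
#' summed); single support is `stance - double`. Cycles whose span is not
#' covered by the contralateral sequence are flagged and excluded.
#'
#' @param cycles_ipsi data frame from [segment_cycles()].
#' @param seq_contra the contralateral [gait_event_sequence()].
#' @return data frame with `cycle_index`, `ic_s`, `to_s`, `next_ic_s`,
#'   `stance_ms`, `swing_ms`, `single_stance_ms`, `double_stance_ms`,
#'   `cycle_ms`; its `n_flagged` attribute counts excluded cycles.
#' @export
compute_phase_durations <- function(cycles_ipsi, seq_contra) {
  contra <- stance_intervals(seq_contra)
  covered_from <- if (nrow(seq_contra)) min(seq_contra$time_s) else Inf
  covered_to <- if (nrow(seq_contra)) max(seq_contra$time_s) else -Inf
  rows <- lapply(seq_len(nrow(cycles_ipsi)), function(i) {
    cy <- cycles_ipsi[i, ]
    if (cy$ic_s < covered_from || cy$to_s > covered_to) return(NULL)
    stance <- cy$to_s - cy$ic_s
    dbl <- interval_overlap(cy$ic_s, cy$to_s, contra)
    data.frame(cycle_index = cy$cycle_index, ic_s = cy$ic_s, to_s = cy$to_s,
               next_ic_s = cy$next_ic_s,
               stance_ms = 1000 * stance,
               swing_ms = 1000 * (cy$next_ic_s - cy$to_s),
               single_stance_ms = 1000 * (stance - dbl),
               double_stance_ms = 1000 * dbl,
               cycle_ms = 1000 * (cy$next_ic_s - cy$ic_s))
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(cycle_index = integer(0), ic_s = numeric(0),
               to_s = numeric(0), next_ic_s = numeric(0),
               stance_ms = numeric(0), swing_ms = numeric(0),
               single_stance_ms = numeric(0), double_stance_ms = numeric(0),
               cycle_ms = numeric(0))
  attr(out, "n_flagged") <- sum(!keep)
  out
}

#' Mean vertical force during single stance
#'
#' Arithmetic mean of the smoothed summed cell pressure over the samples
#' falling inside the cycle's single-stance interval(s) — the parts of
#' `[IC, TO)` during which the contralateral foot is airborne — divided by
#' `force_scale` to land on the kg/cm^2 reporting scale.
#'
#' @param recording the ipsilateral [insole_recording()].
#' @param cycle one row of [compute_phase_durations()] output (or any list
#'   with `ic_s`, `to_s`).
#' @param contra_seq the contralateral [gait_event_sequence()].
#' @param force_scale divisor applied to the summed pressure (default 1).
#' @param smoothed optional pre-smoothed pressure sum; computed when
#'   `NULL`.
#' @param thresholds smoothing settings when `smoothed` is `NULL`.
#' @return mean force in kg/cm^2, or `NA` (with a warning) when the cycle
#'   has no single-stance sample.
#' @export
mean_force_single_stance <- function(recording, cycle, contra_seq,
                                     force_scale = 1, smoothed = NULL,
                                     thresholds = detection_thresholds()) {
  if (is.null(smoothed))
    smoothed <- smooth_series(rowSums(recording$cell_pressures), thresholds)
  ts <- frame_times(recording)
  contra <- stance_intervals(contra_seq)
  idx <- which(ts >= cycle$ic_s & ts < cycle$to_s)
  if (length(idx)) {
    in_contra <- rep(FALSE, length(idx))
    if (nrow(contra))
      for (r in seq_len(nrow(contra)))
        in_contra <- in_contra | (ts[idx] >= contra[r, 1] &
                                    ts[idx] < contra[r, 2])
    idx <- idx[!in_contra]
  }
  if (!length(idx)) {
    warning("mean_force_single_stance: cycle at ", round(cycle$ic_s, 3),
            " s has no single-stance sample; flagged")
    return(NA_real_)
  }
  mean(smoothed[idx]) / force_scale
}

#' Stance-normalized force curve
#'
#' Linear interpolation of the summed pressure onto `n_points` evenly
#' spaced fractions of the stance phase `[IC, TO]`. The curve is
#' normalized over stance rather than the whole cycle because the signal
#' is identically near zero in swing.
#'
#' @param recording an [insole_recording()].
#' @param cycle row with `ic_s` and `to_s`.
#' @param n_points grid size (default 101).
#' @param smoothed optional pre-smoothed pressure sum.
#' @param thresholds smoothing settings when `smoothed` is `NULL`.
#' @return numeric vector of length `n_points` (class
#'   `normalized_force_curve`), or `NULL` with a warning for a degenerate
#'   stance (< 2 samples).
#' @export
normalize_force_curve <- function(recording, cycle, n_points = 101L,
                                  smoothed = NULL,
                                  thresholds = detection_thresholds()) {
  if (is.null(smoothed))
    smoothed <- smooth_series(rowSums(recording$cell_pressures), thresholds)
  ts <- frame_times(recording)
  idx <- which(ts >= cycle$ic_s & ts <= cycle$to_s)
  if (length(idx) < 2L) {
    warning("normalize_force_curve: degenerate stance at ",
            round(cycle$ic_s, 3), " s; flagged")
    return(NULL)
  }
  grid <- cycle$ic_s + (cycle$to_s - cycle$ic_s) *
    seq(0, 1, length.out = n_points)
  vals <- stats::approx(ts[idx], smoothed[idx], xout = grid, rule = 2)$y
  structure(pmax(vals, 0), class = "normalized_force_curve")
}

#' Per-cycle gait parameters for one foot
#'
#' Runs cycle segmentation, phase durations, mean force during single
#' stance and the stance-normalized force curve over one foot of a trial.
#'
#' @param recording the ipsilateral [insole_recording()].
#' @param seq_ipsi its [gait_event_sequence()].
#' @param seq_contra the contralateral [gait_event_sequence()].
#' @param thresholds a [detection_thresholds()] (smoothing settings).
#' @param force_scale see [mean_force_single_stance()].
#' @param n_points force-curve grid size.
#' @param trim_boundary see [segment_cycles()].
#' @return list with `params` (data frame, one row per usable cycle, with a
#'   `foot` column and the [gait_parameter_names()] columns) and `curves`
#'   (cycles x `n_points` matrix).
#' @export
extract_cycle_parameters <- function(recording, seq_ipsi, seq_contra,
                                     thresholds = detection_thresholds(),
                                     force_scale = 1, n_points = 101L,
                                     trim_boundary = TRUE) {
  smoothed <- smooth_series(rowSums(recording$cell_pressures), thresholds)
  cycles <- segment_cycles(seq_ipsi, trim_boundary = trim_boundary)
  dur <- compute_phase_durations(cycles, seq_contra)
  if (!nrow(dur))
    return(list(params = cbind(foot = character(0), dur,
                               mean_force = numeric(0)),
                curves = matrix(numeric(0), 0, n_points)))
  mf <- vapply(seq_len(nrow(dur)), function(i)
    mean_force_single_stance(recording, dur[i, ], seq_contra,
                             force_scale = force_scale,
                             smoothed = smoothed), 0)
  curves <- t(vapply(seq_len(nrow(dur)), function(i)
    as.numeric(normalize_force_curve(recording, dur[i, ],
                                     n_points = n_points,
                                     smoothed = smoothed)),
    numeric(n_points)))
  ok <- !is.na(mf)
  if (any(!ok))
    warning("extract_cycle_parameters: ", sum(!ok),
            " cycle(s) without single stance excluded")
  params <- data.frame(foot = recording$foot_side,
                       dur[ok, , drop = FALSE],
                       mean_force = mf[ok], row.names = NULL)
  list(params = params, curves = curves[ok, , drop = FALSE])
}
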