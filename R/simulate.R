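#' Walking-condition presets
#'
#' The eight 6-minute-walk-test (TDM6) conditions: one overground walk, one
#' symmetric dual-belt treadmill walk at 1.2 m/s, and six treadmill walks
#' with induced asymmetry obtained by speeding up one belt by 16/33/50%
#' (1.4, 1.6, 1.8 m/s) while the other stays at 1.2 m/s.
#'
#' @return data frame with columns `condition_name`, `belt_speed_right_mps`,
#'   `belt_speed_left_mps`, `asymmetric`, `driven_side`, `overground`.
#' @export
condition_presets <- function() {
  data.frame(
    condition_name = c("TDM6-SYM-GROUND", "TDM6-SYM-MGAIT",
                       "TDM6-ASYM-MGAIT-16L", "TDM6-ASYM-MGAIT-33L",
                       "TDM6-ASYM-MGAIT-50L", "TDM6-ASYM-MGAIT-16R",
                       "TDM6-ASYM-MGAIT-33R", "TDM6-ASYM-MGAIT-50R"),
    belt_speed_right_mps = c(NA, 1.2, 1.2, 1.2, 1.2, 1.4, 1.6, 1.8),
    belt_speed_left_mps  = c(NA, 1.2, 1.4, 1.6, 1.8, 1.2, 1.2, 1.2),
    asymmetric = c(FALSE, FALSE, rep(TRUE, 6)),
    driven_side = c(NA, NA, "left", "left", "left",
                    "right", "right", "right"),
    overground = c(TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a healthy
#' adult walking 6-minute tests, three trials per condition, insole sampled
#' at 110 Hz with 18 capacitive cells and 8-bit digitization. The walking
#' model is a steady-state alternating gait: both feet share one cycle
#' duration, the foot on the faster belt shortens its stance fraction, and
#' double support (which in steady gait equals
#' `stance_left + stance_right - cycle`) shrinks for both feet as a result.
#'
#' @param condition_name a label from [condition_presets()], or any custom
#'   name when belt speeds are supplied explicitly.
#' @param belt_speed_left_mps,belt_speed_right_mps belt speeds in m/s;
#'   defaults come from the preset (the overground condition is modelled as
#'   symmetric 1.2 m/s walking with inflated variance components).
#' @param n_trials trials per condition (protocol value 3).
#' @param trial_duration_s trial length in seconds (protocol value 360; the
#'   test-suite uses shorter trials).
#' @param cycle_duration_s mean gait-cycle duration at the 1.2 m/s
#'   reference speed.
#' @param stance_fraction mean stance fraction of the cycle at reference
#'   speed (0.64 gives the conventional ~730/1145 ms split).
#' @param interfoot_phase contralateral initial-contact offset as a
#'   fraction of the cycle (0.5 = alternating gait).
#' @param peak_pressure_kg_cm2 peak of the summed-cell pressure during
#'   stance; with the default double-bump profile the mean force during
#'   single stance lands near 8.5 kg/cm^2.
#' @param asym_stance_gain fractional stance-fraction reduction of the
#'   driven (faster-belt) foot per unit of belt-speed ratio above 1.
#' @param nondriven_stance_gain same for the non-driven foot (small).
#' @param cadence_speed_exp exponent coupling cycle duration to mean belt
#'   speed, `T = cycle_duration_s * (1.2 / v_mean)^exp`.
#' @param within_trial_sd named list of step-to-step standard deviations:
#'   `cycle_s`, `stance_s`, `phase_s` (interfoot offset jitter) in seconds
#'   and `force` (kg/cm^2, on the summed-pressure peak).
#' @param between_trial_sd named list of trial-to-trial standard deviations
#'   with the same names.
#' @param overground_sd_factor multiplier applied to the within-trial sds
#'   and cell noise for the overground condition (unpaced overground
#'   walking is markedly noisier step to step than treadmill walking).
#' @param overground_between_factor multiplier applied to the
#'   between-trial sds for the overground condition; trial means drift
#'   much less than individual steps, so this factor is far smaller than
#'   `overground_sd_factor`.
#' @param cell_noise_sd per-cell, per-frame pressure noise sd (kg/cm^2).
#' @param quantize_8bit attach 8-bit raw counts (`TRUE`, the device
#'   behaviour) computed as `round(pressure * counts_per_unit)`.
#' @param counts_per_unit raw counts per kg/cm^2 per cell (25 puts the
#'   8-bit full scale at 10.2 kg/cm^2).
#' @param seed integer RNG seed for the whole condition; per-trial
#'   substreams are derived deterministically from it.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(condition_name = "TDM6-SYM-MGAIT",
                              belt_speed_left_mps = NULL,
                              belt_speed_right_mps = NULL,
                              n_trials = 3L,
                              trial_duration_s = 360,
                              cycle_duration_s = 1.145,
                              stance_fraction = 0.64,
                              interfoot_phase = 0.5,
                              peak_pressure_kg_cm2 = 10.5,
                              asym_stance_gain = 0.33,
                              nondriven_stance_gain = 0.04,
                              cadence_speed_exp = 0.3,
                              within_trial_sd = list(cycle_s = 0.008,
                                                     stance_s = 0.005,
                                                     phase_s = 0.003,
                                                     force = 0.08),
                              between_trial_sd = list(cycle_s = 0.010,
                                                      stance_s = 0.010,
                                                      phase_s = 0.002,
                                                      force = 0.03),
                              overground_sd_factor = 8,
                              overground_between_factor = 1.7,
                              cell_noise_sd = 0.004,
                              quantize_8bit = TRUE,
                              counts_per_unit = 25,
                              seed = 1L) {
  presets <- condition_presets()
  row <- presets[presets$condition_name == condition_name, ]
  overground <- nrow(row) == 1L && isTRUE(row$overground)
  if (is.null(belt_speed_left_mps))
    belt_speed_left_mps <- if (nrow(row) == 1L && !overground)
      row$belt_speed_left_mps else 1.2
  if (is.null(belt_speed_right_mps))
    belt_speed_right_mps <- if (nrow(row) == 1L && !overground)
      row$belt_speed_right_mps else 1.2
  if (belt_speed_left_mps <= 0 || belt_speed_right_mps <= 0)
    stop("simulation_config: belt speeds must be positive", call. = FALSE)
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("simulation_config: stance_fraction must be in (0, 1)",
         call. = FALSE)
  if (interfoot_phase <= 0 || interfoot_phase >= 1)
    stop("simulation_config: interfoot_phase must be in (0, 1)",
         call. = FALSE)
  if (n_trials < 2L)
    stop("simulation_config: n_trials must be >= 2", call. = FALSE)
  sd_ok <- function(l) all(vapply(l, function(v) is.finite(v) && v >= 0,
                                  TRUE))
  if (!sd_ok(within_trial_sd) || !sd_ok(between_trial_sd) ||
      cell_noise_sd < 0)
    stop("simulation_config: standard deviations must be >= 0",
         call. = FALSE)
  fac <- if (overground) overground_sd_factor else 1
  fac_bt <- if (overground) overground_between_factor else 1
  cfg <- list(condition_name = condition_name,
              belt_speed_left_mps = belt_speed_left_mps,
              belt_speed_right_mps = belt_speed_right_mps,
              overground = overground,
              n_trials = as.integer(n_trials),
              trial_duration_s = trial_duration_s,
              cycle_duration_s = cycle_duration_s,
              stance_fraction = stance_fraction,
              interfoot_phase = interfoot_phase,
              peak_pressure_kg_cm2 = peak_pressure_kg_cm2,
              asym_stance_gain = asym_stance_gain,
              nondriven_stance_gain = nondriven_stance_gain,
              cadence_speed_exp = cadence_speed_exp,
              within_trial_sd = lapply(within_trial_sd, `*`, fac),
              between_trial_sd = lapply(between_trial_sd, `*`, fac_bt),
              cell_noise_sd = cell_noise_sd * fac,
              quantize_8bit = isTRUE(quantize_8bit),
              counts_per_unit = counts_per_unit,
              sample_rate_hz = 110,
              seed = as.integer(seed))
  geo <- gait_geometry(cfg)
  # stance must stay inside its cycle; stance and cycle noises are
  # independent, so a 4-sigma root-sum-of-squares margin is required
  slack <- 4 * sqrt(cfg$within_trial_sd$stance_s^2 +
                      cfg$between_trial_sd$stance_s^2 +
                      cfg$within_trial_sd$cycle_s^2 +
                      cfg$between_trial_sd$cycle_s^2)
  if (max(geo$stance_left_s, geo$stance_right_s) + slack >= geo$cycle_s)
    stop("simulation_config: infeasible geometry - stance plus noise ",
         "would overlap consecutive cycles of the same foot", call. = FALSE)
  if (geo$stance_left_s + geo$stance_right_s <= geo$cycle_s)
    stop("simulation_config: infeasible geometry - no double support ",
         "(stance fractions too small for alternating gait)", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# Mean gait geometry implied by a config: common cycle duration and
# per-foot stance durations, with the driven foot shortened.
gait_geometry <- function(cfg) {
  v_mean <- mean(c(cfg$belt_speed_left_mps, cfg$belt_speed_right_mps))
  cycle_s <- cfg$cycle_duration_s * (1.2 / v_mean)^cfg$cadence_speed_exp
  rho <- max(cfg$belt_speed_left_mps, cfg$belt_speed_right_mps) /
    min(cfg$belt_speed_left_mps, cfg$belt_speed_right_mps)
  f_driven <- cfg$stance_fraction * (1 - cfg$asym_stance_gain * (rho - 1))
  f_nondrv <- cfg$stance_fraction *
    (1 - cfg$nondriven_stance_gain * (rho - 1))
  if (cfg$belt_speed_left_mps > cfg$belt_speed_right_mps) {
    f_left <- f_driven; f_right <- f_nondrv; driven <- "left"
  } else if (cfg$belt_speed_right_mps > cfg$belt_speed_left_mps) {
    f_left <- f_nondrv; f_right <- f_driven; driven <- "right"
  } else {
    f_left <- f_right <- cfg$stance_fraction; driven <- NA_character_
  }
  list(cycle_s = cycle_s,
       stance_left_s = f_left * cycle_s,
       stance_right_s = f_right * cycle_s,
       driven_side = driven)
}

# Normalized double-bump stance loading profile on u in [0, 1): two
# Gaussian lobes (heel strike ~28%, push-off ~72% of stance) over a base
# plateau, times a loading/unloading ramp with a small contact floor (the
# foot loads its heel essentially instantaneously at contact), scaled so
# max = 1. Values outside [0, 1) are 0.
stance_shape <- function(u, ramp = 0.045, floor = 0.12, lobe1 = 0.28,
                         lobe2 = 0.72, lobe_sd = 0.11, plateau = 0.55) {
  f <- function(v) {
    env <- pmax(pmin(v / ramp, (1 - v) / ramp, 1), floor)
    bumps <- exp(-0.5 * ((v - lobe1) / lobe_sd)^2) +
      exp(-0.5 * ((v - lobe2) / lobe_sd)^2) + plateau
    ifelse(v >= 0 & v < 1, env * bumps, 0)
  }
  f(u) / max(f(seq(0, 0.999, length.out = 1001)))
}

# Region envelopes distributing the summed profile over 18 cells:
# 6 heel cells load early, 6 midfoot cells mid-stance, 6 forefoot late.
cell_weights <- function(u) {
  g <- cbind(heel = exp(-0.5 * ((u - 0.22) / 0.20)^2),
             mid  = exp(-0.5 * ((u - 0.50) / 0.24)^2),
             fore = exp(-0.5 * ((u - 0.78) / 0.20)^2))
  w <- g[, rep(1:3, each = 6), drop = FALSE] + 0.02
  w / rowSums(w)
}

#' Simulate one walking condition
#'
#' Generates `n_trials` dual-foot insole recordings plus ground truth. Per
#' trial, trial-level effects are drawn for cycle duration, stance duration
#' and force amplitude (between-trial variance); per cycle, step-to-step
#' noise is added (within-trial variance). Event times define each foot's
#' stance intervals; every stance is rendered as a double-bump summed
#' pressure profile distributed across the 18 cells with a heel-to-forefoot
#' activation progression, sampled at 110 Hz, with optional 8-bit raw
#' counts. Swing frames are zero plus cell noise.
#'
#' @param config a [simulation_config()].
#' @return list of trials; each trial is a list with `left` and `right`
#'   [insole_recording()]s and `truth`, itself a list with `events`
#'   (data frame `foot, kind, time_s`), `cycles` (per-foot true cycle
#'   parameters on the same scale as [extract_cycle_parameters()]) and
#'   `trial_effects`.
#' @export
simulate_condition <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lapply(seq_len(config$n_trials), function(j)
    simulate_trial(config, trial = j))
}

#' Simulate a single trial of a condition
#' @param config a [simulation_config()].
#' @param trial trial number (drives the deterministic RNG substream).
#' @return one trial element as described in [simulate_condition()].
#' @export
simulate_trial <- function(config, trial = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  # deterministic substream: whole-session reproducibility with distinct
  # noise per trial
  set.seed((config$seed %% 100000L) * 13L + 7919L * as.integer(trial))
  geo <- gait_geometry(config)
  wt <- config$within_trial_sd; bt <- config$between_trial_sd
  eff <- list(cycle_s = stats::rnorm(1, 0, bt$cycle_s),
              stance_left_s = stats::rnorm(1, 0, bt$stance_s),
              stance_right_s = stats::rnorm(1, 0, bt$stance_s),
              phase_s = stats::rnorm(1, 0, bt$phase_s),
              force = stats::rnorm(1, 0, bt$force))

  n_cycles <- floor((config$trial_duration_s - 1) / geo$cycle_s)
  if (n_cycles < 3L)
    stop("simulate_trial: trial too short for 3 gait cycles", call. = FALSE)
  cyc <- pmax(geo$cycle_s + eff$cycle_s +
                stats::rnorm(n_cycles, 0, wt$cycle_s), 0.3)
  ic_left <- 0.5 + cumsum(c(0, cyc[-n_cycles]))
  stance_l <- pmax(geo$stance_left_s + eff$stance_left_s +
                     stats::rnorm(n_cycles, 0, wt$stance_s), 0.1)
  ic_right <- ic_left + config$interfoot_phase * cyc + eff$phase_s +
    stats::rnorm(n_cycles, 0, wt$phase_s)
  stance_r <- pmax(geo$stance_right_s + eff$stance_right_s +
                     stats::rnorm(n_cycles, 0, wt$stance_s), 0.1)
  amp_l <- pmax(config$peak_pressure_kg_cm2 + eff$force +
                  stats::rnorm(n_cycles, 0, wt$force), 0.5)
  amp_r <- pmax(config$peak_pressure_kg_cm2 + eff$force +
                  stats::rnorm(n_cycles, 0, wt$force), 0.5)

  left <- render_foot(ic_left, stance_l, amp_l, config, "left")
  right <- render_foot(ic_right, stance_r, amp_r, config, "right")

  truth_events <- rbind(
    data.frame(foot = "left",
               kind = rep(c("initial_contact", "toe_off"), n_cycles),
               time_s = as.vector(rbind(ic_left, ic_left + stance_l))),
    data.frame(foot = "right",
               kind = rep(c("initial_contact", "toe_off"), n_cycles),
               time_s = as.vector(rbind(ic_right, ic_right + stance_r))))

  cyc_l <- truth_cycles(ic_left, stance_l, ic_right, stance_r,
                        left, config, "left")
  cyc_r <- truth_cycles(ic_right, stance_r, ic_left, stance_l,
                        right, config, "right")
  list(left = left, right = right,
       truth = list(events = truth_events,
                    cycles = rbind(cyc_l, cyc_r),
                    trial_effects = eff))
}

# Render one foot's pressure frames from its stance intervals.
render_foot <- function(ic, stance, amp, config, side) {
  fs <- config$sample_rate_hz
  n <- floor(config$trial_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  press <- matrix(0, n, N_CELLS)
  for (k in seq_along(ic)) {
    i0 <- max(1L, ceiling(ic[k] * fs) + 1L)
    i1 <- min(n, floor((ic[k] + stance[k]) * fs) + 1L)
    if (i1 < i0) next
    u <- (t[i0:i1] - ic[k]) / stance[k]
    s <- amp[k] * stance_shape(u)
    press[i0:i1, ] <- s * cell_weights(u)
  }
  if (config$cell_noise_sd > 0)
    press <- pmax(press + stats::rnorm(length(press), 0,
                                       config$cell_noise_sd), 0)
  raw <- NULL
  if (config$quantize_8bit)
    raw <- matrix(pmin(pmax(round(press * config$counts_per_unit), 0L),
                       RAW_MAX), nrow(press), ncol(press))
  insole_recording(press, sample_rate_hz = fs, foot_side = side,
                   raw_counts = raw, start_time_s = 0)
}

# True per-cycle parameters from the continuous event times; double support
# is the overlap of contralateral stance with the ipsilateral stance, so
# single + double = stance and stance + swing = cycle hold exactly.
truth_cycles <- function(ic, stance, ic_c, stance_c, recording, config,
                         side) {
  n <- length(ic) - 1L
  if (n < 1L) return(NULL)
  contra <- cbind(ic_c, ic_c + stance_c)
  S <- rowSums(recording$cell_pressures)
  fs <- config$sample_rate_hz
  out <- lapply(seq_len(n), function(k) {
    a <- ic[k]; b <- a + stance[k]; a2 <- ic[k + 1L]
    dbl <- sum(pmax(0, pmin(b, contra[, 2]) - pmax(a, contra[, 1])))
    # single-stance samples: inside [a, b] but outside contralateral stance
    idx <- which((seq_along(S) - 1) / fs >= a & (seq_along(S) - 1) / fs < b)
    ts <- (idx - 1) / fs
    in_contra <- vapply(ts, function(x)
      any(x >= contra[, 1] & x < contra[, 2]), TRUE)
    mf <- if (any(!in_contra)) mean(S[idx[!in_contra]]) else NA_real_
    data.frame(foot = side, cycle_index = k,
               start_s = a,
               stance_ms = 1000 * (b - a),
               swing_ms = 1000 * (a2 - b),
               single_stance_ms = 1000 * (b - a - dbl),
               double_stance_ms = 1000 * dbl,
               cycle_ms = 1000 * (a2 - a),
               mean_force = mf)
  })
  do.call(rbind, out)
}

#' Simulate a two-way parameter table for reliability recovery tests
#'
#' Draws `y_ij = mu + s_i + e_ij` for `n_subjects` rows (e.g. gait-cycle
#' indices) and `k_trials` columns, the mixed-effects model underlying
#' ICC(3,k). The closed-form population ICC,
#' `sigma_s^2 / (sigma_s^2 + sigma_e^2 / k)`, is attached for recovery
#' testing.
#'
#' @param subject_sd between-row sd `sigma_s`.
#' @param error_sd residual sd `sigma_e`.
#' @param n_subjects number of rows (>= 2).
#' @param k_trials number of columns (>= 2).
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return matrix `n_subjects x k_trials` with attributes
#'   `population_icc_3k`, `subject_sd`, `error_sd`.
#' @export
simulate_parameter_table <- function(subject_sd, error_sd, n_subjects,
                                     k_trials, mu = 0, seed = 1L) {
  if (subject_sd < 0 || error_sd < 0)
    stop("simulate_parameter_table: sds must be >= 0", call. = FALSE)
  if (n_subjects < 2L || k_trials < 2L)
    stop("simulate_parameter_table: need >= 2 subjects and >= 2 trials",
         call. = FALSE)
  set.seed(seed)
  s <- stats::rnorm(n_subjects, 0, subject_sd)
  y <- mu + matrix(s, n_subjects, k_trials) +
    matrix(stats::rnorm(n_subjects * k_trials, 0, error_sd),
           n_subjects, k_trials)
  icc <- if (subject_sd == 0 && error_sd == 0) NA_real_
  else subject_sd^2 / (subject_sd^2 + error_sd^2 / k_trials)
  structure(y, population_icc_3k = icc, subject_sd = subject_sd,
            error_sd = error_sd)
}
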