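seq_from <- function(foot, kinds, times) {
  gait_event_sequence(foot, kinds, times, round(times * FS))
}

test_that("cycles are ipsilateral IC-TO-IC triples with boundary trimming", {
  s <- seq_from("left",
                c("initial_contact", "toe_off", "initial_contact",
                  "toe_off", "initial_contact"),
                c(0, 0.6, 1.0, 1.6, 2.0))
  all_cycles <- segment_cycles(s, trim_boundary = FALSE)
  expect_equal(nrow(all_cycles), 2L)
  expect_equal(all_cycles$ic_s, c(0, 1.0))
  expect_equal(all_cycles$to_s, c(0.6, 1.6))
  expect_equal(all_cycles$next_ic_s, c(1.0, 2.0))
  # trailing open cycle dropped
  s2 <- seq_from("left", c("initial_contact", "toe_off",
                           "initial_contact"), c(0, 0.6, 1.0))
  expect_equal(nrow(segment_cycles(s2, trim_boundary = FALSE)), 1L)
  # empty sequence
  e <- suppressWarnings(
    build_event_sequence(integer(0), integer(0),
                         insole_recording(matrix(0, 20, 18),
                                          foot_side = "left")))
  expect_equal(nrow(segment_cycles(e, trim_boundary = FALSE)), 0L)
  expect_warning(out <- segment_cycles(s2), "fewer than 3")
  expect_equal(nrow(out), 0L)
})

test_that("phase durations follow the interval-intersection definition", {
  # ipsi stance [0, 730] ms, next IC at 1000; contra stances
  # [-500, 160] and [415, 890] ms
  ipsi <- seq_from("left", c("initial_contact", "toe_off",
                             "initial_contact", "toe_off"),
                   c(0, 0.730, 1.0, 1.73))
  contra <- seq_from("right",
                     c("initial_contact", "toe_off", "initial_contact",
                       "toe_off"),
                     c(-0.5, 0.160, 0.415, 0.890))
  cyc <- segment_cycles(ipsi, trim_boundary = FALSE)[1, ]
  d <- compute_phase_durations(cyc, contra)
  expect_equal(d$stance_ms, 730)
  expect_equal(d$double_stance_ms, 160 + 315)   # two sub-periods summed
  expect_equal(d$single_stance_ms, 730 - 475)
  expect_equal(d$swing_ms, 270)
  expect_equal(d$cycle_ms, 1000)

  # contralateral airborne throughout the stance: all support is single
  far <- seq_from("right", c("initial_contact", "toe_off"), c(-3, -2.5))
  d2 <- compute_phase_durations(cyc, far)
  expect_equal(nrow(d2), 0L)  # stance not covered by contralateral data
  far2 <- seq_from("right",
                   c("initial_contact", "toe_off", "initial_contact",
                     "toe_off"), c(-3, -2.5, 2.0, 2.6))
  d3 <- compute_phase_durations(cyc, far2)
  expect_equal(d3$double_stance_ms, 0)
  expect_equal(d3$single_stance_ms, d3$stance_ms)
})

test_that("zero-noise symmetric pipelines give equal feet up to grid quantization", {
  # truth is exactly symmetric; detected events snap to the 110 Hz grid,
  # whose phase differs between the feet, so parameters agree to within
  # one sample per event endpoint
  tr <- simulate_trial(zero_noise_config(duration = 30), 1)
  sl <- detect_events(tr$left); sr <- detect_events(tr$right)
  pl <- extract_cycle_parameters(tr$left, sl, sr)$params
  pr <- extract_cycle_parameters(tr$right, sr, sl)$params
  n <- min(nrow(pl), nrow(pr))
  for (v in c("stance_ms", "swing_ms", "single_stance_ms",
              "double_stance_ms")) {
    expect_lt(max(abs(pl[[v]][1:n] - pr[[v]][1:n])), 2000 / FS + 1e-9)
    expect_lt(abs(mean(pl[[v]][1:n]) - mean(pr[[v]][1:n])), 1000 / FS)
  }
})

test_that("mean force during single stance is the arithmetic sample mean", {
  # constant summed pressure over a hand-built recording
  press <- matrix(0.5, 400, 18)        # summed signal = 9 everywhere
  r <- insole_recording(press, foot_side = "left")
  cyc <- data.frame(ic_s = 1.0, to_s = 1.7)
  contra <- seq_from("right",
                     c("initial_contact", "toe_off", "initial_contact",
                       "toe_off"), c(0.2, 0.9, 1.8, 2.5))
  expect_equal(mean_force_single_stance(r, cyc, contra), 9,
               tolerance = 1e-9)
  # force_scale divides onto the reporting scale
  expect_equal(mean_force_single_stance(r, cyc, contra, force_scale = 2),
               4.5, tolerance = 1e-9)
  # empty single-stance interval is flagged, not fabricated
  wall <- seq_from("right", c("initial_contact", "toe_off"), c(0.0, 3.0))
  expect_warning(v <- mean_force_single_stance(r, cyc, wall),
                 "no single-stance sample")
  expect_true(is.na(v))
})

test_that("simulated mean force matches its ground truth", {
  tr <- simulate_trial(zero_noise_config(duration = 30), 1)
  sl <- detect_events(tr$left); sr <- detect_events(tr$right)
  p <- extract_cycle_parameters(tr$left, sl, sr)$params
  truth <- tr$truth$cycles
  truth <- truth[truth$foot == "left", ]
  m <- merge(p, truth, by = "cycle_index", suffixes = c("", ".t"))
  expect_gt(nrow(m), 20)
  expect_lt(mean(abs(m$mean_force - m$mean_force.t)), 0.15)
})

test_that("stance-normalized curves interpolate exactly and idempotently", {
  n <- 300
  ramp <- matrix(seq(0, 1, length.out = n) / 18, n, 18)
  r <- insole_recording(ramp, foot_side = "left")
  cyc <- data.frame(ic_s = 0.5, to_s = 2.0)
  # constant signal -> constant curve
  rc <- insole_recording(matrix(2 / 18, n, 18), foot_side = "left")
  expect_equal(as.numeric(normalize_force_curve(rc, cyc)), rep(2, 101),
               tolerance = 1e-9)
  # linear signal -> linear curve with matching interior values
  cv <- as.numeric(normalize_force_curve(r, cyc))
  expect_length(cv, 101)
  grid_t <- 0.5 + 1.5 * seq(0, 1, length.out = 101)
  expected <- approx((0:(n - 1)) / 110,
                     smooth_series(rowSums(ramp)), xout = grid_t)$y
  expect_equal(cv, pmax(expected, 0), tolerance = 1e-9)
  expect_true(all(diff(cv[5:95]) > 0))
  # degenerate stance flagged
  expect_warning(out <- normalize_force_curve(r, data.frame(ic_s = 0.5,
                                                            to_s = 0.5)),
                 "degenerate")
  expect_null(out)
})

test_that("noisy-simulation durations stay within two samples of truth", {
  tr <- noisy_trial_60s()
  sl <- detect_events(tr$left); sr <- detect_events(tr$right)
  p <- extract_cycle_parameters(tr$left, sl, sr)$params
  truth <- tr$truth$cycles[tr$truth$cycles$foot == "left", ]
  m <- merge(p, truth, by = "cycle_index", suffixes = c("", ".t"))
  expect_gt(nrow(m), 40)
  for (v in c("stance_ms", "swing_ms", "single_stance_ms",
              "double_stance_ms"))
    expect_lt(mean(abs(m[[v]] - m[[paste0(v, ".t")]])), 2000 / FS)
  # default-config sanity: stance is 55-70% of the cycle
  frac <- mean(p$stance_ms / p$cycle_ms)
  expect_gt(frac, 0.55); expect_lt(frac, 0.70)
})
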