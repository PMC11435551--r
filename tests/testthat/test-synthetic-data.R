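test_that("zero-noise symmetric simulation has equal feet and the configured phase offset", {
  cfg <- zero_noise_config(duration = 30)
  tr <- simulate_trial(cfg, 1)
  tc <- tr$truth$cycles
  L <- tc[tc$foot == "left", ]
  R <- tc[tc$foot == "right", ]
  n <- min(nrow(L), nrow(R))
  expect_equal(L$stance_ms[1:n], R$stance_ms[1:n], tolerance = 1e-9)
  expect_equal(L$cycle_ms[1:n], R$cycle_ms[1:n], tolerance = 1e-9)
  expect_lt(max(abs(L$cycle_ms - L$cycle_ms[1])), 1e-9)
  # interfoot initial-contact offset = interfoot_phase * cycle
  ev <- tr$truth$events
  ic_l <- ev$time_s[ev$foot == "left" & ev$kind == "initial_contact"]
  ic_r <- ev$time_s[ev$foot == "right" & ev$kind == "initial_contact"]
  expect_equal(ic_r[1:n] - ic_l[1:n],
               rep(0.5 * L$cycle_ms[1] / 1000, n), tolerance = 1e-9)
})

test_that("identical seeds reproduce recordings bit for bit; different seeds differ", {
  cfg <- simulation_config("TDM6-SYM-MGAIT", trial_duration_s = 20,
                           seed = 11)
  a <- simulate_trial(cfg, 1)
  b <- simulate_trial(cfg, 1)
  expect_identical(a$left$cell_pressures, b$left$cell_pressures)
  expect_identical(a$right$raw_counts, b$right$raw_counts)
  cfg2 <- simulation_config("TDM6-SYM-MGAIT", trial_duration_s = 20,
                            seed = 12)
  c <- simulate_trial(cfg2, 1)
  expect_false(identical(a$left$cell_pressures, c$left$cell_pressures))
  # trials of one session use distinct substreams
  expect_false(identical(a$left$cell_pressures,
                         simulate_trial(cfg, 2)$left$cell_pressures))
})

test_that("truth phase durations satisfy the gait identities exactly", {
  cfg <- simulation_config("TDM6-ASYM-MGAIT-33R", trial_duration_s = 40,
                           seed = 5)
  tc <- simulate_trial(cfg, 2)$truth$cycles
  expect_lt(max(abs(tc$single_stance_ms + tc$double_stance_ms -
                      tc$stance_ms)), 1e-9)
  expect_lt(max(abs(tc$stance_ms + tc$swing_ms - tc$cycle_ms)), 1e-9)
})

test_that("belt-speed asymmetry shortens the driven foot's stance in truth", {
  for (cond in c("TDM6-ASYM-MGAIT-50L", "TDM6-ASYM-MGAIT-50R")) {
    cfg <- zero_noise_config(cond, duration = 30, seed = 2)
    tc <- simulate_trial(cfg, 1)$truth$cycles
    driven <- if (grepl("L$", cond)) "left" else "right"
    other <- setdiff(c("left", "right"), driven)
    expect_lt(mean(tc$stance_ms[tc$foot == driven]),
              mean(tc$stance_ms[tc$foot == other]))
  }
})

test_that("within-trial variance of simulated durations matches the configured sd", {
  cfg <- simulation_config("TDM6-SYM-MGAIT", trial_duration_s = 360,
                           seed = 21)
  tc <- simulate_trial(cfg, 1)$truth$cycles
  st <- tc$stance_ms[tc$foot == "left"]
  expect_gt(length(st), 300)
  expect_equal(sd(st), 1000 * cfg$within_trial_sd$stance_s,
               tolerance = 0.15)
  cy <- tc$cycle_ms[tc$foot == "left"]
  expect_equal(sd(cy), 1000 * cfg$within_trial_sd$cycle_s,
               tolerance = 0.15)
})

test_that("infeasible geometry and invalid settings are rejected", {
  expect_error(simulation_config(stance_fraction = 1.2), "stance_fraction")
  expect_error(simulation_config(stance_fraction = 0.98),
               "infeasible geometry")
  expect_error(simulation_config(stance_fraction = 0.3),
               "no double support")
  expect_error(simulation_config(n_trials = 1), "n_trials")
  expect_error(simulation_config(belt_speed_left_mps = -1),
               "belt speeds")
  expect_error(
    simulation_config(within_trial_sd = list(cycle_s = -1, stance_s = 0,
                                             phase_s = 0, force = 0)),
    "standard deviations")
})

test_that("two-way parameter tables carry the closed-form population ICC", {
  expect_equal(attr(simulate_parameter_table(1, 0, 10, 3),
                    "population_icc_3k"), 1)
  expect_equal(attr(simulate_parameter_table(0, 1, 10, 3),
                    "population_icc_3k"), 0)
  # subject_sd = error_sd, k = 3: 1 / (1 + 1/3) = 0.75
  expect_equal(attr(simulate_parameter_table(2, 2, 10, 3),
                    "population_icc_3k"), 0.75)
  expect_error(simulate_parameter_table(-1, 1, 10, 3), "sds")
  expect_error(simulate_parameter_table(1, 1, 1, 3), ">= 2")
})

test_that("the condition table lists the eight protocol conditions", {
  p <- condition_presets()
  expect_equal(nrow(p), 8L)
  expect_equal(sum(p$asymmetric), 6L)
  expect_equal(p$belt_speed_left_mps[p$condition_name ==
                                       "TDM6-ASYM-MGAIT-50L"], 1.8)
  expect_equal(p$belt_speed_right_mps[p$condition_name ==
                                        "TDM6-ASYM-MGAIT-50L"], 1.2)
})
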