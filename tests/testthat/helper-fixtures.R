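# Shared fixtures: everything is generated in code at test time.

FS <- 110

zero_noise_sds <- function()
  list(cycle_s = 0, stance_s = 0, phase_s = 0, force = 0)

zero_noise_config <- function(condition = "TDM6-SYM-MGAIT",
                              duration = 60, seed = 7, ...) {
  simulation_config(condition, trial_duration_s = duration,
                    within_trial_sd = zero_noise_sds(),
                    between_trial_sd = zero_noise_sds(),
                    cell_noise_sd = 0, seed = seed, ...)
}

# A rectangular "stance" pulse series: amplitude amp on 0-based samples
# [on, off), zero elsewhere.
square_pulse <- function(n, on, off, amp = 100) {
  s <- numeric(n)
  s[(on + 1):off] <- amp
  s
}

# Independent ICC(3,k) oracle: two-way ANOVA mean squares via stats::aov.
icc_oracle_aov <- function(m) {
  df <- data.frame(y = as.vector(m),
                   row = factor(as.vector(row(m))),
                   col = factor(as.vector(col(m))))
  a <- anova(stats::aov(y ~ row + col, data = df))
  bms <- a["row", "Mean Sq"]
  ems <- a["Residuals", "Mean Sq"]
  (bms - ems) / bms
}

# Match each detected event to the nearest ground-truth event of the same
# kind; returns absolute errors in samples.
event_errors_samples <- function(seq, truth, foot, fs = FS) {
  tf <- truth[truth$foot == foot, ]
  unlist(lapply(c("initial_contact", "toe_off"), function(k) {
    det <- seq$time_s[seq$kind == k]
    tru <- tf$time_s[tf$kind == k]
    vapply(det, function(x) min(abs(tru - x)), 0) * fs
  }))
}

# Memoised medium-size runs shared across test files.
.cache <- new.env(parent = emptyenv())

full_run_60s <- function() {
  if (is.null(.cache$full_run))
    .cache$full_run <- run_pipeline(trial_duration_s = 60, seed = 3)
  .cache$full_run
}

noisy_trial_60s <- function() {
  if (is.null(.cache$noisy_trial)) {
    cfg <- simulation_config("TDM6-SYM-MGAIT", trial_duration_s = 60,
                             seed = 7)
    .cache$noisy_trial <- simulate_trial(cfg, 1)
  }
  .cache$noisy_trial
}
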