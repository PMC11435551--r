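#' Standard error of measurement from per-trial variances
#'
#' `SEM = sqrt( sum(sigma_i^2) / n )`: the square root of the mean of the
#' within-trial variances, one variance per repeated trial of a condition.
#' Within-trial variance is the sample variance (denominator `n_i - 1`)
#' across the gait cycles of that trial.
#'
#' @param trial_variances numeric vector of per-trial variances (>= 0), one
#'   per trial.
#' @return SEM in the parameter's units.
#' @export
sem <- function(trial_variances) {
  if (!length(trial_variances))
    stop("sem: at least one trial variance required", call. = FALSE)
  if (any(trial_variances < 0) || anyNA(trial_variances))
    stop("sem: variances must be non-negative", call. = FALSE)
  sqrt(mean(trial_variances))
}

#' SEM as a percentage of the parameter mean
#' @param sem_value SEM in parameter units.
#' @param mean_value parameter mean (non-zero).
#' @return `100 * sem / mean`.
#' @export
sem_percent <- function(sem_value, mean_value) {
  if (!is.finite(mean_value) || mean_value == 0)
    stop("sem_percent: undefined for zero mean", call. = FALSE)
  100 * sem_value / mean_value
}

#' Pointwise SEM of stance-normalized force curves, averaged
#'
#' The force signal is compared across trials at each instant of the
#' normalized cycle: at each of the grid points, the within-trial variance
#' across cycles feeds the SEM formula, and the pointwise SEMs are then
#' averaged over the grid.
#'
#' @param curve_sets list with one element per trial, each a cycles x grid
#'   matrix of [normalize_force_curve()] values (all trials on the same
#'   grid).
#' @return scalar SEM in force units.
#' @export
curve_sem <- function(curve_sets) {
  if (length(curve_sets) < 2L)
    stop("curve_sem: need at least 2 trials", call. = FALSE)
  g <- unique(vapply(curve_sets, ncol, 0L))
  if (length(g) != 1L)
    stop("curve_sem: trials use different grids", call. = FALSE)
  for (i in seq_along(curve_sets))
    if (nrow(curve_sets[[i]]) < 2L)
      stop("curve_sem: trial ", i, " has fewer than 2 cycles",
           call. = FALSE)
  # per-trial pointwise variance across cycles: trials x grid
  v <- t(vapply(curve_sets, function(m) apply(m, 2, stats::var),
                numeric(g)))
  mean(sqrt(colMeans(v)))
}

#' Minimum detectable difference at 95% confidence
#'
#' `MDD95 = 1.96 * sqrt(2) * SEM`: the smallest between-session change
#' distinguishable from test-retest noise at 95% confidence.
#'
#' @param sem_value SEM (>= 0).
#' @return MDD95 in the same units.
#' @export
mdd95 <- function(sem_value) {
  if (any(sem_value < 0)) stop("mdd95: SEM must be >= 0", call. = FALSE)
  1.96 * sqrt(2) * sem_value
}

#' Effect size of induced asymmetry
#'
#' `ES = (mean_asym - mean_without) / sd_without`: the signed standardized
#' mean difference between a walking condition with induced asymmetry and
#' a reference condition without, scaled by the reference condition's
#' standard deviation. No absolute value is taken; classification
#' ([classify_es()]) uses the magnitude.
#'
#' @param mean_asym parameter mean under induced asymmetry.
#' @param mean_without parameter mean without induced asymmetry.
#' @param sd_without standard deviation without induced asymmetry (> 0).
#' @return dimensionless signed effect size.
#' @export
effect_size <- function(mean_asym, mean_without, sd_without) {
  if (!is.finite(sd_without) || sd_without <= 0)
    stop("effect_size: sd_without must be positive", call. = FALSE)
  (mean_asym - mean_without) / sd_without
}

#' ICC(3,k): average-measures consistency intraclass correlation
#'
#' Two-way mixed-effects model: rows are the measured units (here, gait
#' cycles paired by index), columns the k repeated trials. From the two-way
#' ANOVA decomposition, `ICC(3,k) = (BMS - EMS) / BMS` with BMS the
#' between-rows mean square and EMS the residual mean square, the
#' Shrout-Fleiss average-measures consistency form.
#'
#' @param measurements numeric matrix, subjects x k trials. Rows containing
#'   missing values are dropped (listwise deletion) up to
#'   `max_missing_fraction`.
#' @param max_missing_fraction maximum tolerated fraction of dropped rows.
#' @return ICC(3,k) value (can be negative for inconsistent data; `NaN`
#'   when BMS = 0).
#' @export
icc_3k <- function(measurements, max_missing_fraction = 0.25) {
  m <- as.matrix(measurements)
  if (ncol(m) < 2L)
    stop("icc_3k: need at least 2 trials (columns)", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (mean(!complete) > max_missing_fraction)
    stop("icc_3k: ", sum(!complete), " of ", nrow(m),
         " rows have missing cells, above the tolerated fraction ",
         max_missing_fraction, call. = FALSE)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L)
    stop("icc_3k: need at least 2 complete subjects (rows)", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / bms
}

#' Classify an ICC value
#'
#' Bins: poor (< 0.40), moderate (0.40-0.60), good (0.60-0.80), very good
#' (> 0.80). Boundary values are assigned to the upper bin (0.60 is
#' "good", 0.80 is "very good").
#'
#' @param value finite ICC value (vectorized).
#' @return character vector of labels.
#' @export
classify_icc <- function(value) {
  stopifnot(all(is.finite(value)))
  cut(value, breaks = c(-Inf, 0.40, 0.60, 0.80, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "very good")) |>
    as.character()
}

#' Classify an effect size by magnitude
#'
#' Bins on `|ES|`: very small (< 0.2), small (0.2-0.5), moderate
#' (0.5-0.8), large (0.8-1.2), very large (> 1.2); boundaries go to the
#' upper bin.
#'
#' @param value finite signed effect size (vectorized).
#' @return character vector of labels.
#' @export
classify_es <- function(value) {
  stopifnot(all(is.finite(value)))
  cut(abs(value), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, Inf), right = FALSE,
      labels = c("very small", "small", "moderate", "large",
                 "very large")) |>
    as.character()
}

#' Construct a reliability report object
#'
#' Container for the four aggregated tables produced by
#' [aggregate_report()]; see that function for their contents.
#'
#' @param summary,mdd,effect_sizes,es_census data frames.
#' @return object of class `reliability_report`.
#' @export
reliability_report <- function(summary, mdd, effect_sizes, es_census) {
  stopifnot(is.data.frame(summary), is.data.frame(mdd),
            is.data.frame(effect_sizes), is.data.frame(es_census))
  if (nrow(summary) &&
      any(abs(summary$mdd95 - mdd95(summary$sem)) > 1e-9))
    stop("reliability_report: mdd95 must equal 1.96*sqrt(2)*sem in every ",
         "cell", call. = FALSE)
  structure(list(summary = summary, mdd = mdd,
                 effect_sizes = effect_sizes, es_census = es_census),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(paste0("<reliability_report> %d summary cells, %d MDD rows, ",
                     "%d effect sizes\n"),
              nrow(x$summary), nrow(x$mdd), nrow(x$effect_sizes)))
  invisible(x)
}

# Trial-level means/variances of one parameter for one foot of a condition.
trial_stats <- function(cond, foot, param) {
  vals <- lapply(cond$trials, function(t) t[[foot]][[param]])
  list(means = vapply(vals, mean, 0),
       vars = vapply(vals, stats::var, 0),
       n_cycles = vapply(vals, length, 0L))
}

# cycles x trials matrix paired by cycle index, truncated to the minimum
# common cycle count across the trials of the condition.
cycle_trial_matrix <- function(cond, foot, param) {
  vals <- lapply(cond$trials, function(t) t[[foot]][[param]])
  n <- min(vapply(vals, length, 0L))
  vapply(vals, function(v) v[seq_len(n)], numeric(n))
}

#' Aggregate condition datasets into a reliability report
#'
#' Implements the condition-level aggregation rules of the metrology
#' protocol:
#' * `summary` — per (parameter, foot, condition): mean and sd of the
#'   per-trial means, SEM (via [sem()]; for the force parameter via
#'   [curve_sem()] on the normalized curves when present), SEM%, MDD95,
#'   MDD95%, ICC(3,k) on the cycle-by-trial matrix, and its label.
#' * `mdd` — one row per parameter for each of the condition groups
#'   overground (O), treadmill symmetric (T) and treadmill asymmetric
#'   pooled (TA): the SEM used is the largest across feet, and for TA the
#'   largest across all asymmetric conditions; MDD95 derives from that
#'   SEM, with the percent taken over the group's grand mean.
#' * `effect_sizes` — per (parameter, foot, asymmetric condition) and pair
#'   O-TA / T-TA: signed [effect_size()] against the reference condition's
#'   per-foot mean and sd, with labels; force is excluded (its curves are
#'   individual-specific, so only the four spatio-temporal durations are
#'   compared).
#' * `es_census` — per pair, counts and percentages of cases per
#'   [classify_es()] bin over all parameter x condition x foot cases.
#'
#' @param datasets list of [condition_dataset()] objects (any subset of
#'   the preset conditions; missing reference conditions simply yield
#'   fewer report rows).
#' @return a [reliability_report()].
#' @export
aggregate_report <- function(datasets) {
  names(datasets) <- vapply(datasets, function(d) d$condition_name, "")
  presets <- condition_presets()
  params <- gait_parameter_names()
  feet <- c("left", "right")

  rows <- list()
  for (cond in datasets) for (foot in feet) for (param in params) {
    st <- trial_stats(cond, foot, param)
    use_curves <- param == "mean_force" &&
      !is.null(cond$trials[[1]][[paste0(foot, "_curves")]])
    s <- if (use_curves)
      curve_sem(lapply(cond$trials, `[[`, paste0(foot, "_curves")))
    else sem(st$vars)
    m <- mean(st$means)
    icc <- icc_3k(cycle_trial_matrix(cond, foot, param))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond$condition_name, foot = foot, parameter = param,
      mean = m, sd = stats::sd(st$means), sem = s,
      sem_percent = sem_percent(s, m),
      mdd95 = mdd95(s), mdd95_percent = sem_percent(mdd95(s), m),
      icc_3k = icc, icc_label = classify_icc(icc),
      n_cycles = sum(st$n_cycles))
  }
  summary <- do.call(rbind, rows)

  asym_names <- presets$condition_name[presets$asymmetric]
  groups <- list(O = intersect("TDM6-SYM-GROUND", names(datasets)),
                 T = intersect("TDM6-SYM-MGAIT", names(datasets)),
                 TA = intersect(asym_names, names(datasets)))
  mdd_rows <- list()
  for (g in names(groups)) {
    conds <- groups[[g]]
    if (!length(conds)) next
    for (param in params) {
      cells <- summary[summary$condition %in% conds &
                         summary$parameter == param, ]
      s_max <- max(cells$sem)              # largest SEM across feet
      m_ref <- mean(cells$mean)            # (and across pooled conditions)
      mdd_rows[[length(mdd_rows) + 1L]] <- data.frame(
        group = g, parameter = param, sem_used = s_max,
        mdd95 = mdd95(s_max),
        mdd95_percent = sem_percent(mdd95(s_max), m_ref))
    }
  }
  mdd <- if (length(mdd_rows)) do.call(rbind, mdd_rows) else
    data.frame(group = character(0), parameter = character(0),
               sem_used = numeric(0), mdd95 = numeric(0),
               mdd95_percent = numeric(0))

  es_params <- setdiff(params, "mean_force")
  refs <- c(O = "TDM6-SYM-GROUND", T = "TDM6-SYM-MGAIT")
  es_rows <- list()
  for (pair in names(refs)) {
    ref <- refs[[pair]]
    if (!ref %in% names(datasets)) next
    for (an in intersect(asym_names, names(datasets)))
      for (foot in feet) for (param in es_params) {
        st_ref <- trial_stats(datasets[[ref]], foot, param)
        st_asy <- trial_stats(datasets[[an]], foot, param)
        es <- effect_size(mean(st_asy$means), mean(st_ref$means),
                          stats::sd(st_ref$means))
        es_rows[[length(es_rows) + 1L]] <- data.frame(
          pair = paste0(pair, "-TA"), condition_asym = an, foot = foot,
          parameter = param, effect_size = es, es_label = classify_es(es))
      }
  }
  effect_sizes <- if (length(es_rows)) do.call(rbind, es_rows) else
    data.frame(pair = character(0), condition_asym = character(0),
               foot = character(0), parameter = character(0),
               effect_size = numeric(0), es_label = character(0))

  bins <- c("very small", "small", "moderate", "large", "very large")
  census_rows <- list()
  for (pair in unique(effect_sizes$pair)) {
    lab <- effect_sizes$es_label[effect_sizes$pair == pair]
    cnt <- table(factor(lab, levels = bins))
    census_rows[[length(census_rows) + 1L]] <- data.frame(
      pair = pair, bin = bins, n = as.integer(cnt),
      percent = 100 * as.integer(cnt) / length(lab))
  }
  es_census <- if (length(census_rows)) do.call(rbind, census_rows) else
    data.frame(pair = character(0), bin = character(0), n = integer(0),
               percent = numeric(0))

  reliability_report(summary, mdd, effect_sizes, es_census)
}
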