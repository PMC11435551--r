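#' Run the full synthetic metrology pipeline
#'
#' End-to-end orchestration: simulate the requested walking conditions
#' (3 trials each), detect gait events on every recording, extract
#' per-cycle parameters and normalized force curves, and aggregate the
#' reliability report. All randomness derives from `seed`; re-running with
#' an identical configuration reproduces the outputs bit for bit.
#'
#' @param conditions character vector of condition labels from
#'   [condition_presets()] (default: all eight). Unknown names are
#'   rejected.
#' @param seed integer master seed; each condition gets a deterministic
#'   sub-seed.
#' @param trial_duration_s trial length in seconds (protocol value 360).
#' @param n_trials trials per condition (protocol value 3).
#' @param thresholds a [detection_thresholds()].
#' @param sim_args named list of extra arguments passed to
#'   [simulation_config()] (noise levels etc.).
#' @param out_dir if not `NULL`, report CSVs, per-cycle parameter CSVs and
#'   a JSON run manifest are written there.
#' @param verbose emit one progress line per condition/trial.
#' @return list with `report` (a [reliability_report()]), `datasets`
#'   (named list of [condition_dataset()]), `diagnostics` (per-trial event
#'   and cycle counts) and `manifest`.
#' @export
run_pipeline <- function(conditions = condition_presets()$condition_name,
                         seed = 1L, trial_duration_s = 360, n_trials = 3L,
                         thresholds = detection_thresholds(),
                         sim_args = list(), out_dir = NULL,
                         verbose = FALSE) {
  presets <- condition_presets()
  unknown <- setdiff(conditions, presets$condition_name)
  if (length(unknown))
    stop("run_pipeline: unknown condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  datasets <- list()
  diagnostics <- list()
  for (ci in seq_along(conditions)) {
    cn <- conditions[ci]
    cond_seed <- (as.integer(seed) %% 1000000L) + 101L *
      match(cn, presets$condition_name)
    cfg <- do.call(simulation_config,
                   c(list(condition_name = cn, n_trials = n_trials,
                          trial_duration_s = trial_duration_s,
                          seed = cond_seed), sim_args))
    trials <- simulate_condition(cfg)
    built <- list()
    for (tj in seq_along(trials)) {
      tr <- trials[[tj]]
      seq_l <- detect_events(tr$left, thresholds)
      seq_r <- detect_events(tr$right, thresholds)
      ex_l <- extract_cycle_parameters(tr$left, seq_l, seq_r, thresholds)
      ex_r <- extract_cycle_parameters(tr$right, seq_r, seq_l, thresholds)
      if (!nrow(ex_l$params) || !nrow(ex_r$params))
        stop("run_pipeline: stage gait_parameters produced no cycles for ",
             cn, " trial ", tj, call. = FALSE)
      built[[tj]] <- list(left = ex_l$params, right = ex_r$params,
                          left_curves = ex_l$curves,
                          right_curves = ex_r$curves)
      dg <- data.frame(condition = cn, trial = tj,
                       frames = n_frames(tr$left),
                       events_left = nrow(seq_l), events_right = nrow(seq_r),
                       dropped_left = sum(unlist(attr(seq_l,
                                                      "diagnostics"))),
                       dropped_right = sum(unlist(attr(seq_r,
                                                       "diagnostics"))),
                       cycles_left = nrow(ex_l$params),
                       cycles_right = nrow(ex_r$params))
      diagnostics[[length(diagnostics) + 1L]] <- dg
      if (verbose)
        message(sprintf(
          "[%s trial %d] frames=%d events L/R=%d/%d cycles L/R=%d/%d",
          cn, tj, dg$frames, dg$events_left, dg$events_right,
          dg$cycles_left, dg$cycles_right))
    }
    datasets[[cn]] <- condition_dataset(cn, built, require_n = n_trials)
  }
  report <- aggregate_report(datasets)
  diagnostics <- do.call(rbind, diagnostics)
  manifest <- list(
    package = "insolemetry",
    version = as.character(utils::packageVersion("insolemetry")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    conditions = conditions,
    n_trials = as.integer(n_trials),
    trial_duration_s = trial_duration_s,
    thresholds = unclass(thresholds),
    sim_args = sim_args,
    cycles_total = sum(diagnostics$cycles_left + diagnostics$cycles_right))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "reliability"))
    for (cn in names(datasets)) for (tj in seq_len(n_trials)) {
      tr <- datasets[[cn]]$trials[[tj]]
      write_cycle_parameters(
        rbind(tr$left, tr$right),
        file.path(out_dir, sprintf("cycles_%s_trial%d.csv", cn, tj)))
    }
    utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(report = report, datasets = datasets, diagnostics = diagnostics,
       manifest = manifest)
}

#' Recompute the verifiable worked-example report cells
#'
#' The package ships, as plain-text fixtures, the internally-consistent
#' cells of a published repeatability table for this insole system: every
#' minimum-detectable-difference cell whose generating SEM is printed, and
#' every effect-size cell that is reproducible from its printed means and
#' standard deviation. This function recomputes each cell from its printed
#' inputs — `MDD95 = 1.96*sqrt(2)*SEM` and
#' `ES = (mean_asym - mean_without)/sd_without` — and checks agreement at
#' the printed precision.
#'
#' @return data frame with columns `check` (`"mdd95"`/`"effect_size"`),
#'   `parameter`, `group`, `expected` (printed value), `computed`,
#'   `tolerance` (half a unit in the last printed digit) and `match`.
#' @export
worked_examples <- function() {
  mdd_file <- system.file("extdata", "worked_examples_mdd.csv",
                          package = "insolemetry", mustWork = TRUE)
  es_file <- system.file("extdata", "worked_examples_es.csv",
                         package = "insolemetry", mustWork = TRUE)
  m <- utils::read.csv(mdd_file)
  e <- utils::read.csv(es_file)
  m_comp <- mdd95(m$sem)
  m_tol <- 0.5 * 10^(-m$printed_decimals) + 1e-9
  e_comp <- mapply(effect_size, e$mean_asym, e$mean_without, e$sd_without)
  e_tol <- 0.5 * 10^(-e$printed_decimals) + 1e-9
  rbind(
    data.frame(check = "mdd95", parameter = m$parameter, group = m$group,
               expected = m$mdd95_printed, computed = m_comp,
               tolerance = m_tol,
               match = abs(m_comp - m$mdd95_printed) <= m_tol),
    data.frame(check = "effect_size", parameter = e$parameter,
               group = e$pair, expected = e$es_printed, computed = e_comp,
               tolerance = e_tol,
               match = abs(e_comp - e$es_printed) <= e_tol))
}
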