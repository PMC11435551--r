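#' Read an insole recording from CSV
#'
#' The on-disk schema is one file per foot with a mandatory header row and
#' columns `time_s, cell_01..cell_18` (pressure in kg/cm^2), optionally
#' followed by `raw_01..raw_18` (8-bit counts). UTF-8, `.` decimal
#' separator. Timestamps must advance by exactly one sample period; the
#' sampling rate is inferred from the time column unless given.
#'
#' @param path CSV file path.
#' @param foot_side `"left"` or `"right"`; defaults to a `foot_side`
#'   comment-free filename guess being deliberately avoided — it must be
#'   supplied or stored in the `foot` column written by [write_recording()].
#' @param sample_rate_hz optional; if `NULL`, inferred from the median time
#'   step.
#' @return an [insole_recording()].
#' @export
read_recording <- function(path, foot_side = NULL, sample_rate_hz = NULL) {
  if (!file.exists(path))
    stop("read_recording: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  cell_cols <- sprintf("cell_%02d", 1:N_CELLS)
  if (!("time_s" %in% names(df)))
    stop("read_recording: schema error in ", path, ": missing column time_s",
         call. = FALSE)
  present <- grepl("^cell_[0-9]+$", names(df))
  if (sum(present) != N_CELLS || !all(cell_cols %in% names(df)))
    stop("read_recording: integrity error in ", path, ": expected ",
         N_CELLS, " pressure columns cell_01..cell_18, found ",
         sum(present), call. = FALSE)
  if (is.null(foot_side)) {
    if ("foot" %in% names(df)) foot_side <- as.character(df$foot[1])
    else stop("read_recording: foot_side not given and no foot column in ",
              path, call. = FALSE)
  }
  t <- df$time_s
  if (nrow(df) < 1L)
    stop("read_recording: integrity error in ", path, ": no frames",
         call. = FALSE)
  if (anyNA(t) || (length(t) > 1L && any(diff(t) <= 0)))
    stop("read_recording: integrity error in ", path,
         ": time_s must strictly increase", call. = FALSE)
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (length(t) > 1L) 1 / stats::median(diff(t)) else 110
  }
  raw_cols <- sprintf("raw_%02d", 1:N_CELLS)
  raw <- if (all(raw_cols %in% names(df)))
    as.matrix(df[raw_cols]) else NULL
  insole_recording(as.matrix(df[cell_cols]),
                   sample_rate_hz = sample_rate_hz,
                   foot_side = foot_side, raw_counts = raw,
                   start_time_s = t[1])
}

#' Write an insole recording to CSV
#'
#' Inverse of [read_recording()]; column order is deterministic
#' (`foot, time_s, cell_01..cell_18[, raw_01..raw_18]`).
#'
#' @param recording an [insole_recording()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  p <- recording$cell_pressures
  colnames(p) <- sprintf("cell_%02d", 1:N_CELLS)
  df <- data.frame(foot = recording$foot_side,
                   time_s = frame_times(recording),
                   p, check.names = FALSE)
  if (!is.null(recording$raw_counts)) {
    r <- recording$raw_counts
    colnames(r) <- sprintf("raw_%02d", 1:N_CELLS)
    df <- cbind(df, r)
  }
  ok <- try(utils::write.csv(df, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("write_recording: cannot write ", path, ": ",
         attr(ok, "condition")$message, call. = FALSE)
  invisible(path)
}

#' Format a report cell as "value (percent%)"
#'
#' Reliability tables print each absolute index next to its size relative
#' to the parameter mean. The percentage is computed from the *rounded*
#' value, which is how such tables are conventionally self-consistent: a
#' reader dividing the printed cells reproduces the printed percent.
#'
#' @param value absolute index (e.g. an SEM or MDD95), full precision.
#' @param mean parameter mean used as the percent denominator.
#' @param value_digits decimals for the value (default 2).
#' @param pct_digits decimals for the percent (default 2).
#' @return character scalar like `"0.86 (10.58%)"`.
#' @export
format_value_percent <- function(value, mean, value_digits = 2,
                                 pct_digits = 2) {
  v <- round(value, value_digits)
  pct <- round(100 * v / mean, pct_digits)
  sprintf("%s (%s%%)", format(v, trim = TRUE, scientific = FALSE),
          format(pct, trim = TRUE, scientific = FALSE))
}

#' Write a reliability report to CSV files
#'
#' Writes the four tables of a [reliability_report()] —
#' `summary`, `mdd`, `effect_sizes`, `es_census` — as
#' `<stem>_summary.csv` etc., plus a human-readable `<stem>_table.txt` in
#' which each parameter row carries the smallest and largest cell across
#' feet, the convention used for two-line cells in published reliability
#' tables.
#'
#' @param report a [reliability_report()].
#' @param stem output path stem (directory must exist).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "reliability_report"))
  files <- character(0)
  for (nm in c("summary", "mdd", "effect_sizes", "es_census")) {
    f <- paste0(stem, "_", nm, ".csv")
    ok <- try(utils::write.csv(report[[nm]], f, row.names = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("write_report: cannot write ", f, ": ",
           attr(ok, "condition")$message, call. = FALSE)
    files <- c(files, f)
  }
  txt <- paste0(stem, "_table.txt")
  writeLines(format_report_lines(report), txt)
  invisible(c(files, txt))
}

#' Read a reliability report back from CSV files
#' @param stem the path stem used in [write_report()].
#' @return a [reliability_report()].
#' @export
read_report <- function(stem) {
  parts <- lapply(c("summary", "mdd", "effect_sizes", "es_census"),
                  function(nm) {
                    f <- paste0(stem, "_", nm, ".csv")
                    if (!file.exists(f))
                      stop("read_report: missing ", f, call. = FALSE)
                    utils::read.csv(f, stringsAsFactors = FALSE)
                  })
  names(parts) <- c("summary", "mdd", "effect_sizes", "es_census")
  reliability_report(parts$summary, parts$mdd, parts$effect_sizes,
                     parts$es_census)
}

# Pretty two-line-per-parameter text rendering of the summary table:
# first line the smallest cell across feet, second line the largest.
format_report_lines <- function(report) {
  s <- report$summary
  out <- character(0)
  for (cond in unique(s$condition)) {
    out <- c(out, sprintf("== %s ==", cond))
    sc <- s[s$condition == cond, , drop = FALSE]
    for (p in unique(sc$parameter)) {
      sp <- sc[sc$parameter == p, , drop = FALSE]
      lo <- sp[which.min(sp$sem), ]
      hi <- sp[which.max(sp$sem), ]
      for (row in list(lo, hi)) {
        out <- c(out, sprintf(
          "%-18s mean %.2f (sd %.2f)  SEM %s  MDD95 %s  ICC %.3f [%s]",
          p, row$mean, row$sd,
          format_value_percent(row$sem, row$mean),
          format_value_percent(row$mdd95, row$mean),
          row$icc_3k, row$icc_label))
      }
    }
  }
  out
}

#' Write per-cycle gait parameters to CSV
#' @param params data frame from [extract_cycle_parameters()] (or one foot's
#'   table with a `foot` column).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cycle_parameters <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' Read per-cycle gait parameters from CSV
#' @param path file written by [write_cycle_parameters()].
#' @return data frame with one row per foot x cycle.
#' @export
read_cycle_parameters <- function(path) {
  if (!file.exists(path))
    stop("read_cycle_parameters: no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a pipeline / detection configuration file
#'
#' Accepts YAML or JSON (decided by extension). The file may set any of the
#' arguments of [detection_thresholds()], [simulation_config()] and
#' [run_pipeline()]; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param known character vector of permitted keys; `NULL` skips the check.
#' @return named list.
#' @export
read_config <- function(path, known = NULL) {
  if (!file.exists(path))
    stop("read_config: no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(known)) {
    bad <- setdiff(names(cfg), known)
    if (length(bad))
      stop("read_config: unknown keys in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}
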