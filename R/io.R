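#' Read and write volume-series CSV files
#'
#' The volume-series dialect has a required header `time_days,volume_cm3`
#' and one row per measurement. Reading validates the series (numeric
#' cells, positive volumes, non-decreasing times) with a distinct message
#' per failure mode; a written series reads back equal up to float
#' formatting.
#'
#' @param path Path to a CSV file.
#' @return `read_volume_series()`: a validated volume-series tibble.
#' @export
read_volume_series <- function(path) {
  df <- read_checked_csv(path, c("time_days", "volume_cm3"))
  bad <- which(df$volume_cm3 <= 0)
  if (length(bad)) {
    abort(paste0("non-positive volume in ", path, " at data row ",
                 bad[1], " (", df$volume_cm3[bad[1]], " cm^3)."))
  }
  if (is.unsorted(df$time_days)) {
    abort(paste0("times in ", path, " must be non-decreasing."))
  }
  df
}

#' @rdname read_volume_series
#' @param series A volume-series data frame (`time_days`, `volume_cm3`).
#' @return `write_volume_series()`: the input, invisibly.
#' @export
write_volume_series <- function(series, path) {
  series <- check_volume_series(series)
  readr::write_csv(series, path)
  invisible(series)
}

#' Read and write fractionation-schedule CSV files
#'
#' Header `time_days,dose_gy`, one row per fraction; validated with
#' [validate_schedule()] (positive doses, strictly increasing times).
#'
#' @param path Path to a CSV file.
#' @return `read_schedule()`: a validated schedule tibble.
#' @export
read_schedule <- function(path) {
  validate_schedule(read_checked_csv(path, c("time_days", "dose_gy")))
}

#' @rdname read_schedule
#' @param schedule A schedule data frame.
#' @return `write_schedule()`: the input, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- validate_schedule(schedule)
  readr::write_csv(schedule, path)
  invisible(schedule)
}

read_checked_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e)))
  )
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  df <- df[required_cols]
  for (col in required_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) || anyNA(df[[col]])) {
      row <- if (length(bad)) bad[1] else which(is.na(df[[col]]))[1]
      abort(paste0("non-numeric or missing value in column `", col,
                   "` of ", path, " at data row ", row, "."))
    }
    df[[col]] <- vals
  }
  tibble::as_tibble(df)
}

#' Default run configuration
#'
#' All tunables of the simulate/fit/synth/compare workflows with their
#' documented defaults. An empty config file is valid; file values override
#' these defaults and command-line flags override the file. The effective
#' config is echoed into every output record for provenance.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    alpha = 0.35,                 # /Gy
    beta = 0.035,                 # /Gy^2 (alpha/beta = 10 Gy)
    corr_a = 1,                   # simulation default: conventional model
    corr_b = 0,
    t_pot = 5.5,                  # days (lung default; cervix: 4.5)
    t_half = 40,                  # days
    v0 = 80,                      # cm^3
    corr_a_bounds = c(0.01, 3),
    corr_b_bounds = c(-5, 1),
    grid_n = 21,
    n_starts = 5,
    residual_space = "absolute",  # or "relative"
    v0_range = c(7.6, 375.2),     # cm^3, synthetic cohort draw
    t_half_range = c(13.9, 90.6), # days
    corr_a_range = c(0.15, 0.9),
    corr_b_range = c(-3, -0.4),
    n_fractions = 25,
    dose_gy = 2,
    fractions_per_week = 5,
    sample_times = c(0, 14, 28, 42),
    noise_cv = 0.05,
    log_level = "info",
    seed = 1
  )
}

#' Read a run configuration file
#'
#' Reads a flat-key YAML config and merges it over [default_config()].
#' Unknown keys are an error (typo protection); an empty or absent file
#' yields the defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return The effective configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) {
    abort(paste0("config file ", path, " must contain a key: value mapping."))
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config key(s) in ", path, ": ",
                 paste(unknown, collapse = ", "), "."))
  }
  for (k in names(user)) cfg[[k]] <- unlist(user[[k]], use.names = FALSE)
  cfg
}

#' Write a fit record as JSON
#'
#' Serializes a fit (or model comparison) together with the effective
#' configuration and the package version, so every artifact is
#' self-describing.
#'
#' @param fit A `radvol_fit` or `radvol_comparison` object.
#' @param path Output JSON path.
#' @param config The effective configuration list to echo.
#' @return The record list, invisibly.
#' @export
write_fit_record <- function(fit, path, config = default_config()) {
  cmp <- inherits(fit, "radvol_comparison")
  f <- if (cmp) fit$fit else fit
  stopifnot(inherits(f, "radvol_fit"))
  record <- list(
    package = "radvol",
    version = as.character(packageVersion("radvol")),
    corr_a_hat = f$corr_a_hat,
    corr_b_hat = f$corr_b_hat,
    r_squared = f$r_squared,
    r0_squared = if (cmp) fit$r0_squared else NULL,
    objective = f$objective,
    converged = f$converged,
    n_starts_used = f$n_starts_used,
    residual_space = f$residual_space,
    corr_a_bounds = f$corr_a_bounds,
    corr_b_bounds = f$corr_b_bounds,
    residuals = f$residuals,
    config = config
  )
  record <- record[!vapply(record, is.null, logical(1))]
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(record)
}
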