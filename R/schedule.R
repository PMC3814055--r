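#' Expand a shorthand fractionation regimen into an explicit schedule
#'
#' Builds a tibble of dose fractions for a conventional weekday regimen:
#' `fractions_per_week` consecutive daily fractions followed by a weekend
#' gap, repeated until `n_fractions` have been delivered. The default is
#' the conventional course of 2 Gy per fraction, 5 fractions per week,
#' 25 fractions (50 Gy total over 5 weeks).
#'
#' @param n_fractions Total number of fractions, >= 1.
#' @param dose_gy Dose per fraction in Gy, > 0 (scalar, recycled).
#' @param fractions_per_week Treatment days per 7-day week, 1..7.
#' @param start_day Day of the first fraction on the volume-series time
#'   axis (day 0 = first volume measurement).
#' @return A schedule tibble with columns `time_days` (strictly
#'   increasing) and `dose_gy`.
#' @examples
#' regimen_schedule(10)             # two treatment weeks
#' regimen_schedule(3, dose_gy = 8) # hypofractionated
#' @export
regimen_schedule <- function(n_fractions = 25, dose_gy = 2,
                             fractions_per_week = 5, start_day = 0) {
  stopifnot(is.numeric(n_fractions), length(n_fractions) == 1, n_fractions >= 1,
            is.numeric(fractions_per_week), length(fractions_per_week) == 1)
  n_fractions <- as.integer(n_fractions)
  if (fractions_per_week < 1 || fractions_per_week > 7) {
    abort("`fractions_per_week` must be between 1 and 7.")
  }
  fractions_per_week <- as.integer(fractions_per_week)
  i <- seq_len(n_fractions) - 1L
  times <- start_day + 7 * (i %/% fractions_per_week) + i %% fractions_per_week
  validate_schedule(tibble::tibble(time_days = as.numeric(times),
                                   dose_gy = as.numeric(dose_gy) + 0 * times))
}

#' Two-dose-level probe schedule for parameter identifiability
#'
#' With a uniform-dose schedule the correction factors are structurally
#' confounded: the volume trajectory depends on (A, B) only through the
#' single per-fraction survival \eqn{S = e^{-A N(d) + B}}, so every pair on
#' the line \eqn{-A N(d) + B = \log S} fits a uniform course equally well.
#' Separating A from B requires at least two distinct dose levels, and the
#' second level must arrive while the viable pool still carries appreciable
#' mass (late fractions act on an already-depleted pool and leave
#' numerically invisible signatures). This designed two-fraction probe — a
#' moderate dose at day 0 and a high dose ten days later — keeps both
#' survival levels observable and makes (A, B) jointly identifiable from a
#' four-point volume series. It is the design used by the package's
#' parameter-recovery studies.
#'
#' @param doses Length-2 dose vector in Gy, low then high.
#' @param times Length-2 fraction times in days.
#' @return A schedule tibble (`time_days`, `dose_gy`).
#' @examples
#' probe_schedule()
#' @export
probe_schedule <- function(doses = c(2, 8), times = c(0, 10)) {
  stopifnot(length(doses) == 2, length(times) == 2)
  validate_schedule(tibble::tibble(time_days = as.numeric(times),
                                   dose_gy = as.numeric(doses)))
}

#' Validate a fractionation schedule
#'
#' Checks that a data frame has numeric `time_days` and `dose_gy` columns,
#' all doses positive, all times non-negative and strictly increasing
#' (zero inter-fraction interval is not allowed).
#'
#' @param schedule A data frame with columns `time_days`, `dose_gy`.
#' @return The schedule as a tibble, invisibly validated.
#' @export
validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule)) {
    abort("`schedule` must be a data frame.")
  }
  missing_cols <- setdiff(c("time_days", "dose_gy"), names(schedule))
  if (length(missing_cols)) {
    abort(paste0("schedule is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  schedule <- tibble::as_tibble(schedule)[c("time_days", "dose_gy")]
  if (!is.numeric(schedule$time_days) || !is.numeric(schedule$dose_gy) ||
      any(!is.finite(schedule$time_days)) || any(!is.finite(schedule$dose_gy))) {
    abort("schedule columns `time_days` and `dose_gy` must be finite numerics.")
  }
  if (any(schedule$dose_gy <= 0)) {
    abort("all fraction doses must be > 0 Gy.")
  }
  if (any(schedule$time_days < 0)) {
    abort("fraction times must be >= 0 days.")
  }
  if (nrow(schedule) > 1 && any(diff(schedule$time_days) <= 0)) {
    abort("fraction times must be strictly increasing.")
  }
  schedule
}
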