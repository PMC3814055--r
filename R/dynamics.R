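#' Construct a two-compartment cell state
#'
#' The population state carries relative counts of viable (`n_viable`) and
#' lethally damaged (`n_dead`) cells. Counts are dimensionless: the
#' absolute cell number and the per-cell volume constant are unidentifiable
#' from volume data, so states are normalized with initial total 1 and
#' volume recovered as `total * v0`.
#'
#' @param n_viable Relative viable cell count(s), >= 0.
#' @param n_dead Relative lethally damaged cell count(s), >= 0.
#' @return A tibble with columns `n_viable`, `n_dead` (one row per state).
#' @examples
#' cell_state() # all-viable baseline
#' @export
cell_state <- function(n_viable = 1, n_dead = 0) {
  if (!is.numeric(n_viable) || !is.numeric(n_dead) ||
      any(!is.finite(n_viable)) || any(!is.finite(n_dead))) {
    abort("cell counts must be finite numerics.")
  }
  if (any(n_viable < 0) || any(n_dead < 0)) {
    abort("cell counts must be non-negative.")
  }
  tibble::tibble(n_viable = n_viable, n_dead = n_dead)
}

check_state <- function(state) {
  if (!is.data.frame(state) ||
      !all(c("n_viable", "n_dead") %in% names(state))) {
    abort("`state` must be a data frame with columns `n_viable`, `n_dead`.")
  }
  state
}

#' Apply one dose fraction to a cell state
#'
#' Instantaneous kill bookkeeping: the viable pool is multiplied by the
#' surviving fraction `s` and its killed complement `(1 - s) * n_viable`
#' moves into the lethally damaged pool, so the total count is exactly
#' conserved at the instant of irradiation.
#'
#' @param state A cell-state data frame (see [cell_state()]); vectorized
#'   over rows.
#' @param s Surviving fraction, > 0 (scalar or one per row).
#' @return The post-fraction state tibble.
#' @examples
#' cell_state(100, 0) |> apply_fraction(s = 0.2)
#' @export
apply_fraction <- function(state, s) {
  state <- check_state(state)
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0)) {
    abort("surviving fraction `s` must be > 0 and finite.")
  }
  tibble::tibble(
    n_viable = state$n_viable * s,
    n_dead = state$n_dead + state$n_viable * (1 - s)
  )
}

#' Evolve a cell state over an inter-fraction interval
#'
#' Between fractions the viable pool regrows exponentially,
#' \eqn{N_l \exp(\lambda \Delta t)}, and the damaged pool clears,
#' \eqn{N_d \exp(-\mu \Delta t)}.
#'
#' @inheritParams apply_fraction
#' @param kinetics A [kinetic_params()] object.
#' @param dt Interval length in days, >= 0 (scalar or one per row).
#' @return The evolved state tibble.
#' @examples
#' cell_state(1, 1) |> evolve_interval(kinetic_params(5.5, 10), dt = 5.5)
#' @export
evolve_interval <- function(state, kinetics, dt) {
  state <- check_state(state)
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (!is.numeric(dt) || any(!is.finite(dt)) || any(dt < 0)) {
    abort("`dt` must be >= 0 and finite (days).")
  }
  tibble::tibble(
    n_viable = state$n_viable * exp(kinetics$lambda * dt),
    n_dead = state$n_dead * exp(-kinetics$mu * dt)
  )
}

# Core event-driven engine on bare numerics. `eval_times` must be sorted
# ascending; a fraction coinciding with an evaluation time is applied first
# ("post-fraction" reporting convention). Returns viable/dead counts
# relative to an all-viable unit state at t = 0.
sim_states <- function(eval_times, frac_times, frac_surv, lambda, mu) {
  nv <- 1; nd <- 0; t_cur <- 0
  n_ev <- length(eval_times)
  out_v <- numeric(n_ev); out_d <- numeric(n_ev)
  k <- 1L; n_fr <- length(frac_times)
  for (i in seq_len(n_ev)) {
    t_target <- eval_times[i]
    while (k <= n_fr && frac_times[k] <= t_target) {
      dt <- frac_times[k] - t_cur
      nv <- nv * exp(lambda * dt)
      nd <- nd * exp(-mu * dt)
      s <- frac_surv[k]
      nd <- nd + nv * (1 - s)
      nv <- nv * s
      t_cur <- frac_times[k]
      k <- k + 1L
    }
    dt <- t_target - t_cur
    nv <- nv * exp(lambda * dt)
    nd <- nd * exp(-mu * dt)
    t_cur <- t_target
    out_v[i] <- nv
    out_d[i] <- nd
  }
  list(viable = out_v, dead = out_d)
}

#' Simulate tumor volume over a fractionated course
#'
#' Forward-simulates the two-compartment population model under a
#' fractionation schedule and returns the tumor volume at each requested
#' time. The state starts all-viable at `t = 0` (the time of the first
#' volume measurement) with total count normalized to 1, alternates
#' instantaneous fraction kills ([apply_fraction()]) with exponential
#' inter-event evolution ([evolve_interval()]), and maps back to volume as
#' `v0 * (n_viable + n_dead)`. Evaluation at an arbitrary time applies a
#' partial-interval evolution from the most recent event; when an
#' evaluation time coincides with a fraction time the fraction is applied
#' first, so the reported volume is post-fraction. After the final
#' fraction, viable regrowth at rate \eqn{\lambda} continues indefinitely.
#'
#' All times are in days on the same axis as the schedule; the time units
#' of schedule and evaluation times cannot be cross-checked and must agree.
#'
#' @param schedule A schedule data frame (`time_days`, `dose_gy`); may have
#'   zero rows for untreated growth.
#' @param eval_times Numeric vector of evaluation times in days, >= 0,
#'   sorted ascending.
#' @param v0 Initial tumor volume in cm^3 (> 0), the volume scale.
#' @param radio An [lq_params()] object (alpha, beta, corr_a, corr_b).
#' @param kinetics A [kinetic_params()] object.
#' @return A tibble with columns `time_days`, `volume_cm3`, `n_viable`,
#'   `n_dead` (relative counts).
#' @examples
#' regimen_schedule(25) |>
#'   simulate_course(eval_times = c(0, 14, 28, 42), v0 = 80,
#'                   radio = lq_params(corr_a = 0.6, corr_b = -1.5),
#'                   kinetics = kinetic_params(5.5, 40.5))
#' @export
simulate_course <- function(schedule, eval_times, v0, radio, kinetics) {
  schedule <- validate_schedule(schedule)
  stopifnot(inherits(radio, "lq_params"), inherits(kinetics, "kinetic_params"))
  if (!is.numeric(v0) || length(v0) != 1 || !is.finite(v0) || v0 <= 0) {
    abort("`v0` must be a single positive volume in cm^3.")
  }
  if (!is.numeric(eval_times) || length(eval_times) < 1 ||
      any(!is.finite(eval_times))) {
    abort("`eval_times` must be a non-empty finite numeric vector (days).")
  }
  if (any(eval_times < 0)) {
    abort("evaluation times before the series origin (t = 0) are not allowed.")
  }
  if (is.unsorted(eval_times)) {
    abort("`eval_times` must be sorted ascending.")
  }
  surv <- survival_fraction(radio, schedule$dose_gy)
  st <- sim_states(eval_times, schedule$time_days, surv,
                   kinetics$lambda, kinetics$mu)
  tibble::tibble(
    time_days = eval_times,
    volume_cm3 = v0 * (st$viable + st$dead),
    n_viable = st$viable,
    n_dead = st$dead
  )
}
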