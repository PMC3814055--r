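#' Specify a synthetic patient
#'
#' A synthetic patient couples ground-truth correction factors and kinetic
#' parameters with a fractionation schedule and a sampling design, so the
#' fitting surface can be exercised with known truth. Defaults emulate the
#' clinical validation setting: initial volumes and halving times spanning
#' the reported nine-patient ranges, a conventional 2 Gy x 25 fraction
#' course with weekend gaps, and 4 volume measurements at 14-day intervals
#' (baseline CT on day 0, follow-ups every two weeks).
#'
#' Measurement noise is multiplicative lognormal with median 1 and the
#' given coefficient of variation: contouring error on CT scales with the
#' volume being contoured.
#'
#' @param v0 Initial tumor volume, cm^3.
#' @param t_half Volume halving time, days.
#' @param t_pot Potential doubling time, days (5.5 lung, 4.5 cervix).
#' @param corr_a,corr_b Ground-truth correction factors.
#' @param alpha,beta Assumed LQ coefficients used by the forward model.
#' @param schedule Fractionation schedule data frame.
#' @param sample_times Measurement times in days, >= 0 and sorted.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   >= 0.
#' @param seed Optional integer seed; fixed seed gives reproducible noise.
#' @return An object of class `synthetic_patient` (a named list).
#' @export
synthetic_patient <- function(v0 = 80, t_half = 40, t_pot = 5.5,
                              corr_a = 0.6, corr_b = -1.5,
                              alpha = 0.35, beta = 0.035,
                              schedule = regimen_schedule(),
                              sample_times = c(0, 14, 28, 42),
                              noise_cv = 0.05, seed = NULL) {
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0) {
    abort("`noise_cv` must be a single number >= 0.")
  }
  if (any(sample_times < 0)) {
    abort("sample times before the series origin (t = 0) are not allowed.")
  }
  if (is.unsorted(sample_times)) {
    abort("`sample_times` must be sorted ascending.")
  }
  structure(
    list(v0 = v0, t_half = t_half, t_pot = t_pot,
         corr_a = corr_a, corr_b = corr_b, alpha = alpha, beta = beta,
         schedule = validate_schedule(schedule),
         sample_times = sample_times, noise_cv = noise_cv, seed = seed),
    class = "synthetic_patient"
  )
}

with_patient_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a noiseless and a noisy volume trajectory for one patient
#'
#' The noiseless trajectory is the forward model evaluated at the sampling
#' times; the noisy trajectory multiplies each volume by an independent
#' lognormal factor with median 1 and coefficient of variation
#' `spec$noise_cv`. The noiseless series does not depend on the seed, and
#' identical seeds reproduce identical noisy series.
#'
#' @param spec A [synthetic_patient()] specification.
#' @return A tibble with columns `time_days`, `volume_true_cm3`
#'   (noiseless) and `volume_cm3` (noisy observation).
#' @examples
#' generate_trajectory(synthetic_patient(seed = 1))
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_patient"))
  radio <- lq_params(alpha = spec$alpha, beta = spec$beta,
                     corr_a = spec$corr_a, corr_b = spec$corr_b)
  kin <- kinetic_params(t_pot = spec$t_pot, t_half = spec$t_half)
  truth <- simulate_course(spec$schedule, spec$sample_times, spec$v0,
                           radio, kin)
  n <- nrow(truth)
  noise <- if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))  # median-1 lognormal with given CV
    with_patient_seed(spec$seed, exp(rnorm(n, mean = 0, sd = sdlog)))
  } else {
    rep(1, n)
  }
  tibble::tibble(
    time_days = truth$time_days,
    volume_true_cm3 = truth$volume_cm3,
    volume_cm3 = truth$volume_cm3 * noise
  )
}

cohort_t_pot <- c(lung = 5.5, cervix = 4.5)

#' Generate a synthetic patient cohort with known ground truth
#'
#' Draws `n` patients with initial volumes and halving times uniform over
#' the cohort ranges, ground-truth correction factors uniform over ranges
#' bracketing the reported clinical fits, the cohort's potential doubling
#' time (5.5 days lung, 4.5 days cervix) and the default conventional
#' regimen, then simulates each patient's noiseless and noisy trajectory.
#'
#' @param n Number of patients, >= 1.
#' @param cohort `"lung"` or `"cervix"`; length 1 or `n` (mixed cohorts).
#' @param seed Integer seed controlling both the parameter draws and the
#'   per-patient measurement noise.
#' @param v0_range,t_half_range Cohort ranges (cm^3, days) sampled
#'   uniformly; defaults span the reported nine-patient cohort.
#' @param corr_a_range,corr_b_range Ground-truth ranges for A and B.
#' @param noise_cv Measurement-noise coefficient of variation.
#' @param schedule Fractionation schedule shared by the cohort.
#' @param sample_times Measurement times in days.
#' @return A tibble with one row per patient: `patient`, `cohort`, the
#'   drawn parameters, per-patient `seed`, and a `trajectory` list-column
#'   of [generate_trajectory()] tibbles.
#' @examples
#' generate_cohort(3, cohort = "lung", seed = 42)
#' @export
generate_cohort <- function(n, cohort = "lung", seed = 1,
                            v0_range = c(7.6, 375.2),
                            t_half_range = c(13.9, 90.6),
                            corr_a_range = c(0.15, 0.9),
                            corr_b_range = c(-3, -0.4),
                            noise_cv = 0.05,
                            schedule = regimen_schedule(),
                            sample_times = c(0, 14, 28, 42)) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (!is.character(cohort) || !length(cohort) %in% c(1L, n) ||
      !all(cohort %in% names(cohort_t_pot))) {
    abort('`cohort` must be "lung" or "cervix" (length 1 or n).')
  }
  cohort <- rep_len(cohort, n)
  specs <- with_patient_seed(seed, {
    tibble::tibble(
      patient = seq_len(n),
      cohort = cohort,
      v0 = runif(n, v0_range[1], v0_range[2]),
      t_half = runif(n, t_half_range[1], t_half_range[2]),
      t_pot = unname(cohort_t_pot[cohort]),
      corr_a = runif(n, corr_a_range[1], corr_a_range[2]),
      corr_b = runif(n, corr_b_range[1], corr_b_range[2]),
      noise_cv = noise_cv,
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  specs$trajectory <- purrr::pmap(
    specs[c("v0", "t_half", "t_pot", "corr_a", "corr_b", "noise_cv", "seed")],
    function(v0, t_half, t_pot, corr_a, corr_b, noise_cv, seed) {
      generate_trajectory(synthetic_patient(
        v0 = v0, t_half = t_half, t_pot = t_pot,
        corr_a = corr_a, corr_b = corr_b,
        schedule = schedule, sample_times = sample_times,
        noise_cv = noise_cv, seed = seed
      ))
    }
  )
  specs
}
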