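#' Radiosensitivity parameters for the modified linear-quadratic model
#'
#' Bundles the linear and quadratic sensitivity coefficients
#' \eqn{\alpha} (per Gy) and \eqn{\beta} (per Gy\eqn{^2}) with the two
#' correction factors of the modified survival law
#' \eqn{S = \exp(-A(\alpha D + \beta D^2) + B)}. `corr_a` multiplies the
#' mean lethal-event count and must be positive; `corr_b` is an additive
#' offset on the log-survival scale and may take any sign (fitted values in
#' the clinical validation cohort are all negative).
#'
#' The defaults \eqn{\alpha = 0.35} Gy\eqn{^{-1}} and
#' \eqn{\alpha/\beta = 10} Gy (\eqn{\beta = 0.035} Gy\eqn{^{-2}}) are
#' standard literature values for tumors. Because `corr_a` multiplies
#' \eqn{\alpha D + \beta D^2}, it is only identifiable *relative to* the
#' assumed \eqn{\alpha, \beta}: a fitted \eqn{\hat A} means
#' \eqn{\hat A \alpha}, \eqn{\hat A \beta} jointly, and cannot be
#' interpreted without stating which \eqn{\alpha, \beta} were assumed.
#'
#' @param alpha Linear sensitivity coefficient, per Gy. Must be >= 0.
#' @param beta Quadratic sensitivity coefficient, per Gy^2. Must be >= 0;
#'   `alpha` and `beta` may not both be zero.
#' @param corr_a Multiplicative correction factor A (dimensionless, > 0).
#' @param corr_b Additive correction factor B (dimensionless, any sign).
#'
#' @return An object of class `lq_params`: a named list with the four
#'   components.
#' @examples
#' p <- lq_params()
#' survival_fraction(p, dose = 2)
#' @export
lq_params <- function(alpha = 0.35, beta = 0.035, corr_a = 1, corr_b = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(beta), length(beta) == 1, is.finite(beta),
            is.numeric(corr_a), length(corr_a) == 1, is.finite(corr_a),
            is.numeric(corr_b), length(corr_b) == 1, is.finite(corr_b))
  if (alpha < 0 || beta < 0) {
    abort("`alpha` and `beta` must both be non-negative.")
  }
  if (alpha == 0 && beta == 0) {
    abort("`alpha` and `beta` may not both be zero.")
  }
  if (corr_a <= 0) {
    abort("`corr_a` must be strictly positive.")
  }
  structure(
    list(alpha = alpha, beta = beta, corr_a = corr_a, corr_b = corr_b),
    class = "lq_params"
  )
}

#' @export
print.lq_params <- function(x, ...) {
  cat("<lq_params>  alpha =", x$alpha, "/Gy,  beta =", x$beta,
      "/Gy^2,  A =", x$corr_a, ",  B =", x$corr_b, "\n")
  invisible(x)
}

check_dose <- function(dose) {
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    abort("`dose` must be finite and numeric.")
  }
  if (any(dose < 0)) {
    abort("`dose` must be non-negative (Gy).")
  }
  dose
}

#' Mean number of lethal events for a given dose
#'
#' The linear-quadratic mean lethal-event count
#' \eqn{N = \alpha D + \beta D^2}. This is the *uncorrected* count: the
#' correction factors A and B act in [survival_fraction()], not here.
#'
#' @param params An [lq_params()] object (only `alpha` and `beta` are used).
#' @param dose Dose in Gy; scalar or vector, each element >= 0.
#' @return Dimensionless event count, same length as `dose`.
#' @examples
#' mean_lethal_events(lq_params(0.35, 0.035), dose = 2) # 0.84
#' @export
mean_lethal_events <- function(params, dose) {
  stopifnot(inherits(params, "lq_params"))
  dose <- check_dose(dose)
  params$alpha * dose + params$beta * dose^2
}

#' Surviving fraction under the modified linear-quadratic model
#'
#' Evaluates \eqn{S = \exp(-A(\alpha D + \beta D^2) + B)}. The result is
#' strictly positive and is *not* clamped to 1: combinations with
#' \eqn{B > 0} (or zero dose with \eqn{B \ge 0}) can yield \eqn{S > 1},
#' which is reported with a warning rather than hidden, so that a fitting
#' routine can see — and bound away — ill-posed parameter regions. The
#' exponent is formed in log space; underflow of \eqn{S} to zero at extreme
#' doses is allowed.
#'
#' @inheritParams mean_lethal_events
#' @return Surviving fraction(s), strictly positive (possibly > 1).
#' @examples
#' survival_fraction(lq_params(corr_a = 0.8, corr_b = -1), dose = 2)
#' @export
survival_fraction <- function(params, dose) {
  stopifnot(inherits(params, "lq_params"))
  dose <- check_dose(dose)
  log_s <- -params$corr_a * (params$alpha * dose + params$beta * dose^2) +
    params$corr_b
  s <- exp(log_s)
  if (any(s > 1)) {
    warn("survival fraction exceeds 1 for some doses (corr_b > effective kill); not clamped.")
  }
  s
}

#' Surviving fraction under the conventional linear-quadratic model
#'
#' The classical LQ survival curve \eqn{S = e^{-N} = e^{-(\alpha D + \beta D^2)}},
#' i.e. the modified model with \eqn{A = 1}, \eqn{B = 0}. Always in (0, 1].
#'
#' @param alpha Linear coefficient, per Gy.
#' @param beta Quadratic coefficient, per Gy^2.
#' @param dose Dose in Gy, >= 0 (vectorized).
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' conventional_survival(0.35, 0.035, 2)
#' @export
conventional_survival <- function(alpha, beta, dose) {
  p <- lq_params(alpha = alpha, beta = beta, corr_a = 1, corr_b = 0)
  dose <- check_dose(dose)
  exp(-(p$alpha * dose + p$beta * dose^2))
}
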