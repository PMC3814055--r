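# Shared fixtures and independent oracles, built in code.

lung_kinetics <- function(t_half = 40.5) kinetic_params(t_pot = 5.5, t_half = t_half)

# Closed-form state after the k-th fraction of a uniform schedule
# (k fractions of equal surviving fraction s, spacing dt, first at t = 0),
# derived independently of the event-driven recursion: the viable pool is
# s^k * exp(lambda (k-1) dt); each fraction j deposits (1 - s) times the
# then-viable pool s^(j-1) exp(lambda (j-1) dt) into the dead pool, which
# then decays for the remaining (k - j) intervals.
closed_form_uniform <- function(v0, k, s, dt, lambda, mu) {
  j <- seq_len(k)
  viable <- s^k * exp(lambda * (k - 1) * dt)
  dead <- sum((1 - s) * s^(j - 1) * exp(lambda * (j - 1) * dt) *
                exp(-mu * (k - j) * dt))
  v0 * (viable + dead)
}

# Designed identifiable recovery setting shared across fitting tests.
recovery_setting <- function() {
  list(schedule = probe_schedule(),
       kinetics = lung_kinetics(),
       sample_times = c(0, 14, 28, 42),
       v0 = 80)
}

noiseless_series <- function(corr_a, corr_b, setting = recovery_setting()) {
  simulate_course(setting$schedule, setting$sample_times, setting$v0,
                  lq_params(corr_a = corr_a, corr_b = corr_b),
                  setting$kinetics)[c("time_days", "volume_cm3")]
}
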