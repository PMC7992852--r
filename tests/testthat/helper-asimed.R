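# shared fixtures: small cohorts and specs that keep unit tests fast

quick_config <- function(n_int = c(A = 40, B = 55), n_con = c(A = 40, B = 30),
                         seed = 1, missing = FALSE, ...) {
  cohort_config(n_intervention = n_int, n_control = n_con,
                missingness = list(enabled = missing), seed = seed, ...)
}

quick_scored <- function(config = quick_config()) {
  d <- simulate_cohort(config)
  score_asi(d, compute_bounds(d))
}

quick_spec <- function(outcome = "dass_depression", boot = 50, ...) {
  mediation_spec(outcome, boot = boot, ...)
}

# a tiny deterministic behaviour profile covering all raw columns
toy_profile <- function(n = 1) {
  tibble::tibble(
    mvpa_sessions = rep(3, n), rt_days = rep(2, n),
    vigorous_fraction = rep(0.25, n), mvpa_minutes = rep(150, n),
    sitting_minutes = rep(480, n), daytime_sleepiness = rep(1, n),
    sleep_quality = rep(2, n), sleep_midpoint = rep(180, n),
    sleep_variability = rep(4, n), sleep_efficiency = rep(85, n),
    sleep_duration_hours = rep(7.5, n)
  )
}
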